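#' Correlate hotspot strengths between two libraries
#'
#' Correlation of NormHpM strengths over hotspots of a shared template.
#' Pairs where either side is zero (no corrected signal) are excluded and
#' counted.
#'
#' @param a,b `hotspot_table`s over the same template (joined on `hotspot`).
#' @param method `"pearson"` or `"spearman"`.
#' @return Tibble `(method, estimate, p.value, n, n_excluded)`.
#' @export
hotspot_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pairs <- dplyr::inner_join(
    dplyr::select(a, "hotspot", na = "norm_hpm"),
    dplyr::select(b, "hotspot", nb = "norm_hpm"), by = "hotspot")
  keep <- pairs$na > 0 & pairs$nb > 0
  n_exc <- sum(!keep)
  pairs <- pairs[keep, ]
  if (nrow(pairs) < 3) stop("fewer than 3 usable hotspot pairs")
  if (method == "pearson") {
    ct <- stats::cor.test(pairs$na, pairs$nb, method = "pearson")
    est <- unname(ct$estimate); p <- ct$p.value
  } else {
    sp <- spearman_cor(pairs$na, pairs$nb)
    est <- sp$estimate; p <- sp$p.value
  }
  tibble::tibble(method = method, estimate = est, p.value = p,
                 n = nrow(pairs), n_excluded = n_exc)
}

#' Per-hotspot log2 fold change of NormHpM
#'
#' `log2(NormHpM_a / NormHpM_b)` per shared hotspot. Hotspots with zero on
#' either side are flagged-excluded (`defined = FALSE`, value `NA`); no
#' pseudocount is applied.
#'
#' @param a,b `hotspot_table`s sharing a template.
#' @return Tibble `(hotspot, chrom, midpoint, norm_a, norm_b, log2fc,
#'   defined)`.
#' @export
log2_ratio_per_hotspot <- function(a, b) {
  pairs <- dplyr::inner_join(
    dplyr::select(a, "hotspot", "chrom", "start", "end", norm_a = "norm_hpm"),
    dplyr::select(b, "hotspot", norm_b = "norm_hpm"), by = "hotspot")
  pairs |>
    dplyr::mutate(
      midpoint = (.data$start + .data$end) / 2,
      defined = .data$norm_a > 0 & .data$norm_b > 0,
      log2fc = ifelse(.data$defined, log2(.data$norm_a / .data$norm_b), NA_real_)
    ) |>
    dplyr::select("hotspot", "chrom", "midpoint", "norm_a", "norm_b",
                  "log2fc", "defined")
}

# Degree-1 local regression with tricube weights over the nearest
# span-fraction of points, evaluated at x0. Closed-form weighted
# least-squares (normal equations).
local_linear <- function(x, y, x0, span) {
  n <- length(x)
  q <- max(2L, ceiling(span * n))
  vapply(x0, function(p) {
    d <- abs(x - p)
    dq <- sort(d)[min(q, n)]
    if (dq == 0) dq <- max(d[d > 0], 1)
    w <- (1 - pmin(d / dq, 1)^3)^3
    use <- w > 0
    if (sum(use) < 2 || stats::var(x[use]) == 0) {
      return(sum(w * y) / sum(w))
    }
    xx <- x[use] - p; yy <- y[use]; ww <- w[use]
    sw <- sum(ww); sx <- sum(ww * xx); sxx <- sum(ww * xx^2)
    sy <- sum(ww * yy); sxy <- sum(ww * xx * yy)
    det <- sw * sxx - sx^2
    if (det <= .Machine$double.eps * sw * sxx) return(sy / sw)
    (sxx * sy - sx * sxy) / det  # intercept at x = p
  }, numeric(1))
}

#' Smooth per-hotspot ratios along a chromosome
#'
#' Local linear regression (degree 1, tricube weights over the nearest
#' `span` fraction of points) of log2 fold changes against hotspot midpoint,
#' evaluated at each midpoint, per chromosome — highlighting spatial trends
#' in relative hotspot strength. Chromosomes with fewer than 5 defined points
#' are passed through unsmoothed and flagged.
#'
#' @param ratios Output of [log2_ratio_per_hotspot()].
#' @param span Fraction of points in each local fit, in (0, 1].
#' @return `ratios` with added columns `smoothed` and `smooth_ok`.
#' @export
smooth_ratio <- function(ratios, span = 0.4) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  ratios |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      ok <- df$defined
      if (sum(ok) < 5) {
        df$smoothed <- df$log2fc
        df$smooth_ok <- FALSE
      } else {
        df$smoothed <- NA_real_
        df$smoothed[ok] <- local_linear(df$midpoint[ok], df$log2fc[ok],
                                        df$midpoint[ok], span)
        df$smooth_ok <- TRUE
      }
      df
    }) |>
    dplyr::ungroup()
}

#' Bin per-hotspot ratios into centromere-anchored intervals
#'
#' Bin boundaries are anchored at the centromere: bin `k` covers
#' `[cen + bin * k, cen + bin * (k + 1))`, `k` negative left of the
#' centromere, clipped to the chromosome (terminal partial bins retained).
#' The bin value is `log2(sum NormHpM_a / sum NormHpM_b)` over hotspots whose
#' midpoint falls in the bin; bins where either side's sum is zero (or that
#' contain no hotspots) are flagged undefined.
#'
#' @param ratios Output of [log2_ratio_per_hotspot()].
#' @param chromosomes Tibble `(chrom, length, cen)`.
#' @param bin Bin width in bp (default 50 kb).
#' @return A `binned_ratio` tibble `(chrom, k, start, end, norm_a, norm_b,
#'   log2fc, n_hotspots, defined)` with chromosome size ranks as the
#'   `size_rank` attribute.
#' @export
bin_ratios_50kb <- function(ratios, chromosomes, bin = 50000) {
  chromosomes <- tibble::as_tibble(chromosomes)
  if (any(chromosomes$cen <= 0 | chromosomes$cen >= chromosomes$length)) {
    stop("centromere outside chromosome")
  }
  out <- purrr::pmap_dfr(chromosomes, function(chrom, length, cen, ...) {
    k <- seq(floor((1 - cen) / bin), floor((length - cen) / bin))
    grid <- tibble::tibble(
      chrom = chrom, k = k,
      start = pmax(cen + bin * k, 1),
      end = pmin(cen + bin * (k + 1) - 1, length)
    )
    r <- ratios[ratios$chrom == chrom, ]
    r$k <- floor((r$midpoint - cen) / bin)
    agg <- r |>
      dplyr::group_by(.data$k) |>
      dplyr::summarise(norm_a = sum(.data$norm_a), norm_b = sum(.data$norm_b),
                       n_hotspots = dplyr::n(), .groups = "drop")
    dplyr::left_join(grid, agg, by = "k") |>
      dplyr::mutate(
        norm_a = dplyr::coalesce(.data$norm_a, 0),
        norm_b = dplyr::coalesce(.data$norm_b, 0),
        n_hotspots = dplyr::coalesce(.data$n_hotspots, 0L),
        defined = .data$norm_a > 0 & .data$norm_b > 0,
        log2fc = ifelse(.data$defined, log2(.data$norm_a / .data$norm_b), NA_real_)
      )
  })
  rank_tbl <- chromosomes[order(-chromosomes$length), "chrom", drop = TRUE]
  structure(out, class = c("binned_ratio", class(out)), size_rank = rank_tbl,
            bin = bin)
}

#' Prepare an association-timing track
#'
#' Post-processes a per-position chromosomal association-time track (hours):
#' removes low-confidence points, smooths each chromosome with degree-1
#' tricube local regression at span `loess_numerator / n_points` (clamped to
#' (0, 1]), then segments into non-overlapping bins anchored at position 0,
#' taking the per-bin mean of the smoothed values.
#'
#' @param track Tibble `(chrom, pos, time, confidence)`; `confidence` is
#'   logical (or coercible) with `TRUE` = keep.
#' @param loess_numerator Numerator of the per-chromosome span (default 80,
#'   normalising smoothing for chromosome size).
#' @param bin Bin width in bp (default 50 kb).
#' @return A `timing_track` tibble `(chrom, start, end, time, n_points)`.
#' @export
prepare_timing_track <- function(track, loess_numerator = 80, bin = 50000) {
  track <- tibble::as_tibble(track)
  track <- track[as.logical(track$confidence), ]
  if (nrow(track) == 0) stop("no points left after confidence filtering")
  out <- track |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      span <- min(1, loess_numerator / nrow(df))
      df$sm <- if (nrow(df) >= 3) {
        local_linear(df$pos, df$time, df$pos, span)
      } else df$time
      df$bin_k <- floor((df$pos - 1) / bin)
      df |>
        dplyr::group_by(.data$bin_k) |>
        dplyr::summarise(time = mean(.data$sm), n_points = dplyr::n(),
                         .groups = "drop") |>
        dplyr::mutate(start = .data$bin_k * bin + 1,
                      end = (.data$bin_k + 1) * bin)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", "start", "end", "time", "n_points")
  structure(out, class = c("timing_track", class(out)), bin = bin)
}

#' Correlate binned fold changes with association timing
#'
#' Pairs each centromere-anchored ratio bin with the timing track by
#' overlap-weighted averaging of the position-anchored timing bins, then
#' reports the Spearman rank correlation of (association time, log2 fold
#' change). The raw sign convention is reported explicitly: a negative
#' coefficient means early-associating (small time) regions have the larger
#' fold change.
#'
#' @param binned A `binned_ratio`.
#' @param timing A `timing_track`.
#' @return Object of class `fc_timing_cor` with a [glance()] method: list
#'   with `estimate`, `p.value`, `n`, `sign_convention`, and the paired-bin
#'   tibble `pairs`.
#' @export
correlate_fc_with_timing <- function(binned, timing) {
  pairs <- binned[binned$defined, c("chrom", "start", "end", "log2fc")]
  pairs$time <- purrr::pmap_dbl(
    pairs[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      tb <- timing[timing$chrom == chrom, ]
      ov <- pmin(tb$end, end) - pmax(tb$start, start) + 1
      keep <- ov > 0
      if (!any(keep)) return(NA_real_)
      sum(tb$time[keep] * ov[keep]) / sum(ov[keep])
    })
  pairs <- pairs[!is.na(pairs$time), ]
  if (nrow(pairs) < 3) stop("fewer than 3 paired bins")
  sp <- spearman_cor(pairs$time, pairs$log2fc)
  structure(
    list(estimate = sp$estimate, p.value = sp$p.value, n = nrow(pairs),
         sign_convention = paste(
           "Spearman of (association time, log2FC);",
           "negative = early regions enriched in the numerator library"),
         pairs = pairs),
    class = "fc_timing_cor")
}

#' @export
print.fc_timing_cor <- function(x, ...) {
  cat(sprintf("<fc_timing_cor> Spearman R = %.3f, p = %.3g, n = %d bins\n",
              x$estimate, x$p.value, x$n))
  cat(" ", x$sign_convention, "\n")
  invisible(x)
}

#' @export
glance.fc_timing_cor <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, p.value = x$p.value, n = x$n)
}

# Spearman rho with large-sample t-approximation p (n >= 10) or exact
# permutation enumeration (n < 10).
spearman_cor <- function(x, y) {
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  if (n >= 10) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    perms <- all_permutations(n)
    rx <- rank(x)
    ry <- rank(y)
    rhos <- apply(perms, 1, function(ix) stats::cor(rx, ry[ix]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  list(estimate = rho, p.value = min(p, 1))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
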