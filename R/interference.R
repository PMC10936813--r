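#' Multicopy-probe correction
#'
#' When the probe used to detect double cuts hybridises to `copies` loci but
#' only one carries the assayed hotspot pair, only `1/copies` of the parental
#' lane signal derives from the locus; the measured DC fraction is therefore
#' multiplied by `copies` (the classic x3 correction for a triplicated
#' marker). Results are capped at 1; capped entries are flagged via the
#' `overflow` attribute and a warning.
#'
#' @param frequency Raw frequency (fraction of lane signal), in `[0, 1]`.
#'   Vectorised.
#' @param copies Integer >= 1 copy number of the probe target.
#' @return Corrected frequency, capped at 1, with logical attribute
#'   `overflow` marking capped entries.
#' @export
#' @examples
#' correct_multicopy(0.02, 3)  # 0.06
correct_multicopy <- function(frequency, copies) {
  if (any(copies < 1)) stop("copies must be >= 1")
  if (any(frequency < 0 | frequency > 1)) stop("frequency must be in [0, 1]")
  out <- frequency * copies
  over <- out > 1
  if (any(over)) {
    warning("corrected frequency exceeds 1; capped")
    out[over] <- 1
  }
  structure(out, overflow = over)
}

#' Occlusion correction for a distal hotspot
#'
#' A probe reading across a proximal hotspot underestimates a distal hotspot:
#' chromatids cut at both produce the double-cut fragment instead of the
#' distal single fragment. The corrected single-cut frequency is the measured
#' proximal-fragment frequency plus the double-cut frequency.
#'
#' @param proximal_fragment Measured (occluded) distal single frequency.
#' @param dc Double-cut frequency between the occluding and target hotspots.
#' @return Corrected single-cut frequency.
#' @export
correct_distal_single <- function(proximal_fragment, dc) {
  if (any(proximal_fragment < 0 | proximal_fragment > 1 | dc < 0 | dc > 1)) {
    stop("frequencies must be in [0, 1]")
  }
  proximal_fragment + dc
}

#' Average frequencies over timepoints
#'
#' Reduces technical variation by averaging each assay's frequency over the
#' requested timepoints (default 6 h and 8 h), per repeat. Repeats missing
#' one of the requested timepoints are averaged over what is present and
#' flagged (`complete = FALSE`), never silently dropped.
#'
#' @param table Cut-frequency tibble with columns `repeat_id`, `timepoint_h`,
#'   `assay`, `kind`, `frequency`.
#' @param timepoints Numeric vector of timepoints (hours) to average.
#' @return Tibble with one row per repeat x assay: `repeat_id`, `assay`,
#'   `kind`, `frequency` (mean), `n_timepoints`, `complete`.
#' @export
average_timepoints <- function(table, timepoints = c(6, 8)) {
  if (length(timepoints) == 0) stop("empty timepoint list")
  table |>
    dplyr::filter(.data$timepoint_h %in% timepoints) |>
    dplyr::group_by(.data$repeat_id, .data$assay, .data$kind) |>
    dplyr::summarise(
      frequency = mean(.data$frequency),
      n_timepoints = dplyr::n(),
      complete = dplyr::n() == length(timepoints),
      .groups = "drop"
    )
}

#' Expected double-cut frequency under independence
#'
#' The chance frequency of coincident cuts at two hotspots is the product of
#' their single-cut frequencies.
#'
#' @param f1,f2 Single-cut frequencies in `[0, 1]`.
#' @return `f1 * f2`.
#' @export
#' @examples
#' expected_dc(0.10, 0.05)  # 0.005
expected_dc <- function(f1, f2) {
  if (any(f1 < 0 | f1 > 1 | f2 < 0 | f2 > 1)) stop("frequencies must be in [0, 1]")
  f1 * f2
}

#' DSB interference from observed and expected double cuts
#'
#' Interference is `-log2(observed / expected)` (the negative log2 of the
#' coefficient of coincidence): positive values mean fewer coincident cuts
#' than chance (interference), values near zero independence, negative values
#' clustering. Because the ratio is unstable when both terms approach zero,
#' entries where either falls at or below `epsilon` are excluded explicitly
#' (flagged, value `NA`) rather than reported as +/-Inf.
#'
#' @param observed,expected Observed and expected DC frequencies (>= 0).
#'   Vectorised.
#' @param epsilon Exclusion threshold on both inputs (fraction units).
#' @return Tibble with columns `observed`, `expected`, `coc`, `interference`,
#'   `excluded`.
#' @export
#' @examples
#' interference(0.015, 0.005)  # -log2(3) ~ -1.585: clustering
interference <- function(observed, expected, epsilon = 1e-4) {
  if (any(observed < 0 | expected < 0)) stop("negative frequencies")
  excluded <- observed <= epsilon | expected <= epsilon
  coc <- ifelse(excluded, NA_real_, observed / expected)
  tibble::tibble(
    observed = observed, expected = expected, coc = coc,
    interference = -log2(coc), excluded = excluded
  )
}

#' Per-repeat interference from a cut-frequency table
#'
#' The full locus-level recipe: average the requested timepoints per repeat,
#' apply the multicopy correction to the DC assay (from its `copies` column
#' or the `dc_copies` argument), form expected DCs as the product of the two
#' single-cut frequencies, and return one interference value per repeat.
#'
#' @param table Cut-frequency tibble (`repeat_id`, `timepoint_h`, `assay`,
#'   `kind`, `frequency`, optional `copies`).
#' @param dc Assay id of the observed double cuts.
#' @param single1,single2 Assay ids of the two single-cut measurements.
#' @param timepoints Timepoints to average (default 6 and 8 h).
#' @param epsilon Near-zero exclusion threshold; see [interference()].
#' @param dc_copies Copy-number correction applied to the DC frequency
#'   (overrides the table's `copies` column if given).
#' @return Tibble with one row per repeat: `repeat_id`, `f1`, `f2`,
#'   `observed`, `expected`, `coc`, `interference`, `excluded`.
#' @export
dsb_interference <- function(table, dc, single1, single2,
                             timepoints = c(6, 8), epsilon = 1e-4,
                             dc_copies = NULL) {
  avg <- average_timepoints(table, timepoints)
  need <- c(dc, single1, single2)
  if (!all(need %in% avg$assay)) {
    stop("assays absent from table: ", paste(setdiff(need, avg$assay), collapse = ", "))
  }
  if (is.null(dc_copies)) {
    dc_copies <- if ("copies" %in% names(table)) {
      max(table$copies[table$assay == dc], 1)
    } else 1
  }
  wide <- avg |>
    dplyr::filter(.data$assay %in% need) |>
    dplyr::select("repeat_id", "assay", "frequency") |>
    tidyr::pivot_wider(names_from = "assay", values_from = "frequency")
  obs <- as.numeric(correct_multicopy(wide[[dc]], dc_copies))
  exp_dc <- expected_dc(wide[[single1]], wide[[single2]])
  res <- interference(obs, exp_dc, epsilon)
  tibble::tibble(repeat_id = wide$repeat_id,
                 f1 = wide[[single1]], f2 = wide[[single2]]) |>
    dplyr::bind_cols(res)
}

#' Aggregate per-repeat interference and compare two genotypes
#'
#' Aggregates each group's non-excluded per-repeat interference values
#' (mean, sample SD, n) and compares the groups with a pooled-variance
#' two-sample two-tailed t-test. Excluded repeats are reported, not imputed.
#' If the pooled variance is zero the test is degenerate and handled by a
#' documented rule: p = 1 when the means are equal, p = 0 otherwise, with
#' `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors of per-repeat interference values (NAs treated
#'   as excluded repeats), or tibbles from [dsb_interference()] (the
#'   `interference` column is used).
#' @param labels Group labels (length 2).
#' @return An object of class `interference_comparison` with [tidy()] and
#'   [glance()] methods: a list with `groups` (per-group mean/sd/n and count
#'   of excluded repeats) and `test` (t, df, p, degenerate flag).
#' @export
#' @examples
#' aggregate_and_compare(c(0.9, 1.1, 1.0), c(-0.1, 0.1, 0.0))
aggregate_and_compare <- function(a, b, labels = c("A", "B")) {
  pull_vals <- function(x) {
    if (is.data.frame(x)) x$interference else as.numeric(x)
  }
  va <- pull_vals(a); vb <- pull_vals(b)
  if (length(va) == 0 || length(vb) == 0) stop("empty group")
  na_exc <- c(sum(is.na(va)), sum(is.na(vb)))
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) == 0 || length(vb) == 0) stop("no non-excluded repeats in a group")
  groups <- tibble::tibble(
    group = labels,
    mean = c(mean(va), mean(vb)),
    sd = c(stats::sd(va), stats::sd(vb)),
    n = c(length(va), length(vb)),
    n_excluded = na_exc
  )
  test <- if (length(va) < 2 || length(vb) < 2) {
    tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = NA)
  } else {
    pooled <- ((length(va) - 1) * stats::var(va) + (length(vb) - 1) * stats::var(vb)) /
      (length(va) + length(vb) - 2)
    if (pooled == 0) {
      tibble::tibble(t = NA_real_, df = length(va) + length(vb) - 2,
                     p = as.numeric(mean(va) == mean(vb)), degenerate = TRUE)
    } else {
      tt <- stats::t.test(va, vb, var.equal = TRUE)
      tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value, degenerate = FALSE)
    }
  }
  structure(list(groups = groups, test = test, values = list(va, vb)),
            class = "interference_comparison")
}

#' @export
print.interference_comparison <- function(x, ...) {
  cat("<interference_comparison>\n")
  print(x$groups)
  cat(sprintf("pooled-variance two-tailed t-test: t = %s, df = %s, p = %s%s\n",
              format(x$test$t, digits = 3), format(x$test$df),
              format(x$test$p, digits = 3),
              if (isTRUE(x$test$degenerate)) " (degenerate: zero pooled variance)" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.interference_comparison <- function(x, ...) {
  x$groups
}

#' @export
glance.interference_comparison <- function(x, ...) {
  tibble::tibble(
    mean_a = x$groups$mean[1], mean_b = x$groups$mean[2],
    diff = x$groups$mean[1] - x$groups$mean[2],
    t = x$test$t, df = x$test$df, p.value = x$test$p,
    degenerate = x$test$degenerate
  )
}
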