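#' Pool FullMaps with equal library weighting
#'
#' Each library is first normalised to HpM, then the per-position unweighted
#' mean across libraries is taken (positions absent from a library contribute
#' zero). The pooled map's declared depth is set to one million reads so its
#' counts *are* HpM; pooling is therefore idempotent.
#'
#' @param maps List of `fullmap` objects sharing a chromosome namespace.
#' @return A pooled `fullmap` (counts in HpM units, split evenly between the
#'   Watson and Crick columns in proportion to the input strand totals).
#' @export
pool_fullmaps <- function(maps) {
  if (length(maps) < 1) stop("need at least one map")
  stopifnot(all(vapply(maps, inherits, logical(1), "fullmap")))
  k <- length(maps)
  per <- purrr::imap(maps, function(m, i) {
    tot <- fullmap_total(m)
    tibble::tibble(chrom = m$chrom, pos = m$pos,
                   watson = m$watson * 1e6 / tot / k,
                   crick = m$crick * 1e6 / tot / k)
  })
  pooled <- dplyr::bind_rows(per) |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(watson = sum(.data$watson), crick = sum(.data$crick),
                     .groups = "drop")
  as_fullmap(pooled, total_reads = 1e6, name = "pooled")
}

#' Hann window weights
#'
#' Raw weights `w_k = 0.5 * (1 - cos(2 * pi * k / (N - 1)))`, `k = 0..N-1`,
#' normalised to sum to 1. For the default 201 bp window the raw weights sum
#' to `(N - 1) / 2 = 100`, so a unit impulse smooths to a peak of 1/100.
#'
#' @param window Odd integer window size >= 3.
#' @return Numeric vector of length `window` summing to 1.
#' @export
hann_window <- function(window = 201) {
  if (window %% 2 == 0) stop("window must be odd")
  if (window < 3) stop("window must be >= 3")
  k <- seq_len(window) - 1
  w <- 0.5 * (1 - cos(2 * pi * k / (window - 1)))
  w / sum(w)
}

# Dense per-chromosome HpM vectors from a fullmap (strand-combined).
dense_hpm <- function(map, chrom_lengths = NULL) {
  tot <- fullmap_total(map)
  chroms <- unique(map$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) max(map$pos[map$chrom == ch]),
                            numeric(1))
  } else {
    chrom_lengths <- chrom_lengths[chroms]
  }
  purrr::map(stats::setNames(chroms, chroms), function(ch) {
    sub <- map[map$chrom == ch, ]
    v <- numeric(chrom_lengths[[ch]])
    v[sub$pos] <- (sub$watson + sub$crick) * 1e6 / tot
    v
  })
}

# Hann-smooth one dense vector; zero-padded ends so total mass is conserved
# on the padded domain. pad = TRUE returns the padded flanks too.
smooth_vector <- function(x, window, pad = FALSE) {
  w <- hann_window(window)
  half <- (window - 1) / 2
  padded <- c(numeric(2 * half), x, numeric(2 * half))
  sm <- as.numeric(stats::filter(padded, w, sides = 2))
  if (pad) sm[(half + 1):(3 * half + length(x))]
  else sm[(2 * half + 1):(2 * half + length(x))]
}

#' Hann-smooth a break map
#'
#' Smooths the strand-combined per-bp HpM signal with a normalised Hann
#' window (default 201 bp), treating missing positions as zero and
#' zero-padding chromosome ends. Total signal is conserved on the padded
#' domain (mass smoothed past a chromosome end is truncated from the
#' returned, unpadded profile).
#'
#' @param map A `fullmap`.
#' @param window Odd window size in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths; default
#'   is the last covered position per chromosome.
#' @param pad If `TRUE`, the half-window zero-padded flanks are included
#'   (positions below 1 and beyond the chromosome end), on which total
#'   signal is exactly conserved.
#' @return Tibble `(chrom, pos, hpm_smooth)`, dense over each chromosome.
#' @export
hann_smooth <- function(map, window = 201, chrom_lengths = NULL, pad = FALSE) {
  stopifnot(inherits(map, "fullmap"))
  dense <- dense_hpm(map, chrom_lengths)
  half <- (window - 1) / 2
  purrr::imap_dfr(dense, function(v, ch) {
    sm <- smooth_vector(v, window, pad = pad)
    tibble::tibble(chrom = ch,
                   pos = seq_along(sm) - if (pad) half else 0,
                   hpm_smooth = sm)
  })
}

# maximal runs of TRUE in a logical vector -> tibble(start, end)
runs_above <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

# merge intervals whose gap (next.start - prev.end - 1) is < merge_gap
merge_close <- function(iv, merge_gap) {
  if (nrow(iv) < 2) return(iv)
  iv <- iv[order(iv$start), ]
  out_start <- iv$start[1]; out_end <- iv$end[1]
  starts <- ends <- numeric(0)
  for (i in 2:nrow(iv)) {
    if (iv$start[i] - out_end - 1 < merge_gap) {
      out_end <- max(out_end, iv$end[i])
    } else {
      starts <- c(starts, out_start); ends <- c(ends, out_end)
      out_start <- iv$start[i]; out_end <- iv$end[i]
    }
  }
  tibble::tibble(start = c(starts, out_start), end = c(ends, out_end))
}

#' Call DSB hotspots from a smoothed break map
#'
#' The CC-seq hotspot-calling recipe: smooth the strand-combined HpM profile
#' with a Hann window, take maximal runs of positions at or above the HpM
#' cutoff, merge runs separated by less than `merge_gap` bp, then keep
#' intervals at least `min_len` bp long containing at least `min_reads` of
#' raw count mass. Thresholding precedes merging so that merged composites
#' are treated as single hotspots for the length/read filters.
#'
#' @param map A `fullmap` (raw counts, or HpM-scale counts for pooled maps;
#'   the count mass interpretation is recorded in the output attributes).
#' @param cutoff Smoothed-HpM cutoff (default 0.193; the lowered null-control
#'   value used when no hotspots call at the default is 0.125).
#' @param window Hann window size in bp.
#' @param min_len Minimum hotspot length in bp.
#' @param min_reads Minimum raw count mass within the interval.
#' @param merge_gap Intervals separated by fewer than this many bp are merged.
#' @param chrom_lengths Optional named chromosome lengths.
#' @return A `hotspot_template`: tibble `(hotspot, chrom, start, end)` with
#'   1-based inclusive coordinates, sorted and non-overlapping, with the
#'   calling parameters stored as attributes.
#' @export
call_hotspots <- function(map, cutoff = 0.193, window = 201, min_len = 25,
                          min_reads = 25, merge_gap = 200,
                          chrom_lengths = NULL) {
  stopifnot(inherits(map, "fullmap"))
  if (any(c(cutoff, min_len, min_reads, merge_gap) < 0)) {
    stop("negative thresholds")
  }
  dense <- dense_hpm(map, chrom_lengths)
  raw <- split(map, map$chrom)
  out <- purrr::imap_dfr(dense, function(v, ch) {
    sm <- smooth_vector(v, window)
    iv <- runs_above(sm >= cutoff)
    if (nrow(iv) == 0) return(tibble::tibble(chrom = character(),
                                             start = numeric(), end = numeric()))
    iv <- merge_close(iv, merge_gap)
    sub <- raw[[ch]]
    cnt <- numeric(length(v))
    cnt[sub$pos] <- sub$watson + sub$crick
    cs <- c(0, cumsum(cnt))
    mass <- cs[pmin(iv$end, length(v)) + 1] - cs[pmax(iv$start, 1)]
    keep <- (iv$end - iv$start + 1) >= min_len & mass >= min_reads
    tibble::tibble(chrom = ch, start = iv$start[keep], end = iv$end[keep])
  })
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out$hotspot <- if (nrow(out)) paste0("HS", sprintf("%04d", seq_len(nrow(out)))) else character()
  structure(dplyr::select(out, "hotspot", "chrom", "start", "end"),
            class = c("hotspot_template", "tbl_df", "tbl", "data.frame"),
            params = list(cutoff = cutoff, window = window, min_len = min_len,
                          min_reads = min_reads, merge_gap = merge_gap,
                          mass_unit = if (fullmap_total(map) == 1e6) "pooled HpM mass" else "raw reads"))
}

#' Construct a hotspot template from intervals
#'
#' Builds a `hotspot_template` (sorted, 1-based inclusive) from a data frame
#' of `chrom`, `start`, `end` (ids generated when absent) — for importing
#' externally defined hotspot catalogues.
#'
#' @param df Data frame with `chrom`, `start`, `end` and optionally
#'   `hotspot`.
#' @return A `hotspot_template`.
#' @export
hotspot_template <- function(df) as_hotspot_template(df)

as_hotspot_template <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"hotspot" %in% names(df)) {
    df$hotspot <- paste0("HS", sprintf("%04d", seq_len(nrow(df))))
  }
  structure(dplyr::arrange(df[, c("hotspot", "chrom", "start", "end")],
                           .data$chrom, .data$start),
            class = c("hotspot_template", "tbl_df", "tbl", "data.frame"))
}

#' Combine hotspot templates from several libraries
#'
#' Hotspots are called per library and then combined into a single template:
#' the union of intervals, with overlapping or abutting intervals merged.
#' Per-source presence flags (`in_<name>`) record which libraries contributed
#' to each combined hotspot.
#'
#' @param templates Named list of `hotspot_template` objects.
#' @return A combined `hotspot_template` with presence-flag columns.
#' @export
combine_templates <- function(templates) {
  if (length(templates) < 1) stop("need at least one template")
  if (is.null(names(templates))) names(templates) <- paste0("lib", seq_along(templates))
  all_iv <- purrr::imap_dfr(templates, function(t, nm) {
    tibble::tibble(chrom = t$chrom, start = t$start, end = t$end, source = nm)
  })
  merged <- all_iv |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$start), ]
      grp <- cumsum(c(1, df$start[-1] > cummax(df$end)[-nrow(df)] + 1))
      df |>
        dplyr::mutate(grp = grp) |>
        dplyr::group_by(.data$grp) |>
        dplyr::summarise(start = min(.data$start), end = max(.data$end),
                         sources = list(unique(.data$source)), .groups = "drop") |>
        dplyr::select(-"grp")
    }) |>
    dplyr::ungroup()
  for (nm in names(templates)) {
    merged[[paste0("in_", nm)]] <- purrr::map_lgl(merged$sources, ~ nm %in% .x)
  }
  merged$sources <- NULL
  out <- as_hotspot_template(merged)
  flag_cols <- paste0("in_", names(templates))
  merged2 <- dplyr::arrange(tibble::as_tibble(merged), .data$chrom, .data$start)
  for (fc in flag_cols) out[[fc]] <- merged2[[fc]]
  out
}

#' Estimate per-bp background from long ORFs
#'
#' Long ORFs are presumed free of genuine break signal, so the read density
#' inside them estimates the library's non-specific background. The estimate
#' is the total HpM within the `n_orfs` longest qualifying ORFs (length
#' strictly greater than `min_orf_len`) divided by their total length.
#'
#' @param map A `fullmap`.
#' @param orfs Tibble `(chrom, start, end)` of ORF intervals.
#' @param min_orf_len Minimum qualifying ORF length, bp.
#' @param n_orfs Number of longest qualifying ORFs to use; if fewer qualify,
#'   all are used with a warning.
#' @return Background HpM per bp (numeric scalar).
#' @export
estimate_background <- function(map, orfs, min_orf_len = 5500, n_orfs = 47) {
  stopifnot(inherits(map, "fullmap"))
  orfs <- tibble::as_tibble(orfs)
  orfs$len <- orfs$end - orfs$start + 1
  qual <- orfs[orfs$len > min_orf_len, ]
  if (nrow(qual) == 0) stop("no ORFs exceed the minimum length")
  if (nrow(qual) < n_orfs) {
    warning("only ", nrow(qual), " ORFs qualify; using all of them")
  } else {
    qual <- qual[order(-qual$len), ][seq_len(n_orfs), ]
  }
  hp <- fullmap_hpm(map)
  tot_hpm <- sum(purrr::pmap_dbl(qual, function(chrom, start, end, ...) {
    sum(hp$hpm[hp$chrom == chrom & hp$pos >= start & hp$pos <= end])
  }))
  tot_hpm / sum(qual$len)
}

#' Remove hotspots overlapping an excluded region
#'
#' Drops template hotspots with any overlap of the given region (e.g. the
#' repetitive rDNA array, where called intervals are artefactual); the count
#' of removals is reported via message and the `n_removed` attribute.
#'
#' @param template A `hotspot_template`.
#' @param region One-row data frame `(chrom, start, end)`.
#' @return Filtered template with attribute `n_removed`.
#' @export
exclude_region <- function(template, region) {
  region <- tibble::as_tibble(region)
  if (!all(c("chrom", "start", "end") %in% names(region)) ||
        any(region$end < region$start)) {
    stop("malformed region")
  }
  hit <- rep(FALSE, nrow(template))
  for (i in seq_len(nrow(region))) {
    hit <- hit | (template$chrom == region$chrom[i] &
                    template$start <= region$end[i] &
                    template$end >= region$start[i])
  }
  message(sum(hit), " hotspot(s) removed in excluded region")
  out <- template[!hit, ]
  attr(out, "n_removed") <- sum(hit)
  attr(out, "params") <- attr(template, "params")
  out
}

# Sum hp$hpm within each (sorted, non-overlapping) interval of iv.
interval_mass <- function(hp, iv) {
  out <- numeric(nrow(iv))
  for (ch in unique(iv$chrom)) {
    rows <- which(iv$chrom == ch)
    sub <- hp[hp$chrom == ch, ]
    if (!nrow(sub)) next
    o <- order(iv$start[rows])
    starts <- iv$start[rows][o]; ends <- iv$end[rows][o]
    idx <- findInterval(sub$pos, starts)
    ok <- idx >= 1 & sub$pos <= ends[pmax(idx, 1)]
    sums <- tapply(sub$hpm[ok], idx[ok], sum)
    res <- numeric(length(rows))
    res[as.integer(names(sums))] <- sums
    out[rows[o]] <- res
  }
  out
}

#' Hotspot strengths: HpM, background-corrected signal, NormHpM
#'
#' For each template hotspot the raw HpM mass is summed, the estimated
#' background (`background * length`) subtracted and floored at zero, and
#' the corrected signal expressed as a fraction of the total corrected signal
#' over all hotspots, scaled per million: `sum(NormHpM) == 1e6` exactly.
#'
#' @param map A `fullmap`.
#' @param template A `hotspot_template`.
#' @param background Background HpM per bp (from [estimate_background()]).
#' @return A `hotspot_table`: tibble `(hotspot, chrom, start, end, length,
#'   hpm, corrected, norm_hpm, floored)`.
#' @export
hotspot_strengths <- function(map, template, background = 0) {
  stopifnot(inherits(map, "fullmap"))
  if (background < 0) stop("background must be >= 0")
  if (nrow(template) == 0) stop("empty hotspot template")
  hp <- fullmap_hpm(map)
  hpm <- interval_mass(hp, template)
  len <- template$end - template$start + 1
  corrected <- hpm - background * len
  floored <- corrected < 0
  corrected[floored] <- 0
  if (sum(corrected) == 0) stop("all corrected hotspot signals are zero")
  out <- tibble::tibble(
    hotspot = template$hotspot, chrom = template$chrom,
    start = template$start, end = template$end, length = len,
    hpm = hpm, corrected = corrected,
    norm_hpm = corrected / sum(corrected) * 1e6,
    floored = floored
  )
  structure(out, class = c("hotspot_table", class(out)))
}

#' Overlap summary between two hotspot templates
#'
#' Counts hotspots unique to each template and those sharing at least one bp
#' with the other (the Venn-diagram comparison between hotspot catalogues).
#'
#' @param a,b `hotspot_template` (or `hotspot_table`) objects.
#' @param strengths_a,strengths_b Optional `hotspot_table`s supplying
#'   `norm_hpm` strength distributions per overlap class.
#' @return List with `counts` (n_a, n_b, a_only, b_only, shared_a, shared_b,
#'   shared_pairs) and `classes` (per-hotspot overlap flags, with strengths
#'   if provided).
#' @export
overlap_templates <- function(a, b, strengths_a = NULL, strengths_b = NULL) {
  ov_flag <- function(x, y) {
    vapply(seq_len(nrow(x)), function(i) {
      any(y$chrom == x$chrom[i] & y$start <= x$end[i] & y$end >= x$start[i])
    }, logical(1))
  }
  a_in_b <- ov_flag(a, b)
  b_in_a <- ov_flag(b, a)
  pairs <- sum(vapply(seq_len(nrow(a)), function(i) {
    sum(b$chrom == a$chrom[i] & b$start <= a$end[i] & b$end >= a$start[i])
  }, numeric(1)))
  classes <- dplyr::bind_rows(
    tibble::tibble(template = "a", hotspot = a$hotspot, shared = a_in_b),
    tibble::tibble(template = "b", hotspot = b$hotspot, shared = b_in_a)
  )
  if (!is.null(strengths_a)) {
    classes <- dplyr::left_join(
      classes,
      dplyr::bind_rows(
        tibble::tibble(template = "a", hotspot = strengths_a$hotspot,
                       norm_hpm = strengths_a$norm_hpm),
        if (!is.null(strengths_b)) {
          tibble::tibble(template = "b", hotspot = strengths_b$hotspot,
                         norm_hpm = strengths_b$norm_hpm)
        }),
      by = c("template", "hotspot"))
  }
  list(
    counts = tibble::tibble(
      n_a = nrow(a), n_b = nrow(b),
      a_only = sum(!a_in_b), b_only = sum(!b_in_a),
      shared_a = sum(a_in_b), shared_b = sum(b_in_a),
      shared_pairs = pairs
    ),
    classes = classes
  )
}
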