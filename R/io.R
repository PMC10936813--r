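#' Read a FullMap TSV
#'
#' Expects the tab-separated dialect with header `Chr Pos Watson Crick`,
#' 1-based positions, integer counts, sparse (zero rows omitted). Duplicate
#' `(Chr, Pos)` rows and malformed rows are rejected with the offending line
#' number. The library total is taken from a sidecar manifest
#' (`<path>.manifest.yaml`, written by [write_fullmap()]) when present,
#' otherwise computed from the counts.
#'
#' @param path Path to the TSV.
#' @param total_reads Optional explicit total mapped reads (overrides the
#'   manifest).
#' @return A `fullmap`.
#' @export
read_fullmap <- function(path, total_reads = NULL) {
  header <- readLines(path, n = 1)
  if (!identical(header, "Chr\tPos\tWatson\tCrick")) {
    stop("FullMap header must be 'Chr\tPos\tWatson\tCrick'")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    Chr = readr::col_character(), Pos = readr::col_double(),
    Watson = readr::col_double(), Crick = readr::col_double()
  ), progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob)) {
    stop("malformed FullMap row at line ", prob$row[1] + 1, " of ", path)
  }
  dup <- duplicated(df[, c("Chr", "Pos")])
  if (any(dup)) {
    stop("duplicated (Chr, Pos) row at line ", which(dup)[1] + 1, " of ", path)
  }
  manifest <- paste0(path, ".manifest.yaml")
  name <- basename(path)
  if (is.null(total_reads) && file.exists(manifest)) {
    m <- yaml::read_yaml(manifest)
    total_reads <- m$total_reads
    name <- m$name %||% name
  }
  as_fullmap(
    tibble::tibble(chrom = df$Chr, pos = df$Pos, watson = df$Watson,
                   crick = df$Crick),
    total_reads = total_reads, name = name)
}

#' Write a FullMap TSV (with sidecar manifest)
#'
#' @param map A `fullmap`.
#' @param path Output path; a `<path>.manifest.yaml` sidecar records the
#'   library name and total mapped reads.
#' @return `path`, invisibly.
#' @export
write_fullmap <- function(map, path) {
  stopifnot(inherits(map, "fullmap"))
  readr::write_tsv(
    tibble::tibble(Chr = map$chrom, Pos = map$pos, Watson = map$watson,
                   Crick = map$crick),
    path, progress = FALSE)
  yaml::write_yaml(list(name = attr(map, "name"),
                        total_reads = fullmap_total(map)),
                   paste0(path, ".manifest.yaml"))
  invisible(path)
}

#' Read / write cut-frequency tables
#'
#' TSV with header columns `repeat_id`, `timepoint_h`, `assay`, `kind`,
#' `frequency` and optional correction metadata (`copies`, `side`).
#'
#' @param path File path.
#' @return A cut-frequency tibble.
#' @export
read_cut_frequencies <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("repeat_id", "timepoint_h", "assay", "kind", "frequency")
  if (!all(need %in% names(df))) {
    stop("cut-frequency table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$frequency < 0 | df$frequency > 1)) {
    stop("frequencies must be fractions in [0, 1]")
  }
  df
}

#' @rdname read_cut_frequencies
#' @param table Cut-frequency tibble.
#' @export
write_cut_frequencies <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read / write hotspot tables
#'
#' @param path File path.
#' @return A `hotspot_table` (or `hotspot_template` if no strength columns).
#' @export
read_hotspot_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (all(c("hpm", "norm_hpm") %in% names(df))) {
    structure(df, class = c("hotspot_table", class(df)))
  } else {
    as_hotspot_template(df)
  }
}

#' @rdname read_hotspot_table
#' @param table A `hotspot_table` or `hotspot_template`.
#' @export
write_hotspot_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Export a hotspot template or table as BED
#'
#' Converts 1-based inclusive `[start, end]` to BED's 0-based half-open
#' `[start - 1, end)`. The score column is NormHpM scaled to 0-1000 when
#' strengths are available, 0 otherwise.
#'
#' @param x A `hotspot_template` or `hotspot_table` (sorted).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_bed <- function(x, path) {
  df <- tibble::as_tibble(x)
  if (nrow(df) > 1) {
    o <- order(df$chrom, df$start)
    if (!identical(o, seq_len(nrow(df)))) stop("unsorted template")
  }
  score <- if ("norm_hpm" %in% names(df) && nrow(df) && max(df$norm_hpm) > 0) {
    round(df$norm_hpm / max(df$norm_hpm) * 1000)
  } else rep(0L, nrow(df))
  bed <- tibble::tibble(
    chrom = df$chrom, start = df$start - 1, end = df$end,
    name = df$hotspot, score = score, strand = "."
  )
  readr::write_tsv(bed, path, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a BED file back into a hotspot template
#'
#' @param path BED path written by [export_bed()].
#' @return A `hotspot_template` (1-based inclusive coordinates).
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  as_hotspot_template(tibble::tibble(
    hotspot = df$name, chrom = df$chrom, start = df$start + 1, end = df$end))
}

#' Export a smoothed profile as bedGraph
#'
#' Adjacent positions with equal values are run-length collapsed; zero-value
#' runs are omitted.
#'
#' @param profile Tibble `(chrom, pos, value)` (e.g. [hann_smooth()] output,
#'   with its value column renamed or passed via `value_col`).
#' @param path Output path.
#' @param value_col Name of the value column.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(profile, path, value_col = "hpm_smooth") {
  df <- tibble::tibble(chrom = profile$chrom, pos = profile$pos,
                       value = profile[[value_col]])
  out <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$pos), ]
      new_run <- c(TRUE, d$value[-1] != d$value[-nrow(d)] |
                     d$pos[-1] != d$pos[-nrow(d)] + 1)
      grp <- cumsum(new_run)
      d |>
        dplyr::mutate(grp = grp) |>
        dplyr::group_by(.data$grp) |>
        dplyr::summarise(start = min(.data$pos) - 1, end = max(.data$pos),
                         value = .data$value[1], .groups = "drop") |>
        dplyr::select(-"grp")
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$value != 0)
  readr::write_tsv(out[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All tunable pipeline parameters with their standard defaults: the 201 bp
#' Hann window, 0.193 HpM calling cutoff (0.125 for the catalytically dead
#' null control), 25 bp / 25 read minima, <200 bp merge gap, 50 kb bins,
#' 80/N local-regression numerator, 47 ORFs > 5.5 kb for background
#' calibration, 6 and 8 h timepoint averaging and the 1e-4 near-zero
#' exclusion threshold.
#'
#' @return Nested named list; round-trips through [write_config()] /
#'   [read_config()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    layout = layout_config(),
    simulate = list(n_cells = 1000L, dt = 0.1, t_max = 10,
                    genotypes = list(
                      control = list(tel1 = TRUE, ndt80 = TRUE),
                      arrested = list(tel1 = TRUE, ndt80 = FALSE))),
    hotspots = list(cutoff = 0.193, null_cutoff = 0.125, window = 201L,
                    min_len = 25, min_reads = 25, merge_gap = 200,
                    min_orf_len = 5500, n_orfs = 47L),
    interference = list(timepoints = c(6, 8), epsilon = 1e-4),
    compare = list(bin = 50000, span = 0.4, loess_numerator = 80)
  )
}

#' Read / write a run configuration (YAML)
#'
#' @param path File path.
#' @return For `read_config()`, the configuration list merged over
#'   [default_config()].
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Pick the strongest multi-hotspot domain and define single/single/DC assays
# on its two strongest hotspots (the pipeline's default locus-level readout).
default_domain_assays <- function(layout) {
  hs <- layout$hotspots
  multi <- hs |>
    dplyr::group_by(.data$domain) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::ungroup()
  if (!nrow(multi)) return(NULL)
  best_dom <- multi |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(total = sum(.data$rate), .groups = "drop") |>
    dplyr::slice_max(.data$total, n = 1, with_ties = FALSE)
  pair <- multi |>
    dplyr::filter(.data$domain == best_dom$domain) |>
    dplyr::slice_max(.data$rate, n = 2, with_ties = FALSE) |>
    dplyr::arrange(.data$midpoint)
  dplyr::bind_rows(
    assay_table("s1", "single", pair$hotspot[1], side = "left"),
    assay_table("s2", "single", pair$hotspot[2], side = "right"),
    assay_table("dc", "dc", pair$hotspot[1], partner = pair$hotspot[2]))
}

#' Run the simulation-to-comparison pipeline
#'
#' Executes the selected stages against a configuration: build the layout and
#' simulate each configured genotype (writing FullMap and cut-frequency
#' TSVs); compute per-repeat interference at the strongest multi-hotspot
#' domain; call hotspots per genotype and combine templates, with NormHpM
#' strengths; and — when at least two genotypes are configured — per-hotspot
#' ratios, centromere-anchored 50 kb binned ratios and the correlation with
#' the layout's association-timing track. A YAML manifest records the seed,
#' parameters and realised primed fraction per domain.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "interference", "hotspots", "compare")`.
#' @return Named list of in-memory results, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         stages = c("simulate", "interference", "hotspots",
                                    "compare")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  layout <- build_layout(config$layout, seed = config$seed)
  res$layout <- layout

  if ("simulate" %in% stages) {
    assays <- default_domain_assays(layout)
    res$populations <- purrr::imap(config$simulate$genotypes, function(g, nm) {
      p <- sim_params(
        tel1 = isTRUE(g$tel1), ndt80 = isTRUE(g$ndt80),
        suppression = g$suppression %||% (if (isTRUE(g$tel1)) 0.8 else 0),
        n_cells = config$simulate$n_cells, dt = config$simulate$dt,
        t_max = config$simulate$t_max,
        background_rate = g$background_rate %||% 0,
        seed = config$seed)
      pop <- simulate_population(layout, p)
      map <- breaks_to_fullmap(pop)
      write_fullmap(map, file.path(out_dir, paste0(nm, ".fullmap.tsv")))
      freq <- if (!is.null(assays)) {
        tab <- breaks_to_assay(pop, assays, mode = "ideal")
        write_cut_frequencies(tab, file.path(out_dir, paste0(nm, ".frequencies.tsv")))
        tab
      }
      list(pop = pop, map = map, frequencies = freq)
    })
  }

  if ("interference" %in% stages && length(res$populations)) {
    res$interference <- purrr::imap_dfr(res$populations, function(x, nm) {
      if (is.null(x$frequencies)) return(tibble::tibble())
      tp <- unique(x$frequencies$timepoint_h)
      dsb_interference(x$frequencies, dc = "dc", single1 = "s1",
                       single2 = "s2", timepoints = tp,
                       epsilon = config$interference$epsilon) |>
        dplyr::mutate(genotype = nm, .before = 1)
    })
    if (nrow(res$interference)) {
      readr::write_tsv(res$interference,
                       file.path(out_dir, "interference.tsv"), progress = FALSE)
    }
  }

  if ("hotspots" %in% stages && length(res$populations)) {
    hcfg <- config$hotspots
    templates <- purrr::map(res$populations, function(x) {
      call_hotspots(x$map, cutoff = hcfg$cutoff, window = hcfg$window,
                    min_len = hcfg$min_len, min_reads = hcfg$min_reads,
                    merge_gap = hcfg$merge_gap)
    })
    template <- combine_templates(templates)
    res$template <- template
    res$strengths <- purrr::imap(res$populations, function(x, nm) {
      bg <- if (nrow(layout$orfs)) {
        suppressWarnings(estimate_background(x$map, layout$orfs,
                                             hcfg$min_orf_len, hcfg$n_orfs))
      } else 0
      st <- hotspot_strengths(x$map, template, bg)
      write_hotspot_table(st, file.path(out_dir, paste0(nm, ".hotspots.tsv")))
      st
    })
  }

  if ("compare" %in% stages && length(res$strengths) >= 2) {
    nms <- names(res$strengths)[1:2]
    ratios <- log2_ratio_per_hotspot(res$strengths[[nms[1]]],
                                     res$strengths[[nms[2]]])
    readr::write_tsv(ratios, file.path(out_dir, "hotspot_ratios.tsv"),
                     progress = FALSE)
    binned <- bin_ratios_50kb(ratios, layout$chromosomes,
                              bin = config$compare$bin)
    readr::write_tsv(tibble::as_tibble(binned),
                     file.path(out_dir, "binned_ratios.tsv"), progress = FALSE)
    res$ratios <- ratios
    res$binned <- binned
    timing_raw <- dplyr::left_join(
      layout$hotspots[, c("hotspot", "chrom", "midpoint", "domain")],
      layout$domains[, c("domain", "rec114_time")], by = "domain")
    timing <- prepare_timing_track(
      tibble::tibble(chrom = timing_raw$chrom, pos = timing_raw$midpoint,
                     time = timing_raw$rec114_time, confidence = TRUE),
      loess_numerator = config$compare$loess_numerator,
      bin = config$compare$bin)
    res$timing <- timing
    res$fc_timing <- tryCatch(correlate_fc_with_timing(binned, timing),
                              error = function(e) NULL)
  }

  manifest <- list(
    seed = config$seed,
    config = config,
    primed_fraction = if (length(res$populations)) {
      purrr::map(res$populations,
                 function(x) as.list(stats::setNames(
                   x$pop$primed_fraction$f_realised,
                   x$pop$primed_fraction$domain)))
    }
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(res)
}
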