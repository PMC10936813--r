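#' Create a FullMap from a data frame
#'
#' A FullMap is the per-base, strand-resolved break-count table produced by
#' covalent-complex sequencing: one row per position with Watson and Crick
#' counts, plus a declared library depth (total mapped reads) used to express
#' counts as hits per million mapped reads (HpM).
#'
#' @param x Data frame with columns `chrom`, `pos` (1-based), `watson`,
#'   `crick`. Positions must be unique within a chromosome; counts >= 0.
#' @param total_reads Total mapped reads of the library. Default: sum of all
#'   counts.
#' @param name Library name.
#' @return A tibble of class `fullmap` with attributes `total_reads`, `name`.
#' @export
as_fullmap <- function(x, total_reads = NULL, name = "library") {
  x <- tibble::as_tibble(x)[, c("chrom", "pos", "watson", "crick")]
  if (anyDuplicated(x[, c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) rows in FullMap")
  }
  if (any(x$watson < 0 | x$crick < 0)) stop("negative counts in FullMap")
  x <- dplyr::arrange(x, .data$chrom, .data$pos)
  if (is.null(total_reads)) total_reads <- sum(x$watson) + sum(x$crick)
  structure(x, class = c("fullmap", class(x)),
            total_reads = as.numeric(total_reads), name = name)
}

#' @export
print.fullmap <- function(x, ...) {
  cat("<fullmap> '", attr(x, "name"), "': ", nrow(x), " positions, ",
      format(attr(x, "total_reads"), big.mark = ","), " mapped reads\n", sep = "")
  NextMethod()
}

fullmap_total <- function(map) attr(map, "total_reads")

#' Add an HpM column to a FullMap
#'
#' `HpM(position) = (watson + crick) * 1e6 / total mapped reads`.
#'
#' @param map A `fullmap`.
#' @return The map with an added `hpm` column.
#' @export
fullmap_hpm <- function(map) {
  stopifnot(inherits(map, "fullmap"))
  tot <- fullmap_total(map)
  dplyr::mutate(tibble::as_tibble(map),
                hpm = (.data$watson + .data$crick) * 1e6 / tot)
}

#' Convert simulated breaks to a CC-seq-style FullMap
#'
#' Each cut contributes one Watson count at its position and one Crick count
#' at position + 1 (the two covalently bound break ends). Uniform background
#' reads are then added at rate `beta` (`params$background_rate`): the number
#' of background reads is Poisson with mean `beta * genome_bp * M / 1e6`
#' where `M` is the declared library depth (`params$total_reads`), so the
#' expected background HpM per bp equals `beta`. Background positions are
#' uniform over the genome with random strand.
#'
#' @param pop A `population_breaks`.
#' @param census Optional census time (hours); only cuts formed before
#'   `min(census, exit time)` are counted. Default: all cuts.
#' @return A `fullmap`.
#' @export
breaks_to_fullmap <- function(pop, census = NULL) {
  stopifnot(inherits(pop, "population_breaks"))
  params <- pop$params
  cuts <- pop$cuts
  if (!is.null(census)) {
    cuts <- dplyr::left_join(pop$cuts, pop$cells, by = "cell")
    cuts <- dplyr::filter(cuts, .data$time < pmin(census, .data$exit_time))
  }
  chroms <- pop$layout$chromosomes

  watson <- dplyr::count(cuts, .data$chrom, pos = .data$pos, name = "watson")
  crick <- dplyr::count(cuts, .data$chrom, pos = .data$pos + 1, name = "crick")

  beta <- params$background_rate
  if (beta > 0) {
    set.seed(cell_seed(params$seed, 999983))
    genome_bp <- sum(chroms$length)
    n_bg <- stats::rpois(1, beta * genome_bp * params$total_reads / 1e6)
    if (n_bg > 0) {
      g <- sort(ceiling(stats::runif(n_bg) * genome_bp))
      brk <- cumsum(chroms$length)
      ci <- findInterval(g - 1, brk) + 1L
      pos <- g - c(0, brk)[ci]
      strand_w <- stats::runif(n_bg) < 0.5
      bg <- tibble::tibble(chrom = chroms$chrom[ci], pos = pos, w = strand_w)
      watson <- dplyr::bind_rows(
        watson, dplyr::count(dplyr::filter(bg, .data$w), .data$chrom,
                             pos = .data$pos, name = "watson"))
      crick <- dplyr::bind_rows(
        crick, dplyr::count(dplyr::filter(bg, !.data$w), .data$chrom,
                            pos = .data$pos, name = "crick"))
      watson <- dplyr::summarise(dplyr::group_by(watson, .data$chrom, .data$pos),
                                 watson = sum(.data$watson), .groups = "drop")
      crick <- dplyr::summarise(dplyr::group_by(crick, .data$chrom, .data$pos),
                                crick = sum(.data$crick), .groups = "drop")
    }
  }

  out <- dplyr::full_join(watson, crick, by = c("chrom", "pos")) |>
    dplyr::mutate(watson = dplyr::coalesce(.data$watson, 0L),
                  crick = dplyr::coalesce(.data$crick, 0L)) |>
    dplyr::arrange(.data$chrom, .data$pos)
  as_fullmap(out, total_reads = params$total_reads, name = "simulated")
}

#' Define single-cut and double-cut assays
#'
#' @param assay Assay id.
#' @param kind `"single"` or `"dc"`.
#' @param hotspot Target hotspot (singles) or first hotspot of the pair (DCs).
#' @param partner Second hotspot of a DC pair (`NA` for singles).
#' @param side Probe side for blot-mode singles: `"left"` or `"right"` (the
#'   direction the probe reads from). `NA` for DCs.
#' @return A tibble usable as the `assays` argument of [breaks_to_assay()].
#' @export
assay_table <- function(assay, kind, hotspot, partner = NA_character_,
                        side = NA_character_) {
  tibble::tibble(assay = assay, kind = kind, hotspot = hotspot,
                 partner = partner, side = side)
}

#' Summarise simulated breaks into blot-style cut frequencies
#'
#' Produces the Southern-blot quantification surface: frequencies of single
#' cuts and inter-hotspot double cuts (DCs) as fractions of chromatids (the
#' analogue of fraction-of-lane signal). Two modes:
#'
#' * `ideal`: a single counts every chromatid cut at the target hotspot; a DC
#'   counts every chromatid cut at both hotspots, regardless of other cuts.
#' * `blot`: emulates what a gel reports. A single counts a chromatid only if
#'   the *nearest* cut on the probe side is at the target hotspot (a closer
#'   cut occludes the fragment); a DC counts a chromatid cut at both hotspots
#'   with no cut in between (an intervening cut destroys the DC fragment).
#'
#' Frequencies are taken at each census time in `params$census` (default: one
#' census at `t_max`); a cut is visible at census `t` if it formed before
#' `min(t, exit time)`.
#'
#' @param pop A `population_breaks`.
#' @param assays Tibble from [assay_table()] (rows may be concatenated with
#'   `dplyr::bind_rows()`).
#' @param mode `"ideal"` or `"blot"`.
#' @param repeat_id Replicate label recorded in the output.
#' @return A cut-frequency tibble with columns `repeat_id`, `timepoint_h`,
#'   `assay`, `kind`, `frequency` (fraction of chromatids), `copies`, `side`.
#' @export
breaks_to_assay <- function(pop, assays, mode = c("ideal", "blot"),
                            repeat_id = 1L) {
  stopifnot(inherits(pop, "population_breaks"))
  mode <- match.arg(mode)
  hs <- pop$layout$hotspots
  known <- c(assays$hotspot, assays$partner)
  known <- known[!is.na(known)]
  if (!all(known %in% hs$hotspot)) {
    stop("assay references unknown hotspot: ",
         paste(setdiff(known, hs$hotspot), collapse = ", "))
  }
  if (any(assays$kind == "single" & mode == "blot" &
            !(assays$side %in% c("left", "right")))) {
    stop("blot-mode single assays need side = 'left' or 'right'")
  }
  census <- pop$params$census %||% pop$params$t_max
  n_chromatids <- pop$params$n_cells * 4

  cuts <- dplyr::left_join(pop$cuts, pop$cells, by = "cell")
  out <- purrr::map_dfr(census, function(tp) {
    vis <- dplyr::filter(cuts, .data$time < pmin(tp, .data$exit_time))
    vis$mol <- paste(vis$cell, vis$chromatid, vis$chrom, sep = ".")
    purrr::pmap_dfr(assays, function(assay, kind, hotspot, partner, side, ...) {
      freq <- if (kind == "single") {
        target <- dplyr::filter(vis, .data$hotspot == .env$hotspot)
        if (mode == "ideal") {
          dplyr::n_distinct(target$mol) / n_chromatids
        } else {
          # nearest cut from the probe side must be the target hotspot
          chr <- hs$chrom[match(hotspot, hs$hotspot)]
          on_chr <- dplyr::filter(vis, .data$chrom == chr)
          nearest <- on_chr |>
            dplyr::group_by(.data$mol) |>
            dplyr::summarise(
              hit = .data$hotspot[if (side == "left") which.min(.data$pos)
                                  else which.max(.data$pos)],
              .groups = "drop")
          sum(nearest$hit == hotspot) / n_chromatids
        }
      } else {
        a <- dplyr::filter(vis, .data$hotspot == .env$hotspot)
        b <- dplyr::filter(vis, .data$hotspot == .env$partner)
        both <- dplyr::inner_join(
          dplyr::select(a, "mol", pos_a = "pos"),
          dplyr::select(b, "mol", pos_b = "pos"), by = "mol")
        if (mode == "ideal" || nrow(both) == 0) {
          dplyr::n_distinct(both$mol) / n_chromatids
        } else {
          both$lo <- pmin(both$pos_a, both$pos_b)
          both$hi <- pmax(both$pos_a, both$pos_b)
          blocked <- dplyr::left_join(
            dplyr::select(both, "mol", "lo", "hi"),
            dplyr::select(vis, "mol", mid = "pos"), by = "mol",
            relationship = "many-to-many") |>
            dplyr::group_by(.data$mol) |>
            dplyr::summarise(
              blocked = any(.data$mid > .data$lo & .data$mid < .data$hi),
              .groups = "drop")
          sum(!blocked$blocked) / n_chromatids
        }
      }
      tibble::tibble(repeat_id = repeat_id, timepoint_h = tp, assay = assay,
                     kind = kind, frequency = freq, copies = 1L, side = side)
    })
  })
  out
}
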