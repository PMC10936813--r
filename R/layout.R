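#' Build a synthetic genome layout for the DSB simulator
#'
#' Constructs the simulator's world model: a set of chromosomes with
#' centromeres, DSB hotspots with intrinsic firing rates, contiguous priming
#' domains with a spatial priming-time gradient, background-calibration ORF
#' intervals, and (optionally) an excluded rDNA-like region.
#'
#' Hotspots are placed along each chromosome with approximately exponential
#' spacing and lognormally distributed intrinsic firing rates (per chromatid,
#' per hour). Adjacent hotspots are grouped greedily (left to right) into
#' priming domains: a domain is a maximal run of adjacent hotspots whose
#' end-to-end midpoint span does not exceed `max_domain_span`. Each domain is
#' assigned a mean priming time that increases with the distance of the domain
#' midpoint from the centromere:
#' `tau_d = tau0 + tau_per_mb * distance_Mb`. The same deterministic value is
#' recorded as the domain's expected chromosomal association time
#' (`rec114_time`), emulating the regional association timing of pro-DSB
#' factors.
#'
#' Default rates are calibrated so that, for the default genome configuration,
#' the expected number of breaks per cell (summed over hotspots as
#' `4 * (1 - exp(-w * T))` at a typical prophase window `T`) falls in the
#' 100-200 range characteristic of a single meiotic cell.
#'
#' @param config A list of layout parameters; see [layout_config()] for the
#'   fields and defaults. Fields supplied here override the defaults.
#' @param seed Integer seed; the layout is deterministic given `config` and
#'   `seed`.
#'
#' @return An object of class `genome_layout`: a list with tibbles
#'   `chromosomes` (chrom, length, cen), `hotspots` (hotspot, chrom, midpoint,
#'   width, rate, domain), `domains` (domain, chrom, start, end, span, tau,
#'   rec114_time), `orfs`, and `rdna` (or `NULL`), plus the resolved `config`.
#' @seealso [simulate_population()], [layout_two_hotspots()]
#' @export
#' @examples
#' lay <- build_layout(list(n_chromosomes = 2, chrom_length = 2e5), seed = 1)
#' lay$domains
build_layout <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(layout_config(), config)
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (cfg$n_chromosomes < 1) stop("need at least one chromosome")
  if (cfg$hotspot_spacing <= 0 || cfg$hotspot_width <= 0) {
    stop("hotspot spacing parameters must be positive")
  }
  if (cfg$max_domain_span <= 0) stop("max_domain_span must be positive")

  lengths <- rep_len(cfg$chrom_length, cfg$n_chromosomes)
  if (any(lengths <= 0)) stop("non-positive chromosome length")
  cen <- if (is.null(cfg$cen)) round(lengths * 0.45) else rep_len(cfg$cen, cfg$n_chromosomes)
  if (any(cen <= 0 | cen >= lengths)) stop("centromere outside chromosome")

  chroms <- tibble::tibble(
    chrom = paste0("chr", utils::as.roman(seq_len(cfg$n_chromosomes))),
    length = as.numeric(lengths),
    cen = as.numeric(cen)
  )

  set.seed(as.integer(seed) %% .Machine$integer.max)

  # ORFs first (hotspot-free zones used for background calibration)
  orfs <- purrr::pmap_dfr(chroms, function(chrom, length, cen) {
    n <- max(0L, round(cfg$n_orfs * length / sum(chroms$length)))
    if (n == 0L) return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
    len <- round(stats::runif(n, cfg$orf_length_min, cfg$orf_length_max))
    start <- round(sort(stats::runif(n, 1, length - max(len))))
    tibble::tibble(chrom = chrom, start = start, end = pmin(start + len - 1, length))
  })

  hs <- purrr::pmap_dfr(chroms, function(chrom, length, cen) {
    gaps <- stats::rexp(ceiling(length / cfg$hotspot_spacing) * 2,
                        1 / (0.75 * cfg$hotspot_spacing))
    pos <- round(cumsum(cfg$hotspot_spacing / 4 + gaps))
    pos <- pos[pos > cfg$hotspot_width & pos < length - cfg$hotspot_width]
    co <- orfs[orfs$chrom == chrom, ]
    if (nrow(co)) {
      inside <- vapply(pos, function(p) any(p >= co$start & p <= co$end), logical(1))
      pos <- pos[!inside]
    }
    n <- length(pos)
    tibble::tibble(
      chrom = chrom,
      midpoint = pos,
      width = round(stats::runif(n, cfg$hotspot_width * 0.5, cfg$hotspot_width * 1.5)),
      rate = stats::rlnorm(n, meanlog = log(cfg$rate_mean) - cfg$rate_sdlog^2 / 2,
                           sdlog = cfg$rate_sdlog)
    )
  })
  hs <- dplyr::arrange(hs, .data$chrom, .data$midpoint)
  hs$hotspot <- paste0("H", sprintf("%04d", seq_len(nrow(hs))))
  hs <- dplyr::select(hs, "hotspot", dplyr::everything())

  hs <- assign_domains(hs, cfg$max_domain_span)
  domains <- hs |>
    dplyr::group_by(.data$domain, .data$chrom) |>
    dplyr::summarise(
      start = min(.data$midpoint), end = max(.data$midpoint),
      span = max(.data$midpoint) - min(.data$midpoint),
      .groups = "drop"
    ) |>
    dplyr::left_join(chroms, by = "chrom") |>
    dplyr::mutate(
      rec114_time = priming_gradient((.data$start + .data$end) / 2, .data$cen,
                                     cfg$tau0, cfg$tau_per_mb),
      tau = .data$rec114_time
    ) |>
    dplyr::select("domain", "chrom", "start", "end", "span", "tau", "rec114_time") |>
    dplyr::arrange(.data$domain)

  rdna <- cfg$rdna
  if (!is.null(rdna)) rdna <- tibble::as_tibble(rdna)

  structure(
    list(chromosomes = chroms, hotspots = hs, domains = domains,
         orfs = orfs, rdna = rdna, config = cfg, seed = as.integer(seed)),
    class = "genome_layout"
  )
}

#' Default layout configuration
#'
#' Defaults emulate a budding-yeast-scale genome: 16 chromosomes (~12 Mb
#' total), ~4000 hotspots at ~3 kb mean spacing with 100-300 bp widths,
#' priming domains capped at 15 kb span, and ~50 long (>5.5 kb) ORFs reserved
#' as hotspot-free background-calibration regions. The mean intrinsic firing
#' rate (0.0012 per chromatid per hour) puts the expected number of DSBs per
#' cell in the 100-200 range over a typical 8 h prophase window.
#'
#' @return Named list of layout parameters.
#' @export
layout_config <- function() {
  list(
    n_chromosomes = 16L,
    chrom_length = round(seq(2.3e5, 1.3e6, length.out = 16)),
    cen = NULL,                 # default: 45% of chromosome length
    hotspot_spacing = 3000,     # mean inter-hotspot spacing, bp
    hotspot_width = 200,        # mean hotspot width, bp
    rate_mean = 0.0012,         # mean firing rate per chromatid per hour
    rate_sdlog = 1,             # lognormal spread of rates
    max_domain_span = 15000,    # max end-to-end span of a priming domain, bp
    tau0 = 3,                   # priming time at the centromere, hours
    tau_per_mb = 10,            # priming-time gradient, hours per Mb from cen
    n_orfs = 50L,               # ORFs reserved for background calibration
    orf_length_min = 5600,
    orf_length_max = 8000,
    rdna = NULL
  )
}

# Greedy maximal-run grouping: extend the current domain while the end-to-end
# midpoint span stays within max_span.
assign_domains <- function(hotspots, max_span) {
  hotspots <- dplyr::arrange(hotspots, .data$chrom, .data$midpoint)
  dom <- integer(nrow(hotspots))
  d <- 0L
  for (ch in unique(hotspots$chrom)) {
    idx <- which(hotspots$chrom == ch)
    start_pos <- -Inf
    for (i in idx) {
      if (hotspots$midpoint[i] - start_pos > max_span) {
        d <- d + 1L
        start_pos <- hotspots$midpoint[i]
      }
      dom[i] <- d
    }
  }
  hotspots$domain <- paste0("D", sprintf("%04d", dom))
  hotspots
}

# Deterministic priming/association-time gradient (hours), increasing with
# distance from the centromere.
priming_gradient <- function(pos, cen, tau0, tau_per_mb) {
  tau0 + tau_per_mb * abs(pos - cen) / 1e6
}

#' Minimal two-hotspot layout
#'
#' Convenience constructor for the locus-scale scenarios used to study the
#' coefficient of coincidence: one chromosome carrying a single priming domain
#' with two hotspots a configurable distance apart (mirroring a strong hotspot
#' pair separated by a few kb).
#'
#' @param distance_bp Distance between the two hotspot midpoints.
#' @param rate Intrinsic firing rate per chromatid per hour (length 1 or 2).
#' @param width Hotspot width in bp.
#' @param chrom_length Chromosome length in bp.
#' @param tau Mean priming time of the (single) domain, hours.
#' @return A `genome_layout` with one domain containing both hotspots.
#' @export
#' @examples
#' layout_two_hotspots(distance_bp = 2400, rate = 0.1)
layout_two_hotspots <- function(distance_bp = 2400, rate = 0.1, width = 200,
                                chrom_length = 1e5, tau = 0) {
  mid <- chrom_length / 2
  pos <- round(c(mid - distance_bp / 2, mid + distance_bp / 2))
  rate <- rep_len(rate, 2)
  chroms <- tibble::tibble(chrom = "chrI", length = chrom_length, cen = round(mid))
  hs <- tibble::tibble(
    hotspot = c("H0001", "H0002"), chrom = "chrI", midpoint = pos,
    width = width, rate = rate, domain = "D0001"
  )
  domains <- tibble::tibble(
    domain = "D0001", chrom = "chrI", start = pos[1], end = pos[2],
    span = diff(pos), tau = tau, rec114_time = tau
  )
  cfg <- utils::modifyList(layout_config(), list(max_domain_span = max(15000, diff(pos) + 1)))
  structure(
    list(chromosomes = chroms, hotspots = hs, domains = domains,
         orfs = tibble::tibble(chrom = character(), start = numeric(), end = numeric()),
         rdna = NULL, config = cfg, seed = NA_integer_),
    class = "genome_layout"
  )
}

#' Expected breaks per cell under a layout
#'
#' Closed-form expectation of the number of cut chromatids per cell, summing
#' `4 * (1 - exp(-w * T))` over hotspots for a DSB-permissive window of `T`
#' hours with no suppression, assuming all domains primed.
#'
#' @param layout A `genome_layout`.
#' @param window Window length `T` in hours.
#' @return Expected breaks per cell (numeric scalar).
#' @export
expected_breaks_per_cell <- function(layout, window = 8) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(4 * (1 - exp(-layout$hotspots$rate * window)))
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x$chromosomes), " chromosomes, ",
      nrow(x$hotspots), " hotspots, ", nrow(x$domains), " domains\n", sep = "")
  invisible(x)
}
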