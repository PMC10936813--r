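#' Simulation parameters for per-cell DSB formation
#'
#' Bundles the genotype flags and stochastic-model parameters of the per-cell
#' simulator. The two genotype switches mirror the biology: `tel1` enables
#' distance-dependent suppression of further cutting after a DSB (strength
#' `suppression`, exponential decay length `decay_bp`) and, when Ndt80 is
#' present, lengthens the mean prophase-exit time (checkpoint signalling);
#' `ndt80 = FALSE` arrests every cell in late prophase, i.e. the
#' DSB-permissive window runs to `t_max` in every cell.
#'
#' @param tel1 Logical; is Tel1 present? When `FALSE`, `suppression` must be 0.
#' @param ndt80 Logical; is Ndt80 present? When `FALSE` every cell's exit time
#'   is exactly `t_max` (prophase arrest).
#' @param exit_mean,exit_sd Mean and SD (hours) of the normal prophase-exit
#'   time, truncated to `[0, t_max]`. Defaults encode the accelerated exit of
#'   Tel1-deficient cells: 8 h when Tel1 is present, 6.5 h when absent. These
#'   are configurable model choices, not measured values.
#' @param t_max Arrest time / latest possible exit, hours.
#' @param priming_jitter_sd SD (hours) of per-cell jitter added to each
#'   domain's mean priming time; priming times are floored at 0.
#' @param suppression Suppression strength `s` in `[0, 1]`; the hazard of an
#'   uncut hotspot is multiplied by `prod(1 - s * exp(-d / decay_bp))` over
#'   prior cuts at distance `d` (same chromatid by default), floored at 0.
#' @param decay_bp Suppression decay length `lambda`, bp.
#' @param cis_only Logical; if `FALSE` suppression acts across all four
#'   chromatids (trans action). The biology does not resolve cis vs trans;
#'   cis-only is the default.
#' @param dt Time step of the discrete hazard simulation, hours.
#' @param n_cells Number of cells to simulate.
#' @param background_rate Uniform background read rate `beta`, expected HpM
#'   per bp added when converting breaks to a FullMap.
#' @param total_reads Declared library depth (mapped reads) used for HpM
#'   scaling of simulated FullMaps.
#' @param census Optional vector of census times (hours) at which assay
#'   frequencies are taken; default is a single census at `t_max`.
#' @param seed Root seed. Per-cell substreams are derived by a fixed counter
#'   scheme (`(seed + 48271 * cell) mod (2^31 - 1)`), so increasing `n_cells`
#'   extends, rather than reshuffles, the population.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(tel1 = TRUE, ndt80 = TRUE,
                       exit_mean = if (tel1) 8 else 6.5, exit_sd = 1,
                       t_max = 10, priming_jitter_sd = 0,
                       suppression = if (tel1) 0.8 else 0, decay_bp = 10000,
                       cis_only = TRUE, dt = 0.1, n_cells = 1000L,
                       background_rate = 0, total_reads = 1e6,
                       census = NULL, seed = 1L) {
  if (!tel1 && suppression != 0) {
    stop("suppression must be 0 when tel1 is off")
  }
  if (dt <= 0) stop("dt must be positive")
  if (any(c(exit_sd, priming_jitter_sd, suppression, decay_bp,
            background_rate, total_reads) < 0)) {
    stop("rates and scales must be non-negative")
  }
  if (suppression > 1) stop("suppression must be in [0, 1]")
  if (t_max <= 0 || n_cells < 1) stop("t_max and n_cells must be positive")
  structure(
    list(tel1 = tel1, ndt80 = ndt80, exit_mean = exit_mean, exit_sd = exit_sd,
         t_max = t_max, priming_jitter_sd = priming_jitter_sd,
         suppression = suppression, decay_bp = decay_bp, cis_only = cis_only,
         dt = dt, n_cells = as.integer(n_cells),
         background_rate = background_rate, total_reads = total_reads,
         census = census, seed = as.integer(seed)),
    class = "sim_params"
  )
}

cell_seed <- function(seed, cell) {
  as.integer((as.double(seed) + 48271 * as.double(cell)) %% 2147483647)
}

#' Simulate a population of cells forming Spo11 DSBs
#'
#' Realises the primed-domain model cell by cell. Each cell draws a prophase
#' exit time `T` (clamped to `[0, t_max]`; exactly `t_max` when `ndt80` is
#' off) and, for every domain, a priming time
#' `t_d = max(0, tau_d + jitter)`. From `t_d` to `T`, in discrete steps of
#' `dt`, each still-uncut hotspot-chromatid fires with probability
#' `w * dt * sigma`, where `sigma` multiplies `(1 - s * exp(-d / lambda))`
#' over prior cuts at distance `d` on the same chromatid (all chromatids if
#' `cis_only = FALSE`), floored at 0. Four chromatids are simulated
#' independently. Cut positions are the hotspot midpoint plus uniform jitter
#' within the hotspot width.
#'
#' When `s = 0` hotspot-chromatids are independent and firing times are drawn
#' directly from the (identical-in-law) truncated geometric distribution,
#' which is much faster; `method = "step"` forces the generic step-by-step
#' loop (useful for common-random-number comparisons across `s`).
#'
#' @param layout A `genome_layout`.
#' @param params A `sim_params`. `w * dt` may not exceed 1 for any hotspot.
#' @param method `"auto"` (default), `"geometric"` (requires `s = 0`) or
#'   `"step"`.
#' @return An object of class `population_breaks`: list with tibbles `cuts`
#'   (cell, chromatid, chrom, hotspot, pos, time), `cells` (cell, exit_time),
#'   `priming` (cell, domain, t_prime), and `primed_fraction` (domain,
#'   f_realised = share of cells with `t_prime < exit_time`), plus `params`
#'   and `layout`.
#' @export
#' @examples
#' lay <- layout_two_hotspots(rate = 0.2)
#' pop <- simulate_population(lay, sim_params(ndt80 = FALSE, tel1 = FALSE,
#'                                            n_cells = 50, seed = 7))
#' pop$primed_fraction
simulate_population <- function(layout, params,
                                method = c("auto", "geometric", "step")) {
  stopifnot(inherits(layout, "genome_layout"), inherits(params, "sim_params"))
  method <- match.arg(method)
  hs <- layout$hotspots
  if (any(hs$rate * params$dt > 1)) {
    stop("w * dt exceeds 1 for at least one hotspot; reduce dt")
  }
  if (method == "auto") {
    method <- if (params$suppression == 0) "geometric" else "step"
  }
  if (method == "geometric" && params$suppression != 0) {
    stop("geometric sampling requires suppression = 0")
  }

  doms <- layout$domains
  dom_idx <- match(hs$domain, doms$domain)
  n_h <- nrow(hs); n_d <- nrow(doms)
  chrom_len <- layout$chromosomes$length[match(hs$chrom, layout$chromosomes$chrom)]

  # precompute suppression kernel for the step method (same-chromosome only;
  # distances between hotspot midpoints)
  if (method == "step") {
    D <- abs(outer(hs$midpoint, hs$midpoint, "-"))
    same_chr <- outer(hs$chrom, hs$chrom, "==")
    kern <- 1 - params$suppression * exp(-D / params$decay_bp)
    kern[!same_chr] <- 1
    kern <- pmax(kern, 0)
    # log kernel for fast sigma products; 1e-300 floor keeps exp() at 0
    # for fully suppressive terms without -Inf * 0 artefacts
    logkern <- log(pmax(kern, 1e-300))
    n_steps_max <- ceiling(params$t_max / params$dt)
    p_base <- hs$rate * params$dt
  }

  cuts_list <- vector("list", params$n_cells)
  exit_time <- numeric(params$n_cells)
  primed <- matrix(0, nrow = params$n_cells, ncol = n_d)

  for (cell in seq_len(params$n_cells)) {
    set.seed(cell_seed(params$seed, cell))
    T_c <- if (params$ndt80) {
      min(max(stats::rnorm(1, params$exit_mean, params$exit_sd), 0), params$t_max)
    } else params$t_max
    t_d <- pmax(0, doms$tau + stats::rnorm(n_d, 0, params$priming_jitter_sd))
    exit_time[cell] <- T_c
    primed[cell, ] <- t_d
    t_start <- t_d[dom_idx]

    if (method == "geometric") {
      p <- hs$rate * params$dt
      n_steps <- pmax(0, floor((T_c - t_start) / params$dt))
      pfire <- 1 - (1 - p)^n_steps
      hit_h <- integer(0); hit_ch <- integer(0); hit_t <- numeric(0)
      for (ch in 1:4) {
        u <- stats::runif(n_h)
        hit <- which(u < pfire)
        if (length(hit)) {
          k <- pmax(1, ceiling(log1p(-u[hit]) / log1p(-p[hit])))
          hit_h <- c(hit_h, hit)
          hit_ch <- c(hit_ch, rep.int(ch, length(hit)))
          hit_t <- c(hit_t, t_start[hit] + k * params$dt)
        }
      }
      cell_cuts <- list(chromatid = hit_ch, h = hit_h, time = hit_t)
    } else {
      cut <- matrix(FALSE, n_h, 4)
      cut_time <- matrix(NA_real_, n_h, 4)
      k_first <- min(max(0, floor(min(t_start) / params$dt)), n_steps_max)
      for (k in seq_len(n_steps_max - k_first) + k_first) {
        tk <- k * params$dt
        if (tk > T_c) break
        eligible <- tk > t_start
        if (!any(eligible)) next
        sig <- if (any(cut)) {
          if (params$cis_only) {
            exp(logkern %*% cut)
          } else {
            matrix(exp(logkern %*% (rowSums(cut) > 0)), n_h, 4)
          }
        } else 1
        P <- p_base * sig
        U <- matrix(stats::runif(n_h * 4), n_h, 4)
        cand <- (U < P) & eligible & !cut
        nc <- sum(cand)
        if (nc == 0) next
        if (nc > 1 && params$suppression > 0) {
          # resolve same-step candidates sequentially in random order:
          # each later candidate, drawn at rate p*sigma_old, is thinned to
          # rate p*sigma_new by accepting with probability sigma_new/sigma_old
          idx <- which(cand, arr.ind = TRUE)
          ord <- sample.int(nrow(idx))
          for (j in seq_len(nc - 1)) {
            e <- ord[j + 1]
            h <- idx[e, 1]; ch <- idx[e, 2]
            newly <- idx[ord[seq_len(j)], , drop = FALSE]
            newly <- newly[cand[newly], , drop = FALSE]
            rel <- if (params$cis_only) newly[newly[, 2] == ch, 1] else newly[, 1]
            if (length(rel)) {
              ratio <- exp(sum(logkern[h, rel]))
              if (stats::runif(1) >= ratio) cand[idx[e, 1], idx[e, 2]] <- FALSE
            }
          }
        }
        cut_time[cand] <- tk
        cut <- cut | cand
      }
      idx <- which(cut, arr.ind = TRUE)
      cell_cuts <- list(chromatid = as.integer(idx[, 2]),
                        h = as.integer(idx[, 1]), time = cut_time[idx])
    }

    n_cuts <- length(cell_cuts$h)
    if (n_cuts) {
      jit <- stats::runif(n_cuts, -0.5, 0.5) * hs$width[cell_cuts$h]
      cell_cuts$pos <- pmin(pmax(round(hs$midpoint[cell_cuts$h] + jit), 1),
                            chrom_len[cell_cuts$h])
      cell_cuts$cell <- rep.int(cell, n_cuts)
      cuts_list[[cell]] <- cell_cuts
    }
  }

  cuts_list <- cuts_list[!vapply(cuts_list, is.null, logical(1))]
  if (!length(cuts_list)) {
    cuts <- tibble::tibble(cell = integer(), chromatid = integer(),
                           chrom = character(), hotspot = character(),
                           pos = numeric(), time = numeric())
  } else {
    h_all <- unlist(lapply(cuts_list, `[[`, "h"), use.names = FALSE)
    cuts <- tibble::tibble(
      cell = unlist(lapply(cuts_list, `[[`, "cell"), use.names = FALSE),
      chromatid = unlist(lapply(cuts_list, `[[`, "chromatid"), use.names = FALSE),
      chrom = hs$chrom[h_all], hotspot = hs$hotspot[h_all],
      pos = unlist(lapply(cuts_list, `[[`, "pos"), use.names = FALSE),
      time = unlist(lapply(cuts_list, `[[`, "time"), use.names = FALSE)
    ) |>
      dplyr::arrange(.data$cell, .data$chromatid, .data$chrom, .data$pos)
  }

  f_real <- colMeans(primed < exit_time)
  structure(
    list(
      cuts = cuts,
      cells = tibble::tibble(cell = seq_len(params$n_cells), exit_time = exit_time),
      priming = tibble::tibble(
        cell = rep(seq_len(params$n_cells), each = n_d),
        domain = rep(doms$domain, params$n_cells),
        t_prime = as.vector(t(primed))
      ),
      primed_fraction = tibble::tibble(domain = doms$domain, f_realised = f_real),
      params = params, layout = layout
    ),
    class = "population_breaks"
  )
}

#' @export
print.population_breaks <- function(x, ...) {
  cat("<population_breaks> ", x$params$n_cells, " cells, ",
      nrow(x$cuts), " cuts\n", sep = "")
  invisible(x)
}

#' Closed-form primed fraction of a domain
#'
#' Probability that a domain is primed before the cell exits prophase,
#' `P(t_d < T)`, under the configured distributions: priming time
#' `t_d ~ tau_d + N(0, jitter_sd)` and exit time `T ~ N(exit_mean, exit_sd)`
#' (or `T = t_max` exactly when `ndt80` is off), giving
#' `Phi((mu_T - tau_d) / sqrt(sd_T^2 + sd_jitter^2))`. Truncation of `T` to
#' `[0, t_max]` and flooring of `t_d` at 0 are neglected, so the closed form
#' is accurate when both means sit well inside the window. When both SDs are
#' zero the comparison is the strict inequality `tau_d < mu_T` (ties give 0).
#'
#' This serves as the analytic oracle for the realised `f_d` reported by
#' [simulate_population()].
#'
#' @param layout A `genome_layout`.
#' @param params A `sim_params`.
#' @param domain Domain id (e.g. `"D0001"`).
#' @return Probability in `[0, 1]`.
#' @export
primed_fraction <- function(layout, params, domain) {
  stopifnot(inherits(layout, "genome_layout"), inherits(params, "sim_params"))
  i <- match(domain, layout$domains$domain)
  if (is.na(i)) stop("unknown domain: ", domain)
  tau <- layout$domains$tau[i]
  mu_T <- if (params$ndt80) params$exit_mean else params$t_max
  sd_T <- if (params$ndt80) params$exit_sd else 0
  s <- sqrt(sd_T^2 + params$priming_jitter_sd^2)
  if (s == 0) return(as.numeric(tau < mu_T))
  stats::pnorm((mu_T - tau) / s)
}
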