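# Shared fixtures and independent brute-force oracles, built in code.

two_hotspot_assays <- function() {
  dplyr::bind_rows(
    assay_table("s1", "single", "H0001", side = "left"),
    assay_table("s2", "single", "H0002", side = "right"),
    assay_table("dc", "dc", "H0001", partner = "H0002")
  )
}

# interference of a two-hotspot domain from ideal-mode assay frequencies
measure_interference <- function(pop, mode = "ideal") {
  tab <- breaks_to_assay(pop, two_hotspot_assays(), mode = mode)
  obs <- tab$frequency[tab$assay == "dc"]
  expd <- prod(tab$frequency[tab$assay != "dc"])
  -log2(obs / expd)
}

# near-saturating hotspots so that, given priming, cut probability is ~1 and
# the coefficient of coincidence isolates the primed-fraction effect
coc_population <- function(f = 0.5, n_cells = 20000, seed = 3) {
  if (f == 1) {
    lay <- layout_two_hotspots(rate = 20, tau = 0)
    prm <- sim_params(tel1 = FALSE, ndt80 = FALSE, dt = 0.025,
                      n_cells = n_cells, seed = seed)
  } else {
    stopifnot(f == 0.5)
    lay <- layout_two_hotspots(rate = 20, tau = 6)
    prm <- sim_params(tel1 = FALSE, ndt80 = TRUE, exit_mean = 6, exit_sd = 1,
                      dt = 0.025, n_cells = n_cells, seed = seed)
  }
  simulate_population(lay, prm)
}

# random sparse break profile on one small chromosome
random_profile <- function(len = 3000, seed = 1) {
  set.seed(seed)
  counts <- stats::rpois(len, 0.05)
  n_peaks <- sample(0:4, 1)
  for (i in seq_len(n_peaks)) {
    w <- sample(10:120, 1)
    c0 <- sample(seq(50, len - w - 50), 1)
    counts[c0:(c0 + w)] <- counts[c0:(c0 + w)] + stats::rpois(w + 1, runif(1, 0.5, 6))
  }
  keep <- counts > 0
  as_fullmap(tibble::tibble(chrom = "chrI", pos = which(keep),
                            watson = counts[keep], crick = 0L),
             total_reads = 1e6)
}

# Brute-force hotspot caller: position-by-position smoothing, scanning run
# detection, pairwise merging, then filters. Independent of the package's
# vectorised implementation.
brute_force_call <- function(map, len, cutoff, window, min_len, min_reads,
                             merge_gap) {
  x <- numeric(len)
  x[map$pos] <- (map$watson + map$crick) * 1e6 / attr(map, "total_reads")
  k <- 0:(window - 1)
  w <- 0.5 * (1 - cos(2 * pi * k / (window - 1)))
  w <- w / sum(w)
  half <- (window - 1) / 2
  sm <- numeric(len)
  for (i in seq_len(len)) {
    s <- 0
    for (j in seq_len(window)) {
      p <- i + j - 1 - half
      if (p >= 1 && p <= len) s <- s + w[j] * x[p]
    }
    sm[i] <- s
  }
  # runs at/above cutoff
  starts <- ends <- integer(0)
  inside <- FALSE
  for (i in seq_len(len)) {
    if (sm[i] >= cutoff && !inside) { starts <- c(starts, i); inside <- TRUE }
    if (sm[i] < cutoff && inside) { ends <- c(ends, i - 1); inside <- FALSE }
  }
  if (inside) ends <- c(ends, len)
  # merge gaps < merge_gap
  if (length(starts) > 1) {
    i <- 1
    while (i < length(starts)) {
      if (starts[i + 1] - ends[i] - 1 < merge_gap) {
        ends[i] <- ends[i + 1]
        starts <- starts[-(i + 1)]; ends <- ends[-(i + 1)]
      } else i <- i + 1
    }
  }
  # filters
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    mass <- sum((map$watson + map$crick)[map$pos >= starts[i] & map$pos <= ends[i]])
    keep[i] <- (ends[i] - starts[i] + 1) >= min_len && mass >= min_reads
  }
  tibble::tibble(start = starts[keep], end = ends[keep])
}

# Brute-force degree-1 tricube local regression via stats::lm at each point
# (independent oracle for the package's closed-form implementation).
lm_local_linear <- function(x, y, x0, span) {
  n <- length(x)
  q <- max(2L, ceiling(span * n))
  vapply(x0, function(p) {
    d <- abs(x - p)
    dq <- sort(d)[min(q, n)]
    if (dq == 0) dq <- max(d[d > 0], 1)
    w <- (1 - pmin(d / dq, 1)^3)^3
    df <- data.frame(x = x - p, y = y, w = w)
    df <- df[df$w > 0, ]
    if (nrow(df) < 2 || stats::var(df$x) == 0) {
      return(sum(df$w * df$y) / sum(df$w))
    }
    fit <- stats::lm(y ~ x, data = df, weights = w)
    unname(stats::coef(fit)[1])
  }, numeric(1))
}
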