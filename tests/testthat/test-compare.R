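fake_table <- function(norm, chrom = "chrI", start = NULL) {
  n <- length(norm)
  if (is.null(start)) start <- seq(1000, by = 5000, length.out = n)
  structure(
    tibble::tibble(
      hotspot = paste0("HS", sprintf("%04d", seq_len(n))),
      chrom = chrom, start = start, end = start + 200,
      length = 201, hpm = norm, corrected = norm,
      norm_hpm = norm / sum(norm) * 1e6, floored = FALSE),
    class = c("hotspot_table", "tbl_df", "tbl", "data.frame"))
}

test_that("self-correlation is exactly 1; permutation breaks it", {
  set.seed(2)
  a <- fake_table(rlnorm(200))
  expect_equal(hotspot_correlation(a, a)$estimate, 1)
  b <- a
  b$norm_hpm <- sample(b$norm_hpm)
  r <- hotspot_correlation(a, b)$estimate
  expect_lt(abs(r), 0.15)
  sp <- hotspot_correlation(a, a, method = "spearman")
  expect_equal(sp$estimate, 1)
  expect_error(hotspot_correlation(a[1:2, ], a[1:2, ]), "fewer than 3")
})

test_that("zero-strength hotspots are excluded from correlations and ratios", {
  a <- fake_table(c(10, 20, 30, 0, 40))
  b <- fake_table(c(10, 20, 30, 5, 0))
  r <- hotspot_correlation(a, b)
  expect_equal(r$n, 3)
  expect_equal(r$n_excluded, 2)
  lr <- log2_ratio_per_hotspot(a, b)
  expect_equal(sum(!lr$defined), 2)
  expect_true(all(is.na(lr$log2fc[!lr$defined])))
})

test_that("log2 ratios are antisymmetric and match hand computation", {
  a <- fake_table(c(2, 4, 2))
  b <- fake_table(c(1, 4, 3))
  ab <- log2_ratio_per_hotspot(a, b)
  ba <- log2_ratio_per_hotspot(b, a)
  expect_equal(ab$log2fc, -ba$log2fc)
  # hand: NormHpM_a = (0.25, 0.5, 0.25)*1e6, NormHpM_b = (0.125, 0.5, 0.375)*1e6
  expect_equal(ab$log2fc, log2(c(0.25 / 0.125, 1, 0.25 / 0.375)))
  # identical tables give all zeros
  expect_equal(log2_ratio_per_hotspot(a, a)$log2fc, rep(0, 3))
})

test_that("local-regression smoothing is exact on constants and lines", {
  set.seed(5)
  x <- sort(runif(60, 0, 1e5))
  ratios <- tibble::tibble(hotspot = paste0("h", 1:60), chrom = "chrI",
                           midpoint = x, norm_a = 1, norm_b = 1,
                           log2fc = 0.7, defined = TRUE)
  sm <- smooth_ratio(ratios, span = 0.3)
  expect_equal(sm$smoothed, rep(0.7, 60), tolerance = 1e-10)
  ratios$log2fc <- 2 + 3e-5 * x
  sm2 <- smooth_ratio(ratios, span = 0.3)
  expect_equal(sm2$smoothed, ratios$log2fc, tolerance = 1e-8)
  expect_error(smooth_ratio(ratios, span = 0), "span")
  # fewer than 5 points: passthrough with flag
  few <- smooth_ratio(ratios[1:4, ], span = 0.5)
  expect_false(any(few$smooth_ok))
  expect_equal(few$smoothed, few$log2fc)
})

test_that("smoothing agrees with a weighted-lm oracle on a step input", {
  set.seed(8)
  x <- sort(runif(80, 0, 1000))
  y <- ifelse(x < 500, -1, 1) + rnorm(80, 0, 0.05)
  got <- meiodsb:::local_linear(x, y, x, span = 0.35)
  want <- lm_local_linear(x, y, x, span = 0.35)
  expect_equal(got, want, tolerance = 1e-8)
  # smoothed step is monotone through the transition
  mid <- got[x > 350 & x < 650]
  expect_true(all(diff(mid) > -1e-6))
})

test_that("centromere-anchored bins cover the chromosome and account mass", {
  chroms <- tibble::tibble(chrom = "chrI", length = 120000, cen = 60000)
  a <- fake_table(rep(10, 12), start = seq(5000, 115000, by = 10000))
  b <- fake_table(c(rep(10, 6), rep(40, 6)), start = seq(5000, 115000, by = 10000))
  ratios <- log2_ratio_per_hotspot(a, b)
  binned <- bin_ratios_50kb(ratios, chroms)
  expect_equal(binned$k, c(-2, -1, 0, 1))
  expect_equal(binned$start, c(1, 10000, 60000, 110000))
  expect_equal(binned$end, c(9999, 59999, 109999, 120000))
  # mass accounting: binned NormHpM sums equal the unbinned totals
  expect_equal(sum(binned$norm_a), sum(ratios$norm_a))
  expect_equal(sum(binned$norm_b), sum(ratios$norm_b))
  # equal strengths everywhere -> all defined bins zero
  same <- bin_ratios_50kb(log2_ratio_per_hotspot(a, a), chroms)
  expect_true(all(same$log2fc[same$defined] == 0))
  # 4:1 NormHpM mass in one bin -> log2 fold change of 2
  a2 <- fake_table(c(4, 1), start = c(20000, 70000))
  b2 <- fake_table(c(1, 4), start = c(20000, 70000))
  bn <- bin_ratios_50kb(log2_ratio_per_hotspot(a2, b2), chroms)
  k1 <- bn[bn$k == -1, ]
  expect_equal(k1$log2fc, 2)
  expect_error(bin_ratios_50kb(ratios, tibble::tibble(
    chrom = "chrI", length = 100, cen = 200)), "centromere")
})

test_that("timing tracks are confidence-filtered, smoothed and binned", {
  # constant track stays constant
  tr <- tibble::tibble(chrom = "chrI", pos = seq(1000, 99000, by = 1000),
                       time = 4, confidence = TRUE)
  tt <- prepare_timing_track(tr)
  expect_equal(tt$time, rep(4, nrow(tt)), tolerance = 1e-10)
  expect_equal(tt$start, c(1, 50001))
  # low-confidence points are removed
  tr2 <- tr
  tr2$confidence[1:50] <- FALSE
  tt2 <- prepare_timing_track(tr2)
  expect_equal(sum(tt2$n_points), 49)
  expect_error(prepare_timing_track(dplyr::mutate(tr, confidence = FALSE)),
               "confidence")
  # gradient recovered within smoothing tolerance (vs lm oracle)
  set.seed(3)
  tr3 <- tibble::tibble(chrom = "chrI", pos = sort(runif(160, 1, 2e5)),
                        time = 2 + 1e-5 * sort(runif(160, 1, 2e5)),
                        confidence = TRUE)
  tt3 <- prepare_timing_track(tr3)
  span <- min(1, 80 / 160)
  sm_oracle <- lm_local_linear(tr3$pos, tr3$time, tr3$pos, span)
  bins <- floor((tr3$pos - 1) / 50000)
  want <- tapply(sm_oracle, bins, mean)
  expect_equal(tt3$time, as.numeric(want), tolerance = 1e-8)
})

test_that("fold-change/timing correlation flags perfect monotone relations", {
  binned <- structure(tibble::tibble(
    chrom = "chrI", k = 0:9, start = seq(1, by = 50000, length.out = 10),
    end = seq(50000, by = 50000, length.out = 10),
    norm_a = 1, norm_b = 1, log2fc = seq(2, -2, length.out = 10),
    n_hotspots = 1L, defined = TRUE),
    class = c("binned_ratio", "tbl_df", "tbl", "data.frame"))
  timing <- structure(tibble::tibble(
    chrom = "chrI", start = seq(1, by = 50000, length.out = 10),
    end = seq(50000, by = 50000, length.out = 10),
    time = seq(1, 10), n_points = 5L),
    class = c("timing_track", "tbl_df", "tbl", "data.frame"))
  ct <- correlate_fc_with_timing(binned, timing)
  expect_equal(abs(ct$estimate), 1)
  expect_lt(ct$p.value, 0.01)
  expect_equal(ct$n, 10)
})

test_that("small-n Spearman p-values come from exact permutation", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  sp <- meiodsb:::spearman_cor(x, y)
  # enumerate all 120 permutations by hand
  perms <- meiodsb:::all_permutations(5)
  rhos <- apply(perms, 1, function(ix) cor(rank(x), rank(y)[ix]))
  expect_equal(sp$p.value, mean(abs(rhos) >= abs(sp$estimate) - 1e-12))
  # cross-check the rho itself against cor.test
  expect_equal(sp$estimate,
               unname(cor.test(x, y, method = "spearman")$estimate))
})
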