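make_map <- function(pos, counts, len = NULL, total = 1e6) {
  as_fullmap(tibble::tibble(chrom = "chrI", pos = pos, watson = counts,
                            crick = 0L), total_reads = total)
}

test_that("Hann weights are normalised with the expected peak gain", {
  w <- hann_window(201)
  expect_equal(sum(w), 1)
  expect_equal(max(w), 1 / 100)  # raw window sum is (N - 1)/2 = 100
  expect_error(hann_window(200), "odd")
  # impulse of mass m smooths to peak m/100
  m <- 42
  map <- make_map(500, m)
  sm <- hann_smooth(map, 201, chrom_lengths = c(chrI = 1000))
  expect_equal(max(sm$hpm_smooth), m / 100)
  # constant signal is preserved in the interior
  mapc <- make_map(1:1000, rep(2L, 1000))
  smc <- hann_smooth(mapc, 21, chrom_lengths = c(chrI = 1000))
  expect_equal(smc$hpm_smooth[200:800], rep(2, 601))
})

test_that("smoothing conserves total signal on the padded domain", {
  set.seed(4)
  counts <- rpois(2000, 1) + 1L
  map <- make_map(1:2000, counts)
  sm <- hann_smooth(map, 201, chrom_lengths = c(chrI = 2000), pad = TRUE)
  before <- sum(counts)  # counts are HpM at 1e6 declared reads
  expect_lt(abs(sum(sm$hpm_smooth) - before) / before, 1e-9)
})

test_that("calling applies cutoff, merge and minima in order", {
  # one 30 bp supra-cutoff block with ample reads -> one hotspot
  map <- make_map(1000:1029, rep(2L, 30))
  tpl <- call_hotspots(map, cutoff = 0.05, window = 21, min_len = 25,
                       min_reads = 25, merge_gap = 200,
                       chrom_lengths = c(chrI = 3000))
  expect_equal(nrow(tpl), 1)
  # two blocks separated by 150 bp merge into one
  map2 <- make_map(c(1000:1049, 1200:1249), rep(3L, 100))
  tpl2 <- call_hotspots(map2, cutoff = 0.5, window = 21, min_len = 25,
                        min_reads = 25, merge_gap = 200,
                        chrom_lengths = c(chrI = 3000))
  expect_equal(nrow(tpl2), 1)
  expect_lte(tpl2$start, 1049)
  expect_gte(tpl2$end, 1200)
  # a 20 bp run fails the 25 bp minimum
  map3 <- make_map(1000:1010, rep(5L, 11))
  tpl3 <- call_hotspots(map3, cutoff = 2, window = 11, min_len = 25,
                        min_reads = 1, merge_gap = 50,
                        chrom_lengths = c(chrI = 3000))
  expect_equal(nrow(tpl3), 0)
  expect_error(call_hotspots(map, cutoff = -1), "negative")
})

test_that("caller agrees with the brute-force oracle on random profiles", {
  for (s in 1:20) {
    map <- random_profile(len = 3000, seed = s)
    got <- call_hotspots(map, cutoff = 0.4, window = 21, min_len = 25,
                         min_reads = 25, merge_gap = 60,
                         chrom_lengths = c(chrI = 3000))
    want <- brute_force_call(map, 3000, cutoff = 0.4, window = 21,
                             min_len = 25, min_reads = 25, merge_gap = 60)
    expect_equal(got$start, want$start, info = paste("seed", s))
    expect_equal(got$end, want$end, info = paste("seed", s))
  }
})

test_that("template combination is a merged union with presence flags", {
  t1 <- meiodsb:::as_hotspot_template(
    tibble::tibble(chrom = "chrI", start = c(100, 500), end = c(200, 600)))
  t2 <- meiodsb:::as_hotspot_template(
    tibble::tibble(chrom = "chrI", start = 150, end = 300))
  comb <- combine_templates(list(a = t1, b = t2))
  expect_equal(comb$start, c(100, 500))
  expect_equal(comb$end, c(300, 600))
  expect_equal(comb$in_a, c(TRUE, TRUE))
  expect_equal(comb$in_b, c(TRUE, FALSE))
  # idempotence
  again <- combine_templates(list(x = comb))
  expect_equal(again$start, comb$start)
  expect_equal(again$end, comb$end)
  # disjoint templates concatenate
  t3 <- meiodsb:::as_hotspot_template(
    tibble::tibble(chrom = "chrII", start = 10, end = 20))
  both <- combine_templates(list(a = t1, c = t3))
  expect_equal(nrow(both), 3)
})

test_that("background estimation recovers a uniform density", {
  map <- make_map(1:20000, rep(3L, 20000))
  orfs <- tibble::tibble(chrom = "chrI", start = c(1000, 8000),
                         end = c(7000, 14000))
  expect_equal(estimate_background(map, orfs, min_orf_len = 5500, n_orfs = 2), 3)
  # zero signal inside ORFs
  map0 <- make_map(15000:16000, rep(3L, 1001))
  expect_equal(estimate_background(map0, orfs, min_orf_len = 5500, n_orfs = 2), 0)
  expect_warning(estimate_background(map, orfs, min_orf_len = 5500, n_orfs = 47),
                 "qualify")
  expect_error(estimate_background(map, orfs, min_orf_len = 1e6), "no ORFs")
})

test_that("region exclusion removes overlapping hotspots and reports", {
  set.seed(9)
  tpl <- meiodsb:::as_hotspot_template(tibble::tibble(
    chrom = "chrI", start = seq(1000, 20050, by = 1000),
    end = seq(1000, 20050, by = 1000) + 100))
  expect_equal(nrow(tpl), 20)
  region <- tibble::tibble(chrom = "chrI", start = 4500, end = 7500)
  expect_message(out <- exclude_region(tpl, region), "3 hotspot")
  expect_equal(nrow(out), 17)
  expect_equal(attr(out, "n_removed"), 3)
  # no overlap leaves the template unchanged
  expect_message(same <- exclude_region(tpl, tibble::tibble(
    chrom = "chrII", start = 1, end = 1e6)), "0 hotspot")
  expect_equal(nrow(same), 20)
})

test_that("NormHpM strengths are conserved, proportional and floored", {
  map <- make_map(c(100:110, 300:310), c(rep(6L, 11), rep(2L, 11)))
  tpl <- meiodsb:::as_hotspot_template(tibble::tibble(
    chrom = "chrI", start = c(100, 300), end = c(110, 310)))
  st <- hotspot_strengths(map, tpl, background = 0)
  expect_equal(sum(st$norm_hpm), 1e6)
  expect_equal(st$norm_hpm, c(750000, 250000))  # 3:1 corrected signal
  one <- hotspot_strengths(map, tpl[1, ], background = 0)
  expect_equal(one$norm_hpm, 1e6)
  # negative corrected signal floors to zero with a flag
  stf <- hotspot_strengths(map, tpl, background = 3)
  expect_true(stf$floored[2])
  expect_equal(stf$corrected[2], 0)
  expect_equal(sum(stf$norm_hpm), 1e6)
  expect_error(hotspot_strengths(map, tpl[0, ], 0), "empty")
})

test_that("template overlap counts match a constructed fixture", {
  a <- meiodsb:::as_hotspot_template(tibble::tibble(
    chrom = "chrI", start = seq(100, 1000, by = 100)[1:10],
    end = seq(100, 1000, by = 100)[1:10] + 30))
  # 7 of b's intervals overlap a's, 5 extra are disjoint
  b <- meiodsb:::as_hotspot_template(tibble::tibble(
    chrom = "chrI",
    start = c(a$start[1:7] + 10, 2000, 2100, 2200, 2300, 2400),
    end = c(a$start[1:7] + 40, 2050, 2150, 2250, 2350, 2450)))
  ov <- overlap_templates(a, b)
  expect_equal(ov$counts$shared_pairs, 7)
  expect_equal(ov$counts$a_only, 3)
  expect_equal(ov$counts$b_only, 5)
  # identical templates are fully shared; disjoint share nothing
  self <- overlap_templates(a, a)
  expect_equal(self$counts$a_only, 0)
  expect_equal(self$counts$shared_a, 10)
  dis <- overlap_templates(a, meiodsb:::as_hotspot_template(
    tibble::tibble(chrom = "chrII", start = 1, end = 10)))
  expect_equal(dis$counts$shared_pairs, 0)
})

test_that("pooling normalises to HpM and is idempotent", {
  m1 <- make_map(c(10, 20), c(4L, 2L), total = 2e6)  # HpM 2, 1
  m2 <- make_map(c(10, 30), c(4L, 8L), total = 1e6)  # HpM 4, 8
  pool <- pool_fullmaps(list(a = m1, b = m2))
  hp <- fullmap_hpm(pool)
  expect_equal(hp$hpm[hp$pos == 10], 3)   # mean of 2 and 4
  expect_equal(hp$hpm[hp$pos == 20], 0.5) # mean of 1 and 0
  expect_equal(hp$hpm[hp$pos == 30], 4)
  # single library: its own HpM profile
  solo <- pool_fullmaps(list(m1))
  expect_equal(fullmap_hpm(solo)$hpm, c(2, 1))
  # idempotence
  twice <- pool_fullmaps(list(pool))
  expect_equal(fullmap_hpm(twice)$hpm, hp$hpm)
})

test_that("calling recovers planted hotspots with signal well above cutoff", {
  cfg <- list(n_chromosomes = 2L, chrom_length = 2e5, hotspot_spacing = 5000,
              rate_mean = 0.002, tau0 = 0, tau_per_mb = 0, n_orfs = 4L)
  lay <- build_layout(cfg, seed = 19)
  pop <- simulate_population(lay, sim_params(tel1 = FALSE, ndt80 = FALSE,
                                             n_cells = 2000, seed = 19))
  map <- breaks_to_fullmap(pop)
  tpl <- call_hotspots(map, chrom_lengths = c(
    chrI = 2e5, chrII = 2e5))
  # expected smoothed peak ~ 2 * E[cuts] / width (uniform mass under a
  # normalised Hann window); require it to clear twice the calling cutoff
  hs <- lay$hotspots
  e_cuts <- 4 * 2000 * (1 - exp(-hs$rate * 10))
  peak <- 2 * e_cuts / hs$width
  strong <- hs[peak > 2 * 0.193, ]
  hit <- vapply(seq_len(nrow(strong)), function(i) {
    same <- tpl[tpl$chrom == strong$chrom[i], ]
    any(abs((same$start + same$end) / 2 - strong$midpoint[i]) <=
          strong$width[i] / 2)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})
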