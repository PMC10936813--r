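test_that("multicopy correction multiplies, caps and flags", {
  expect_equal(as.numeric(correct_multicopy(0.02, 3)), 0.06)
  expect_equal(as.numeric(correct_multicopy(0.10, 1)), 0.10)
  expect_warning(capped <- correct_multicopy(0.40, 3), "capped")
  expect_equal(as.numeric(capped), 1.0)
  expect_true(attr(capped, "overflow"))
  expect_error(correct_multicopy(0.1, 0), "copies")
})

test_that("distal-single correction is the sum of fragment and DC", {
  expect_equal(correct_distal_single(0.08, 0.02), 0.10)
  expect_equal(correct_distal_single(0.3, 0), 0.3)
  expect_error(correct_distal_single(1.2, 0), "\\[0, 1\\]")
})

test_that("timepoint averaging is an unweighted mean with missing flags", {
  tbl <- tibble::tibble(
    repeat_id = rep(1:3, each = 2),
    timepoint_h = rep(c(6, 8), 3),
    assay = "s1", kind = "single",
    frequency = c(0.10, 0.12, 0.20, 0.24, 0.05, 0.07)
  )
  avg <- average_timepoints(tbl, c(6, 8))
  expect_equal(avg$frequency, c(0.11, 0.22, 0.06))
  expect_true(all(avg$complete))
  # single requested timepoint is a passthrough
  one <- average_timepoints(tbl, 6)
  expect_equal(one$frequency, c(0.10, 0.20, 0.05))
  # a repeat missing a timepoint is flagged, not dropped
  miss <- average_timepoints(tbl[-2, ], c(6, 8))
  expect_equal(nrow(miss), 3)
  expect_false(miss$complete[miss$repeat_id == 1])
  expect_error(average_timepoints(tbl, numeric(0)), "empty")
})

test_that("expected DCs are the product of single frequencies", {
  expect_equal(expected_dc(0.10, 0.05), 0.005)
  expect_equal(expected_dc(0, 0.7), 0)
  expect_equal(expected_dc(1, 1), 1)
})

test_that("interference is -log2 of the coefficient of coincidence", {
  expect_equal(interference(0.01, 0.01)$interference, 0)
  expect_equal(interference(0.015, 0.005)$interference, -log2(3))
  expect_equal(interference(0.005, 0.010)$interference, 1.0)
  # antisymmetry under swapping observed and expected
  expect_equal(interference(0.004, 0.02)$interference,
               -interference(0.02, 0.004)$interference)
  # near-zero exclusion: flagged, never infinite
  res <- interference(c(0, 0.00005, 0.02), c(0.01, 0.01, 0.00009))
  expect_equal(res$excluded, c(TRUE, TRUE, TRUE))
  expect_true(all(is.na(res$interference)))
  expect_error(interference(-0.1, 0.1), "negative")
})

test_that("dsb_interference runs the full per-repeat recipe", {
  tbl <- tidyr::expand_grid(repeat_id = 1:2, timepoint_h = c(6, 8)) |>
    dplyr::mutate(
      s1 = c(0.10, 0.12, 0.09, 0.11), s2 = c(0.05, 0.05, 0.06, 0.04),
      dc = c(0.004, 0.006, 0.002, 0.004)) |>
    tidyr::pivot_longer(c("s1", "s2", "dc"), names_to = "assay",
                        values_to = "frequency") |>
    dplyr::mutate(kind = ifelse(assay == "dc", "dc", "single"),
                  copies = ifelse(assay == "dc", 3L, 1L))
  res <- dsb_interference(tbl, dc = "dc", single1 = "s1", single2 = "s2")
  expect_equal(nrow(res), 2)
  # repeat 1 by hand: obs = 0.005 * 3, exp = 0.11 * 0.05
  expect_equal(res$observed[1], 0.015)
  expect_equal(res$expected[1], 0.11 * 0.05)
  expect_equal(res$interference[1], -log2(0.015 / 0.0055))
})

test_that("aggregate_and_compare matches the pooled-variance formula", {
  set.seed(20)
  a <- rnorm(6, 1, 0.3); b <- rnorm(5, 0, 0.3)
  cmp <- aggregate_and_compare(a, b)
  # independent closed-form pooled t
  sp2 <- ((5 * var(a) + 4 * var(b)) / 9)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 6 + 1 / 5))
  p_hand <- 2 * pt(-abs(t_hand), df = 9)
  expect_equal(cmp$test$t, t_hand)
  expect_equal(cmp$test$p, p_hand)
  expect_equal(cmp$groups$n, c(6L, 5L))

  # identical groups: t = 0, p = 1
  same <- aggregate_and_compare(c(0.5, 0.7, 0.9), c(0.9, 0.5, 0.7))
  expect_equal(same$test$t, 0)
  expect_equal(same$test$p, 1)

  # zero pooled variance with different means: degenerate rule p = 0
  deg <- aggregate_and_compare(c(-1, -1), c(1, 1))
  expect_true(deg$test$degenerate)
  expect_equal(deg$test$p, 0)
  deg2 <- aggregate_and_compare(c(1, 1), c(1, 1))
  expect_equal(deg2$test$p, 1)

  # NAs are excluded repeats, reported not imputed
  with_na <- aggregate_and_compare(c(a, NA), b)
  expect_equal(with_na$groups$n_excluded, c(1L, 0L))
  expect_equal(with_na$groups$n, c(6L, 5L))
  expect_error(aggregate_and_compare(numeric(0), b), "empty")
})

test_that("tidy and glance expose the comparison", {
  cmp <- aggregate_and_compare(c(1, 1.2, 0.8), c(0, 0.1, -0.1),
                               labels = c("arrest", "short"))
  td <- generics::tidy(cmp)
  expect_equal(td$group, c("arrest", "short"))
  gl <- generics::glance(cmp)
  expect_equal(gl$diff, td$mean[1] - td$mean[2])
  expect_true(gl$p.value < 0.05)
})
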