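# train/test split and the two-model comparison harness

test_that("the split isolates the undiluted calibration set", {
  plate <- default_test_plate()
  s <- split_train_test(plate)
  expect_equal(nrow(s$train), 12)
  expect_equal(nrow(s$test), 78)
  expect_length(intersect(s$train$well_id, s$test$well_id), 0)
  # two replicates each of the 5 standards plus blank
  expect_equal(sum(s$train$sample_type == "standard"), 10)
  expect_equal(sum(s$train$sample_type == "blank"), 2)
  expect_true(all(s$train$dilution_factor == 1))
  # QC wells land in the test set at every dilution
  qc <- dplyr::filter(s$test, sample_type == "qc")
  expect_equal(sort(unique(qc$dilution_factor)), c(1, 1.5, 2, 2.5, 3, 3.5, 4))
  # no unknowns anywhere
  expect_false(any(c(s$train$sample_type, s$test$sample_type) == "unknown"))
})

test_that("degenerate designs are refused by the split", {
  plate <- default_test_plate()
  no_dil1 <- dplyr::filter(plate, !(sample_type == "standard" & dilution_factor == 1))
  expect_error(split_train_test(no_dil1), class = "elisacal_invalid_design")

  only_train <- simulate_plate(
    plate_design(qc_level = NULL, dilution_factors = 1, n_blanks = 2,
                 unknown_dilutions = numeric(0), unknown_replicates = 1),
    seed = 1)
  expect_error(split_train_test(only_train), class = "elisacal_invalid_design")
})

test_that("width ratios behave linearly and respect the band", {
  mk <- function(width, n = 6) {
    tibble::tibble(od = seq_len(n), median = 1,
                   ci50_lo = 1 - width / 4, ci50_hi = 1 + width / 4,
                   ci95_lo = 1 - width / 2, ci95_hi = 1 + width / 2,
                   n_out_of_range = 0L, samples = replicate(n, 1, simplify = FALSE))
  }
  expect_equal(interval_width_ratio(mk(2), mk(2)), 1.0)
  expect_equal(interval_width_ratio(mk(1), mk(2)), 0.5)
  truth <- c(0.05, 0.2, 0.5, 1, 3, 6)
  expect_equal(interval_width_ratio(mk(1), mk(2), truth, band = c(0.1, 2)), 0.5)
  expect_error(interval_width_ratio(mk(1), mk(2), truth, band = c(10, 20)),
               class = "elisacal_invalid_config")
  expect_error(interval_width_ratio(mk(1), mk(2, n = 5)),
               class = "elisacal_invalid_config")
})

test_that("predictive sum of squares matches hand-worked and brute-force values", {
  # two wells, two draws, hand-set errors (1,2) and (0,3): SS = (5, 9)
  preds <- tibble::tibble(
    od = c(1, 1), median = c(1, 1),
    ci50_lo = 0, ci50_hi = 0, ci95_lo = 0, ci95_hi = 0, n_out_of_range = 0L,
    samples = list(c(1, 0), c(2, 3)))
  truth <- c(0, 0)
  ps <- predictive_ss(preds, truth)
  expect_equal(ps$per_draw, c(5, 9))
  expect_equal(ps$mean, 7)

  # perfect predictions: SS identically zero
  perfect <- tibble::tibble(
    od = 1, median = 0.5, ci50_lo = 0.5, ci50_hi = 0.5,
    ci95_lo = 0.5, ci95_hi = 0.5, n_out_of_range = 0L,
    samples = list(rep(0.5, 4)))
  ps0 <- predictive_ss(perfect, 0.5)
  expect_true(all(ps0$per_draw == 0))
  expect_equal(unname(ps0$ci95), c(0, 0))

  # on a real prediction set: independent double loop over draws and wells
  plate <- default_test_plate()
  fit <- fit_standard_curve(prepare_curve_data(plate, "log"), "log")
  draws <- draw_posterior(fit, n_sims = 200, seed = 41)
  test <- split_train_test(plate)$test
  # mid-range ODs: every draw of the tight full-data posterior can invert them
  mid <- which(test$od > 0.4 & test$od < 1.6)[1:10]
  pr <- predict_conc(draws, test$od[mid])
  tr <- test$effective_conc[mid]
  ps <- predictive_ss(pr, tr)
  brute <- numeric(200)
  for (j in 1:200) {
    for (w in 1:10) {
      xs <- pr$samples[[w]]
      fill <- max(xs[!is.na(xs)])
      xj <- if (is.na(xs[j])) fill else xs[j]
      brute[j] <- brute[j] + (xj - tr[w])^2
    }
  }
  # rowSums accumulates in extended precision; agree to the last few ulps
  expect_equal(ps$per_draw, brute, tolerance = 1e-12)
})

test_that("coverage counts interval hits exactly", {
  at_truth <- tibble::tibble(ci50_lo = 1, ci50_hi = 1, ci95_lo = 1, ci95_hi = 1)
  expect_equal(coverage(at_truth, 1, 0.95), 1)
  expect_equal(coverage(at_truth, 2, 0.95), 0)
  mixed <- tibble::tibble(ci50_lo = c(0, 5), ci50_hi = c(2, 6),
                          ci95_lo = c(-1, 4), ci95_hi = c(3, 7))
  expect_equal(coverage(mixed, c(1, 1), 0.95), 0.5)
  expect_equal(coverage(mixed, c(1, 5.5), 0.5), 1)
})

test_that("the comparison pipeline is deterministic and complete", {
  plate <- default_test_plate()
  cmp1 <- compare_models(plate, n_sims = 400, seed = 5)
  cmp2 <- compare_models(plate, n_sims = 400, seed = 5)
  expect_identical(glance(cmp1), glance(cmp2))

  g <- glance(cmp1)
  expect_gt(g$width_ratio_all, 0)
  expect_gt(g$width_ratio_band, 0)
  expect_true(all(c(g$coverage95_log, g$coverage95_conc) >= 0 &
                    c(g$coverage95_log, g$coverage95_conc) <= 1))
  for (fm in c("log", "conc")) {
    expect_lte(cmp1$pss[[fm]]$ci95[["lo"]], cmp1$pss[[fm]]$ci95[["hi"]])
  }
  # goodness-of-fit step used all 90 known wells in both forms
  expect_equal(cmp1$gof$n, c(90, 90))
})

test_that("a single-draw comparison still completes (smoke)", {
  plate <- default_test_plate()
  cmp <- compare_models(plate, n_sims = 1, seed = 6)
  expect_s3_class(cmp, "model_comparison")
  expect_true(is.finite(cmp$width_ratio_all) || is.na(cmp$width_ratio_all))
})

test_that("comparison metrics ignore the ordering of test wells", {
  plate <- default_test_plate()
  # permute the diluted (test-bound) wells; training wells keep their order
  is_test_bound <- with(plate, sample_type %in% c("standard", "qc") & dilution_factor > 1)
  idx <- seq_len(nrow(plate))
  set.seed(13)
  idx[is_test_bound] <- sample(idx[is_test_bound])
  shuffled <- plate[idx, ]
  g1 <- glance(compare_models(plate, n_sims = 300, seed = 7))
  g2 <- glance(compare_models(shuffled, n_sims = 300, seed = 7))
  expect_equal(g1$width_ratio_all, g2$width_ratio_all, tolerance = 1e-12)
  expect_equal(g1$pss_mean_log, g2$pss_mean_log, tolerance = 1e-12)
  expect_equal(g1$coverage95_log, g2$coverage95_log)
})

test_that("log-form predictive intervals are narrower under a log-form truth", {
  # qualitative direction over a handful of seeds (the full study runs in the
  # acceptance suite)
  ratios <- vapply(1:8, function(i) {
    plate <- simulate_plate(noise_sd = 0.1, unknown_truth = 0.9, seed = 900 + i)
    cmp <- suppressWarnings(compare_models(plate, n_sims = 800, seed = 901 + i))
    cmp$width_ratio_all
  }, numeric(1))
  expect_lt(median(ratios, na.rm = TRUE), 1)
})
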