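# forward evaluation, closed-form inversion, reparameterization, self-start

test_that("concentration-scale evaluation matches hand-computed values", {
  p <- fpl_conc_params(2.0, 1.5, 0.8, 0.1)
  # midpoint: OD halfway between the asymptotes at x = alpha3
  expect_equal(eval_fpl_conc(p, 0.8), (2.0 + 0.1) / 2)
  # zero concentration returns the alpha1 asymptote exactly
  expect_identical(eval_fpl_conc(p, 0), 2.0)
  # frozen value from independent arithmetic: 0.1 + 1.9/(1 + 4^1.5)
  expect_equal(eval_fpl_conc(p, 3.2), 0.3111111111111111, tolerance = 1e-12)
  expect_error(eval_fpl_conc(p, -0.1), class = "elisacal_domain_error")
  # decreasing orientation: alpha2 < 0 swaps the x = 0 limit
  pneg <- fpl_conc_params(0.1, -1.5, 0.8, 2.0)
  expect_identical(eval_fpl_conc(pneg, 0), 2.0)
})

test_that("log-scale evaluation matches hand-computed values and saturates", {
  q <- fpl_log_params(A = 2.0, B = 0.1, xmid = -0.2, scal = -0.7)
  expect_equal(eval_fpl_log(q, -0.2), (2.0 + 0.1) / 2)
  # frozen value from independent arithmetic evaluation of the formula
  expect_equal(eval_fpl_log(q, 1.0), 1.710043536799, tolerance = 1e-10)
  # with scal < 0 the z -> +inf asymptote is A, the z -> -inf asymptote B
  expect_equal(eval_fpl_log(q, -0.2 + 100 * 0.7), 2.0, tolerance = 1e-12)
  expect_equal(eval_fpl_log(q, -0.2 - 100 * 0.7), 0.1, tolerance = 1e-12)
  # no overflow anywhere on the line, including infinities
  for (z in c(-1e6, 1e6, -Inf, Inf)) expect_true(is.finite(eval_fpl_log(q, z)))
})

test_that("inversion round-trips both forms across eight decades", {
  set.seed(42)
  xs <- exp(seq(log(1e-4), log(1e4), length.out = 60))
  for (rep in 1:10) {
    p <- random_conc_params()
    expect_equal(invert_fpl_conc(p, eval_fpl_conc(p, xs)), xs, tolerance = 1e-8)
    q <- random_log_params()
    expect_equal(invert_fpl_log(q, eval_fpl_log(q, log(xs))), xs, tolerance = 1e-8)
  }
})

test_that("inversion midpoints and boundary ODs behave as documented", {
  p <- fpl_conc_params(2.0, 1.5, 0.8, 0.1)
  expect_equal(invert_fpl_conc(p, 1.05), 0.8)
  # the zero-concentration asymptote is attained at x = 0
  expect_identical(invert_fpl_conc(p, 2.0), 0)
  expect_error(invert_fpl_conc(p, 0.1), class = "elisacal_out_of_range")
  expect_error(invert_fpl_conc(p, 2.5), class = "elisacal_out_of_range")
  expect_identical(invert_fpl_conc(p, 2.5, out_of_range = "na"), NA_real_)

  q <- fpl_log_params(A = 2.0, B = 0.1, xmid = -0.2, scal = -0.7)
  expect_equal(invert_fpl_log(q, 1.05), exp(-0.2))
  expect_error(invert_fpl_log(q, 2.0), class = "elisacal_out_of_range")
  expect_true(is.na(invert_fpl_log(q, 2.1, out_of_range = "na")))
})

test_that("the two parameterizations define the same curve family", {
  p <- fpl_conc_params(2.0, 1.5, 0.8, 0.1)
  q <- conc_to_log_params(p)
  expect_equal(unclass(q),
               c(A = 0.1, B = 2.0, xmid = log(0.8), scal = -2 / 3),
               tolerance = 1e-14)
  set.seed(7)
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 100))
  for (rep in 1:20) {
    p <- random_conc_params()
    q <- conc_to_log_params(p)
    expect_lt(max(abs(eval_fpl_conc(p, grid) - eval_fpl_log(q, log(grid)))), 1e-12)
    # the mapping is an exact algebraic bijection
    back <- log_to_conc_params(q)
    expect_equal(unclass(back), unclass(p), tolerance = 1e-15)
  }
})

test_that("curves are strictly monotone between their asymptotes", {
  set.seed(11)
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 200))
  for (rep in 1:10) {
    p <- random_conc_params()
    d <- diff(eval_fpl_conc(p, grid))
    expect_true(all(d > 0) || all(d < 0))
    # direction follows the sign of alpha2 (decreasing OD for alpha2 > 0
    # when alpha1 > alpha4)
    expect_equal(unique(sign(d)),
                 -sign(p[["alpha2"]]) * sign(p[["alpha1"]] - p[["alpha4"]]))
  }
})

test_that("self-start seeds converge to the generating curve on clean data", {
  truth_log <- fpl_log_params(0.15, 1.8, log(0.75), -0.35)
  tab <- noise_free_table(truth_log, scale = "log")
  init <- self_start_log(tab)
  fit <- fit_standard_curve(tab, "log", start = init)
  expect_true(fit$converged)
  expect_equal(unclass(fit$params)[names(unclass(truth_log))],
               unclass(truth_log), tolerance = 1e-6)

  truth_conc <- log_to_conc_params(truth_log)
  tabc <- noise_free_table(truth_conc, scale = "conc")
  fitc <- fit_standard_curve(tabc, "conc")
  expect_true(fitc$converged)
  expect_equal(unname(unclass(fitc$params)), unname(unclass(truth_conc)),
               tolerance = 1e-6)
})

test_that("self-start handles both orientations and rejects degenerate input", {
  # increasing assay: OD rises with concentration
  up <- fpl_log_params(A = 1.9, B = 0.2, xmid = 0, scal = 0.5)
  z <- seq(-3, 3, length.out = 12)
  tab <- tibble::tibble(predictor = z, response = eval_fpl_log(up, z))
  fit <- fit_standard_curve(tab, "log")
  expect_true(fit$converged)
  expect_equal(eval_fpl_log(fit$params, z), tab$response, tolerance = 1e-6)

  expect_error(self_start_log(tibble::tibble(predictor = z, response = 1)),
               class = "elisacal_selfstart_error")
  expect_error(self_start_log(tibble::tibble(predictor = c(1, 2, 3),
                                             response = c(1, 2, 3))),
               class = "elisacal_selfstart_error")
  expect_error(self_start_conc(tibble::tibble(predictor = c(0, 0, 0, 1, 2),
                                              response = c(2, 2, 2, 1.5, 1))),
               class = "elisacal_selfstart_error")
})

test_that("coefficient constructors enforce their invariants", {
  expect_error(fpl_conc_params(2, 0, 0.8, 0.1), class = "elisacal_invalid_params")
  expect_error(fpl_conc_params(2, 1, -0.8, 0.1), class = "elisacal_invalid_params")
  expect_error(fpl_conc_params(1, 1, 0.8, 1), class = "elisacal_invalid_params")
  expect_error(fpl_log_params(1, 2, 0, 0), class = "elisacal_invalid_params")
  expect_error(fpl_log_params(1, 1, 0, 1), class = "elisacal_invalid_params")
})
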