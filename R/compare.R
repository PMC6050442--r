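#' Split a plate into calibration (train) and validation (test) wells
#'
#' Reproduces the cross-validation split of the dilution-series design: the
#' training set is the undiluted calibration set a routine assay would use —
#' standard wells at dilution factor 1 plus enough blanks to make two
#' replicates of each of the 6 calibration levels (12 wells under the default
#' design). Every other known-concentration well (diluted standards, QC at all
#' dilutions, remaining blanks) goes to the test set; unknowns are excluded
#' from both.
#'
#' @param plate A plate tibble.
#' @return A list with tibbles `train` and `test`.
#' @export
#' @examples
#' plate <- simulate_plate(seed = 1, unknown_truth = 0.9)
#' lengths(split_train_test(plate))
split_train_test <- function(plate) {
  plate <- plate |>
    dplyr::mutate(effective_conc = .data$nominal_conc / .data$dilution_factor)
  known <- dplyr::filter(plate, .data$sample_type != "unknown")
  std1 <- dplyr::filter(known, .data$sample_type == "standard",
                        .data$dilution_factor == 1)
  if (nrow(std1) == 0) {
    stop_elisacal("design has no undiluted standard wells to train on",
                  "elisacal_invalid_design")
  }
  n_rep <- max(table(std1$nominal_conc))
  blanks <- dplyr::filter(known, .data$sample_type == "blank")
  train <- dplyr::bind_rows(std1, utils::head(blanks, n_rep))
  test <- dplyr::anti_join(known, train, by = "well_id")
  if (nrow(test) == 0) {
    stop_elisacal("no known-concentration wells left to test on",
                  "elisacal_invalid_design")
  }
  list(train = train, test = test)
}

#' Ratio of mean 95% predictive-interval widths between two models
#'
#' The headline comparison statistic: the mean width of the 95% credible
#' intervals of the log-scale model's predictions divided by the same mean for
#' the concentration-scale model, over a common set of test wells. A ratio
#' below 1 means the log-scale curve predicts with less uncertainty. `band`
#' restricts the mean to wells whose true concentration lies inside a closed
#' interval (e.g. `c(0.1, 2)` ug/L, a regulatory range of concern).
#'
#' @param preds_log,preds_conc `conc_prediction` tibbles over the same wells,
#'   in the same order.
#' @param truth True concentrations of those wells (needed when `band` is
#'   used).
#' @param band Optional `c(lo, hi)` restriction on true concentration,
#'   endpoints included.
#' @return A single ratio.
#' @export
interval_width_ratio <- function(preds_log, preds_conc, truth = NULL, band = NULL) {
  if (nrow(preds_log) != nrow(preds_conc)) {
    stop_elisacal("prediction sets must cover the same wells",
                  "elisacal_invalid_config")
  }
  keep <- rep(TRUE, nrow(preds_log))
  if (!is.null(band)) {
    if (is.null(truth) || length(truth) != nrow(preds_log)) {
      stop_elisacal("band restriction needs one truth per prediction",
                    "elisacal_invalid_config")
    }
    keep <- truth >= band[1] & truth <= band[2]
    if (!any(keep)) {
      stop_elisacal("no test wells inside the band", "elisacal_invalid_config")
    }
  }
  w_log <- preds_log$ci95_hi[keep] - preds_log$ci95_lo[keep]
  w_conc <- preds_conc$ci95_hi[keep] - preds_conc$ci95_lo[keep]
  mean(w_log) / mean(w_conc)
}

#' Per-draw predictive sum of squares
#'
#' The out-of-sample accuracy metric on the draw level: for Monte-Carlo draw
#' `j`, \eqn{SS_j = \sum_{wells} (\hat x_j - x_{true})^2} over the test wells,
#' using each draw's raw (unclipped) inversion. The draw-level distribution of
#' `SS_j` is summarized by its mean and central 95% interval; an unstable
#' parameterization betrays itself by occasional draws with astronomically
#' large `SS_j` that inflate the mean far beyond the interval. Draws at which
#' a well's curve could not be inverted contribute that well's largest finite
#' inversion (the most extreme concentration actually attempted), so no draw
#' is silently dropped.
#'
#' @param preds A `conc_prediction` tibble over the test wells (carries the
#'   raw per-draw samples).
#' @param truth True concentrations, one per row of `preds`.
#' @return A list: `per_draw` (length `n_sims`), `mean`, and `ci95`.
#' @export
predictive_ss <- function(preds, truth) {
  if (length(truth) != nrow(preds)) {
    stop_elisacal("need one truth per predicted well", "elisacal_invalid_config")
  }
  mat <- do.call(cbind, preds$samples)       # n_sims x n_wells
  if (is.null(mat)) stop_elisacal("no samples in predictions", "elisacal_invalid_config")
  for (j in seq_len(ncol(mat))) {
    nas <- is.na(mat[, j])
    if (any(nas)) {
      fill <- suppressWarnings(max(mat[!nas, j]))
      if (!is.finite(fill)) fill <- suppressWarnings(max(mat[!is.na(mat)]))
      mat[nas, j] <- fill
    }
  }
  err2 <- (mat - matrix(truth, nrow(mat), ncol(mat), byrow = TRUE))^2
  per_draw <- rowSums(err2)
  # squaring astronomically unstable draws can overflow to Inf; the interval
  # is then taken over the finite draws while the mean reports Inf honestly
  ci <- if (sum(is.finite(per_draw)) >= 2) credible_interval(per_draw, 0.95)
        else range(per_draw) |> setNames(c("lo", "hi"))
  list(per_draw = per_draw, mean = mean(per_draw), ci95 = ci)
}

#' Credible-interval coverage of known concentrations
#'
#' Fraction of test wells whose central credible interval at the given level
#' contains the well's true concentration.
#'
#' @param preds A `conc_prediction` tibble.
#' @param truth True concentrations, one per row.
#' @param level 0.5 or 0.95 (the two intervals the predictions carry).
#' @return Proportion in \[0, 1\].
#' @export
coverage <- function(preds, truth, level = 0.95) {
  if (length(truth) != nrow(preds)) {
    stop_elisacal("need one truth per predicted well", "elisacal_invalid_config")
  }
  if (level == 0.95) {
    mean(truth >= preds$ci95_lo & truth <= preds$ci95_hi)
  } else if (level == 0.5) {
    mean(truth >= preds$ci50_lo & truth <= preds$ci50_hi)
  } else {
    stop_elisacal("predictions carry 50% and 95% intervals only",
                  "elisacal_invalid_config")
  }
}

#' Compare the two 4PL parameterizations end to end
#'
#' The full two-step comparison experiment on one plate. Step 1, goodness of
#' fit: both forms are fit to all known-concentration wells (the log form
#' after the zero-substitution rule) and their RSS and residual SE reported.
#' Step 2, predictive uncertainty: the plate is split by
#' [split_train_test()], each form is refit on the 12-well training set,
#' every test well's concentration is predicted from `n_sims` posterior curve
#' draws, and the prediction sets are reduced to interval-width ratios
#' (overall and inside `band`), per-draw predictive sums of squares, and
#' 95%-interval coverage. Wells where a model cannot invert a single draw are
#' dropped from that comparison (counted in `n_dropped_wells`); width ratios
#' use the wells both models predicted. Deterministic given `seed`.
#'
#' @param plate A plate tibble.
#' @param n_sims Posterior draws per model (default 10000).
#' @param seed Integer seed for the posterior draws.
#' @param zero_policy,c0 Zero-well handling for the log form (see
#'   [prepare_curve_data()]).
#' @param band True-concentration band for the restricted width ratio,
#'   endpoints included (default `c(0.1, 2)` ug/L).
#' @param levels Credible-interval levels (default `c(0.5, 0.95)`).
#' @return An object of class `model_comparison`: list with `gof` (tibble, one
#'   row per form), `width_ratio_all`, `width_ratio_band`, `pss` (per form:
#'   mean and 95% interval), `coverage` (per form), `preds` (per form,
#'   `conc_prediction` over the compared test wells), `test` (the test
#'   wells), `n_dropped_wells`, `converged` (per form), and the configuration.
#'   `glance()` flattens the headline numbers to one row.
#' @export
#' @examples
#' plate <- simulate_plate(seed = 1, unknown_truth = 0.9)
#' cmp <- compare_models(plate, n_sims = 500, seed = 2)
#' glance(cmp)
compare_models <- function(plate, n_sims = 10000, seed = 1,
                           zero_policy = "substitute", c0 = 0.05,
                           band = c(0.1, 2), levels = c(0.5, 0.95)) {
  if (n_sims < 1) stop_elisacal("n_sims must be >= 1", "elisacal_invalid_config")
  if (band[1] >= band[2]) stop_elisacal("band must satisfy lo < hi", "elisacal_invalid_config")

  forms <- c("log", "conc")
  # step 1: goodness of fit on all known wells
  full_fits <- purrr::map(setNames(forms, forms), function(fm) {
    fit_standard_curve(prepare_curve_data(plate, fm, zero_policy, c0), fm)
  })
  gof <- purrr::map_dfr(full_fits, glance)

  # step 2: out-of-sample predictive uncertainty from the 12-point fits
  split <- split_train_test(plate)
  train_fits <- purrr::map(setNames(forms, forms), function(fm) {
    tryCatch(
      fit_standard_curve(prepare_curve_data(split$train, fm, zero_policy, c0), fm),
      error = function(e) NULL)
  })
  converged <- purrr::map_lgl(train_fits, ~ !is.null(.x) && .x$converged && !is.null(.x$cov))

  test <- split$test |>
    dplyr::mutate(effective_conc = .data$nominal_conc / .data$dilution_factor)

  result <- list(gof = gof, full_fits = full_fits, train_fits = train_fits,
                 converged = converged, test = test,
                 config = list(n_sims = n_sims, seed = seed,
                               zero_policy = zero_policy, c0 = c0,
                               band = band, levels = levels))
  class(result) <- "model_comparison"
  if (!all(converged)) {
    warn(paste0("train fit failed to converge for form(s): ",
                paste(forms[!converged], collapse = ", "),
                "; emitting goodness-of-fit results only"))
    result$width_ratio_all <- NA_real_
    result$width_ratio_band <- NA_real_
    return(result)
  }

  # separate substreams per model so draws are independent
  preds <- purrr::imap(train_fits, function(fit, fm) {
    offset <- if (fm == "log") 0L else 1L
    draws <- draw_posterior(fit, n_sims = n_sims, seed = seed * 2L + offset)
    predict_per_well(draws, test$od, levels)
  })

  # compare on wells both models could predict at all
  ok <- !is.na(preds$log$median) & !is.na(preds$conc$median)
  n_dropped <- sum(!ok)
  test_ok <- test[ok, ]
  preds_ok <- purrr::map(preds, ~ .x[ok, ])
  truth <- test_ok$effective_conc

  result$test_all <- test
  result$test <- test_ok
  result$preds <- preds_ok
  result$n_dropped_wells <- n_dropped
  result$width_ratio_all <- interval_width_ratio(preds_ok$log, preds_ok$conc)
  result$width_ratio_band <- tryCatch(
    interval_width_ratio(preds_ok$log, preds_ok$conc, truth, band),
    elisacal_error = function(e) NA_real_)
  result$pss <- purrr::map(preds_ok, function(p) {
    ps <- predictive_ss(p, truth)
    ps$per_draw <- NULL                     # keep the report light
    ps
  })
  result$coverage <- purrr::map(preds_ok, ~ list(
    level50 = coverage(.x, truth, 0.5),
    level95 = coverage(.x, truth, 0.95)))
  result
}

## predict_conc that tolerates per-well total inversion failure: such wells
## get an all-NA row instead of aborting the whole comparison
predict_per_well <- function(draws, od, levels = c(0.5, 0.95)) {
  rows <- lapply(od, function(o) {
    tryCatch(
      predict_conc(draws, o, levels),
      elisacal_prediction_impossible = function(e) {
        tibble::tibble(od = o, median = NA_real_,
                       ci50_lo = NA_real_, ci50_hi = NA_real_,
                       ci95_lo = NA_real_, ci95_hi = NA_real_,
                       n_out_of_range = draws$n_sims,
                       samples = list(rep(NA_real_, draws$n_sims)))
      })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("conc_prediction", class(out))
  attr(out, "model_form") <- draws$fit$model_form
  attr(out, "n_sims") <- draws$n_sims
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<4PL parameterization comparison>\n\nGoodness of fit (all known wells):\n")
  print(as.data.frame(x$gof), row.names = FALSE, digits = 4)
  if (!is.null(x$width_ratio_all) && !is.na(x$width_ratio_all)) {
    cat(sprintf("\nMean 95%% interval width ratio (log / conc): %.3g\n",
                x$width_ratio_all))
    cat(sprintf("  restricted to [%g, %g] ug/L: %.3g\n",
                x$config$band[1], x$config$band[2], x$width_ratio_band))
    for (fm in names(x$pss)) {
      cat(sprintf("Predictive SS, %s form: mean %.4g, 95%% interval (%.4g, %.4g)\n",
                  fm, x$pss[[fm]]$mean, x$pss[[fm]]$ci95[1], x$pss[[fm]]$ci95[2]))
    }
    for (fm in names(x$coverage)) {
      cat(sprintf("95%% interval coverage, %s form: %.3f\n",
                  fm, x$coverage[[fm]]$level95))
    }
    if (x$n_dropped_wells > 0) {
      cat(sprintf("(%d test well(s) dropped: not invertible under one model)\n",
                  x$n_dropped_wells))
    }
  } else {
    cat("\n(predictive comparison unavailable: a training fit did not converge)\n")
  }
  invisible(x)
}

#' One-row summary of a model comparison
#'
#' @param x,... A `model_comparison`; further arguments ignored.
#' @return A one-row tibble with the headline statistics.
#' @method glance model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(
    rss_log = x$gof$rss[x$gof$model_form == "log"],
    rss_conc = x$gof$rss[x$gof$model_form == "conc"],
    sigma_log = x$gof$sigma[x$gof$model_form == "log"],
    sigma_conc = x$gof$sigma[x$gof$model_form == "conc"],
    width_ratio_all = x$width_ratio_all %||% NA_real_,
    width_ratio_band = x$width_ratio_band %||% NA_real_,
    pss_mean_log = if (is.null(x$pss)) NA_real_ else x$pss$log$mean,
    pss_mean_conc = if (is.null(x$pss)) NA_real_ else x$pss$conc$mean,
    coverage95_log = if (is.null(x$coverage)) NA_real_ else x$coverage$log$level95,
    coverage95_conc = if (is.null(x$coverage)) NA_real_ else x$coverage$conc$level95,
    n_dropped_wells = x$n_dropped_wells %||% NA_integer_
  )
}
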