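#' Build the regression table for a standard-curve fit
#'
#' Turns a plate dataset into the (predictor, response) table a 4PL fit
#' consumes. Unknown wells are excluded; each remaining well's effective
#' concentration is `nominal_conc / dilution_factor`. The concentration-scale
#' form keeps zero-concentration wells at `x = 0`. The log-scale form cannot:
#' its predictor is `ln(effective_conc)`, so blanks are handled by
#' `zero_policy` — `"substitute"` reassigns them the low reference
#' concentration `c0` (default 0.05 ug/L, whose natural log of about -3 sits
#' just left of the lowest nonzero standard), `"drop"` removes them.
#'
#' @param plate A plate tibble (see [read_plate_csv()] for the schema).
#' @param model_form `"log"` or `"conc"`.
#' @param zero_policy `"substitute"` or `"drop"`; log form only.
#' @param c0 Substitution concentration for zero wells, ug/L.
#' @return A tibble with columns `well_id`, `true_conc` (effective, after any
#'   substitution), `predictor` (concentration or its natural log), `response`
#'   (OD), and `weight` (reserved; all 1).
#' @export
#' @examples
#' plate <- simulate_plate(seed = 1, unknown_truth = 0.9)
#' prepare_curve_data(plate, "log")
prepare_curve_data <- function(plate, model_form = c("log", "conc"),
                               zero_policy = c("substitute", "drop"),
                               c0 = 0.05) {
  model_form <- match.arg(model_form)
  zero_policy <- match.arg(zero_policy)
  known <- plate |>
    dplyr::filter(.data$sample_type != "unknown") |>
    dplyr::mutate(effective_conc = .data$nominal_conc / .data$dilution_factor)
  if (any(known$effective_conc < 0)) {
    stop_elisacal("negative concentrations in plate", "elisacal_validation_error")
  }
  if (model_form == "conc") {
    out <- known |>
      dplyr::transmute(.data$well_id, true_conc = .data$effective_conc,
                       predictor = .data$effective_conc,
                       response = .data$od, weight = 1)
  } else {
    if (zero_policy == "substitute") {
      if (c0 <= 0) stop_elisacal("c0 must be > 0", "elisacal_validation_error")
      known$effective_conc[known$effective_conc == 0] <- c0
    } else {
      known <- dplyr::filter(known, .data$effective_conc > 0)
    }
    out <- known |>
      dplyr::transmute(.data$well_id, true_conc = .data$effective_conc,
                       predictor = log(.data$effective_conc),
                       response = .data$od, weight = 1)
  }
  if (nrow(out) < 5) {
    stop_elisacal("need at least 5 known-concentration wells", "elisacal_validation_error")
  }
  out
}

#' Fit a four-parameter logistic standard curve
#'
#' Nonlinear least-squares estimation of either 4PL form by
#' Levenberg-Marquardt (via [minpack.lm::nlsLM()]), seeded by the package's
#' self-starters unless `start` is given. The fit is unconstrained: no bounds
#' or orderings are imposed on the coefficients, so any instability of a
#' parameterization shows up in the fit and its covariance rather than being
#' masked. Convergence is declared on a relative residual-sum-of-squares
#' change below 1e-10, with at most 500 iterations; a fit that exhausts the
#' iteration budget is returned with `converged = FALSE` rather than raising.
#'
#' The coefficient covariance is the usual large-sample approximation
#' `sigma^2 (J'J)^-1` with `J` the Jacobian of fitted values at the optimum,
#' `sigma^2 = RSS / (n - 4)`.
#'
#' @param data A regression table from [prepare_curve_data()], or any data
#'   frame with numeric `predictor` and `response` columns (plus optionally
#'   `true_conc`).
#' @param model_form `"log"` (predictor is natural-log concentration) or
#'   `"conc"` (predictor is concentration).
#' @param start Optional starting coefficients ([fpl_log_params()] or
#'   [fpl_conc_params()] matching `model_form`); default: self-start.
#' @return An object of class `fpl_fit`: a list with elements `model_form`,
#'   `params` (classed coefficient set), `cov` (4x4), `sigma_hat`, `df`,
#'   `rss`, `residuals`, `fitted`, `converged`, `n`, and `data`. Supports
#'   [tidy()], [glance()], [augment()], `predict()` and [autoplot()].
#' @export
#' @examples
#' plate <- simulate_plate(seed = 1, unknown_truth = 0.9)
#' fit <- fit_standard_curve(prepare_curve_data(plate, "log"), "log")
#' glance(fit)
fit_standard_curve <- function(data, model_form = c("log", "conc"), start = NULL) {
  model_form <- match.arg(model_form)
  if (!all(c("predictor", "response") %in% names(data))) {
    stop_elisacal("data needs 'predictor' and 'response' columns",
                  "elisacal_validation_error")
  }
  df_fit <- data.frame(predictor = as.numeric(data$predictor),
                       response = as.numeric(data$response))
  if (anyNA(df_fit) || any(!is.finite(df_fit$predictor))) {
    stop_elisacal("predictor/response must be finite and complete",
                  "elisacal_validation_error")
  }
  if (nrow(df_fit) < 5) {
    stop_elisacal("need at least 5 points to fit 4 coefficients",
                  "elisacal_validation_error")
  }

  if (is.null(start)) {
    start <- if (model_form == "log") self_start_log(df_fit) else self_start_conc(df_fit)
  }
  start <- as.list(unclass(start))

  formula <- if (model_form == "log") {
    response ~ A + (B - A) / (1 + exp((xmid - predictor) / scal))
  } else {
    response ~ alpha4 + (alpha1 - alpha4) / (1 + (predictor / alpha3)^alpha2)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)
  # retry ladder: an exactly-placed self-start on degenerate (e.g. noise-free,
  # symmetric) data can present a singular gradient; a deterministic relative
  # jitter of the start recovers those corner cases
  fit <- NULL
  for (eps in c(0, 1e-3, 3e-2)) {
    start_try <- lapply(seq_along(start), function(k) {
      v <- start[[k]]
      (if (v == 0) eps else v * (1 + eps * c(1, -1, 1, -1)[k]))
    })
    names(start_try) <- names(start)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(formula, data = df_fit, start = start_try, control = ctrl)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
  }

  if (inherits(fit, "error")) {
    # optimizer could not produce an iterate: report the starting values,
    # flagged unconverged, with no covariance
    coefs <- unlist(start)
    fitted <- eval_curve(as_fpl_params(coefs, model_form), model_form, df_fit$predictor)
    res <- df_fit$response - fitted
    return(new_fpl_fit(model_form, coefs, cov = NULL, res = res, fitted = fitted,
                       converged = FALSE, data = data))
  }

  coefs <- coef(fit)
  converged <- isTRUE(fit$convInfo$isConv)
  res <- as.numeric(resid(fit))
  fitted <- df_fit$response - res
  covm <- tryCatch({
    sm <- summary(fit)
    sm$cov.unscaled * sm$sigma^2
  }, error = function(e) NULL)
  new_fpl_fit(model_form, coefs, covm, res, fitted, converged, data)
}

new_fpl_fit <- function(model_form, coefs, cov, res, fitted, converged, data) {
  n <- length(res)
  rss <- sum(res^2)
  dfree <- n - 4L
  params <- tryCatch(as_fpl_params(coefs, model_form), error = function(e) NULL)
  structure(list(
    model_form = model_form,
    params = params,
    coefficients = coefs,
    cov = cov,
    sigma_hat = if (dfree > 0) sqrt(rss / dfree) else NA_real_,
    df = dfree,
    rss = rss,
    residuals = res,
    fitted = fitted,
    converged = converged,
    n = n,
    data = tibble::as_tibble(data)
  ), class = "fpl_fit")
}

eval_curve <- function(params, model_form, predictor) {
  if (model_form == "log") eval_fpl_log(params, predictor)
  else eval_fpl_conc(params, predictor)
}

invert_curve <- function(params, model_form, od, out_of_range = "na") {
  if (model_form == "log") invert_fpl_log(params, od, out_of_range)
  else invert_fpl_conc(params, od, out_of_range)
}

#' @export
print.fpl_fit <- function(x, ...) {
  cat(sprintf("<4PL fit, %s scale>  n = %d, converged: %s\n",
              x$model_form, x$n, x$converged))
  print(signif(x$coefficients, 5))
  cat(sprintf("RSS %.4g, residual SE %.4g on %d df\n", x$rss, x$sigma_hat, x$df))
  invisible(x)
}

#' Predict ODs from a fitted standard curve
#'
#' @param object An `fpl_fit`.
#' @param newdata Optional data frame with a `predictor` column (on the fit's
#'   own scale); default: the training data.
#' @param ... Unused.
#' @return Numeric vector of fitted ODs.
#' @export
predict.fpl_fit <- function(object, newdata = NULL, ...) {
  pred <- if (is.null(newdata)) object$data$predictor else newdata$predictor
  eval_curve(object$params, object$model_form, pred)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a 4PL fit
#'
#' `tidy()` returns one row per coefficient with standard errors from the
#' large-sample covariance; `glance()` returns a one-row model summary;
#' `augment()` returns the training data with fitted values and residuals.
#'
#' @param x,... An `fpl_fit` object; further arguments ignored.
#' @return A tibble.
#' @method tidy fpl_fit
#' @export
tidy.fpl_fit <- function(x, ...) {
  se <- if (is.null(x$cov)) rep(NA_real_, 4) else sqrt(pmax(diag(x$cov), 0))
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients),
                 std.error = se)
}

#' @rdname tidy.fpl_fit
#' @method glance fpl_fit
#' @export
glance.fpl_fit <- function(x, ...) {
  tibble::tibble(model_form = x$model_form, n = x$n, df.residual = x$df,
                 rss = x$rss, sigma = x$sigma_hat, converged = x$converged)
}

#' @rdname tidy.fpl_fit
#' @method augment fpl_fit
#' @export
augment.fpl_fit <- function(x, ...) {
  x$data |>
    dplyr::mutate(.fitted = x$fitted, .resid = x$residuals)
}

#' Residual diagnostics for a standard-curve fit
#'
#' Summaries of the checks a regression on plate data should pass: residual
#' mean near zero, a roughly normal residual distribution, and constant
#' residual spread. Normality is scored as the correlation between residual
#' order statistics and normal quantiles (the numeric analogue of a Q-Q
#' plot); heteroscedasticity as the Spearman correlation between absolute
#' residuals and fitted values.
#'
#' @param fit An `fpl_fit`.
#' @return A one-row tibble: `mean_resid`, `sigma`, `rss`, `normality_score`,
#'   `heteroscedasticity_score`, `n`, `df`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "fpl_fit"))
  r <- fit$residuals
  n <- length(r)
  norm_score <- if (n >= 3 && sd(r) > 0) {
    cor(sort(r), qnorm(stats::ppoints(n)))
  } else NA_real_
  het_score <- if (n >= 3 && sd(r) > 0 && sd(fit$fitted) > 0) {
    suppressWarnings(cor(abs(r), fit$fitted, method = "spearman"))
  } else NA_real_
  tibble::tibble(mean_resid = mean(r), sigma = fit$sigma_hat, rss = fit$rss,
                 normality_score = norm_score,
                 heteroscedasticity_score = het_score,
                 n = n, df = fit$df)
}
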