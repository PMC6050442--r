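#' Draw standard curves from the approximate joint posterior of a fit
#'
#' Normal-theory Monte-Carlo draws of the curve coefficients, the classical
#' simulation recipe for nonlinear-regression predictive uncertainty: for each
#' draw the residual scale is sampled as
#' \eqn{\sigma_j = \hat\sigma \sqrt{df / \chi^2_{df}}} and the coefficient
#' vector conditionally as multivariate normal
#' \eqn{\theta_j \sim N(\hat\theta, (\sigma_j/\hat\sigma)^2 \, \widehat{cov})}.
#' Each draw is one plausible standard curve consistent with the calibration
#' data. Draws are unconstrained — a drawn curve may be an invalid sigmoid
#' (e.g. shape through zero); such draws are kept, because downstream
#' inversion behaviour under instability is exactly what the draws are meant
#' to expose.
#'
#' @param fit A converged `fpl_fit` with an available covariance.
#' @param n_sims Number of draws (default 10000).
#' @param seed Integer seed; the same `(fit, n_sims, seed)` reproduces the
#'   draws exactly.
#' @return An object of class `fpl_posterior`: list with `coef_draws`
#'   (`n_sims` x 4 matrix), `sigma_draws`, `n_sims`, `seed`, and `fit`.
#' @seealso [predict_conc()]
#' @export
#' @examples
#' plate <- simulate_plate(seed = 1, unknown_truth = 0.9)
#' fit <- fit_standard_curve(prepare_curve_data(plate, "log"), "log")
#' draws <- draw_posterior(fit, n_sims = 1000, seed = 42)
draw_posterior <- function(fit, n_sims = 10000, seed = NULL) {
  stopifnot(inherits(fit, "fpl_fit"))
  if (n_sims < 1) stop_elisacal("n_sims must be >= 1", "elisacal_invalid_config")
  if (is.null(fit$cov)) {
    stop_elisacal("fit has no coefficient covariance (singular Jacobian?)",
                  "elisacal_no_covariance")
  }
  if (fit$df < 1) stop_elisacal("need residual df >= 1", "elisacal_invalid_config")
  if (!is.null(seed)) set.seed(seed)

  theta <- as.numeric(fit$coefficients)
  sigma_draws <- fit$sigma_hat * sqrt(fit$df / rchisq(n_sims, df = fit$df))
  # scale-free root of cov; eigendecomposition tolerates the tiny negative
  # eigenvalues a near-singular J'J can produce
  eg <- eigen(fit$cov / fit$sigma_hat^2, symmetric = TRUE)
  root <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 4)
  zmat <- matrix(rnorm(n_sims * 4), n_sims, 4)
  coef_draws <- matrix(theta, n_sims, 4, byrow = TRUE) +
    (zmat %*% t(root)) * sigma_draws
  colnames(coef_draws) <- names(fit$coefficients)
  structure(list(coef_draws = coef_draws, sigma_draws = sigma_draws,
                 n_sims = n_sims, seed = seed, fit = fit),
            class = "fpl_posterior")
}

#' @export
print.fpl_posterior <- function(x, ...) {
  cat(sprintf("<%d posterior curve draws, %s scale>\n", x$n_sims, x$fit$model_form))
  print(signif(colMeans(x$coef_draws), 5))
  invisible(x)
}

#' Central credible interval from Monte-Carlo samples
#'
#' Empirical central interval covering the middle `level` fraction of the
#' samples: quantiles at `(1-level)/2` and `1-(1-level)/2`, with linear
#' interpolation between order statistics.
#'
#' @param samples Numeric vector; at least 2 finite values.
#' @param level Coverage level in (0, 1).
#' @return Named numeric `c(lo, hi)`.
#' @export
#' @examples
#' credible_interval(rnorm(1e4), 0.95)
credible_interval <- function(samples, level = 0.95) {
  if (level <= 0 || level >= 1) {
    stop_elisacal("level must be in (0, 1)", "elisacal_invalid_config")
  }
  s <- samples[is.finite(samples)]
  if (length(s) < 2) {
    stop_elisacal("need at least 2 finite samples", "elisacal_invalid_config")
  }
  a <- (1 - level) / 2
  q <- quantile(s, c(a, 1 - a), names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Monte-Carlo inverse prediction of concentration from observed ODs
#'
#' Inverts every drawn standard curve at each observed OD via the closed-form
#' 4PL inverse, giving `n_sims` plausible concentrations per OD; summarizes
#' them with the median and central 50%/95% credible intervals. Draws whose
#' curve cannot be inverted at the OD (the OD falls outside the drawn curve's
#' open asymptote range, or the drawn coefficients yield no real solution) are
#' counted in `n_out_of_range` and excluded from the quantiles; finite
#' inversions are never clipped, however extreme. By default only curve-fit
#' uncertainty is propagated; `add_od_noise = TRUE` additionally perturbs the
#' OD by `N(0, sigma_j^2)` per draw for full predictive uncertainty.
#'
#' The inversion itself uses no random numbers, so predictions for a set of
#' ODs are independent of the order in which they are made; with
#' `add_od_noise = TRUE` each OD gets its own seeded noise stream derived from
#' `noise_seed` and its index.
#'
#' @param draws An `fpl_posterior` from [draw_posterior()].
#' @param od Observed optical density value(s).
#' @param levels Credible-interval levels; the first two (sorted) populate the
#'   `ci50`/`ci95`-style columns. Default `c(0.5, 0.95)`.
#' @param add_od_noise Add per-draw Gaussian OD noise (default `FALSE`).
#' @param noise_seed Seed for the optional OD noise.
#' @return A `conc_prediction` tibble, one row per OD: `od`, `median`,
#'   `ci50_lo`, `ci50_hi`, `ci95_lo`, `ci95_hi`, `n_out_of_range`, and a
#'   `samples` list-column holding all `n_sims` draws (`NA` where
#'   non-invertible). Raises `elisacal_prediction_impossible` if every draw is
#'   out of range for some OD.
#' @export
#' @examples
#' plate <- simulate_plate(seed = 1, unknown_truth = 0.9)
#' fit <- fit_standard_curve(prepare_curve_data(plate, "log"), "log")
#' draws <- draw_posterior(fit, n_sims = 2000, seed = 42)
#' predict_conc(draws, od = 1.0)
predict_conc <- function(draws, od, levels = c(0.5, 0.95),
                         add_od_noise = FALSE, noise_seed = NULL) {
  stopifnot(inherits(draws, "fpl_posterior"))
  if (any(!is.finite(od))) stop_elisacal("od must be finite", "elisacal_invalid_config")
  if (any(levels <= 0 | levels >= 1)) {
    stop_elisacal("levels must be in (0, 1)", "elisacal_invalid_config")
  }
  levels <- sort(levels)
  model_form <- draws$fit$model_form

  sample_mat <- invert_draws(draws, od, add_od_noise, noise_seed)

  # lapply, not purrr::map: the prediction-impossible condition must reach
  # callers with its class intact, not wrapped in an indexed-error chain
  rows <- lapply(seq_along(od), function(i) {
    s <- sample_mat[, i]
    finite <- s[is.finite(s)]
    if (length(finite) == 0) {
      stop_elisacal(
        sprintf("no drawn curve can be inverted at OD %g", od[i]),
        "elisacal_prediction_impossible",
        od = od[i], params = draws$fit$params)
    }
    ci_lo <- if (length(finite) >= 2) credible_interval(finite, levels[1]) else rep(finite[1], 2)
    ci_hi <- if (length(finite) >= 2) credible_interval(finite, levels[min(2, length(levels))]) else rep(finite[1], 2)
    tibble::tibble(od = od[i], median = median(finite),
                   ci50_lo = ci_lo[[1]], ci50_hi = ci_lo[[2]],
                   ci95_lo = ci_hi[[1]], ci95_hi = ci_hi[[2]],
                   n_out_of_range = sum(!is.finite(s)),
                   samples = list(ifelse(is.finite(s), s, NA_real_)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("conc_prediction", class(out))
  attr(out, "model_form") <- model_form
  attr(out, "n_sims") <- draws$n_sims
  out
}

## n_sims x length(od) matrix of per-draw inversions (NA = non-invertible)
invert_draws <- function(draws, od, add_od_noise = FALSE, noise_seed = NULL) {
  model_form <- draws$fit$model_form
  cd <- draws$coef_draws
  n_sims <- draws$n_sims
  out <- matrix(NA_real_, n_sims, length(od))
  for (i in seq_along(od)) {
    od_i <- rep(od[i], n_sims)
    if (add_od_noise) {
      if (!is.null(noise_seed)) set.seed(noise_seed + i - 1L)
      od_i <- od_i + rnorm(n_sims, sd = draws$sigma_draws)
    }
    out[, i] <- if (model_form == "log") {
      invert_log_rows(cd, od_i)
    } else {
      invert_conc_rows(cd, od_i)
    }
  }
  out
}

## vectorized over rows of a coefficient matrix; pure arithmetic, NA on any
## domain violation, no clipping
invert_log_rows <- function(cd, od) {
  A <- cd[, "A"]; B <- cd[, "B"]; xmid <- cd[, "xmid"]; scal <- cd[, "scal"]
  lo <- pmin(A, B); hi <- pmax(A, B)
  ratio <- (B - A) / (od - A) - 1
  x <- suppressWarnings(exp(xmid - scal * log(ratio)))   # NaN for bad draws
  bad <- od <= lo | od >= hi | !is.finite(x)
  x[bad] <- NA_real_
  x
}

invert_conc_rows <- function(cd, od) {
  a1 <- cd[, "alpha1"]; a2 <- cd[, "alpha2"]
  a3 <- cd[, "alpha3"]; a4 <- cd[, "alpha4"]
  lo <- pmin(a1, a4); hi <- pmax(a1, a4)
  base <- (a1 - a4) / (od - a4) - 1
  x <- suppressWarnings(a3 * base^(1 / a2))
  x[od == a1] <- 0
  bad <- (od <= lo | od >= hi | !is.finite(x) | x < 0) & od != a1
  x[bad] <- NA_real_
  x
}

#' @export
print.conc_prediction <- function(x, ...) {
  cat(sprintf("<concentration predictions, %s-scale curve, %d draws each>\n",
              attr(x, "model_form") %||% "?", attr(x, "n_sims") %||% NA))
  NextMethod()
}

#' Tidy concentration predictions
#'
#' Drops the raw `samples` list-column, leaving the per-OD summary table.
#'
#' @param x,... A `conc_prediction`; further arguments ignored.
#' @return A plain tibble.
#' @method tidy conc_prediction
#' @export
tidy.conc_prediction <- function(x, ...) {
  out <- dplyr::select(tibble::as_tibble(x), -"samples")
  class(out) <- setdiff(class(out), "conc_prediction")
  out
}
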