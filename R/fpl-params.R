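#' Four-parameter logistic coefficients, concentration scale
#'
#' Constructs the coefficient set of the 4PL curve defined directly on the
#' concentration scale,
#' \deqn{y = \alpha_4 + \frac{\alpha_1 - \alpha_4}{1 + (x/\alpha_3)^{\alpha_2}},}
#' the parameterization most ELISA kit software fits. `alpha1` is the optical
#' density (OD) at zero concentration, `alpha4` the OD asymptote at infinite
#' concentration, `alpha3` the concentration (ug/L) at which the OD is halfway
#' between the two, and `alpha2` the shape exponent. No ordering between
#' `alpha1` and `alpha4` is imposed: a competitive assay has `alpha1 > alpha4`
#' (OD falls as concentration rises) but the opposite orientation is equally
#' valid and is carried by the sign of `alpha2`.
#'
#' @param alpha1 OD at zero concentration (dimensionless absorbance).
#' @param alpha2 Shape exponent; any nonzero real.
#' @param alpha3 Concentration at mid-response, ug/L; must be positive.
#' @param alpha4 OD asymptote at infinite concentration.
#'
#' @return An object of class `fpl_conc_params`: a named numeric vector with
#'   elements `alpha1`, `alpha2`, `alpha3`, `alpha4`.
#' @seealso [fpl_log_params()], [conc_to_log_params()], [eval_fpl_conc()]
#' @export
#' @examples
#' fpl_conc_params(2, 1.5, 0.8, 0.1)
fpl_conc_params <- function(alpha1, alpha2, alpha3, alpha4) {
  p <- c(alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2),
         alpha3 = as.numeric(alpha3), alpha4 = as.numeric(alpha4))
  if (anyNA(p) || any(!is.finite(p))) {
    stop_elisacal("all four coefficients must be finite", "elisacal_invalid_params")
  }
  if (p[["alpha3"]] <= 0) {
    stop_elisacal("alpha3 (mid-response concentration) must be > 0", "elisacal_invalid_params")
  }
  if (p[["alpha2"]] == 0) {
    stop_elisacal("alpha2 (shape) must be nonzero", "elisacal_invalid_params")
  }
  if (p[["alpha1"]] == p[["alpha4"]]) {
    stop_elisacal("alpha1 and alpha4 (the asymptotes) must differ", "elisacal_invalid_params")
  }
  structure(p, class = "fpl_conc_params")
}

#' Four-parameter logistic coefficients, log-concentration scale
#'
#' Constructs the coefficient set of the 4PL curve on the natural-log
#' concentration scale \eqn{z = \ln x},
#' \deqn{y = A + \frac{B - A}{1 + e^{(x_{mid} - z)/scal}},}
#' the `SSfpl`-style parameterization. `A` and `B` are the two OD asymptotes,
#' `xmid` the log concentration at mid-response, and `scal` the shape/scale in
#' log-concentration units. Which asymptote is approached as \eqn{z \to -\infty}
#' depends on the sign of `scal` (for `scal < 0` it is `B`), so no ordering
#' between `A` and `B` is imposed.
#'
#' @param A,B OD asymptotes (dimensionless absorbance); must differ.
#' @param xmid Natural-log concentration at mid-response.
#' @param scal Shape/scale parameter (log-concentration units); nonzero.
#'
#' @return An object of class `fpl_log_params`: a named numeric vector with
#'   elements `A`, `B`, `xmid`, `scal`.
#' @seealso [fpl_conc_params()], [log_to_conc_params()], [eval_fpl_log()]
#' @export
#' @examples
#' # competitive curve: OD 1.8 near zero concentration falling to 0.15
#' fpl_log_params(A = 0.15, B = 1.8, xmid = log(0.75), scal = -0.35)
fpl_log_params <- function(A, B, xmid, scal) {
  p <- c(A = as.numeric(A), B = as.numeric(B),
         xmid = as.numeric(xmid), scal = as.numeric(scal))
  if (anyNA(p) || any(!is.finite(p))) {
    stop_elisacal("all four coefficients must be finite", "elisacal_invalid_params")
  }
  if (p[["scal"]] == 0) {
    stop_elisacal("scal (shape) must be nonzero", "elisacal_invalid_params")
  }
  if (p[["A"]] == p[["B"]]) {
    stop_elisacal("A and B (the asymptotes) must differ", "elisacal_invalid_params")
  }
  structure(p, class = "fpl_log_params")
}

#' @export
print.fpl_conc_params <- function(x, ...) {
  cat("<4PL coefficients, concentration scale>\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.fpl_log_params <- function(x, ...) {
  cat("<4PL coefficients, log-concentration scale>\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Map 4PL coefficients between the two parameterizations
#'
#' The two 4PL forms describe the same curve family for positive
#' concentrations. `conc_to_log_params()` maps concentration-scale coefficients
#' to the log-scale set `(A = alpha4, B = alpha1, xmid = ln(alpha3),
#' scal = -1/alpha2)`; `log_to_conc_params()` is its exact algebraic inverse.
#' After mapping, `eval_fpl_log(p_log, log(x))` equals
#' `eval_fpl_conc(p_conc, x)` for every `x > 0`.
#'
#' @param params An [fpl_conc_params()] (for `conc_to_log_params`) or
#'   [fpl_log_params()] (for `log_to_conc_params`) object.
#' @return The coefficient set in the other parameterization.
#' @export
#' @examples
#' p <- fpl_conc_params(2, 1.5, 0.8, 0.1)
#' q <- conc_to_log_params(p)
#' all.equal(eval_fpl_log(q, log(3.2)), eval_fpl_conc(p, 3.2))
conc_to_log_params <- function(params) {
  stopifnot(inherits(params, "fpl_conc_params"))
  fpl_log_params(A = params[["alpha4"]], B = params[["alpha1"]],
                 xmid = log(params[["alpha3"]]), scal = -1 / params[["alpha2"]])
}

#' @rdname conc_to_log_params
#' @export
log_to_conc_params <- function(params) {
  stopifnot(inherits(params, "fpl_log_params"))
  fpl_conc_params(alpha1 = params[["B"]], alpha2 = -1 / params[["scal"]],
                  alpha3 = exp(params[["xmid"]]), alpha4 = params[["A"]])
}

## coerce a bare named vector (e.g. nls coefficients) into the classed set
as_fpl_params <- function(coefs, model_form) {
  if (model_form == "conc") {
    fpl_conc_params(coefs[["alpha1"]], coefs[["alpha2"]], coefs[["alpha3"]], coefs[["alpha4"]])
  } else {
    fpl_log_params(coefs[["A"]], coefs[["B"]], coefs[["xmid"]], coefs[["scal"]])
  }
}
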