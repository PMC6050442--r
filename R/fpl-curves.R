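#' Evaluate a 4PL curve
#'
#' Forward evaluation of the four-parameter logistic curve in either
#' parameterization. `eval_fpl_conc()` takes concentrations `x >= 0` (at
#' `x = 0` it returns the zero-concentration asymptote exactly);
#' `eval_fpl_log()` takes natural-log concentrations `z` anywhere on the real
#' line, including `-Inf`/`Inf`, and saturates at the corresponding asymptote
#' without overflowing.
#'
#' @param params Coefficients: [fpl_conc_params()] for `eval_fpl_conc()`,
#'   [fpl_log_params()] for `eval_fpl_log()`.
#' @param x Concentration(s), ug/L; must be `>= 0`.
#' @param z Natural-log concentration(s); any real, `+/-Inf` allowed.
#' @return Numeric vector of optical densities, same length as the input.
#' @seealso [invert_fpl_conc()], [invert_fpl_log()]
#' @export
#' @examples
#' p <- fpl_conc_params(2, 1.5, 0.8, 0.1)
#' eval_fpl_conc(p, c(0, 0.8, 3.2))
#' eval_fpl_log(conc_to_log_params(p), log(c(0.8, 3.2)))
eval_fpl_conc <- function(params, x) {
  stopifnot(inherits(params, "fpl_conc_params"))
  if (any(x < 0, na.rm = TRUE)) {
    stop_elisacal("concentrations must be >= 0", "elisacal_domain_error")
  }
  a1 <- params[["alpha1"]]; a2 <- params[["alpha2"]]
  a3 <- params[["alpha3"]]; a4 <- params[["alpha4"]]
  out <- a4 + (a1 - a4) / (1 + (x / a3)^a2)
  # (0/a3)^a2 is 0 for a2 > 0 and Inf for a2 < 0: both limits are exact, but
  # force the a2 > 0 branch to a1 so no 0*Inf NaN can leak in
  zero <- !is.na(x) & x == 0
  if (any(zero)) out[zero] <- if (a2 > 0) a1 else a4
  out
}

#' @rdname eval_fpl_conc
#' @export
eval_fpl_log <- function(params, z) {
  stopifnot(inherits(params, "fpl_log_params"))
  A <- params[["A"]]; B <- params[["B"]]
  xmid <- params[["xmid"]]; scal <- params[["scal"]]
  # plogis saturates cleanly for arguments of any magnitude
  A + (B - A) * plogis((z - xmid) / scal)
}

#' Invert a 4PL curve at an observed optical density
#'
#' Closed-form inverse prediction: the concentration at which the curve attains
#' an observed OD. The OD must lie strictly between the two asymptotes; as the
#' one exception, `eval_fpl_conc()` attains the zero-concentration asymptote at
#' `x = 0`, so `invert_fpl_conc()` maps that OD to 0. ODs at or beyond the
#' asymptotes are out of range: depending on `out_of_range` they raise an error
#' (class `elisacal_out_of_range`, carrying the violated bounds) or return
#' `NA`. Values are never clipped to the curve's range — extreme but valid
#' inversions are returned raw.
#'
#' @inheritParams eval_fpl_conc
#' @param od Observed optical density value(s).
#' @param out_of_range `"error"` (default) or `"na"`: what to do with ODs at or
#'   beyond the asymptotes.
#' @return Concentration(s), ug/L.
#' @export
#' @examples
#' p <- fpl_conc_params(2, 1.5, 0.8, 0.1)
#' invert_fpl_conc(p, 1.05)           # mid-response OD maps to alpha3
#' invert_fpl_conc(p, eval_fpl_conc(p, 1.7))
invert_fpl_conc <- function(params, od, out_of_range = c("error", "na")) {
  stopifnot(inherits(params, "fpl_conc_params"))
  out_of_range <- match.arg(out_of_range)
  a1 <- params[["alpha1"]]; a2 <- params[["alpha2"]]
  a3 <- params[["alpha3"]]; a4 <- params[["alpha4"]]
  lo <- min(a1, a4); hi <- max(a1, a4)
  bad <- !is.na(od) & (od <= lo | od >= hi) & od != a1
  if (any(bad) && out_of_range == "error") {
    stop_elisacal(
      sprintf("OD %g outside the open asymptote interval (%g, %g)",
              od[bad][1], lo, hi),
      "elisacal_out_of_range", bounds = c(lo, hi))
  }
  x <- suppressWarnings(a3 * ((a1 - a4) / (od - a4) - 1)^(1 / a2))
  x[!is.na(od) & od == a1] <- 0       # zero-concentration asymptote is attained
  x[bad] <- NA_real_
  x
}

#' @rdname invert_fpl_conc
#' @export
invert_fpl_log <- function(params, od, out_of_range = c("error", "na")) {
  stopifnot(inherits(params, "fpl_log_params"))
  out_of_range <- match.arg(out_of_range)
  A <- params[["A"]]; B <- params[["B"]]
  xmid <- params[["xmid"]]; scal <- params[["scal"]]
  lo <- min(A, B); hi <- max(A, B)
  bad <- !is.na(od) & (od <= lo | od >= hi)
  if (any(bad) && out_of_range == "error") {
    stop_elisacal(
      sprintf("OD %g outside the open asymptote interval (%g, %g)",
              od[bad][1], lo, hi),
      "elisacal_out_of_range", bounds = c(lo, hi))
  }
  x <- suppressWarnings(exp(xmid - scal * log((B - A) / (od - A) - 1)))
  x[bad] <- NA_real_
  x
}

#' Self-starting initial values for a 4PL fit
#'
#' Heuristic initialization from the data's geometry, in the spirit of nls
#' self-starter functions: the two asymptotes are the mean ODs of the 2
#' smallest- and 2 largest-predictor points; the midpoint is the predictor
#' whose OD is nearest the asymptote midpoint; the shape comes from the slope
#' of a logit-linearization of the scaled response. Both assay orientations
#' (OD rising or falling with concentration) are handled; the trend's sign is
#' inferred from the data.
#'
#' `self_start_log()` works on (log-concentration, OD) pairs;
#' `self_start_conc()` on (concentration, OD) pairs, where zero concentrations
#' contribute to the low-concentration asymptote estimate but are excluded
#' from the log-scale shape regression.
#'
#' @param data A data frame with numeric columns `predictor` and `response`
#'   (concentration or log-concentration, and OD).
#' @return [fpl_conc_params()] or [fpl_log_params()] initial values. Degenerate
#'   input (fewer than 5 distinct predictors, or essentially constant OD)
#'   raises an error of class `elisacal_selfstart_error`.
#' @export
#' @examples
#' truth <- fpl_log_params(0.15, 1.8, log(0.75), -0.35)
#' z <- log(seq(0.05, 5, length.out = 9))
#' self_start_log(data.frame(predictor = z, response = eval_fpl_log(truth, z)))
self_start_log <- function(data) {
  z <- data$predictor; y <- data$response
  check_selfstart_input(z, y)
  ord <- order(z); z <- z[ord]; y <- y[ord]
  n <- length(z)
  left <- mean(y[1:2]); right <- mean(y[(n - 1):n])   # asymptotes from extremes
  mid_od <- (left + right) / 2
  xmid <- z[which.min(abs(y - mid_od))]
  # logit-linearization: with A = right, B = left the scaled response
  # p = (y - A)/(B - A) equals plogis((z - xmid)/scal), so the slope of
  # logit(p) against z is 1/scal; p decays from 1 to 0 by construction,
  # giving scal < 0, which is a valid representation of either orientation
  # (swapping A/B and negating scal leaves the curve unchanged)
  p <- (y - right) / (left - right)
  keep <- is.finite(p) & p > 0.01 & p < 0.99
  if (sum(keep) >= 3) {
    slope <- coef(stats::lm(qlogis(p[keep]) ~ z[keep]))[[2]]
  } else {
    slope <- -1 / max(sd(z), 0.5)
  }
  if (!is.finite(slope) || slope == 0) slope <- -1
  fpl_log_params(A = right, B = left, xmid = xmid, scal = 1 / slope)
}

#' @rdname self_start_log
#' @export
self_start_conc <- function(data) {
  x <- data$predictor; y <- data$response
  check_selfstart_input(x, y)
  if (any(x < 0)) stop_elisacal("concentrations must be >= 0", "elisacal_domain_error")
  pos <- x > 0
  if (sum(pos) < 5) {
    stop_elisacal("need at least 5 points with positive concentration",
                  "elisacal_selfstart_error")
  }
  init_log <- self_start_log(data.frame(predictor = log(x[pos]), response = y[pos]))
  # zero-concentration wells sharpen the asymptote on the x = 0 side
  if (any(!pos)) {
    zero_od <- mean(y[!pos])
    if (init_log[["scal"]] < 0) {
      init_log <- fpl_log_params(init_log[["A"]], zero_od, init_log[["xmid"]],
                                 init_log[["scal"]])
    } else {
      init_log <- fpl_log_params(zero_od, init_log[["B"]], init_log[["xmid"]],
                                 init_log[["scal"]])
    }
  }
  log_to_conc_params(init_log)
}

check_selfstart_input <- function(x, y) {
  if (length(x) != length(y) || anyNA(x) || anyNA(y)) {
    stop_elisacal("predictor and response must be equal-length and complete",
                  "elisacal_selfstart_error")
  }
  if (length(unique(x)) < 5) {
    stop_elisacal("need at least 5 distinct predictor values",
                  "elisacal_selfstart_error")
  }
  if (diff(range(y)) < 1e-10 * max(1, abs(mean(y)))) {
    stop_elisacal("response is constant: no sigmoid trend to initialize from",
                  "elisacal_selfstart_error")
  }
  invisible(TRUE)
}
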