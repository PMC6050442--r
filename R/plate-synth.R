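#' Default generating curve for synthetic plates
#'
#' The log-scale 4PL truth used by [simulate_plate()] unless another is given:
#' a competitive curve with blank OD 1.8, background OD 0.15, mid-response at
#' 0.75 ug/L and scale -0.35. The values are arbitrary (not estimated from any
#' kit) but chosen so the mid-response sits near 1 ug/L and both asymptotes are
#' expressed within the default design's effective concentration range
#' (0.0375-5 ug/L), which keeps all four coefficients identifiable.
#'
#' @return An [fpl_log_params()] object.
#' @export
default_truth <- function() {
  fpl_log_params(A = 0.15, B = 1.8, xmid = log(0.75), scal = -0.35)
}

#' Enumerate the wells of a dilution-series plate design
#'
#' Builds the well table of a 96-well calibration experiment: a set of stock
#' standard solutions plus a quality-control (QC) solution, each diluted by a
#' sequence of factors with replication; blank (zero-concentration) wells; and
#' unknown-sample wells at their own dilution sequence. The default arguments
#' reproduce a microcystin ELISA design: standards \{0.15, 0.4, 1, 2, 5\} ug/L
#' and QC 0.75 ug/L, dilution factors \{1, 1.5, 2, 2.5, 3, 3.5, 4\}, two
#' replicates (84 non-zero wells), six blanks, and six unknown wells
#' (dilutions 1, 2, 3, two replicates each) — 96 wells in all, 90 of them with
#' known concentration.
#'
#' @param standard_levels Stock standard concentrations, ug/L.
#' @param qc_level QC solution concentration, ug/L (`NULL` to omit).
#' @param dilution_factors Dilution factors applied to every standard and QC
#'   stock; all `>= 1`.
#' @param replicates Replicates per (stock, dilution) combination.
#' @param n_blanks Number of zero-concentration wells.
#' @param unknown_dilutions Dilution factors for the unknown sample.
#' @param unknown_replicates Replicates per unknown dilution.
#' @param extra_low_levels Optional additional low-concentration standards
#'   (e.g. `c(0.05, 0.1)`), added undiluted with `replicates` replicates each —
#'   the design variants that probe the low end of the curve.
#'
#' @return A tibble with one row per well: `well_id`, `sample_type`
#'   (`standard`, `blank`, `qc`, `unknown`), `nominal_conc` (ug/L, `NA` for
#'   unknowns), `dilution_factor`, and `effective_conc = nominal / dilution`
#'   (`NA` for unknowns).
#' @seealso [simulate_plate()]
#' @export
#' @examples
#' d <- plate_design()
#' dplyr::count(d, sample_type)
plate_design <- function(standard_levels = c(0.15, 0.4, 1, 2, 5),
                         qc_level = 0.75,
                         dilution_factors = c(1, 1.5, 2, 2.5, 3, 3.5, 4),
                         replicates = 2,
                         n_blanks = 6,
                         unknown_dilutions = c(1, 2, 3),
                         unknown_replicates = 2,
                         extra_low_levels = NULL) {
  if (replicates < 1 || unknown_replicates < 1) {
    stop_elisacal("replicate counts must be >= 1", "elisacal_invalid_design")
  }
  if (any(dilution_factors < 1)) {
    stop_elisacal("dilution factors must be >= 1", "elisacal_invalid_design")
  }
  stocks <- tibble::tibble(
    nominal_conc = c(standard_levels, qc_level),
    sample_type = c(rep("standard", length(standard_levels)),
                    rep("qc", length(qc_level)))
  )
  known <- tidyr::expand_grid(stocks,
                              dilution_factor = dilution_factors,
                              replicate = seq_len(replicates))
  if (!is.null(extra_low_levels)) {
    known <- dplyr::bind_rows(
      known,
      tidyr::expand_grid(nominal_conc = extra_low_levels,
                         sample_type = "standard",
                         dilution_factor = 1,
                         replicate = seq_len(replicates)))
  }
  blanks <- tibble::tibble(sample_type = "blank", nominal_conc = 0,
                           dilution_factor = 1,
                           replicate = seq_len(max(n_blanks, 0)))
  if (n_blanks == 0) blanks <- blanks[0, ]
  unknowns <- tidyr::expand_grid(sample_type = "unknown",
                                 nominal_conc = NA_real_,
                                 dilution_factor = unknown_dilutions,
                                 replicate = seq_len(unknown_replicates))
  wells <- dplyr::bind_rows(known, blanks, unknowns)
  wells |>
    dplyr::mutate(
      well_id = sprintf("W%02d", dplyr::row_number()),
      effective_conc = .data$nominal_conc / .data$dilution_factor
    ) |>
    dplyr::select("well_id", "sample_type", "nominal_conc",
                  "dilution_factor", "effective_conc")
}

#' Simulate optical densities for a plate design
#'
#' Generates a complete synthetic plate dataset: each well's OD is the
#' generating 4PL curve evaluated at the natural log of its effective
#' concentration, plus i.i.d. Gaussian noise on the OD scale. Blank wells use
#' the curve's zero-concentration limit (the asymptote approached as log
#' concentration falls to \eqn{-\infty}), so one log-scale truth generates
#' consistent data for both model forms. Unknown wells use
#' `unknown_truth / dilution_factor`. Homoscedastic Gaussian OD noise matches
#' the constant-residual-variance assumption of the downstream regression; the
#' default `noise_sd` of 0.10 absorbance units is the scale of residual
#' standard errors seen in real microcystin plates.
#'
#' @param design A well table from [plate_design()], or any tibble with
#'   columns `well_id`, `sample_type`, `nominal_conc`, `dilution_factor`,
#'   `effective_conc`.
#' @param truth Generating curve, an [fpl_log_params()] object.
#' @param noise_sd Gaussian OD noise standard deviation (absorbance units).
#' @param unknown_truth True undiluted concentration of the unknown sample,
#'   ug/L. Required when the design contains unknown wells.
#' @param seed Integer RNG seed; the same seed reproduces the plate exactly.
#' @return The design tibble with an `od` column appended — a plate dataset as
#'   accepted by every fitting and comparison function in the package.
#' @export
#' @examples
#' plate <- simulate_plate(plate_design(), seed = 1, unknown_truth = 0.9)
#' head(plate)
simulate_plate <- function(design = plate_design(),
                           truth = default_truth(),
                           noise_sd = 0.10,
                           unknown_truth = NULL,
                           seed = NULL) {
  stopifnot(inherits(truth, "fpl_log_params"))
  if (noise_sd < 0) stop_elisacal("noise_sd must be >= 0", "elisacal_invalid_design")
  has_unknown <- any(design$sample_type == "unknown")
  if (has_unknown && is.null(unknown_truth)) {
    stop_elisacal("design contains unknown wells: supply unknown_truth",
                  "elisacal_invalid_design")
  }
  if (!is.null(seed)) set.seed(seed)
  conc <- design$effective_conc
  if (has_unknown) {
    unk <- design$sample_type == "unknown"
    conc[unk] <- unknown_truth / design$dilution_factor[unk]
  }
  # log(0) = -Inf: eval_fpl_log saturates at the zero-concentration asymptote
  mu <- eval_fpl_log(truth, log(conc))
  design |>
    dplyr::mutate(od = mu + rnorm(length(mu), sd = noise_sd))
}
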