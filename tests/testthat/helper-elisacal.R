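# shared fixtures: everything is generated in code at test time

# random valid coefficient sets, both orientations, for property-style loops
# shape magnitudes stay within [0.5, 1.5] (|scal| within [2/3, 2]): over the
# tested eight-decade range, steeper curves push ODs so close to an asymptote
# that closed-form inversion is ill-conditioned in double precision
random_conc_params <- function() {
  fpl_conc_params(alpha1 = runif(1, 1, 3),
                  alpha2 = sample(c(-1, 1), 1) * runif(1, 0.5, 1.5),
                  alpha3 = exp(runif(1, -1.5, 1.5)),
                  alpha4 = runif(1, 0, 0.5))
}

random_log_params <- function() {
  fpl_log_params(A = runif(1, 0, 0.5), B = runif(1, 1, 3),
                 xmid = runif(1, -1.5, 1.5),
                 scal = sample(c(-1, 1), 1) * runif(1, 2/3, 2))
}

# noise-free regression table on the fit's own predictor scale
noise_free_table <- function(truth, x = c(0.0375, 0.05, 0.1, 0.15, 0.25, 0.4,
                                          0.75, 1, 1.5, 2, 3, 5),
                             scale = c("log", "conc")) {
  scale <- match.arg(scale)
  pred <- if (scale == "log") log(x) else x
  od <- if (inherits(truth, "fpl_log_params")) {
    eval_fpl_log(truth, log(x))
  } else {
    eval_fpl_conc(truth, x)
  }
  tibble::tibble(predictor = pred, response = od, true_conc = x)
}

default_test_plate <- function(seed = 101, noise_sd = 0.10) {
  simulate_plate(noise_sd = noise_sd, unknown_truth = 0.9, seed = seed)
}
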