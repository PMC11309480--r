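# shared fixtures, all built in code from the package's reference tables

# healthy-population beat model (separate convention), mu_Rp at 100 ms
healthy_separate_model <- function(mu_Rp = 100) {
  reference_beat_model(healthy_reference_params("separate"),
                       mode = "separate", mu_Rp = mu_Rp)
}

healthy_bulk_model <- function(mu_Rp = 100) {
  reference_beat_model(healthy_reference_params("bulk"),
                       mode = "bulk", mu_Rp = mu_Rp)
}

# first beat-block of the early-repolarization case (bulk, beta = -0.08)
ers_a1_model <- function(mu_Rp = 100) {
  reference_beat_model(ers_case_series()[1, ], mode = "bulk",
                       mu_Rp = mu_Rp)
}

# quick noiseless single-beat synthesis + ground-truth-window fit
roundtrip_fit <- function(model, mode = model$mode, config = NULL) {
  sb <- synthesize_beat(model, fs = 1000, noise_sd = 0)
  if (is.null(config)) config <- fit_config(mode)
  fitter <- if (mode == "bulk") fit_rt_bulk else fit_rt_separate
  fitter(sb$signal, sb$fs, sb$truth$fiducials, config)
}

# a random physiologically-ordered beat model
random_beat_model <- function(mode = "separate") {
  mu <- sort(c(stats::runif(1, 80, 120), stats::runif(1, 100, 140),
               stats::runif(1, 280, 380), stats::runif(1, 380, 480)))
  beat_model(
    mu = c(Rp = mu[1], Rn = mu[2], Tn = mu[3], Tp = mu[4]),
    sigma = c(Rp = stats::runif(1, 4, 9), Rn = stats::runif(1, 3, 8),
              Tn = stats::runif(1, 35, 80), Tp = stats::runif(1, 15, 45)),
    k = c(Rp = stats::runif(1, 1, 3), Rn = stats::runif(1, 1, 3),
          Tn = stats::runif(1, 0.4, 2), Tp = stats::runif(1, 0.4, 2)),
    beta = if (mode == "separate") c(R = 0, T = 0) else 0,
    mode = mode
  )
}
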