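# Synthetic ECG generation from the CDF-difference forward model.
#
# Every test and calibration in the package runs against records produced
# here: the generator is the ground truth, storing for each beat the exact
# generating parameters and the model-implied fiducial times.

#' Synthesize one beat from a beat model
#'
#' Evaluates the forward model on a regular grid and optionally adds
#' white Gaussian noise. For bulk models the trapezoid model covers the
#' whole beat; for separate models the beat is piecewise (R-segment model
#' up to the J point, T-segment model after), matching how the two
#' windows are fitted independently.
#'
#' Model-implied fiducial truth uses 3-sigma envelopes: QRS onset =
#' `mu_Rp - 3 sigma_Rp`, J point = `mu_Rn + 3 sigma_Rn`, T end =
#' `mu_Tp + 3 sigma_Tp`, T onset = `max(J, mu_Tn - 3 sigma_Tn)`.
#'
#' @param model A [beat_model()]. Transition means are beat-local times in
#'   ms; leave room before `mu_Rp` for the PQ baseline (default reference
#'   parameter sets place `mu_Rp` at 100 ms or later).
#' @param fs Sampling rate in Hz (default 1000). Below 250 Hz a warning
#'   is issued (T-end resolution).
#' @param noise_sd Additive white-noise SD in mV.
#' @param duration Beat length in ms; default `mu_Tp + 4 sigma_Tp + 60`.
#' @param seed Optional integer; when given the noise draw is local and
#'   reproducible.
#'
#' @return List with `signal` (mV), `t` (ms), `fs`, and `truth` (list:
#'   `fiducials` in beat-local ms and the generating `model`).
#' @export
synthesize_beat <- function(model, fs = 1000, noise_sd = 0,
                            duration = NULL, seed = NULL) {
  stopifnot(inherits(model, "beat_model"))
  if (fs < 250) warning("fs below 250 Hz limits T-end resolution")
  mu <- model$mu; sg <- model$sigma
  if (is.null(duration)) {
    duration <- mu[["Tp"]] + 4 * sg[["Tp"]] + 60
  }
  t <- seq(0, duration - 1000 / fs, by = 1000 / fs)
  fid <- .model_fiducials(model)
  clean <- .eval_beat(model, t, fid)
  noise <- if (noise_sd > 0) {
    .with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  } else {
    numeric(length(t))
  }
  list(signal = clean + noise, t = t, fs = fs,
       truth = list(fiducials = fid, model = model))
}

.model_fiducials <- function(model) {
  mu <- model$mu; sg <- model$sigma
  qrs_onset <- mu[["Rp"]] - 3 * sg[["Rp"]]
  j_point <- mu[["Rn"]] + 3 * sg[["Rn"]]
  t_end <- mu[["Tp"]] + 3 * sg[["Tp"]]
  t_onset <- max(j_point, mu[["Tn"]] - 3 * sg[["Tn"]])
  # peaks from dense evaluation of the noiseless model
  tR <- seq(qrs_onset, j_point, by = 0.5)
  r_wave <- if (model$mode == "bulk") forward_bulk(model, tR) else
    forward_separate(model, tR, "R")
  tT <- seq(t_onset, t_end, by = 0.5)
  t_wave <- if (model$mode == "bulk") forward_bulk(model, tT) else
    forward_separate(model, tT, "T")
  list(qrs_onset = unname(qrs_onset),
       r_peak = .argmax_t(tR, r_wave),
       j_point = unname(j_point),
       t_onset = unname(t_onset),
       t_peak = .argmax_t(tT, t_wave),
       t_end = unname(t_end))
}

.eval_beat <- function(model, t, fid = NULL) {
  if (model$mode == "bulk") return(forward_bulk(model, t))
  if (is.null(fid)) fid <- .model_fiducials(model)
  out <- numeric(length(t))
  r_part <- t < fid$j_point
  out[r_part] <- forward_separate(model, t[r_part], "R")
  out[!r_part] <- forward_separate(model, t[!r_part], "T")
  out
}

#' Generator configuration
#'
#' @param n_beats Number of beats (>= 1).
#' @param fs Sampling rate in Hz.
#' @param mode Forward-model convention, `"bulk"` or `"separate"`.
#' @param scenario `"normal"` (stationary parameters), `"ischemia"`
#'   (cathodic repolarization spread drifts upward before an ST-level
#'   shift appears) or `"ers"` (per-beat parameters cycle through the
#'   early-repolarization case series with its T-wave alternans).
#' @param params One-row data frame of generating parameters (standard
#'   column names); default [healthy_reference_params()] for the chosen
#'   mode. Ignored by the `"ers"` scenario.
#' @param param_sd Optional named numeric of per-beat SDs for any
#'   parameter column; beats then draw parameters independently from
#'   normal distributions around `params` (sigma and k truncated at
#'   realistic floors).
#' @param rri_mean,rri_sd RR-interval mean and SD in ms.
#' @param noise_sd Additive white-noise SD in mV (default 0.01).
#' @param drift_amp,drift_freq Baseline-wander amplitude (mV) and
#'   frequency (Hz).
#' @param mu_Rp Beat-local anodic depolarization mean (ms); sets where in
#'   each RR interval the QRS sits.
#' @param seed Integer seed; mandatory whenever any stochastic element
#'   (param_sd, rri_sd, noise, drift phase) is active.
#' @param scenario_opts Named list overriding scenario defaults
#'   (`onset_sigma`, `sigma_from`, `sigma_to`, `ramp_len`, `onset_st`,
#'   `st_shift` for `"ischemia"`).
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_beats = 100, fs = 1000,
                             mode = c("bulk", "separate"),
                             scenario = c("normal", "ischemia", "ers"),
                             params = NULL, param_sd = NULL,
                             rri_mean = 1000, rri_sd = 25,
                             noise_sd = 0.01,
                             drift_amp = 0, drift_freq = 0.25,
                             mu_Rp = 250, seed = NULL,
                             scenario_opts = list()) {
  mode <- match.arg(mode)
  scenario <- match.arg(scenario)
  if (n_beats < 1) stop("'n_beats' must be >= 1", call. = FALSE)
  stochastic <- noise_sd > 0 || rri_sd > 0 || !is.null(param_sd)
  if (stochastic && is.null(seed)) {
    stop("'seed' is mandatory for stochastic generation", call. = FALSE)
  }
  if (is.null(params)) params <- healthy_reference_params(mode)
  structure(
    list(n_beats = n_beats, fs = fs, mode = mode, scenario = scenario,
         params = params, param_sd = param_sd,
         rri_mean = rri_mean, rri_sd = rri_sd, noise_sd = noise_sd,
         drift_amp = drift_amp, drift_freq = drift_freq,
         mu_Rp = mu_Rp, seed = seed, scenario_opts = scenario_opts),
    class = "generator_config"
  )
}

# per-beat parameter rows for each scenario
.scenario_params <- function(cfg) {
  n <- cfg$n_beats
  base <- cfg$params
  if (cfg$scenario == "ers") {
    tab <- ers_case_series()
    idx <- ((seq_len(n) - 1L) %% nrow(tab)) + 1L
    rows <- tab[idx, , drop = FALSE]
    rownames(rows) <- NULL
    return(rows)
  }
  rows <- base[rep(1L, n), , drop = FALSE]
  rownames(rows) <- NULL
  if (!"beta" %in% names(rows)) rows$beta <- 0
  if (cfg$scenario == "ischemia") {
    o <- utils::modifyList(
      list(onset_sigma = max(2L, floor(n / 2L) - 20L),
           sigma_from = 60, sigma_to = 104, ramp_len = 50L,
           onset_st = NULL, st_shift = -0.1),
      cfg$scenario_opts
    )
    if (is.null(o$onset_st)) o$onset_st <- o$onset_sigma + 15L
    ramp <- rep(o$sigma_from, n)
    after <- seq_len(n) >= o$onset_sigma
    prog <- pmin((seq_len(n) - o$onset_sigma) / o$ramp_len, 1)
    ramp[after] <- o$sigma_from +
      (o$sigma_to - o$sigma_from) * prog[after]
    rows$sigmaTn <- ramp
    # ST shift realized through the cathodic plateau weight: in the bulk
    # model the ST level is kRp - kRn + beta
    st <- rep(0, n)
    st_after <- seq_len(n) >= o$onset_st
    st[st_after] <- o$st_shift *
      pmin((seq_len(n)[st_after] - o$onset_st + 1) / 10, 1)
    rows$kRn <- rows$kRn - st
    rows$kTn <- rows$kTn - st
  }
  rows
}

#' Synthesize a multi-beat ECG record
#'
#' Concatenates beats at drawn RR intervals, adds white noise and
#' optional baseline wander, and returns both the record and a truth
#' table holding every generating parameter and model-implied fiducial
#' per beat.
#'
#' @param cfg A [generator_config()].
#'
#' @return List with `record` (an [ecg_record()], lead `"II"`) and
#'   `truth` (data frame, one row per beat).
#' @export
synthesize_record <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_beats
    rows <- .scenario_params(cfg)
    if (!is.null(cfg$param_sd)) {
      for (nm in names(cfg$param_sd)) {
        if (!nm %in% names(rows)) next
        rows[[nm]] <- stats::rnorm(n, rows[[nm]], cfg$param_sd[[nm]])
        if (startsWith(nm, "sigma")) rows[[nm]] <- pmax(rows[[nm]], 1)
        if (startsWith(nm, "k")) rows[[nm]] <- pmax(rows[[nm]], 0.05)
      }
    }
    rri <- if ("RRI" %in% names(rows) && cfg$scenario == "ers") {
      rows$RRI + stats::rnorm(n, 0, cfg$rri_sd)
    } else {
      stats::rnorm(n, cfg$rri_mean, cfg$rri_sd)
    }
    fs <- cfg$fs
    n_samp <- round(rri * fs / 1000)
    models <- vector("list", n)
    for (i in seq_len(n)) {
      models[[i]] <- reference_beat_model(
        rows[i, , drop = FALSE], mode = cfg$mode, mu_Rp = cfg$mu_Rp,
        beta = if ("beta" %in% names(rows)) rows$beta[i] else 0
      )
      qt_proxy <- models[[i]]$mu[["Tp"]] + 3 * models[[i]]$sigma[["Tp"]] -
        (models[[i]]$mu[["Rp"]] - 3 * models[[i]]$sigma[["Rp"]])
      if (rri[i] < qt_proxy + 100) {
        stop("overlapping beats: RRI ", round(rri[i]),
             " ms < QT + 100 ms at beat ", i, call. = FALSE)
      }
    }
    total <- sum(n_samp)
    signal <- numeric(total)
    onset_samp <- cumsum(c(0L, n_samp[-n]))
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      tloc <- seq(0, by = 1000 / fs, length.out = n_samp[i])
      fid <- .model_fiducials(models[[i]])
      beat <- .eval_beat(models[[i]], tloc, fid)
      # beats start at the preceding baseline; shift so signal is
      # continuous at the join (both ends sit at the resting level)
      signal[onset_samp[i] + seq_len(n_samp[i])] <- beat
      start_ms <- onset_samp[i] * 1000 / fs
      m <- derive_metrics(models[[i]])
      truth[[i]] <- data.frame(
        beat = i, start_ms = start_ms, rri = rri[i],
        muRp = models[[i]]$mu[["Rp"]], muRn = models[[i]]$mu[["Rn"]],
        muTn = models[[i]]$mu[["Tn"]], muTp = models[[i]]$mu[["Tp"]],
        sigmaRp = models[[i]]$sigma[["Rp"]],
        sigmaRn = models[[i]]$sigma[["Rn"]],
        sigmaTp = models[[i]]$sigma[["Tp"]],
        sigmaTn = models[[i]]$sigma[["Tn"]],
        kRp = models[[i]]$k[["Rp"]], kRn = models[[i]]$k[["Rn"]],
        kTp = models[[i]]$k[["Tp"]], kTn = models[[i]]$k[["Tn"]],
        beta = unname(models[[i]]$beta[1]),
        muRTp = m$muRTp, muRTn = m$muRTn,
        muRpn = m$muRpn, muTpn = m$muTpn,
        qrs_onset = start_ms + fid$qrs_onset,
        r_peak = start_ms + fid$r_peak,
        j_point = start_ms + fid$j_point,
        t_onset = start_ms + fid$t_onset,
        t_peak = start_ms + fid$t_peak,
        t_end = start_ms + fid$t_end
      )
    }
    truth <- do.call(rbind, truth)
    tt <- seq_len(total) / fs  # seconds
    if (cfg$noise_sd > 0) {
      signal <- signal + stats::rnorm(total, 0, cfg$noise_sd)
    }
    if (cfg$drift_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      signal <- signal +
        cfg$drift_amp * sin(2 * pi * cfg$drift_freq * tt + phase)
    }
    rec <- ecg_record(matrix(signal, ncol = 1), fs = fs,
                      lead_names = "II")
    list(record = rec, truth = truth)
  })
}
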