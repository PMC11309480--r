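# Record-level pipeline: segmentation -> per-beat fitting -> tensor.

#' Fit every beat of a record and assemble the parameter tensor
#'
#' Runs R-peak detection and fiducial delineation (unless a fiducial
#' table is supplied, e.g. generator truth), fits each usable beat in
#' the requested mode, computes conventional indices, and assembles the
#' results into a [assemble_tensor()] parameter tensor. Unusable or
#' non-converged beats are masked.
#'
#' @param record An [ecg_record()].
#' @param lead Lead name or index to analyze.
#' @param config A [fit_config()]; its `mode` selects the fitter.
#' @param fiducials Optional precomputed `tcg_fiducials`-style data
#'   frame (ms from record start) to bypass the built-in delineator.
#' @param invert_negative Fit leads with net-negative QRS after sign
#'   inversion (flagged in the result).
#'
#' @return List with `tensor` (`tcg_tensor`), `fits`, `fiducials`,
#'   `conventional` and `inverted` (logical).
#' @export
fit_record <- function(record, lead = 1L,
                       config = fit_config("bulk"),
                       fiducials = NULL, invert_negative = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  if (is.character(lead)) lead <- match(lead, record$lead_names)
  signal <- record$signals[, lead]
  fs <- record$fs
  inverted <- FALSE
  centred <- signal - stats::median(signal)
  if (invert_negative &&
      abs(min(centred)) > 1.5 * abs(max(centred))) {
    signal <- -signal
    inverted <- TRUE
  }
  if (is.null(fiducials)) {
    peaks <- detect_r_peaks(signal, fs)
    fiducials <- locate_fiducials(signal, fs, peaks)
  }
  conv <- conventional_indices(signal, fs, fiducials)
  fitter <- switch(config$mode,
                   separate = fit_rt_separate,
                   bulk = fit_rt_bulk,
                   extended = fit_extended)
  fits <- vector("list", nrow(fiducials))
  for (b in seq_len(nrow(fiducials))) {
    fd <- as.list(fiducials[b, c("qrs_onset", "r_peak", "j_point",
                                 "t_onset", "t_peak", "t_end")])
    if (!isTRUE(fiducials$usable[b]) ||
        any(!vapply(fd, is.finite, TRUE))) {
      fits[[b]] <- .failed_fit(config$mode)
      next
    }
    fits[[b]] <- tryCatch(
      fitter(signal, fs, fd, config),
      error = function(e) .failed_fit(config$mode)
    )
  }
  tensor <- assemble_tensor(
    fits, leads = record$lead_names[lead],
    timestamps = fiducials$r_peak, conventional = conv
  )
  list(tensor = tensor, fits = fits, fiducials = fiducials,
       conventional = conv, inverted = inverted)
}

# placeholder result for beats that cannot be fitted: masked, never
# dropped, so beat indexing stays aligned
.failed_fit <- function(mode) {
  model <- beat_model(
    mu = c(Rp = 0, Rn = 0, Tn = 0, Tp = 0),
    sigma = c(Rp = 1, Rn = 1, Tn = 1, Tp = 1),
    k = c(Rp = 0, Rn = 0, Tn = 0, Tp = 0),
    beta = if (mode == "bulk") 0 else c(R = 0, T = 0),
    mode = if (mode == "bulk") "bulk" else "separate"
  )
  structure(
    list(model = model, metrics = derive_metrics(model),
         r2 = c(overall = NA_real_),
         residual_sd = c(overall = NA_real_),
         converged = FALSE, iterations = 0L, cost = NA_real_,
         warnings = "unusable beat", windows = list(), mode = mode),
    class = "tcg_fit"
  )
}

#' Truth table to fiducial table
#'
#' Converts a generator truth table (from [synthesize_record()]) into
#' the fiducial format [fit_record()] accepts, for ground-truth-window
#' fitting.
#'
#' @param truth Truth data frame from the generator.
#' @return A `tcg_fiducials`-style data frame (ms from record start).
#' @export
truth_fiducials <- function(truth) {
  out <- data.frame(
    beat = truth$beat,
    qrs_onset = truth$qrs_onset, r_peak = truth$r_peak,
    j_point = truth$j_point, t_onset = truth$t_onset,
    t_peak = truth$t_peak, t_end = truth$t_end,
    usable = TRUE,
    RRI = c(NA_real_, diff(truth$r_peak)),
    QT = truth$t_end - truth$qrs_onset
  )
  class(out) <- c("tcg_fiducials", "data.frame")
  out
}
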