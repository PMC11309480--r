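# Beat detection and fiducial delineation.
#
# A transparent rule-based delineator: slope thresholds for QRS
# onset/offset, the tangent method for T end, fixed standard-interval
# clamps. Fiducials only set fit windows and initializations, so modest
# landmark error is tolerated downstream.

#' ECG record container
#'
#' @param signals Numeric matrix, one column per lead, in mV.
#' @param fs Sampling rate in Hz (> 0).
#' @param lead_names Character vector of lead names.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signals, fs, lead_names = NULL) {
  signals <- as.matrix(signals)
  if (!is.numeric(fs) || fs <= 0) stop("'fs' must be > 0", call. = FALSE)
  if (is.null(lead_names)) {
    lead_names <- colnames(signals)
    if (is.null(lead_names)) {
      lead_names <- paste0("lead", seq_len(ncol(signals)))
    }
  }
  if (length(lead_names) != ncol(signals)) {
    stop("one lead name per signal column", call. = FALSE)
  }
  colnames(signals) <- lead_names
  structure(list(signals = signals, fs = fs, lead_names = lead_names),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples x %d lead(s) @ %g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              nrow(x$signals) / x$fs))
  cat("leads:", paste(x$lead_names, collapse = ", "), "\n")
  invisible(x)
}

#' Detect R peaks
#'
#' Slope-energy detector: the squared derivative of a lightly smoothed
#' signal, averaged over a 60 ms window, emphasizes the sharp QRS
#' upstroke over broad T waves and low-frequency interference. Runs
#' above 30% of the peak energy become QRS candidates; each yields one
#' R peak at the local absolute signal maximum, and a 200 ms refractory
#' period keeps one peak per beat.
#'
#' @param signal Single-lead samples in mV.
#' @param fs Sampling rate (>= 100 Hz); the record must span >= 2 s.
#' @return Integer sample indices of R peaks (possibly empty, with a
#'   warning, for flat signals).
#' @export
detect_r_peaks <- function(signal, fs) {
  if (fs < 100) stop("'fs' must be >= 100 Hz", call. = FALSE)
  if (length(signal) < 2 * fs) {
    stop("record shorter than 2 s", call. = FALSE)
  }
  centred <- signal - stats::median(signal)
  if (max(abs(centred)) < 0.05) {
    warning("no QRS-like peaks found")
    return(integer(0))
  }
  sm <- .boxcar(signal, max(3L, .odd(round(0.02 * fs))))
  d <- c(0, diff(sm)) * fs / 1000
  energy <- .boxcar(d^2, .odd(round(0.06 * fs)))
  thr <- 0.3 * max(energy)
  cand <- energy >= thr
  if (!any(cand)) {
    warning("no QRS-like peaks found")
    return(integer(0))
  }
  runs <- rle(cand)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  half <- round(0.04 * fs)
  n <- length(signal)
  peaks <- integer(0)
  for (i in which(runs$values)) {
    seg <- max(1L, starts[i] - half):min(n, ends[i] + half)
    peaks <- c(peaks, seg[which.max(abs(centred[seg]))])
  }
  peaks <- unique(peaks)
  # amplitude veto: a true R peak dominates baseline interference
  peaks <- peaks[abs(centred[peaks]) >= 0.4 * max(abs(centred))]
  # refractory: greedy by amplitude, 200 ms exclusion
  refr <- round(0.2 * fs)
  keep <- logical(length(peaks))
  ord <- order(abs(centred[peaks]), decreasing = TRUE)
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(peaks[i] - taken) > refr)) {
      keep[i] <- TRUE
      taken <- c(taken, peaks[i])
    }
  }
  sort(peaks[keep])
}

.odd <- function(w) if (w %% 2L == 0L) w + 1L else w

.boxcar <- function(x, w) {
  out <- stats::filter(x, rep(1 / w, w), sides = 2)
  out[is.na(out)] <- x[is.na(out)]
  as.numeric(out)
}

#' Locate fiducial landmarks for each detected beat
#'
#' QRS onset and J point are the first and last crossings of 10% of the
#' maximum absolute derivative within +/- 80 ms of the R peak; T end
#' comes from the tangent method on the descending T limb (tangent at
#' the steepest down-slope after the T peak, extended to the PQ
#' baseline); T onset defaults to J + 40 ms. Landmarks are clamped to
#' standard intervals (QRS <= 200 ms, QT <= 600 ms); beats where a
#' landmark cannot be placed are flagged unusable.
#'
#' @param signal Single-lead samples in mV.
#' @param fs Sampling rate (Hz).
#' @param r_peaks Integer sample indices from [detect_r_peaks()].
#' @return Data frame of class `tcg_fiducials`: per beat the six
#'   landmark times in ms from record start (`NA` when unusable),
#'   `usable`, plus derived `RRI` and `QT` in ms.
#' @export
locate_fiducials <- function(signal, fs, r_peaks) {
  ms <- function(i) (i - 1L) * 1000 / fs
  n <- length(signal)
  # light smoothing (12 ms boxcar) so slope thresholds and the T-end
  # tangent read waveform slopes, not sample noise
  sm <- .boxcar(signal, max(3L, .odd(round(0.012 * fs))))
  d <- c(0, diff(sm)) * fs / 1000  # mV per ms
  out <- vector("list", length(r_peaks))
  for (b in seq_along(r_peaks)) {
    r <- r_peaks[b]
    w80 <- round(0.08 * fs)
    lo <- max(1L, r - w80); hi <- min(n, r + w80)
    dw <- abs(d[lo:hi])
    thr <- 0.1 * max(dw)
    above <- which(dw >= thr)
    row <- data.frame(beat = b, qrs_onset = NA_real_, r_peak = ms(r),
                      j_point = NA_real_, t_onset = NA_real_,
                      t_peak = NA_real_, t_end = NA_real_,
                      usable = FALSE, RRI = NA_real_, QT = NA_real_)
    if (length(above) >= 2L) {
      onset_i <- lo + above[1] - 1L
      j_i <- lo + above[length(above)] - 1L
      if (ms(j_i) - ms(onset_i) <= 200 && j_i > onset_i) {
        # T peak: largest excursion from baseline in the repolarization
        # search window
        base_lo <- max(1L, onset_i - round(0.04 * fs))
        baseline <- stats::median(sm[base_lo:onset_i])
        t_lo <- j_i + round(0.04 * fs)
        next_r <- if (b < length(r_peaks)) r_peaks[b + 1] else n
        t_hi <- min(n, j_i + round(0.45 * fs), next_r - round(0.1 * fs))
        if (t_hi > t_lo + 8L) {
          seg <- t_lo:t_hi
          tp_i <- seg[which.max(abs(sm[seg] - baseline))]
          # tangent method after the T peak
          down <- tp_i:t_hi
          t_end_ms <- NA_real_
          if (length(down) > 4L) {
            sl_i <- down[which.min(d[down] * sign(sm[tp_i] - baseline))]
            slope <- d[sl_i]
            if (abs(slope) > 1e-6) {
              t_end_ms <- ms(sl_i) + (baseline - sm[sl_i]) / slope
            }
          }
          qt <- t_end_ms - ms(onset_i)
          if (is.finite(t_end_ms) && t_end_ms > ms(tp_i) &&
              qt > 0 && qt <= 600) {
            row$qrs_onset <- ms(onset_i)
            row$j_point <- ms(j_i)
            row$t_onset <- ms(j_i) + 40
            row$t_peak <- ms(tp_i)
            row$t_end <- t_end_ms
            row$QT <- qt
            row$usable <- TRUE
          }
        }
      }
    }
    out[[b]] <- row
  }
  out <- do.call(rbind, out)
  if (nrow(out) > 1L) {
    out$RRI <- c(NA_real_, diff(out$r_peak))
  }
  class(out) <- c("tcg_fiducials", "data.frame")
  out
}

#' Conventional per-beat ECG indices
#'
#' ST level is the mean amplitude over `[J + 60 ms, J + 80 ms]` minus the
#' PQ baseline (median of the 40 ms before QRS onset); QT and RRI come
#' from the fiducial table.
#'
#' @param signal Single-lead samples in mV.
#' @param fs Sampling rate (Hz).
#' @param fiducials A `tcg_fiducials` data frame.
#' @return Data frame with per-beat `STlevel` (mV), `QT` (ms), `RRI`
#'   (ms); `NA` where the beat is unusable or the ST window runs past the
#'   record end.
#' @export
conventional_indices <- function(signal, fs, fiducials) {
  n <- length(signal)
  st <- rep(NA_real_, nrow(fiducials))
  for (b in seq_len(nrow(fiducials))) {
    if (!isTRUE(fiducials$usable[b])) next
    j <- fiducials$j_point[b]
    on <- fiducials$qrs_onset[b]
    i1 <- round((j + 60) * fs / 1000) + 1L
    i2 <- round((j + 80) * fs / 1000) + 1L
    b1 <- max(1L, round((on - 40) * fs / 1000) + 1L)
    b2 <- max(1L, round(on * fs / 1000) + 1L)
    if (i2 > n) next
    st[b] <- mean(signal[i1:i2]) - stats::median(signal[b1:b2])
  }
  data.frame(beat = fiducials$beat, STlevel = st,
             QT = fiducials$QT, RRI = fiducials$RRI)
}
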