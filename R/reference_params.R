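# Built-in reference parameter sets.
#
# The healthy-population values are lead-II means over 699 adults (500
# beats per participant) from an open ambulatory-ECG database; the two
# case series are per-beat (or per-time-point) fitted parameters from a
# coronary-intervention ischemia case and an early-repolarization-syndrome
# case. They serve as generator inputs and as realistic defaults; absolute
# transition means are not part of the tables (only intervals), so a
# mu_Rp reference must be supplied when rebuilding a beat model.

#' Healthy-population mean beat parameters
#'
#' Lead-II population means of the CDF-difference beat model for healthy
#' adults, for the RT-separate and RT-bulk fitting conventions. Units:
#' `k` in mV, `sigma` and interval metrics in ms.
#'
#' @param mode `"separate"` or `"bulk"`.
#' @return One-row data frame with columns `kRp, kRn, kTp, kTn, sigmaRp,
#'   sigmaRn, sigmaTp, sigmaTn, muRTp, muRTn, muRpn, muTpn`.
#' @export
healthy_reference_params <- function(mode = c("separate", "bulk")) {
  mode <- match.arg(mode)
  if (mode == "separate") {
    data.frame(
      kRp = 1.99, kRn = 2.01, kTp = 0.80, kTn = 0.80,
      sigmaRp = 6.71, sigmaRn = 5.83, sigmaTp = 23.56, sigmaTn = 54.29,
      muRTp = 307.35, muRTn = 231.70, muRpn = 22.18, muTpn = 53.48
    )
  } else {
    data.frame(
      kRp = 1.97, kRn = 1.88, kTp = 1.94, kTn = 1.91,
      sigmaRp = 6.56, sigmaRn = 5.51, sigmaTp = 35.73, sigmaTn = 50.07,
      muRTp = 299.98, muRTn = 256.13, muRpn = 20.99, muTpn = 22.86
    )
  }
}

#' Beat model from a parameter-table row
#'
#' Rebuilds a [beat_model()] from one row of a parameter table (as
#' returned by [healthy_reference_params()], [ers_case_series()] or any
#' table using the standard column names), fixing the arbitrary absolute
#' reference `mu_Rp`.
#'
#' @param row One-row data frame with `k*`, `sigma*` and interval columns.
#' @param mode Fitting convention of the parameters.
#' @param mu_Rp Absolute anodic depolarization mean (ms).
#' @param beta Baseline level (mV); taken from the row's `beta` column
#'   when present and this argument is `NULL`, else 0.
#' @return A `beat_model`.
#' @export
reference_beat_model <- function(row, mode = c("separate", "bulk"),
                                 mu_Rp = 100, beta = NULL) {
  mode <- match.arg(mode)
  row <- as.data.frame(row)
  stopifnot(nrow(row) == 1L)
  if (is.null(beta)) {
    beta <- if ("beta" %in% names(row)) row$beta else 0
  }
  beat_model_from_intervals(
    k = c(Rp = row$kRp, Rn = row$kRn, Tn = row$kTn, Tp = row$kTp),
    sigma = c(Rp = row$sigmaRp, Rn = row$sigmaRn,
              Tn = row$sigmaTn, Tp = row$sigmaTp),
    muRTp = row$muRTp, muRTn = row$muRTn, muRpn = row$muRpn,
    mu_Rp = mu_Rp, beta = beta, mode = mode
  )
}

#' Repolarization parameters during staged coronary occlusion
#'
#' RT-bulk T-wave parameters at six time points of a percutaneous coronary
#' intervention (baseline, angiography, three balloon inflations,
#' completion) in an ischemia case. Used to exercise threshold flagging.
#'
#' @return Data frame with one row per time point.
#' @export
pci_case_series <- function() {
  data.frame(
    point = 1:6,
    kTp   = c(1.58, 2.16, 1.78, 1.59, 1.36, 1.69),
    kTn   = c(1.59, 2.38, 1.58, 1.47, 1.54, 1.69),
    sigmaTp = c(37.48, 56.72, 32.35, 31.63, 54.18, 31.81),
    sigmaTn = c(60.39, 86.59, 57.59, 66.97, 104.01, 87.27),
    muRpn = c(23.77, 26.70, 23.25, 23.91, 25.59, 23.05),
    muTpn = c(23.62, 7.77, 67.43, 52.34, 14.32, 30.60),
    muRTp = c(336.25, 360.74, 341.00, 350.72, 408.53, 368.83),
    muRTn = c(288.85, 326.27, 250.32, 274.47, 368.62, 315.18)
  )
}

#' Per-beat bulk parameters of an early-repolarization-syndrome case
#'
#' RT-bulk parameters for 40 sequential 10-beat blocks around an episode
#' of ventricular fibrillation: sections A (sinus rhythm well before VF),
#' B (immediately before), C (immediately after) and D (late recovery).
#' Sections B and C carry beat-to-beat alternation of the cathodic
#' repolarization spread `sigmaTn` (T-wave alternans); the series drives
#' the `"ers"` generator scenario.
#'
#' @return Data frame with `section`, `pulse` and the standard parameter
#'   columns plus `beta`, `RRI` and `QT`.
#' @export
ers_case_series <- function() {
  d <- data.frame(
    section = rep(c("A", "B", "C", "D"), each = 10L),
    pulse = rep(1:10, times = 4L),
    sigmaRp = c(6.90, 6.70, 6.67, 6.70, 6.73, 6.72, 6.95, 6.64, 6.79, 6.74,
                6.86, 6.67, 6.71, 6.72, 6.71, 6.71, 6.71, 6.75, 6.91, 6.79,
                7.63, 7.08, 7.06, 6.34, 6.87, 6.69, 6.96, 7.19, 7.09, 6.98,
                6.87, 6.83, 6.92, 6.92, 7.08, 6.95, 6.93, 6.86, 6.84, 6.96),
    sigmaRn = c(3.76, 3.80, 3.83, 3.75, 3.82, 3.71, 3.82, 3.76, 3.83, 3.80,
                3.91, 3.76, 3.78, 3.84, 3.84, 3.77, 3.74, 3.72, 3.78, 3.79,
                4.10, 3.90, 3.90, 3.58, 3.88, 3.91, 3.85, 3.89, 3.96, 3.92,
                3.92, 3.92, 3.89, 3.86, 3.89, 3.90, 3.93, 3.94, 3.90, 3.91),
    sigmaTp = c(28.29, 29.87, 30.24, 30.31, 30.68, 29.69, 29.01, 29.80, 30.45, 30.64,
                32.58, 31.11, 30.14, 31.29, 31.47, 31.08, 30.84, 29.90, 29.08, 30.34,
                31.25, 29.51, 30.49, 31.06, 30.72, 30.71, 30.34, 30.19, 30.63, 31.26,
                31.72, 31.61, 31.77, 31.27, 30.86, 30.90, 31.74, 31.84, 31.83, 32.06),
    sigmaTn = c(89.01, 86.61, 86.67, 85.65, 85.22, 87.10, 88.76, 86.35, 85.48, 85.96,
                87.23, 89.16, 87.97, 85.70, 85.49, 85.57, 83.99, 88.56, 87.60, 85.11,
                82.52, 78.84, 78.34, 92.84, 78.57, 74.94, 78.60, 79.96, 76.96, 78.00,
                77.88, 77.84, 76.30, 78.71, 80.64, 79.59, 76.74, 77.62, 78.38, 77.66),
    muRTp = c(325.80, 324.23, 324.51, 324.46, 324.54, 325.22, 325.57, 324.06, 324.22, 324.26,
              345.58, 327.44, 326.81, 325.52, 325.44, 325.28, 325.21, 326.20, 326.00, 325.15,
              324.41, 310.85, 309.73, 312.94, 309.09, 307.97, 309.60, 310.64, 309.11, 309.12,
              309.79, 309.98, 309.57, 310.48, 311.25, 311.03, 310.06, 310.25, 310.69, 310.64),
    muRTn = c(266.65, 271.72, 273.64, 272.25, 274.92, 270.72, 266.83, 268.54, 272.67, 272.48,
              297.54, 276.39, 273.13, 276.36, 276.35, 276.18, 274.56, 272.98, 270.41, 274.40,
              265.72, 249.05, 251.28, 254.30, 250.75, 246.32, 250.31, 251.11, 250.91, 253.30,
              256.19, 256.91, 256.69, 256.68, 255.86, 255.56, 258.64, 258.02, 259.24, 259.88),
    muRpn = c(22.15, 21.83, 21.71, 21.72, 21.65, 21.86, 22.12, 21.90, 21.79, 21.72,
              21.84, 21.78, 21.88, 21.64, 21.57, 21.62, 21.59, 21.83, 21.89, 21.70,
              21.92, 21.90, 21.73, 21.78, 21.63, 21.58, 21.82, 21.97, 21.86, 21.73,
              21.76, 21.67, 21.59, 21.73, 21.94, 21.86, 21.71, 21.58, 21.60, 21.54),
    muTpn = c(36.99, 30.68, 29.16, 30.49, 27.97, 32.64, 36.62, 33.62, 29.76, 30.06,
              26.21, 29.27, 31.80, 27.51, 27.52, 27.48, 29.07, 31.39, 33.70, 29.04,
              36.77, 39.91, 36.72, 36.86, 36.71, 40.08, 37.47, 37.55, 36.34, 34.10,
              31.84, 31.40, 31.29, 32.06, 33.45, 33.61, 29.72, 30.65, 29.85, 29.21),
    kRp = c(1.38, 1.54, 1.60, 1.61, 1.63, 1.50, 1.40, 1.52, 1.60, 1.61,
            1.55, 1.41, 1.44, 1.58, 1.61, 1.61, 1.59, 1.46, 1.44, 1.58,
            1.57, 1.58, 1.67, 1.59, 1.69, 1.69, 1.60, 1.53, 1.61, 1.68,
            1.66, 1.68, 1.70, 1.61, 1.51, 1.56, 1.66, 1.67, 1.69, 1.70),
    kRn = c(1.36, 1.53, 1.59, 1.59, 1.62, 1.48, 1.37, 1.50, 1.59, 1.60,
            1.54, 1.39, 1.42, 1.56, 1.59, 1.59, 1.56, 1.44, 1.42, 1.56,
            1.53, 1.54, 1.64, 1.56, 1.67, 1.68, 1.58, 1.49, 1.58, 1.65,
            1.65, 1.67, 1.68, 1.59, 1.50, 1.55, 1.65, 1.66, 1.68, 1.67),
    kTp = c(1.37, 1.53, 1.59, 1.59, 1.62, 1.49, 1.39, 1.51, 1.59, 1.60,
            1.54, 1.40, 1.43, 1.57, 1.60, 1.59, 1.58, 1.45, 1.43, 1.57,
            1.56, 1.58, 1.67, 1.58, 1.68, 1.68, 1.59, 1.52, 1.61, 1.67,
            1.66, 1.67, 1.69, 1.60, 1.51, 1.55, 1.66, 1.67, 1.68, 1.69),
    kTn = c(1.36, 1.53, 1.59, 1.60, 1.62, 1.48, 1.37, 1.51, 1.59, 1.61,
            1.54, 1.40, 1.42, 1.57, 1.60, 1.59, 1.57, 1.44, 1.42, 1.57,
            1.53, 1.54, 1.64, 1.57, 1.67, 1.68, 1.58, 1.49, 1.57, 1.65,
            1.65, 1.67, 1.68, 1.59, 1.49, 1.55, 1.65, 1.66, 1.68, 1.67),
    beta = c(-0.08, -0.06, -0.05, -0.06, -0.06, -0.06, -0.08, -0.06, -0.06, -0.06,
             0.01, -0.06, -0.07, -0.05, -0.06, -0.05, -0.07, -0.05, -0.08, -0.06,
             -0.07, -0.14, -0.16, -0.10, -0.15, -0.13, -0.11, -0.14, -0.17, -0.15,
             -0.11, -0.09, -0.11, -0.10, -0.10, -0.12, -0.11, -0.08, -0.07, -0.09),
    RRI = c(820, 822, 819, 822, 820, 820, 816, 818, 819, 819,
            804, 806, 809, 811, 815, 819, 824, 829, 829, 834,
            741, 736, 734, 733, 731, 731, 734, 735, 736, 738,
            750, 749, 751, 753, 757, 757, 758, 759, 760, 763),
    QT = c(384, 381, 379, 379, 377, 382, 384, 386, 385, 383,
           424, 391, 386, 384, 390, 384, 383, 381, 382, 383,
           453, 390, 387, 441, 377, 374, 383, 434, 387, 376,
           372, 383, 372, 372, 386, 374, 371, 373, 386, 369)
  )
  d
}
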