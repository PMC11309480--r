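# Mahalanobis-distance abnormality scoring of beat-wise parameter
# vectors against a reference beat window (e.g. the waiting period
# before an intervention). Works identically for TCG parameter pairs
# (sigmaTn/sigmaTp, muRTp/muRTn) and conventional index pairs (ST/QT).

#' Fit a reference distribution over a beat window
#'
#' Computes the mean vector and sample covariance of the selected
#' parameters over the reference window, skipping masked beats. When the
#' covariance is ill-conditioned (condition number above `cond_max`) a
#' ridge `eps * trace / dim` is added to the diagonal -- repolarization
#' spreads are strongly correlated, so near-singular reference windows
#' do occur.
#'
#' @param x Numeric matrix or data frame, beats in rows, parameters in
#'   columns (named).
#' @param window Integer beat indices of the reference window; needs at
#'   least `max(10, 2 * ncol(x))` non-missing beats.
#' @param eps Ridge fraction (default 1e-6).
#' @param cond_max Condition-number trigger for regularization.
#'
#' @return An object of class `tcg_reference`: `mean`, `cov`,
#'   `parameters`, `window`, `n_used`, `ridge` (the amount added, 0 when
#'   none).
#' @export
fit_reference <- function(x, window, eps = 1e-6, cond_max = 1e8) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("p", seq_len(ncol(x)))
  }
  d <- ncol(x)
  xw <- x[window, , drop = FALSE]
  ok <- stats::complete.cases(xw)
  n_min <- max(10, 2 * d)
  if (sum(ok) < n_min) {
    stop("reference window needs at least ", n_min,
         " non-missing beats (got ", sum(ok), ")", call. = FALSE)
  }
  xw <- xw[ok, , drop = FALSE]
  m <- colMeans(xw)
  S <- stats::cov(xw)
  ridge <- 0
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  needs_ridge <- min(ev) <= 0 ||
    (max(ev) / max(min(ev), .Machine$double.xmin)) > cond_max
  if (needs_ridge) {
    tr <- sum(diag(S))
    ridge <- if (tr > 0) eps * tr / d else 1e-12
    S <- S + diag(ridge, d)
  }
  structure(
    list(mean = m, cov = S, parameters = colnames(x),
         window = window, n_used = sum(ok), ridge = ridge),
    class = "tcg_reference"
  )
}

#' @export
print.tcg_reference <- function(x, ...) {
  cat("<tcg_reference>", paste(x$parameters, collapse = ", "),
      sprintf("| n = %d beats, ridge = %g\n", x$n_used, x$ridge))
  invisible(x)
}

#' Per-beat Mahalanobis distance against a reference
#'
#' `MD(x) = sqrt((x - m)' S^-1 (x - m))`; the distance (not its square)
#' is reported. Masked beats yield `NA`.
#'
#' @param x Matrix or data frame of beat-wise parameter vectors with the
#'   same columns as the reference.
#' @param ref A [fit_reference()] result.
#' @return Numeric vector of distances, one per row of `x`.
#' @export
md_series <- function(x, ref) {
  stopifnot(inherits(ref, "tcg_reference"))
  x <- as.matrix(x)
  if (ncol(x) != length(ref$mean)) {
    stop("dimension mismatch: reference holds ", length(ref$mean),
         " parameters, data has ", ncol(x), call. = FALSE)
  }
  out <- rep(NA_real_, nrow(x))
  ok <- stats::complete.cases(x)
  if (any(ok)) {
    out[ok] <- sqrt(stats::mahalanobis(x[ok, , drop = FALSE],
                                       ref$mean, ref$cov))
  }
  out
}

#' First beat where the MD series exceeds a reference quantile
#'
#' Scores the whole series against the reference window, takes the
#' `prob` quantile of the reference-window distances as the alarm
#' level, and returns the first target-window beat index strictly above
#' it. A simple change-onset summary for comparing index sets.
#'
#' @param x Parameter matrix (beats x parameters).
#' @param window Reference beat indices.
#' @param target Target beat indices (default: everything after the
#'   reference window).
#' @param prob Reference quantile (default 0.99).
#' @param sustain Number of consecutive beats that must exceed the
#'   threshold (default 3) -- single-beat excursions above a
#'   high reference quantile are expected by chance and do not
#'   constitute an onset.
#' @return List with `crossing` (first beat index of the first sustained
#'   run above threshold, `NA` if never), `threshold`, and the full `md`
#'   series.
#' @export
md_crossing <- function(x, window, target = NULL, prob = 0.99,
                        sustain = 3L) {
  ref <- fit_reference(x, window)
  md <- md_series(x, ref)
  thr <- stats::quantile(md[window], prob, na.rm = TRUE, names = FALSE)
  if (is.null(target)) {
    target <- seq(max(window) + 1L, nrow(as.matrix(x)))
  }
  above <- !is.na(md[target]) & md[target] > thr
  crossing <- NA_integer_
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= sustain)
    if (length(hit)) {
      crossing <- target[ends[hit[1]] - r$lengths[hit[1]] + 1L]
    }
  }
  list(crossing = crossing, threshold = thr, md = md)
}
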