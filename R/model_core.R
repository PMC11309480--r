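# Core beat model: ECG waveforms as differences of Gaussian CDFs.
#
# Each beat is described by four "legs": two rising CDFs for the
# depolarization (R-wave) transition of the anodic (Rp) and cathodic (Rn)
# myocardial groups, and two falling curves k*(1 - Phi) for the
# repolarization (T-wave) transition of the anodic (Tp) and cathodic (Tn)
# groups. The observable signal on a lead is the anodic minus cathodic
# difference plus a baseline level beta.

COMPONENT_NAMES <- c("Rp", "Rn", "Tp", "Tn")
METRIC_NAMES <- c("mu", "sigma", "k")

#' Single Gaussian-CDF leg of the beat model
#'
#' @param polarity `"anodic"` (positive electromotive contribution) or
#'   `"cathodic"` (negative).
#' @param direction `"rising"` (depolarization CDF, 0 at -Inf, `k` at +Inf)
#'   or `"falling"` (repolarization curve `k * (1 - Phi)`, `k` at -Inf,
#'   0 at +Inf).
#' @param mu Transition-time mean in ms relative to the beat reference
#'   (QRS onset).
#' @param sigma Transition-time spread in ms; must be positive.
#' @param k Non-negative amplitude weight in mV.
#'
#' @return An object of class `cdf_component`.
#' @export
cdf_component <- function(polarity = c("anodic", "cathodic"),
                          direction = c("rising", "falling"),
                          mu, sigma, k) {
  polarity <- match.arg(polarity)
  direction <- match.arg(direction)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single positive number (ms)", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stop("'k' must be a single non-negative number (mV)", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu)) {
    stop("'mu' must be a single finite number (ms)", call. = FALSE)
  }
  structure(
    list(polarity = polarity, direction = direction,
         mu = mu, sigma = sigma, k = k),
    class = "cdf_component"
  )
}

#' Evaluate one CDF leg on a time grid
#'
#' Rising legs evaluate to `k * Phi((t - mu) / sigma)`; falling legs to
#' `k * (1 - Phi((t - mu) / sigma))`, where `Phi` is the standard normal
#' CDF. The falling form keeps `sigma` positive and makes the direction
#' explicit rather than encoding it in a reversed argument.
#'
#' @param component A [cdf_component()].
#' @param t Time grid in ms.
#'
#' @return Amplitudes in mV, same length as `t`.
#' @export
eval_component <- function(component, t) {
  stopifnot(inherits(component, "cdf_component"))
  if (component$sigma <= 0) {
    stop("invalid parameter: sigma must be positive", call. = FALSE)
  }
  p <- stats::pnorm((t - component$mu) / component$sigma)
  if (component$direction == "falling") p <- 1 - p
  component$k * p
}

.phi <- function(t, mu, sigma) stats::pnorm((t - mu) / sigma)

#' Construct a per-beat model
#'
#' @param mu Named numeric of transition means (ms): `Rp`, `Rn`, `Tn`, `Tp`.
#' @param sigma Named numeric of spreads (ms), same names; all positive.
#' @param k Named numeric of amplitude weights (mV), same names;
#'   non-negative.
#' @param beta Baseline level(s) in mV. For `mode = "separate"` either a
#'   scalar (used for both segments) or a named vector `c(R = , T = )`;
#'   for `mode = "bulk"` a single level.
#' @param mode `"separate"` (R and T windows modelled independently, two
#'   baseline levels) or `"bulk"` (one joint trapezoid model with a single
#'   level).
#' @param extra Optional data frame of extra CDF pairs for complex QRS
#'   morphologies (delta waves, deep S waves), columns
#'   `mu_p, mu_n, sigma_p, sigma_n, k_p, k_n`; at most 2 rows.
#'
#' @details The physiologic temporal ordering is
#'   `mu_Rp <= mu_Rn <= mu_Tn <= mu_Tp`. Fits violating it are flagged
#'   (see [ordering_violated()]) but never silently reordered.
#'
#' @return An object of class `beat_model`.
#' @export
beat_model <- function(mu, sigma, k, beta = 0,
                       mode = c("separate", "bulk"), extra = NULL) {
  mode <- match.arg(mode)
  mu <- .named4(mu, "mu")
  sigma <- .named4(sigma, "sigma")
  k <- .named4(k, "k")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("all 'sigma' must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("all 'k' must be non-negative and finite", call. = FALSE)
  }
  if (mode == "separate") {
    if (length(beta) == 1L && is.null(names(beta))) {
      beta <- c(R = unname(beta), T = unname(beta))
    }
    if (!all(c("R", "T") %in% names(beta))) {
      stop("separate mode needs beta levels named 'R' and 'T'",
           call. = FALSE)
    }
    beta <- beta[c("R", "T")]
  } else {
    if (length(beta) != 1L) {
      stop("bulk mode carries a single beta level", call. = FALSE)
    }
    beta <- c(bulk = unname(beta))
  }
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    need <- c("mu_p", "mu_n", "sigma_p", "sigma_n", "k_p", "k_n")
    if (!all(need %in% names(extra))) {
      stop("'extra' needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (nrow(extra) > 2L) {
      stop("at most 2 extra CDF pairs are identifiable", call. = FALSE)
    }
  }
  structure(
    list(mu = mu, sigma = sigma, k = k, beta = beta, mode = mode,
         extra = extra),
    class = "beat_model"
  )
}

.named4 <- function(x, what) {
  if (is.null(names(x)) && length(x) == 4L) {
    names(x) <- c("Rp", "Rn", "Tn", "Tp")
  }
  if (!all(COMPONENT_NAMES %in% names(x))) {
    stop("'", what, "' must carry names Rp, Rn, Tn, Tp", call. = FALSE)
  }
  x[c("Rp", "Rn", "Tn", "Tp")]
}

#' Construct a beat model from interval metrics
#'
#' Population tables report the transition means only as intervals
#' (`muRTp = mu_Tp - mu_Rp`, `muRTn = mu_Tn - mu_Rn`,
#' `muRpn = mu_Rn - mu_Rp`); the absolute reference is arbitrary. This
#' helper rebuilds absolute means from the three independent intervals
#' given a reference `mu_Rp`.
#'
#' @param k,sigma Named numerics as in [beat_model()].
#' @param muRTp,muRTn,muRpn Interval metrics in ms.
#' @param mu_Rp Absolute anodic depolarization mean (ms); default 100.
#' @param beta,mode,extra Passed to [beat_model()].
#'
#' @return A `beat_model`.
#' @export
beat_model_from_intervals <- function(k, sigma, muRTp, muRTn, muRpn,
                                      mu_Rp = 100, beta = 0,
                                      mode = c("separate", "bulk"),
                                      extra = NULL) {
  mu <- c(Rp = mu_Rp,
          Rn = mu_Rp + muRpn,
          Tn = mu_Rp + muRpn + muRTn,
          Tp = mu_Rp + muRTp)
  beat_model(mu = mu, sigma = sigma, k = k, beta = beta, mode = mode,
             extra = extra)
}

#' Does a fitted model violate the physiologic temporal ordering?
#'
#' @param model A `beat_model`.
#' @return `TRUE` when `mu_Rp <= mu_Rn <= mu_Tn <= mu_Tp` fails.
#' @export
ordering_violated <- function(model) {
  mu <- model$mu
  !(mu["Rp"] <= mu["Rn"] && mu["Rn"] <= mu["Tn"] && mu["Tn"] <= mu["Tp"])
}

.extra_contrib <- function(extra, t) {
  out <- numeric(length(t))
  if (is.null(extra) || nrow(extra) == 0L) return(out)
  for (i in seq_len(nrow(extra))) {
    out <- out +
      extra$k_p[i] * .phi(t, extra$mu_p[i], extra$sigma_p[i]) -
      extra$k_n[i] * .phi(t, extra$mu_n[i], extra$sigma_n[i])
  }
  out
}

#' Forward model, RT-separate mode
#'
#' The R segment is the difference of the rising anodic and cathodic CDFs
#' plus the R-segment level: `k_Rp Phi_Rp - k_Rn Phi_Rn + beta_R`. The T
#' segment is the difference of the falling anodic and cathodic curves
#' plus the T-segment level:
#' `k_Tp (1 - Phi_Tp) - k_Tn (1 - Phi_Tn) + beta_T`.
#'
#' @param model A `beat_model` with `mode = "separate"`.
#' @param t Time grid in ms (beat-local).
#' @param segment `"R"` or `"T"`.
#'
#' @return Waveform in mV, same length as `t`.
#' @export
forward_separate <- function(model, t, segment = c("R", "T")) {
  stopifnot(inherits(model, "beat_model"))
  segment <- match.arg(segment)
  if (model$mode != "separate") {
    stop("forward_separate() needs a model with mode = 'separate'",
         call. = FALSE)
  }
  if (length(t) == 0L) stop("empty time grid", call. = FALSE)
  mu <- model$mu; sg <- model$sigma; k <- model$k
  if (segment == "R") {
    k[["Rp"]] * .phi(t, mu[["Rp"]], sg[["Rp"]]) -
      k[["Rn"]] * .phi(t, mu[["Rn"]], sg[["Rn"]]) +
      model$beta[["R"]] + .extra_contrib(model$extra, t)
  } else {
    k[["Tp"]] * (1 - .phi(t, mu[["Tp"]], sg[["Tp"]])) -
      k[["Tn"]] * (1 - .phi(t, mu[["Tn"]], sg[["Tn"]])) +
      model$beta[["T"]]
  }
}

#' Forward model, RT-bulk mode
#'
#' Joins each anodic and cathodic depolarization/repolarization pair at
#' the plateau: the anodic "trapezoid" is
#' `A(t) = k_Rp Phi_Rp(t) - k_Tp Phi_Tp(t)` and the cathodic one
#' `C(t) = k_Rn Phi_Rn(t) - k_Tn Phi_Tn(t)`; the signal is
#' `A(t) - C(t) + beta`. When `k_Tp = k_Rp` and `k_Tn = k_Rn` both
#' trapezoids close (return to 0 after the T wave).
#'
#' @param model A `beat_model` with `mode = "bulk"`.
#' @param t Time grid in ms.
#'
#' @return Waveform in mV, same length as `t`.
#' @export
forward_bulk <- function(model, t) {
  stopifnot(inherits(model, "beat_model"))
  if (model$mode != "bulk") {
    stop("forward_bulk() needs a model with mode = 'bulk'", call. = FALSE)
  }
  if (length(t) == 0L) stop("empty time grid", call. = FALSE)
  mu <- model$mu; sg <- model$sigma; k <- model$k
  A <- k[["Rp"]] * .phi(t, mu[["Rp"]], sg[["Rp"]]) -
    k[["Tp"]] * .phi(t, mu[["Tp"]], sg[["Tp"]])
  C <- k[["Rn"]] * .phi(t, mu[["Rn"]], sg[["Rn"]]) -
    k[["Tn"]] * .phi(t, mu[["Tn"]], sg[["Tn"]])
  A - C + model$beta[["bulk"]] + .extra_contrib(model$extra, t)
}

#' Evaluate a beat model on a time grid
#'
#' Dispatches to [forward_bulk()] or [forward_separate()] according to the
#' model's mode; for separate mode the `segment` argument selects the
#' window.
#'
#' @param object A `beat_model`.
#' @param t Time grid (ms).
#' @param segment For separate mode, `"R"` or `"T"`.
#' @param ... Unused.
#' @return Waveform in mV.
#' @export
predict.beat_model <- function(object, t, segment = "R", ...) {
  if (object$mode == "bulk") forward_bulk(object, t)
  else forward_separate(object, t, segment)
}

#' Derived interval metrics of a fitted beat model
#'
#' `muRTp = mu_Tp - mu_Rp` is the collective anodic action-potential
#' duration; `muRTn = mu_Tn - mu_Rn` its cathodic counterpart;
#' `muRpn = mu_Rn - mu_Rp` the depolarization transmural delay and
#' `muTpn = mu_Tp - mu_Tn` the repolarization one. By construction
#' `muRpn + muRTn + muTpn == muRTp` exactly.
#'
#' @param model A `beat_model`.
#' @param fit_stats Optional list with `r2` and `residual_sd` copied
#'   through from a fit.
#'
#' @return A list of class `tcg_metrics`: the four interval metrics plus
#'   all `sigma`'s, `k`'s, `beta`'s and any fit statistics.
#' @export
derive_metrics <- function(model, fit_stats = NULL) {
  mu <- model$mu
  out <- list(
    muRTp = unname(mu["Tp"] - mu["Rp"]),
    muRTn = unname(mu["Tn"] - mu["Rn"]),
    muRpn = unname(mu["Rn"] - mu["Rp"]),
    muTpn = unname(mu["Tp"] - mu["Tn"]),
    sigma = model$sigma,
    k = model$k,
    beta = model$beta
  )
  if (!is.null(fit_stats)) {
    out$r2 <- fit_stats$r2
    out$residual_sd <- fit_stats$residual_sd
  }
  structure(out, class = "tcg_metrics")
}

#' Late-repolarization inversion (fTp/fTn crossing)
#'
#' Finds the latest time in the T window where the anodic and cathodic
#' falling curves intersect with the cathodic tail outlasting the anodic
#' one (`fTn > fTp` beyond the crossing) -- the repolarization-inversion
#' marker seen in ischemia and early-repolarization cases.
#'
#' @param model A `beat_model`.
#' @param dt Scan-grid step in ms (default 1).
#' @param window Optional `c(from, to)` in ms; default
#'   `[mu_Tn - 3 sigma_Tn, mu_Tp + 4 sigma_Tp]`.
#'
#' @return List with `crossed` (logical) and `time` (ms, or `NA` when no
#'   inversion exists).
#' @export
find_repolarization_crossing <- function(model, dt = 1, window = NULL) {
  stopifnot(inherits(model, "beat_model"))
  mu <- model$mu; sg <- model$sigma; k <- model$k
  if (is.null(window)) {
    window <- c(mu[["Tn"]] - 3 * sg[["Tn"]], mu[["Tp"]] + 4 * sg[["Tp"]])
  }
  if (!is.finite(window[1]) || !is.finite(window[2]) ||
      window[2] <= window[1]) {
    warning("degenerate T window; no crossing search performed")
    return(list(crossed = FALSE, time = NA_real_))
  }
  tt <- seq(window[1], window[2], by = dt)
  d <- function(t) {
    k[["Tp"]] * (1 - .phi(t, mu[["Tp"]], sg[["Tp"]])) -
      k[["Tn"]] * (1 - .phi(t, mu[["Tn"]], sg[["Tn"]]))
  }
  dv <- d(tt)
  tol <- 1e-9 * max(k[["Tp"]], k[["Tn"]], 1e-12)
  s <- ifelse(dv > tol, 1L, ifelse(dv < -tol, -1L, 0L))
  # latest transition from anodic-above (+) to cathodic-above (-)
  nz <- which(s != 0L)
  if (length(nz) < 2L) return(list(crossed = FALSE, time = NA_real_))
  cross_idx <- NA_integer_
  prev <- nz[1]
  for (i in nz[-1]) {
    if (s[prev] == 1L && s[i] == -1L) cross_idx <- prev
    prev <- i
  }
  if (is.na(cross_idx)) return(list(crossed = FALSE, time = NA_real_))
  lo <- tt[cross_idx]
  hi <- tt[which(tt > lo & s == -1L)[1]]
  root <- stats::uniroot(d, lower = lo, upper = hi, tol = 1e-8)$root
  list(crossed = TRUE, time = root)
}

#' @export
print.beat_model <- function(x, ...) {
  cat("<beat_model> mode =", x$mode, "\n")
  tab <- rbind(mu = x$mu, sigma = x$sigma, k = x$k)
  print(round(tab, 3))
  cat("beta:", paste(sprintf("%s=%.3f", names(x$beta), x$beta),
                     collapse = " "), "\n")
  if (!is.null(x$extra) && nrow(x$extra) > 0L) {
    cat("extra CDF pairs:", nrow(x$extra), "\n")
  }
  invisible(x)
}

#' @export
print.tcg_metrics <- function(x, ...) {
  cat("<tcg_metrics>\n")
  cat(sprintf("  muRTp=%.2f muRTn=%.2f muRpn=%.2f muTpn=%.2f (ms)\n",
              x$muRTp, x$muRTn, x$muRpn, x$muTpn))
  if (!is.null(x$r2)) {
    cat("  r2:", paste(sprintf("%s=%.4f", names(x$r2), x$r2),
                       collapse = " "), "\n")
  }
  invisible(x)
}
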