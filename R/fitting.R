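# Bounded nonlinear least-squares estimation of beat-model parameters.
#
# Fitting goes through minpack.lm (Levenberg-Marquardt with box bounds).
# Three conventions:
#   * RT-separate: the QRS window and the T window are fitted
#     independently (7 free parameters each: mu_p, mu_n, sigma_p,
#     sigma_n, k_p, k_n, beta).
#   * RT-bulk: one joint trapezoid fit over [QRS onset, T end] with the
#     plateau constraint connecting the depolarization and repolarization
#     CDF pairs -- hard (k_Tp := k_Rp, k_Tn := k_Rn; 11 free) or as a
#     quadratic penalty (13 free).
#   * extended: extra CDF pairs inside the QRS window for complex
#     morphologies, seeded from the plain fit so the extended optimum can
#     never be worse.

#' Fitting configuration
#'
#' @param mode `"separate"`, `"bulk"` or `"extended"`.
#' @param plateau For bulk fits: `"hard"` equates the repolarization
#'   weights to the depolarization ones exactly; `"penalty"` leaves them
#'   free and adds `lambda * ((kTp - kRp)^2 + (kTn - kRn)^2)` to the cost.
#' @param lambda Penalty weight; default `10 * mean(signal^2)` computed at
#'   fit time.
#' @param extra_pairs Number of extra QRS CDF pairs for extended mode
#'   (1 or 2).
#' @param restarts Number of perturbed initializations (the unperturbed
#'   guess plus `restarts - 1` jittered ones); the lowest-cost solution
#'   is kept. Deterministic given `seed`.
#' @param seed Integer seed for the restart jitter.
#' @param bounds Named list of `c(min, max)` for `sigma`, `k`, `beta`,
#'   and `mu_margin` (allowed excursion of means beyond the fit window,
#'   ms).
#' @param max_iter Maximum optimizer iterations.
#' @param ftol,ptol Optimizer cost / step tolerances.
#' @param baseline_correct Subtract the PQ-segment median before fitting
#'   (off by default: the model itself absorbs the level through beta).
#'
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(mode = c("separate", "bulk", "extended"),
                       plateau = c("hard", "penalty"), lambda = NULL,
                       extra_pairs = 1L, restarts = 3L, seed = 1L,
                       bounds = list(sigma = c(1, 200), k = c(0, 20),
                                     beta = c(-2, 2), mu_margin = 50),
                       max_iter = 200L, ftol = 1e-12, ptol = 1e-10,
                       baseline_correct = FALSE) {
  mode <- match.arg(mode)
  plateau <- match.arg(plateau)
  if (!is.null(lambda) && lambda < 0) stop("'lambda' must be >= 0")
  if (mode == "extended" && (extra_pairs < 1L || extra_pairs > 2L)) {
    stop("extended mode supports 1 or 2 extra pairs (more is unidentifiable)",
         call. = FALSE)
  }
  structure(
    list(mode = mode, plateau = plateau, lambda = lambda,
         extra_pairs = as.integer(extra_pairs),
         restarts = as.integer(restarts), seed = as.integer(seed),
         bounds = bounds, max_iter = as.integer(max_iter),
         ftol = ftol, ptol = ptol, baseline_correct = baseline_correct),
    class = "fit_config"
  )
}

.check_fiducials <- function(fiducials) {
  need <- c("qrs_onset", "r_peak", "j_point", "t_onset", "t_peak", "t_end")
  for (nm in need) {
    if (is.null(fiducials[[nm]]) || !is.finite(fiducials[[nm]])) {
      stop("missing fiducial landmark: ", nm, call. = FALSE)
    }
  }
  v <- unlist(fiducials[need])
  if (any(diff(v) < 0)) {
    stop("invalid fiducials: landmarks must be non-decreasing in time (",
         paste(sprintf("%s=%.1f", need, v), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(fiducials)
}

.pq_baseline <- function(signal, t, fiducials) {
  w <- t >= fiducials$qrs_onset - 40 & t <= fiducials$qrs_onset
  if (!any(w)) return(signal[1])
  stats::median(signal[w])
}

#' Initial parameter guess from fiducial landmarks
#'
#' Means straddle the R and T peaks, spreads scale with the QRS and
#' T-wave widths (reflecting the physiologic hierarchy
#' `sigma_Rn < sigma_Rp << sigma_Tp < sigma_Tn`), weights come from the
#' R- and T-wave amplitudes, and the level from the PQ baseline.
#'
#' @param signal Beat samples in mV.
#' @param fs Sampling rate (Hz); the first sample sits at t = 0 ms.
#' @param fiducials Named list of landmark times in ms (`qrs_onset`,
#'   `r_peak`, `j_point`, `t_onset`, `t_peak`, `t_end`).
#' @param mode Model convention for the guess.
#'
#' @return A `beat_model`.
#' @export
initial_guess <- function(signal, fs, fiducials,
                          mode = c("separate", "bulk")) {
  mode <- match.arg(mode)
  .check_fiducials(fiducials)
  t <- (seq_along(signal) - 1L) * 1000 / fs
  base <- .pq_baseline(signal, t, fiducials)
  qrs_w <- fiducials$j_point - fiducials$qrs_onset
  t_w <- fiducials$t_end - fiducials$t_onset
  r_amp <- signal[which.min(abs(t - fiducials$r_peak))] - base
  t_amp <- signal[which.min(abs(t - fiducials$t_peak))] - base
  mu <- c(Rp = fiducials$r_peak - qrs_w / 4,
          Rn = fiducials$r_peak + qrs_w / 4,
          Tn = fiducials$t_peak - t_w / 8,
          Tp = fiducials$t_peak + t_w / 8)
  sigma <- c(Rp = qrs_w / 4, Rn = qrs_w / 4,
             Tn = t_w / 4, Tp = t_w / 8)
  sigma <- pmax(sigma, 1)
  kR <- max(abs(r_amp) * 1.5, 0)
  kT <- if (mode == "bulk") kR else max(abs(t_amp) * 2, 0)
  k <- c(Rp = kR, Rn = kR, Tn = kT, Tp = kT)
  beta <- if (mode == "separate") c(R = base, T = base) else base
  beat_model(mu = mu, sigma = sigma, k = k, beta = beta, mode = mode)
}

#' Goodness of fit of a modelled window
#'
#' @param observed,fitted Equal-length numeric vectors.
#' @return List with `r2` (`NA` with a `"constant"` flag when the
#'   observed window has no variance) and `residual_sd` (sample SD of
#'   residuals).
#' @export
goodness_of_fit <- function(observed, fitted) {
  if (length(observed) != length(fitted)) {
    stop("'observed' and 'fitted' must have equal length", call. = FALSE)
  }
  res <- observed - fitted
  ss_tot <- sum((observed - mean(observed))^2)
  out <- list(
    r2 = if (ss_tot <= 0) NA_real_ else 1 - sum(res^2) / ss_tot,
    residual_sd = stats::sd(res)
  )
  if (ss_tot <= 0) attr(out, "flag") <- "constant"
  out
}

# ---- internal optimizer plumbing ------------------------------------

.lm_fit <- function(par, lower, upper, resid_fn, cfg) {
  par <- pmin(pmax(par, lower), upper)
  ans <- minpack.lm::nls.lm(
    par = par, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = cfg$max_iter, ftol = cfg$ftol, ptol = cfg$ptol)
  )
  list(par = ans$par, deviance = ans$deviance,
       converged = ans$info %in% 1:4, iterations = ans$niter)
}

.restart_jitters <- function(cfg, n_par) {
  jitters <- vector("list", cfg$restarts)
  jitters[[1]] <- rep(0, n_par)
  if (cfg$restarts > 1L) {
    .with_seed(cfg$seed, {
      for (i in 2:cfg$restarts) {
        jitters[[i]] <- stats::rnorm(n_par, 0, 1)
      }
    })
  }
  jitters
}

# jitter: means shift by up to ~5 ms, scales multiply by ~10%
.apply_jitter <- function(par, jitter, is_mu) {
  out <- par
  out[is_mu] <- out[is_mu] + 5 * jitter[is_mu]
  out[!is_mu] <- out[!is_mu] * exp(0.1 * jitter[!is_mu])
  out
}

.best_of_restarts <- function(start, lower, upper, resid_fn, cfg, is_mu) {
  best <- NULL
  for (j in .restart_jitters(cfg, length(start))) {
    st <- .apply_jitter(start, j, is_mu)
    fit <- .lm_fit(st, lower, upper, resid_fn, cfg)
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

.window_samples <- function(signal, t, from, to, label) {
  idx <- which(t >= from & t <= to)
  if (length(idx) < 8L) {
    stop(label, " window holds fewer than 8 samples", call. = FALSE)
  }
  idx
}

.fit_warnings <- function(model, r2, par, lower, upper) {
  w <- character()
  if (ordering_violated(model)) w <- c(w, "ordering violation")
  at_bound <- abs(par - lower) < 1e-9 | abs(upper - par) < 1e-9
  if (any(at_bound)) w <- c(w, "parameter at bound")
  if (any(!is.na(r2) & r2 < 0.5)) w <- c(w, "poor fit (r2 < 0.5)")
  cr <- find_repolarization_crossing(model)
  if (isTRUE(cr$crossed)) w <- c(w, "repolarization crossing")
  w
}

.make_fit_result <- function(model, r2, residual_sd, converged,
                             iterations, cost, par, lower, upper,
                             windows, mode) {
  warnings <- .fit_warnings(model, r2, par, lower, upper)
  structure(
    list(model = model,
         metrics = derive_metrics(model, list(r2 = r2,
                                              residual_sd = residual_sd)),
         r2 = r2, residual_sd = residual_sd,
         converged = converged && !any(r2 < 0.5, na.rm = TRUE),
         iterations = iterations, cost = cost,
         warnings = warnings, windows = windows, mode = mode),
    class = "tcg_fit"
  )
}

#' @export
print.tcg_fit <- function(x, ...) {
  cat("<tcg_fit> mode =", x$mode,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$model)
  cat("r2:", paste(sprintf("%s=%.4f", names(x$r2), x$r2),
                   collapse = " "), "\n")
  if (length(x$warnings)) cat("warnings:",
                              paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# ---- RT-separate -----------------------------------------------------

#' Fit a beat in RT-separate mode
#'
#' Fits the rising CDF difference to the QRS window
#' `[qrs_onset, j_point]` and the falling CDF difference to the T window
#' `[t_onset, t_end]` as two independent bounded least-squares problems
#' (7 free parameters each).
#'
#' @param signal Beat samples in mV; the first sample is t = 0 ms.
#' @param fs Sampling rate (Hz).
#' @param fiducials Named list of landmark times in ms (see
#'   [initial_guess()]).
#' @param config A [fit_config()].
#'
#' @return An object of class `tcg_fit`: the fitted `beat_model`,
#'   derived `tcg_metrics`, per-segment and overall r-squared and
#'   residual SD, convergence flag and warnings.
#' @export
fit_rt_separate <- function(signal, fs, fiducials,
                            config = fit_config("separate")) {
  .check_fiducials(fiducials)
  t <- (seq_along(signal) - 1L) * 1000 / fs
  if (config$baseline_correct) {
    signal <- signal - .pq_baseline(signal, t, fiducials)
  }
  g0 <- initial_guess(signal, fs, fiducials, mode = "separate")
  b <- config$bounds
  idxR <- .window_samples(signal, t, fiducials$qrs_onset,
                          fiducials$j_point, "QRS")
  idxT <- .window_samples(signal, t, fiducials$t_onset,
                          fiducials$t_end, "T")

  fit_seg <- function(idx, mu_names, falling) {
    tw <- t[idx]; yw <- signal[idx]
    par <- c(g0$mu[mu_names], g0$sigma[mu_names], g0$k[mu_names],
             beta = unname(g0$beta[[if (falling) "T" else "R"]]))
    lower <- c(rep(min(tw) - b$mu_margin, 2), rep(b$sigma[1], 2),
               rep(b$k[1], 2), b$beta[1])
    upper <- c(rep(max(tw) + b$mu_margin, 2), rep(b$sigma[2], 2),
               rep(b$k[2], 2), b$beta[2])
    is_mu <- c(TRUE, TRUE, rep(FALSE, 5))
    model_of <- function(p) {
      mp <- .phi(tw, p[1], p[3]); mn <- .phi(tw, p[2], p[4])
      if (falling) p[5] * (1 - mp) - p[6] * (1 - mn) + p[7]
      else p[5] * mp - p[6] * mn + p[7]
    }
    resid_fn <- function(p) yw - model_of(p)
    fit <- .best_of_restarts(par, lower, upper, resid_fn, config, is_mu)
    fit$par <- unname(fit$par)
    fit$fitted <- model_of(fit$par)
    fit$lower <- lower; fit$upper <- upper; fit$y <- yw
    fit
  }

  fR <- fit_seg(idxR, c("Rp", "Rn"), falling = FALSE)
  fT <- fit_seg(idxT, c("Tp", "Tn"), falling = TRUE)

  model <- beat_model(
    mu = c(Rp = fR$par[1], Rn = fR$par[2],
           Tn = fT$par[2], Tp = fT$par[1]),
    sigma = c(Rp = fR$par[3], Rn = fR$par[4],
              Tn = fT$par[4], Tp = fT$par[3]),
    k = c(Rp = fR$par[5], Rn = fR$par[6],
          Tn = fT$par[6], Tp = fT$par[5]),
    beta = c(R = unname(fR$par[7]), T = unname(fT$par[7])),
    mode = "separate"
  )
  gR <- goodness_of_fit(fR$y, fR$fitted)
  gT <- goodness_of_fit(fT$y, fT$fitted)
  gAll <- goodness_of_fit(c(fR$y, fT$y), c(fR$fitted, fT$fitted))
  .make_fit_result(
    model,
    r2 = c(QRS = gR$r2, T = gT$r2, overall = gAll$r2),
    residual_sd = c(QRS = gR$residual_sd, T = gT$residual_sd,
                    overall = gAll$residual_sd),
    converged = fR$converged && fT$converged,
    iterations = fR$iterations + fT$iterations,
    cost = fR$deviance + fT$deviance,
    par = c(fR$par, fT$par),
    lower = c(fR$lower, fT$lower), upper = c(fR$upper, fT$upper),
    windows = list(QRS = range(t[idxR]), T = range(t[idxT])),
    mode = "separate"
  )
}

# ---- RT-bulk ---------------------------------------------------------

.bulk_model_of <- function(tw, p, hard, n_extra = 0L) {
  # p: muRp muRn muTn muTp sRp sRn sTn sTp kRp kRn beta [kTp kTn]
  #    [+ per extra pair: mu_p mu_n sigma_p sigma_n k_p k_n]
  kTp <- if (hard) p[9] else p[12]
  kTn <- if (hard) p[10] else p[13]
  base <- 11L + if (hard) 0L else 2L
  out <- p[9] * .phi(tw, p[1], p[5]) - kTp * .phi(tw, p[4], p[8]) -
    (p[10] * .phi(tw, p[2], p[6]) - kTn * .phi(tw, p[3], p[7])) + p[11]
  if (n_extra > 0L) {
    for (e in seq_len(n_extra)) {
      q <- p[base + (e - 1L) * 6L + 1:6]
      out <- out + q[5] * .phi(tw, q[1], q[3]) -
        q[6] * .phi(tw, q[2], q[4])
    }
  }
  out
}

#' Fit a beat in RT-bulk mode
#'
#' One joint bounded least-squares fit of the trapezoid model over
#' `[qrs_onset, t_end]`, with the plateau constraint connecting each
#' anodic/cathodic depolarization CDF to its repolarization partner:
#' hard (`kTp := kRp`, `kTn := kRn`) or as a quadratic penalty on the
#' weight differences.
#'
#' @inheritParams fit_rt_separate
#' @return A `tcg_fit` with a single beta level; r-squared is reported
#'   for the full window (named `bulk`/`overall`).
#' @export
fit_rt_bulk <- function(signal, fs, fiducials,
                        config = fit_config("bulk")) {
  .check_fiducials(fiducials)
  t <- (seq_along(signal) - 1L) * 1000 / fs
  if (config$baseline_correct) {
    signal <- signal - .pq_baseline(signal, t, fiducials)
  }
  g0 <- initial_guess(signal, fs, fiducials, mode = "bulk")
  b <- config$bounds
  idx <- .window_samples(signal, t, fiducials$qrs_onset,
                         fiducials$t_end, "bulk")
  tw <- t[idx]; yw <- signal[idx]
  hard <- config$plateau == "hard"
  lambda <- config$lambda
  if (is.null(lambda)) lambda <- 10 * mean(yw^2)

  par <- c(g0$mu[c("Rp", "Rn", "Tn", "Tp")],
           g0$sigma[c("Rp", "Rn", "Tn", "Tp")],
           g0$k[c("Rp", "Rn")], beta = unname(g0$beta[[1]]))
  lower <- c(rep(min(tw) - b$mu_margin, 4), rep(b$sigma[1], 4),
             rep(b$k[1], 2), b$beta[1])
  upper <- c(rep(max(tw) + b$mu_margin, 4), rep(b$sigma[2], 4),
             rep(b$k[2], 2), b$beta[2])
  is_mu <- c(rep(TRUE, 4), rep(FALSE, 7))
  if (!hard) {
    par <- c(par, g0$k[c("Tp", "Tn")])
    lower <- c(lower, rep(b$k[1], 2))
    upper <- c(upper, rep(b$k[2], 2))
    is_mu <- c(is_mu, FALSE, FALSE)
  }
  resid_fn <- function(p) {
    r <- yw - .bulk_model_of(tw, p, hard)
    if (!hard) {
      r <- c(r, sqrt(lambda) * (p[12] - p[9]),
             sqrt(lambda) * (p[13] - p[10]))
    }
    r
  }
  fit <- .best_of_restarts(par, lower, upper, resid_fn, config, is_mu)
  p <- unname(fit$par)
  kTp <- if (hard) p[9] else p[12]
  kTn <- if (hard) p[10] else p[13]
  model <- beat_model(
    mu = c(Rp = p[1], Rn = p[2], Tn = p[3], Tp = p[4]),
    sigma = c(Rp = p[5], Rn = p[6], Tn = p[7], Tp = p[8]),
    k = c(Rp = p[9], Rn = p[10], Tn = kTn, Tp = kTp),
    beta = p[11], mode = "bulk"
  )
  fitted <- .bulk_model_of(tw, p, hard)
  g <- goodness_of_fit(yw, fitted)
  .make_fit_result(
    model,
    r2 = c(bulk = g$r2, overall = g$r2),
    residual_sd = c(bulk = g$residual_sd, overall = g$residual_sd),
    converged = fit$converged,
    iterations = fit$iterations, cost = fit$deviance,
    par = p, lower = lower, upper = upper,
    windows = list(bulk = range(tw)),
    mode = "bulk"
  )
}

# ---- extended --------------------------------------------------------

#' Fit a beat with extra QRS CDF pairs (extended mode)
#'
#' Augments the RT-separate model with 1 or 2 additional anodic/cathodic
#' CDF pairs inside the QRS window, for morphologies the four canonical
#' legs cannot represent (delta waves, deep S waves, J waves). The
#' extended fit is seeded from the plain 4-CDF fit with near-zero extra
#' weights, so its optimum cost can never exceed the plain one. The four
#' canonical components are still reported; extra pairs are returned in
#' the model's `extra` table.
#'
#' @inheritParams fit_rt_separate
#' @param config A [fit_config()] with `mode = "extended"` and
#'   `extra_pairs` in 1:2.
#' @return A `tcg_fit` whose model carries the extra pairs.
#' @export
fit_extended <- function(signal, fs, fiducials,
                         config = fit_config("extended")) {
  if (config$extra_pairs < 1L || config$extra_pairs > 2L) {
    stop("extended mode supports 1 or 2 extra pairs", call. = FALSE)
  }
  base_cfg <- config
  base_cfg$mode <- "separate"
  base <- fit_rt_separate(signal, fs, fiducials, base_cfg)

  t <- (seq_along(signal) - 1L) * 1000 / fs
  if (config$baseline_correct) {
    signal <- signal - .pq_baseline(signal, t, fiducials)
  }
  b <- config$bounds
  idxR <- .window_samples(signal, t, fiducials$qrs_onset,
                          fiducials$j_point, "QRS")
  tw <- t[idxR]; yw <- signal[idxR]
  n_e <- config$extra_pairs
  m0 <- base$model

  # start at the plain solution; extras near-flat with tiny weight
  qrs_w <- fiducials$j_point - fiducials$qrs_onset
  par <- c(m0$mu[c("Rp", "Rn")], m0$sigma[c("Rp", "Rn")],
           m0$k[c("Rp", "Rn")], beta = unname(m0$beta[["R"]]))
  for (e in seq_len(n_e)) {
    off <- qrs_w * e / (n_e + 1)
    par <- c(par, fiducials$qrs_onset + off, fiducials$qrs_onset + off,
             qrs_w / 6, qrs_w / 6, 1e-3, 1e-3)
  }
  lower <- c(rep(min(tw) - b$mu_margin, 2), rep(b$sigma[1], 2),
             rep(b$k[1], 2), b$beta[1],
             rep(c(rep(min(tw) - b$mu_margin, 2), rep(b$sigma[1], 2),
                   rep(b$k[1], 2)), n_e))
  upper <- c(rep(max(tw) + b$mu_margin, 2), rep(b$sigma[2], 2),
             rep(b$k[2], 2), b$beta[2],
             rep(c(rep(max(tw) + b$mu_margin, 2), rep(b$sigma[2], 2),
                   rep(b$k[2], 2)), n_e))
  is_mu <- c(TRUE, TRUE, rep(FALSE, 5),
             rep(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), n_e))
  model_of <- function(p) {
    out <- p[5] * .phi(tw, p[1], p[3]) - p[6] * .phi(tw, p[2], p[4]) + p[7]
    for (e in seq_len(n_e)) {
      q <- p[7L + (e - 1L) * 6L + 1:6]
      out <- out + q[5] * .phi(tw, q[1], q[3]) -
        q[6] * .phi(tw, q[2], q[4])
    }
    out
  }
  # small ridge on extra weights: a cancelling anodic/cathodic pair with
  # arbitrary large k is observationally equivalent to no pair at all,
  # so without it the extra weights are unidentifiable on plain beats
  ridge <- sqrt(1e-3)
  resid_fn <- function(p) {
    ke <- unlist(lapply(seq_len(n_e), function(e) {
      p[7L + (e - 1L) * 6L + 5:6]
    }))
    c(yw - model_of(p), ridge * ke)
  }
  fit <- .best_of_restarts(par, lower, upper, resid_fn, config, is_mu)
  p <- unname(fit$par)
  extra <- do.call(rbind, lapply(seq_len(n_e), function(e) {
    q <- p[7L + (e - 1L) * 6L + 1:6]
    data.frame(mu_p = q[1], mu_n = q[2], sigma_p = q[3],
               sigma_n = q[4], k_p = q[5], k_n = q[6])
  }))
  model <- beat_model(
    mu = c(Rp = p[1], Rn = p[2],
           Tn = m0$mu[["Tn"]], Tp = m0$mu[["Tp"]]),
    sigma = c(Rp = p[3], Rn = p[4],
              Tn = m0$sigma[["Tn"]], Tp = m0$sigma[["Tp"]]),
    k = c(Rp = p[5], Rn = p[6],
          Tn = m0$k[["Tn"]], Tp = m0$k[["Tp"]]),
    beta = c(R = unname(p[7]), T = unname(m0$beta[["T"]])),
    mode = "separate", extra = extra
  )
  gR <- goodness_of_fit(yw, model_of(p))
  idxT <- .window_samples(signal, t, fiducials$t_onset,
                          fiducials$t_end, "T")
  fitT <- forward_separate(m0, t[idxT], "T")
  gAll <- goodness_of_fit(c(yw, signal[idxT]), c(model_of(p), fitT))
  r2 <- c(QRS = gR$r2, T = base$r2[["T"]], overall = gAll$r2)
  .make_fit_result(
    model, r2 = r2,
    residual_sd = c(QRS = gR$residual_sd, T = base$residual_sd[["T"]]),
    converged = fit$converged,
    iterations = fit$iterations, cost = fit$deviance,
    par = p, lower = lower, upper = upper,
    windows = list(QRS = range(tw), T = base$windows$T),
    mode = "extended"
  )
}
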