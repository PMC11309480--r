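# The parameter tensor: per-beat, per-lead fitted parameters as a
# 4th-order array [beat, lead, component, metric] with companion
# per-beat columns (levels, derived intervals, fit quality, conventional
# indices). Non-converged beats are masked (NA), never dropped.

#' Assemble fit results into a parameter tensor
#'
#' @param fits Either a list of `tcg_fit` objects (one lead) or a nested
#'   list `fits[[beat]][[lead]]`; every beat must carry the same lead
#'   set.
#' @param leads Character vector of lead names.
#' @param timestamps Optional per-beat timestamps (ms from record start).
#' @param conventional Optional data frame with per-beat `STlevel`, `QT`,
#'   `RRI` (as from [conventional_indices()]).
#'
#' @return An object of class `tcg_tensor`: `params`, a
#'   `beat x lead x component(Rp,Rn,Tp,Tn) x metric(mu,sigma,k)` array
#'   (NA-masked where a fit did not converge), and `info`, a
#'   beat-x-lead data frame of levels, interval metrics, r-squared,
#'   convergence and conventional indices.
#' @export
assemble_tensor <- function(fits, leads = "II", timestamps = NULL,
                            conventional = NULL) {
  if (length(fits) && inherits(fits[[1]], "tcg_fit")) {
    fits <- lapply(fits, function(f) list(f))
  }
  n_beats <- length(fits)
  n_leads <- length(leads)
  bad <- which(vapply(fits, length, 1L) != n_leads)
  if (length(bad)) {
    stop("inconsistent lead sets at beat(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  arr <- array(NA_real_,
               dim = c(n_beats, n_leads, 4L, 3L),
               dimnames = list(NULL, leads, COMPONENT_NAMES, METRIC_NAMES))
  if (is.null(timestamps)) timestamps <- rep(NA_real_, n_beats)
  rows <- vector("list", max(n_beats * n_leads, 0L))
  ri <- 0L
  for (b in seq_len(n_beats)) {
    for (l in seq_len(n_leads)) {
      f <- fits[[b]][[l]]
      stopifnot(inherits(f, "tcg_fit"))
      conv <- isTRUE(f$converged)
      if (conv) {
        m <- f$model
        arr[b, l, , "mu"] <- m$mu[COMPONENT_NAMES]
        arr[b, l, , "sigma"] <- m$sigma[COMPONENT_NAMES]
        arr[b, l, , "k"] <- m$k[COMPONENT_NAMES]
      }
      met <- f$metrics
      beta <- f$model$beta
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        beat = b, lead = leads[l], timestamp = timestamps[b],
        mode = f$mode,
        betaR = if ("R" %in% names(beta)) beta[["R"]] else beta[[1]],
        betaT = if ("T" %in% names(beta)) beta[["T"]] else beta[[1]],
        muRTp = if (conv) met$muRTp else NA_real_,
        muRTn = if (conv) met$muRTn else NA_real_,
        muRpn = if (conv) met$muRpn else NA_real_,
        muTpn = if (conv) met$muTpn else NA_real_,
        r2QRS = if ("QRS" %in% names(f$r2)) f$r2[["QRS"]] else NA_real_,
        r2T = if ("T" %in% names(f$r2)) f$r2[["T"]] else NA_real_,
        r2overall = if ("overall" %in% names(f$r2))
          f$r2[["overall"]] else NA_real_,
        converged = conv
      )
    }
  }
  info <- if (ri) do.call(rbind, rows) else
    data.frame(beat = integer(), lead = character(),
               timestamp = numeric(), mode = character(),
               betaR = numeric(), betaT = numeric(),
               muRTp = numeric(), muRTn = numeric(),
               muRpn = numeric(), muTpn = numeric(),
               r2QRS = numeric(), r2T = numeric(),
               r2overall = numeric(), converged = logical())
  if (!is.null(conventional)) {
    conv_cols <- conventional[match(info$beat, conventional$beat),
                              c("STlevel", "QT", "RRI"), drop = FALSE]
    info <- cbind(info, conv_cols)
  } else {
    info$STlevel <- rep(NA_real_, nrow(info))
    info$QT <- rep(NA_real_, nrow(info))
    info$RRI <- rep(NA_real_, nrow(info))
  }
  rownames(info) <- NULL
  structure(list(params = arr, info = info, leads = leads),
            class = "tcg_tensor")
}

#' @export
print.tcg_tensor <- function(x, ...) {
  d <- dim(x$params)
  cat(sprintf(
    "<tcg_tensor> %d beat(s) x %d lead(s) x 4 components x 3 metrics\n",
    d[1], d[2]))
  cat("masked (non-converged) beat-lead cells:",
      sum(!x$info$converged), "\n")
  invisible(x)
}

.raw_param_names <- as.vector(outer(
  c("mu", "sigma", "k"), COMPONENT_NAMES, paste0))
.derived_param_names <- c("muRTp", "muRTn", "muRpn", "muTpn",
                          "betaR", "betaT", "r2QRS", "r2T", "r2overall",
                          "STlevel", "QT", "RRI")

#' Extract a per-beat parameter time series from the tensor
#'
#' @param tensor A `tcg_tensor`.
#' @param parameter One of the raw names (`muRp`, `sigmaTn`, `kTp`, ...)
#'   or companion names (`muRTp`, `betaR`, `r2QRS`, `STlevel`, `QT`,
#'   `RRI`, ...).
#' @param lead Lead name or index.
#' @return Numeric vector ordered by beat, `NA` at masked beats,
#'   with the beat timestamps as the `"timestamps"` attribute.
#' @export
extract_series <- function(tensor, parameter, lead = 1L) {
  stopifnot(inherits(tensor, "tcg_tensor"))
  if (is.character(lead)) lead <- match(lead, tensor$leads)
  if (is.na(lead) || lead < 1L || lead > length(tensor$leads)) {
    stop("unknown lead", call. = FALSE)
  }
  lead_name <- tensor$leads[lead]
  sub <- tensor$info[tensor$info$lead == lead_name, , drop = FALSE]
  sub <- sub[order(sub$beat), , drop = FALSE]
  if (parameter %in% .raw_param_names) {
    metric <- sub("^(mu|sigma|k).*", "\\1", parameter)
    comp <- sub("^(mu|sigma|k)", "", parameter)
    out <- tensor$params[, lead, comp, metric]
  } else if (parameter %in% .derived_param_names) {
    out <- sub[[parameter]]
    out[!sub$converged & parameter %in%
          c("muRTp", "muRTn", "muRpn", "muTpn")] <- NA_real_
  } else {
    stop("unknown parameter '", parameter, "'; valid names: ",
         paste(c(.raw_param_names, .derived_param_names),
               collapse = ", "), call. = FALSE)
  }
  structure(as.numeric(out), timestamps = sub$timestamp)
}

#' Fixed-threshold flagging rule
#'
#' @param parameter Parameter name the rule applies to.
#' @param high,low Thresholds; values `>= high` are flagged high,
#'   `<= low` flagged low; `low` must be below `high`.
#' @param labels Length-2 character: the clinical labels for the high
#'   and low flags (e.g. elongation/shortening).
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(parameter, high, low,
                           labels = c("elongation", "shortening")) {
  if (!(low < high)) stop("'low' must be below 'high'", call. = FALSE)
  structure(list(parameter = parameter, high = high, low = low,
                 labels = labels),
            class = "threshold_rule")
}

#' Default repolarization-spread flagging rules
#'
#' Ships the fixed case-derived thresholds used for ischemia monitoring:
#' `sigmaTp >= 45` elongation / `<= 35` shortening and `sigmaTn >= 80` /
#' `<= 70`. These are single-case working thresholds, not
#' population-calibrated limits.
#'
#' @return Named list of [threshold_rule()]s.
#' @export
default_threshold_rules <- function() {
  list(
    sigmaTp = threshold_rule("sigmaTp", high = 45, low = 35),
    sigmaTn = threshold_rule("sigmaTn", high = 80, low = 70)
  )
}

#' Apply a threshold rule to a parameter series
#'
#' @param series Numeric per-beat values (`NA` = masked).
#' @param rule A [threshold_rule()].
#' @return Character vector of per-beat labels:
#'   `"high"`, `"low"`, `"normal"` or `"missing"`.
#' @export
flag_thresholds <- function(series, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  out <- rep("normal", length(series))
  out[!is.na(series) & series >= rule$high] <- "high"
  out[!is.na(series) & series <= rule$low] <- "low"
  out[is.na(series)] <- "missing"
  out
}

#' Flatten a parameter tensor to the tabular contract
#'
#' One row per beat x lead with the fixed column set (raw parameters,
#' levels, interval metrics, fit quality, conventional indices).
#'
#' @param x A `tcg_tensor`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.tcg_tensor <- function(x, ...) {
  info <- x$info
  n <- nrow(info)
  get_param <- function(b, l, comp, metric) {
    x$params[b, match(l, x$leads), comp, metric]
  }
  raw <- data.frame(
    muRp = numeric(n), muRn = numeric(n), muTn = numeric(n),
    muTp = numeric(n), sigmaRp = numeric(n), sigmaRn = numeric(n),
    sigmaTp = numeric(n), sigmaTn = numeric(n), kRp = numeric(n),
    kRn = numeric(n), kTp = numeric(n), kTn = numeric(n)
  )
  for (i in seq_len(n)) {
    b <- info$beat[i]; l <- info$lead[i]
    for (comp in COMPONENT_NAMES) {
      raw[[paste0("mu", comp)]][i] <- get_param(b, l, comp, "mu")
      raw[[paste0("sigma", comp)]][i] <- get_param(b, l, comp, "sigma")
      raw[[paste0("k", comp)]][i] <- get_param(b, l, comp, "k")
    }
  }
  cbind(info[c("beat", "lead", "timestamp", "mode")], raw,
        info[c("betaR", "betaT", "muRTp", "muRTn", "muRpn", "muTpn",
               "r2QRS", "r2T", "r2overall", "STlevel", "QT", "RRI",
               "converged")])
}

#' Write the parameter tensor as CSV
#'
#' Masked (non-converged) cells serialize as empty fields and are
#' restored as masks by [read_parameters()]; the round trip is lossless.
#'
#' @param tensor A `tcg_tensor`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(tensor, path) {
  df <- as.data.frame(tensor)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a parameter table back into a tensor
#'
#' @param path CSV written by [write_parameters()].
#' @return A `tcg_tensor`.
#' @export
read_parameters <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num_cols <- setdiff(names(df), c("lead", "mode", "converged"))
  for (nm in num_cols) df[[nm]] <- as.numeric(df[[nm]])
  leads <- unique(df$lead)
  beats <- sort(unique(df$beat))
  n_beats <- length(beats)
  arr <- array(NA_real_,
               dim = c(n_beats, length(leads), 4L, 3L),
               dimnames = list(NULL, leads, COMPONENT_NAMES, METRIC_NAMES))
  for (i in seq_len(nrow(df))) {
    b <- match(df$beat[i], beats); l <- match(df$lead[i], leads)
    for (comp in COMPONENT_NAMES) {
      arr[b, l, comp, "mu"] <- df[[paste0("mu", comp)]][i]
      arr[b, l, comp, "sigma"] <- df[[paste0("sigma", comp)]][i]
      arr[b, l, comp, "k"] <- df[[paste0("k", comp)]][i]
    }
  }
  info <- df[c("beat", "lead", "timestamp", "mode", "betaR", "betaT",
               "muRTp", "muRTn", "muRpn", "muTpn", "r2QRS", "r2T",
               "r2overall", "converged", "STlevel", "QT", "RRI")]
  structure(list(params = arr, info = info, leads = leads),
            class = "tcg_tensor")
}
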