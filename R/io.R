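# Record input/output: plain CSV (time + per-lead voltage columns) and
# a minimal WFDB implementation (format-16 .dat with a standard .hea
# header). No R-side WFDB reader is available as a dependency, so the
# format-16 subset used by the generator's exporter is implemented here
# directly; gain and ADC-zero fields are honored on read and samples are
# always converted to mV.

#' Read an ECG record
#'
#' @param path For CSV, the file path; for WFDB, the path to the `.hea`
#'   header (or the record name without extension).
#' @param format `"auto"` (by extension), `"csv"` or `"wfdb"`.
#' @return An [ecg_record()] in mV.
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
    else "wfdb"
  }
  if (format == "csv") .read_record_csv(path) else .read_record_wfdb(path)
}

#' Write an ECG record
#'
#' @param record An [ecg_record()].
#' @param path Output path: `.csv`, or the `.hea` path / record name for
#'   WFDB (the `.dat` lands next to it).
#' @param format `"auto"`, `"csv"` or `"wfdb"`.
#' @param gain WFDB gain in ADC units per mV (default 200).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("auto", "csv", "wfdb"),
                         gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
    else "wfdb"
  }
  if (format == "csv") .write_record_csv(record, path)
  else .write_record_wfdb(record, path, gain)
  invisible(path)
}

.read_record_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) {
    stop("malformed CSV record: no 'time' column", call. = FALSE)
  }
  if (ncol(df) < 2L) {
    stop("malformed CSV record: no lead columns", call. = FALSE)
  }
  dt <- diff(df$time)
  if (length(dt) < 1L || any(dt <= 0)) {
    stop("malformed CSV record: 'time' must be strictly increasing",
         call. = FALSE)
  }
  fs <- 1 / stats::median(dt)
  leads <- setdiff(names(df), "time")
  ecg_record(as.matrix(df[leads]), fs = round(fs, 6),
             lead_names = leads)
}

.write_record_csv <- function(record, path) {
  n <- nrow(record$signals)
  df <- data.frame(time = (seq_len(n) - 1L) / record$fs)
  for (l in record$lead_names) df[[l]] <- record$signals[, l]
  utils::write.csv(df, path, row.names = FALSE)
}

.wfdb_paths <- function(path) {
  base <- sub("\\.hea$", "", path)
  list(hea = paste0(base, ".hea"), dat = paste0(base, ".dat"),
       name = basename(base))
}

.write_record_wfdb <- function(record, path, gain = 200) {
  p <- .wfdb_paths(path)
  nsig <- ncol(record$signals)
  n <- nrow(record$signals)
  adc <- round(record$signals * gain)
  if (any(abs(adc) > 32767, na.rm = TRUE)) {
    stop("signal exceeds int16 range at gain ", gain, call. = FALSE)
  }
  lines <- sprintf("%s %d %g %d", p$name, nsig, record$fs, n)
  for (l in seq_len(nsig)) {
    lines <- c(lines, sprintf("%s.dat 16 %g/mV 16 0 0 0 0 %s",
                              p$name, gain, record$lead_names[l]))
  }
  writeLines(lines, p$hea)
  # format 16: interleaved two's-complement int16, little-endian
  inter <- as.integer(t(adc))
  con <- file(p$dat, "wb")
  on.exit(close(con))
  writeBin(inter, con, size = 2L, endian = "little")
}

.read_record_wfdb <- function(path) {
  p <- .wfdb_paths(path)
  if (!file.exists(p$hea)) {
    stop("WFDB header not found: ", p$hea, call. = FALSE)
  }
  lines <- readLines(p$hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head_tok) < 3L) {
    stop("malformed WFDB header line: ", lines[1], call. = FALSE)
  }
  nsig <- as.integer(head_tok[2])
  fs <- as.numeric(head_tok[3])
  if (is.na(fs) || fs <= 0) {
    stop("missing or invalid sampling rate in WFDB header",
         call. = FALSE)
  }
  nsamp <- if (length(head_tok) >= 4L) as.integer(head_tok[4]) else NA
  gains <- numeric(nsig); zeros <- numeric(nsig)
  leads <- character(nsig)
  for (s in seq_len(nsig)) {
    tok <- strsplit(trimws(lines[1 + s]), "\\s+")[[1]]
    if (length(tok) < 2L || tok[2] != "16") {
      stop("unsupported WFDB signal format (only 16 is handled): ",
           lines[1 + s], call. = FALSE)
    }
    g <- tok[3]
    if (grepl("/", g) && !grepl("/mV$", g)) {
      stop("unknown units in WFDB gain field: ", g,
           " (only mV supported)", call. = FALSE)
    }
    g <- sub("/mV$", "", g)
    zeros[s] <- if (grepl("\\(", g)) {
      as.numeric(sub(".*\\(([-0-9.]+)\\).*", "\\1", g))
    } else 0
    gains[s] <- as.numeric(sub("\\(.*\\)", "", g))
    if (is.na(gains[s]) || gains[s] == 0) gains[s] <- 200
    leads[s] <- if (length(tok) >= 9L) tok[length(tok)] else
      paste0("lead", s)
  }
  raw <- readBin(p$dat, "integer", n = file.size(p$dat) / 2L,
                 size = 2L, signed = TRUE, endian = "little")
  if (!is.na(nsamp) && length(raw) < nsamp * nsig) {
    stop("WFDB .dat shorter than header declares", call. = FALSE)
  }
  mat <- matrix(raw[seq_len((length(raw) %/% nsig) * nsig)],
                ncol = nsig, byrow = TRUE)
  for (s in seq_len(nsig)) {
    mat[, s] <- (mat[, s] - zeros[s]) / gains[s]
  }
  ecg_record(mat, fs = fs, lead_names = leads)
}
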