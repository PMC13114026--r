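#' Read an EEG recording from disk
#'
#' Two dialects are supported:
#' * `"csv"` — a wide UTF-8 table whose first column is `time_s` and whose
#'   remaining columns are channel labels; hand-inspectable and exact to
#'   printed precision.
#' * `"edf"` — European Data Format: 16-bit integer samples with per-signal
#'   physical scaling, the interchange format of most acquisition systems.
#'
#' Channel labels are validated against the montage's signal labels; a
#' label the montage does not know is an error naming that label.
#'
#' @param path File to read.
#' @param dialect `"csv"` or `"edf"` (default guessed from the extension).
#' @param unit Optional override for the physical unit; by default taken
#'   from file metadata (EDF physical-dimension field) or `"mV"` for CSV.
#' @param montage Montage used for label validation.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, dialect = NULL, unit = NULL,
                     montage = mouse_montage()) {
  if (!file.exists(path)) stop("cannot read EEG file: ", path)
  dialect <- dialect %||% guess_dialect(path)
  dialect <- match.arg(dialect, c("csv", "edf"))
  if (dialect == "csv") read_eeg_csv(path, unit, montage)
  else read_eeg_edf(path, unit, montage)
}

#' Write an EEG recording to disk
#'
#' The written file round-trips through [read_eeg()] with identical
#' metadata and sample values equal within the format's precision (exact
#' for CSV at 15 significant digits; 16-bit quantization of the declared
#' physical range for EDF).
#'
#' For EDF, the physical min/max default to a symmetric range covering the
#' signal; if `phys_range` is supplied and the signal exceeds it, writing
#' fails rather than clipping silently. EDF stores whole 1-second data
#' records, so `fs` must be a whole number and the duration a whole number
#' of seconds.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file.
#' @param dialect `"csv"` or `"edf"` (default guessed from the extension).
#' @param phys_range Optional length-2 numeric, EDF physical (min, max).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path, dialect = NULL, phys_range = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  dialect <- dialect %||% guess_dialect(path)
  dialect <- match.arg(dialect, c("csv", "edf"))
  if (dialect == "csv") write_eeg_csv(rec, path) else write_eeg_edf(rec, path, phys_range)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_dialect <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
}

## ---- CSV dialect -----------------------------------------------------------

read_eeg_csv <- function(path, unit, montage) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  if (names(df)[1] != "time_s")
    stop("CSV EEG dialect requires first column 'time_s'")
  labels <- names(df)[-1]
  t <- df$time_s
  if (length(t) < 2) stop("CSV EEG file needs at least two samples")
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("non-uniform sampling interval in CSV EEG file")
  fs <- 1 / dt[1]
  meta <- read_csv_meta(path)
  eeg_recording(t(as.matrix(df[, -1, drop = FALSE])), fs = fs,
                channel_labels = labels,
                unit = unit %||% meta$unit %||% "mV",
                subject_id = meta$subject_id %||% "",
                strain_tag = meta$strain_tag %||% "",
                montage = montage)
}

# metadata rides in leading comment lines: "# key: value"
read_csv_meta <- function(path) {
  out <- list()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0 || !startsWith(ln, "#")) break
    m <- regmatches(ln, regexec("^#\\s*([a-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

write_eeg_csv <- function(rec, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# unit: %s", rec$unit),
               sprintf("# subject_id: %s", rec$subject_id),
               sprintf("# strain_tag: %s", rec$strain_tag)), con)
  n <- n_samples(rec)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$fs)
  for (ch in rec$channel_labels) df[[ch]] <- rec$samples[ch, ]
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
}

## ---- EDF dialect -----------------------------------------------------------

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  charToRaw(sprintf(paste0("%-", width, "s"), x))
}

# render a number into <= 8 ASCII chars (EDF numeric header field)
edf_num <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot render ", x, " in an 8-character EDF field")
}

write_eeg_edf <- function(rec, path, phys_range = NULL) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF dialect requires an integer sampling rate")
  fs <- as.integer(round(fs))
  N <- n_samples(rec)
  if (N %% fs != 0)
    stop("EDF dialect requires a whole number of seconds of data")
  n_rec <- N %/% fs
  ns <- nrow(rec$samples)

  auto_range <- is.null(phys_range)
  if (auto_range) {
    r <- max(abs(rec$samples), 1e-6) * 1.001
    phys_range <- c(-r, r)
  }
  if (min(rec$samples) < phys_range[1] || max(rec$samples) > phys_range[2])
    stop("signal exceeds declared EDF physical range; refusing to clip")
  # quantize against the values as stored in the 8-char header fields, so
  # the reader reconstructs with exactly the scale the writer used; the
  # auto range is widened until its 8-char rendering still covers the data
  for (attempt in 1:6) {
    pmin_str <- edf_num(phys_range[1]); pmax_str <- edf_num(phys_range[2])
    stored <- c(as.numeric(pmin_str), as.numeric(pmax_str))
    covered <- min(rec$samples) >= stored[1] && max(rec$samples) <= stored[2]
    if (covered || !auto_range) break
    phys_range <- phys_range * 1.01
  }
  if (!covered)
    stop("signal exceeds declared EDF physical range; refusing to clip")
  phys_range <- stored
  dig_min <- -32767L; dig_max <- 32767L
  scale <- (dig_max - dig_min) / (phys_range[2] - phys_range[1])

  con <- file(path, "wb"); on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeBin(edf_pad("0", 8), con)
  writeBin(edf_pad(rec$subject_id, 80), con)
  writeBin(edf_pad(rec$strain_tag, 80), con)
  writeBin(edf_pad("01.01.26", 8), con)
  writeBin(edf_pad("00.00.00", 8), con)
  writeBin(edf_pad(hdr_bytes, 8), con)
  writeBin(edf_pad("", 44), con)
  writeBin(edf_pad(n_rec, 8), con)
  writeBin(edf_pad("1", 8), con)
  writeBin(edf_pad(ns, 4), con)
  for (lab in rec$channel_labels) writeBin(edf_pad(lab, 16), con)
  for (i in seq_len(ns)) writeBin(edf_pad("EEG screw", 80), con)
  for (i in seq_len(ns)) writeBin(edf_pad(rec$unit, 8), con)
  for (i in seq_len(ns)) writeBin(edf_pad(pmin_str, 8), con)
  for (i in seq_len(ns)) writeBin(edf_pad(pmax_str, 8), con)
  for (i in seq_len(ns)) writeBin(edf_pad(dig_min, 8), con)
  for (i in seq_len(ns)) writeBin(edf_pad(dig_max, 8), con)
  for (i in seq_len(ns)) writeBin(edf_pad("none", 80), con)
  for (i in seq_len(ns)) writeBin(edf_pad(fs, 8), con)
  for (i in seq_len(ns)) writeBin(edf_pad("", 32), con)

  dig <- round((rec$samples - phys_range[1]) * scale) + dig_min
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
}

edf_field <- function(raw, off, len) trimws(rawToChar(raw[(off + 1):(off + len)]))

read_eeg_edf <- function(path, unit, montage) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 256) stop("truncated EDF header in ", path)
  subject_id <- edf_field(raw, 8, 80)
  strain_tag <- edf_field(raw, 88, 80)
  n_rec <- as.integer(edf_field(raw, 236, 8))
  rec_dur <- as.numeric(edf_field(raw, 244, 8))
  ns <- as.integer(edf_field(raw, 252, 4))
  sh <- function(block, i, len) {
    base <- 256L + block * ns + (i - 1L) * len
    edf_field(raw, base, len)
  }
  # per-signal header blocks in order: label(16) transducer(80) dim(8)
  # phys_min(8) phys_max(8) dig_min(8) dig_max(8) prefilter(80) nsamp(8)
  offs <- cumsum(c(0, 16, 80, 8, 8, 8, 8, 80, 8)) * ns
  fld <- function(k, i, len) edf_field(raw, 256L + offs[k] + (i - 1L) * len, len)
  labels <- vapply(seq_len(ns), function(i) fld(1, i, 16), "")
  dims <- vapply(seq_len(ns), function(i) fld(3, i, 8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) fld(4, i, 8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) fld(5, i, 8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) fld(6, i, 8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) fld(7, i, 8), ""))
  nsamp <- as.integer(vapply(seq_len(ns), function(i) fld(9, i, 8), ""))
  if (length(unique(nsamp)) != 1L)
    stop("non-uniform sampling rate across EDF channels")
  if (length(unique(dims)) != 1L)
    stop("non-uniform physical unit across EDF channels")
  fs <- nsamp[1] / rec_dur
  hdr_bytes <- 256L + 256L * ns
  ints <- readBin(raw[(hdr_bytes + 1):length(raw)], "integer", size = 2L,
                  n = n_rec * sum(nsamp), endian = "little")
  samples <- matrix(0, nrow = ns, ncol = n_rec * nsamp[1])
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- ints[(pos + 1L):(pos + nsamp[i])]
      pos <- pos + nsamp[i]
      col0 <- (r - 1L) * nsamp[i]
      samples[i, (col0 + 1L):(col0 + nsamp[i])] <-
        pmin[i] + (v - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    }
  }
  eeg_recording(samples, fs = fs, channel_labels = labels,
                unit = unit %||% dims[1], subject_id = subject_id,
                strain_tag = strain_tag, montage = montage)
}

## ---- protocol / staircase tables ------------------------------------------

#' Read or write a concentration protocol as CSV
#'
#' Columns: `concentration`, `start_s`, `duration_s`.
#' @param path CSV file.
#' @return [conc_protocol()] for the reader; `path` invisibly for the writer.
#' @export
read_protocol <- function(path) {
  df <- utils::read.csv(path)
  conc_protocol(df$concentration, df$start_s, df$duration_s)
}

#' @rdname read_protocol
#' @param protocol A [conc_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  utils::write.csv(as.data.frame(protocol), path, row.names = FALSE)
  invisible(path)
}

#' Read or write a staircase log as CSV
#'
#' Columns: `concentration`, `response`; direction and step size are
#' inferred from (or stored in) the trial sequence itself.
#' @param path CSV file.
#' @param direction,step_size,dwell_s Passed to [staircase_log()] on read.
#' @return [staircase_log()] for the reader; `path` invisibly for the writer.
#' @export
read_staircase <- function(path, direction = NULL, step_size = 0.1,
                           dwell_s = 600) {
  df <- utils::read.csv(path)
  if (is.null(direction)) {
    direction <- if (nrow(df) > 1 && df$concentration[2] < df$concentration[1])
      "descending" else "ascending"
  }
  staircase_log(df$concentration, as.logical(df$response), direction,
                step_size = step_size, dwell_s = dwell_s)
}

#' @rdname read_staircase
#' @param log A [staircase_log()].
#' @export
write_staircase <- function(log, path) {
  utils::write.csv(log$trials, path, row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth suppression mask sidecar
#'
#' Long CSV with columns `time_s`, `channel`, `suppressed` — the format
#' used to ship ground truth next to an exported synthetic recording.
#' @param gt A `ground_truth` object from [simulate_recording()].
#' @param rec The matching recording (for `fs` and labels).
#' @param path Output CSV.
#' @export
write_mask_csv <- function(gt, rec, path) {
  n <- length(gt$suppression_mask)
  df <- do.call(rbind, lapply(rec$channel_labels, function(ch)
    data.frame(time_s = (seq_len(n) - 1) / rec$fs, channel = ch,
               suppressed = as.integer(gt$suppression_mask))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
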