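#' The standard six-site mouse EEG montage
#'
#' Builds the default screw-electrode montage used throughout the package:
#' a bilateral prefrontal pair (F1, F2; AP +1.8 mm, ML +/-1.0 mm), a
#' bilateral anterior parietal pair (C1, C2; AP -1.4 mm, ML +/-1.0 mm), a
#' bilateral posterior parietal pair (P1, P2; AP -2.8 mm, ML +/-1.0 mm),
#' and cerebellar reference and ground screws. Coordinates are stereotaxic
#' millimetres relative to bregma (AP positive anterior, ML positive right).
#'
#' The F/C/P labels follow the channel vocabulary used for topographic
#' display; the stereotaxic placement follows the surgical coordinates, so
#' F1/F2 sit over prefrontal cortex and C1/C2, P1/P2 over the anterior and
#' posterior parietal sites respectively. The cerebellar reference
#' coordinates are nominal (posterior midline-adjacent) since only the
#' signal-site geometry enters any computation.
#'
#' @return A `montage` object: a data frame with columns `label`, `ap_mm`,
#'   `ml_mm` and `role` (`"signal"`, `"reference"` or `"ground"`).
#' @export
#' @examples
#' m <- mouse_montage()
#' signal_labels(m)
mouse_montage <- function() {
  montage(data.frame(
    label = c("F1", "F2", "C1", "C2", "P1", "P2", "REF", "GND"),
    ap_mm = c(1.8, 1.8, -1.4, -1.4, -2.8, -2.8, -5.8, -5.8),
    ml_mm = c(-1.0, 1.0, -1.0, 1.0, -1.0, 1.0, -1.0, 1.0),
    role  = c(rep("signal", 6), "reference", "ground"),
    stringsAsFactors = FALSE
  ))
}

#' Construct and validate a montage
#'
#' @param sites Data frame with columns `label` (character, unique),
#'   `ap_mm`, `ml_mm` (numeric, signed mm) and `role` (one of `"signal"`,
#'   `"reference"`, `"ground"`).
#' @return A validated `montage` object.
#' @export
montage <- function(sites) {
  stopifnot(is.data.frame(sites))
  need <- c("label", "ap_mm", "ml_mm", "role")
  if (!all(need %in% names(sites)))
    stop("montage sites need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sites$label))
    stop("montage labels must be unique")
  if (!all(sites$role %in% c("signal", "reference", "ground")))
    stop("montage roles must be signal, reference or ground")
  if (sum(sites$role == "signal") < 1L)
    stop("montage needs at least one signal site")
  if (sum(sites$role == "reference") < 1L)
    stop("montage needs at least one reference site")
  structure(sites, class = c("montage", "data.frame"))
}

#' Signal-site labels of a montage
#' @param m A `montage`.
#' @return Character vector of signal-site labels.
#' @export
signal_labels <- function(m) {
  stopifnot(inherits(m, "montage"))
  m$label[m$role == "signal"]
}

#' Construct a multi-channel EEG recording
#'
#' The container used by every analysis function. Samples are stored as a
#' channels x time numeric matrix; the sampling rate and the physical unit
#' travel with the data so that amplitude thresholds can be unit-checked
#' rather than compared blindly.
#'
#' @param samples Numeric matrix, channels x time (rows are channels).
#' @param fs Sampling rate in samples/s (> 0).
#' @param channel_labels Character vector, one label per row of `samples`;
#'   must be a subset of the montage's signal labels.
#' @param unit Physical unit of the samples (default `"mV"`).
#' @param subject_id,strain_tag Free-text identifiers carried through I/O.
#' @param montage Montage the labels are validated against.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(samples, fs, channel_labels, unit = "mV",
                          subject_id = "", strain_tag = "",
                          montage = mouse_montage()) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples))
    stop("one channel label per row of samples required")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  bad <- setdiff(channel_labels, signal_labels(montage))
  if (length(bad) > 0)
    stop("channel label(s) not in montage: ", paste(bad, collapse = ", "))
  rownames(samples) <- channel_labels
  structure(list(
    samples = samples, fs = fs, channel_labels = channel_labels,
    unit = unit, subject_id = subject_id, strain_tag = strain_tag
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s), unit %s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, x$unit))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (nzchar(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$samples)
duration_s <- function(rec) ncol(rec$samples) / rec$fs

get_channel <- function(rec, channel) {
  if (!channel %in% rec$channel_labels)
    stop("channel not present in recording: ", channel)
  rec$samples[channel, ]
}

#' Construct a stepped-concentration protocol
#'
#' Describes the anesthetic concentration ladder during an EEG recording:
#' an ordered set of non-overlapping, strictly increasing concentration
#' steps, each with a start time and duration. The default is the stepped
#' sevoflurane ladder 2.0, 2.2, ..., 2.8 vol% with 5-minute (300 s) epochs
#' laid back to back from time 0.
#'
#' @param concentrations Numeric vector of step concentrations (vol%),
#'   strictly increasing.
#' @param start_s Step start times in seconds; default packs steps
#'   contiguously from 0.
#' @param duration_s Step duration(s) in seconds (recycled), default 300.
#' @return A `conc_protocol` object (data frame with columns
#'   `concentration`, `start_s`, `duration_s`).
#' @export
conc_protocol <- function(concentrations = seq(2.0, 2.8, by = 0.2),
                          start_s = NULL, duration_s = 300) {
  n <- length(concentrations)
  if (n < 1) stop("protocol needs at least one step")
  duration_s <- rep_len(duration_s, n)
  if (any(duration_s <= 0)) stop("step durations must be positive")
  if (is.null(start_s)) start_s <- cumsum(c(0, duration_s[-n]))
  if (length(start_s) != n) stop("start_s must match concentrations")
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly increasing")
  if (is.unsorted(start_s, strictly = TRUE))
    stop("steps must be time-ordered")
  ends <- start_s + duration_s
  if (any(start_s[-1] < ends[-n] - 1e-12))
    stop("protocol steps must not overlap")
  structure(data.frame(concentration = concentrations,
                       start_s = start_s, duration_s = duration_s),
            class = c("conc_protocol", "data.frame"))
}

#' Slice a recording into per-step sub-recordings
#'
#' Windows are half-open `[start, start + duration)` in seconds, converted
#' to sample indices by `floor(t * fs)`, so that back-to-back steps
#' partition the samples with no double counting.
#'
#' @param rec An [eeg_recording()].
#' @param protocol A [conc_protocol()] fully contained in the recording.
#' @return A list, one element per step, each a list with `concentration`
#'   and `recording` (the sliced `eeg_recording`).
#' @export
slice_by_step <- function(rec, protocol) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(protocol, "conc_protocol"))
  N <- n_samples(rec)
  out <- vector("list", nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    i0 <- floor(protocol$start_s[i] * rec$fs)          # 0-based, inclusive
    i1 <- floor((protocol$start_s[i] + protocol$duration_s[i]) * rec$fs)  # exclusive
    if (i1 > N)
      stop(sprintf("protocol step %d (%.2f vol%%) extends past recording end", i,
                   protocol$concentration[i]))
    sub <- rec
    sub$samples <- rec$samples[, (i0 + 1L):i1, drop = FALSE]
    out[[i]] <- list(concentration = protocol$concentration[i], recording = sub)
  }
  out
}

#' Construct a behavioral staircase log
#'
#' @param concentration Numeric vector of trial concentrations (vol%).
#' @param response Logical vector of trial responses (endpoint-specific
#'   meaning: movement for MAC-type, righting for RR-type).
#' @param direction `"ascending"` or `"descending"`.
#' @param step_size Concentration increment between trials (default 0.1).
#' @param dwell_s Dwell at each concentration in seconds (default 600).
#' @param truncated Logical; `TRUE` if the run hit its safety bound before
#'   a terminating response.
#' @return A `staircase_log` object.
#' @export
staircase_log <- function(concentration, response,
                          direction = c("ascending", "descending"),
                          step_size = 0.1, dwell_s = 600, truncated = FALSE) {
  direction <- match.arg(direction)
  stopifnot(length(concentration) == length(response), step_size > 0)
  if (length(concentration) > 1) {
    d <- diff(concentration)
    want <- if (direction == "ascending") step_size else -step_size
    if (any(abs(d - want) > 1e-9))
      stop("trial concentrations inconsistent with direction/step_size")
  }
  structure(list(
    trials = data.frame(concentration = concentration, response = response),
    direction = direction, step_size = step_size, dwell_s = dwell_s,
    truncated = truncated
  ), class = "staircase_log")
}

#' @export
print.staircase_log <- function(x, ...) {
  cat(sprintf("<staircase_log> %s, %d trial(s), step %.2f vol%%%s\n",
              x$direction, nrow(x$trials), x$step_size,
              if (x$truncated) " [TRUNCATED]" else ""))
  print(x$trials)
  invisible(x)
}
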