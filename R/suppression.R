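#' Burst-suppression detection criteria
#'
#' The amplitude/duration rule: a sample is sub-threshold iff its absolute
#' value is below `amplitude_threshold`; maximal sub-threshold runs
#' lasting *strictly longer* than `min_duration_s` are suppression,
#' everything else is burst. Supra-threshold gaps no longer than
#' `merge_gap_s` between sub-threshold runs are bridged before the
#' duration test (default 0: no merging). The criteria carry their unit
#' and every detection is unit-checked against the recording, because an
#' amplitude criterion in mV applied to a uV recording would be silently
#' meaningless.
#'
#' @param amplitude_threshold Positive amplitude threshold, default 5.
#' @param unit Unit of the threshold, default `"mV"`.
#' @param min_duration_s Minimum (strict) suppression duration in s,
#'   default 0.5.
#' @param merge_gap_s Maximum supra-threshold gap to bridge, default 0.
#' @param detrend Subtract the channel mean before thresholding (default
#'   `FALSE`: the rule applies to the raw referenced signal).
#' @return A `suppression_criteria` object.
#' @export
suppression_criteria <- function(amplitude_threshold = 5, unit = "mV",
                                 min_duration_s = 0.5, merge_gap_s = 0,
                                 detrend = FALSE) {
  stopifnot(amplitude_threshold > 0, min_duration_s > 0, merge_gap_s >= 0)
  structure(list(amplitude_threshold = amplitude_threshold, unit = unit,
                 min_duration_s = min_duration_s, merge_gap_s = merge_gap_s,
                 detrend = detrend),
            class = "suppression_criteria")
}

#' Segment one channel into bursts and suppressions
#'
#' Applies the amplitude/duration rule of [suppression_criteria()] and
#' returns the full segmentation: an ordered, alternating partition of
#' `[0, total_s)` into burst and suppression intervals, the suppression
#' time, and the burst-suppression ratio (BSR) — the percentage of time
#' spent in suppression.
#'
#' Note: burst-suppression studies often include a manual visual
#' identification step. This function applies the deterministic
#' threshold rule *only*; any epoch a human rater would have adjudicated
#' is decided here by the amplitude/duration criterion alone.
#'
#' @param rec An [eeg_recording()]; its unit must equal the criteria unit.
#' @param channel Channel label (default `"F1"`, the frontal site used
#'   for burst-suppression quantification).
#' @param criteria A [suppression_criteria()].
#' @return A `suppression_segmentation`: `intervals` (data frame
#'   `start_s`, `end_s`, `label`), `total_s`, `suppression_time_s`,
#'   `bsr_percent`.
#' @export
detect_suppression <- function(rec, channel = "F1",
                               criteria = suppression_criteria()) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(criteria, "suppression_criteria"))
  if (!identical(rec$unit, criteria$unit))
    stop(sprintf(
      "unit mismatch: recording is in '%s' but criteria are in '%s'",
      rec$unit, criteria$unit))
  x <- get_channel(rec, channel)
  if (length(x) == 0) stop("empty recording")
  if (criteria$detrend) x <- x - mean(x)
  fs <- rec$fs

  sub <- abs(x) < criteria$amplitude_threshold

  # bridge short supra-threshold gaps between sub-threshold runs
  if (criteria$merge_gap_s > 0) {
    r <- rle(sub)
    nr <- length(r$lengths)
    interior <- which(!r$values & seq_len(nr) > 1 & seq_len(nr) < nr)
    bridge <- interior[r$lengths[interior] / fs <= criteria$merge_gap_s + 1e-12]
    r$values[bridge] <- TRUE
    sub <- inverse.rle(r)
  }

  # strict duration rule: suppression iff run length / fs > min_duration_s
  r <- rle(sub)
  keep <- r$values & (r$lengths > criteria$min_duration_s * fs + 1e-9)
  r$values <- keep
  supp <- inverse.rle(r)

  r <- rle(supp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  intervals <- data.frame(
    start_s = (starts - 1) / fs,
    end_s = ends / fs,
    label = ifelse(r$values, "suppression", "burst"),
    stringsAsFactors = FALSE
  )
  supp_s <- sum(supp) / fs
  total_s <- length(x) / fs
  structure(list(
    intervals = intervals, total_s = total_s,
    suppression_time_s = supp_s,
    bsr_percent = 100 * supp_s / total_s
  ), class = "suppression_segmentation")
}

#' @export
print.suppression_segmentation <- function(x, ...) {
  n_supp <- sum(x$intervals$label == "suppression")
  cat(sprintf("<suppression_segmentation> %.1f s total, %d suppression interval(s), BSR %.2f%%\n",
              x$total_s, n_supp, x$bsr_percent))
  invisible(x)
}

#' BSR and suppression time per concentration step
#'
#' Slices the recording by the protocol and runs [detect_suppression()]
#' independently on each step.
#'
#' @inheritParams detect_suppression
#' @param protocol A [conc_protocol()] within the recording.
#' @return Data frame with columns `concentration`, `bsr_percent`,
#'   `suppression_time_s`.
#' @export
bsr_by_step <- function(rec, channel = "F1", protocol = conc_protocol(),
                        criteria = suppression_criteria()) {
  slices <- slice_by_step(rec, protocol)
  out <- lapply(slices, function(sl) {
    seg <- detect_suppression(sl$recording, channel, criteria)
    data.frame(concentration = sl$concentration,
               bsr_percent = seg$bsr_percent,
               suppression_time_s = seg$suppression_time_s)
  })
  do.call(rbind, out)
}

#' Lowest concentration at which suppression appears
#'
#' @param per_step Data frame as from [bsr_by_step()] (needs columns
#'   `concentration` and `bsr_percent`), ordered by concentration.
#' @param epsilon BSR (%) that must be strictly exceeded to count as
#'   suppression onset (default 0: any suppression at all).
#' @return The onset concentration (vol%), or `NA_real_` if no step
#'   exceeds `epsilon`.
#' @export
onset_concentration <- function(per_step, epsilon = 0) {
  if (is.null(per_step) || nrow(per_step) == 0)
    stop("per_step table is empty")
  if (is.unsorted(per_step$concentration, strictly = TRUE))
    stop("per_step must be ordered by strictly increasing concentration")
  hit <- which(per_step$bsr_percent > epsilon)
  if (length(hit) == 0) NA_real_ else per_step$concentration[hit[1]]
}
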