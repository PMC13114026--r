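#' Multitaper spectrogram configuration
#'
#' Defaults follow the analysis convention for anesthesia density spectral
#' arrays: consecutive 2-s windows without overlap, time-bandwidth product
#' `nw = 3` and `k = 5` tapers (the Shannon-number maximum `2*nw - 1`),
#' giving a design half-bandwidth of `nw / window_s = 1.5` Hz.
#'
#' @param window_s Window length in seconds (> 0), default 2.
#' @param overlap_s Window overlap in seconds, default 0 (must be
#'   non-negative and smaller than `window_s`).
#' @param nw Time-bandwidth product, default 3.
#' @param k Number of tapers, default 5; must satisfy `k <= 2*nw - 1`
#'   unless `allow_leaky = TRUE` (higher-order tapers are
#'   leakage-dominated and refused by default).
#' @param demean Remove each window's mean before tapering (default
#'   `TRUE`; anesthesia EEG drifts and the DC bin is retained otherwise).
#' @param weighting `"uniform"` (plain mean over eigenspectra, the common
#'   toolbox default) or `"eigen"` (concentration-weighted).
#' @param allow_leaky Permit `k > 2*nw - 1`.
#' @return A `spectral_config` object.
#' @export
spectral_config <- function(window_s = 2, overlap_s = 0, nw = 3, k = 5,
                            demean = TRUE,
                            weighting = c("uniform", "eigen"),
                            allow_leaky = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(window_s > 0, overlap_s >= 0, overlap_s < window_s, nw > 0, k >= 1)
  if (k > 2 * nw - 1 && !allow_leaky)
    stop("k > 2*nw - 1: tapers beyond the Shannon number are leakage-",
         "dominated; set allow_leaky = TRUE to override")
  structure(list(window_s = window_s, overlap_s = overlap_s, nw = nw, k = k,
                 demean = demean, weighting = weighting,
                 allow_leaky = allow_leaky),
            class = "spectral_config")
}

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` at time-bandwidth
#' product `nw`, via the eigendecomposition of the classical symmetric
#' tridiagonal commuting matrix, plus each taper's spectral concentration
#' (the fraction of its energy inside the design band `W = nw/n` cycles
#' per sample), evaluated as the quadratic form of the sinc concentration
#' kernel. Tapers are orthonormal; concentrations are strictly decreasing
#' in (0, 1). Polarity follows the usual convention: symmetric
#' (even-order) tapers have positive mean, odd-order tapers a positive
#' first moment.
#'
#' @param n Taper length in samples (> 2*nw).
#' @param nw Time-bandwidth product.
#' @param k Number of tapers (1 <= k <= 2*nw - 1 unless `allow_leaky`).
#' @param allow_leaky Permit k beyond the Shannon number.
#' @return List with `tapers` (k x n matrix, rows orthonormal) and
#'   `eigenvalues` (length-k concentrations).
#' @export
compute_dpss <- function(n, nw, k, allow_leaky = FALSE) {
  stopifnot(k >= 1, n > 2 * nw)
  if (k > 2 * nw - 1 && !allow_leaky)
    stop("k > 2*nw - 1: tapers beyond the Shannon number are leakage-",
         "dominated; set allow_leaky = TRUE to override")
  key <- paste(n, nw, k, sep = "|")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)

  W <- nw / n
  i <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  Tm <- matrix(0, n, n)
  Tm[cbind(i + 1, i + 1)] <- diag_v
  Tm[cbind(1:(n - 1), 2:n)] <- off_v
  Tm[cbind(2:n, 1:(n - 1))] <- off_v
  eg <- eigen(Tm, symmetric = TRUE)
  tapers <- t(eg$vectors[, seq_len(k), drop = FALSE])

  # polarity convention, then concentrations via the sinc kernel
  for (j in seq_len(k)) {
    v <- tapers[j, ]
    s <- if ((j - 1) %% 2 == 0) sum(v) else sum(i * v)
    if (s < 0) tapers[j, ] <- -v
  }
  d <- outer(i, i, "-")
  S <- sin(2 * pi * W * d) / (pi * d)
  diag(S) <- 2 * W
  lam <- vapply(seq_len(k), function(j)
    drop(tapers[j, ] %*% S %*% tapers[j, ]), 0)

  out <- list(tapers = tapers, eigenvalues = lam)
  .dpss_cache[[key]] <- out
  out
}

#' Multitaper spectrogram of one channel
#'
#' Slides non-(or partially-)overlapping windows across the channel,
#' removes each window's mean (if configured), tapers with the DPSS
#' family, and averages the one-sided eigenspectra. Scaling is power
#' spectral density in recording-units squared per Hz: `|FFT|^2 / fs`,
#' doubled at all bins except DC and (for even window lengths) Nyquist,
#' so the density integrates to the windowed signal's variance. The FFT
#' length equals the window length (no zero padding), giving a frequency
#' resolution of `1/window_s` Hz and a design bandwidth of
#' `nw/window_s` Hz.
#'
#' @param rec An [eeg_recording()].
#' @param channel Channel label (default first channel).
#' @param cfg A [spectral_config()].
#' @return A `spectrogram` object: `power` (windows x frequencies,
#'   unit^2/Hz), `freqs_hz`, `window_times_s` (window centers), `config`,
#'   `channel`, `fs`.
#' @export
multitaper_spectrogram <- function(rec, channel = rec$channel_labels[1],
                                   cfg = spectral_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "spectral_config"))
  x <- get_channel(rec, channel)
  fs <- rec$fs
  nwin <- floor(cfg$window_s * fs)
  if (length(x) < nwin)
    stop("recording shorter than one spectral window")
  step <- nwin - floor(cfg$overlap_s * fs)
  n_windows <- floor((length(x) - nwin) / step) + 1L
  dp <- compute_dpss(nwin, cfg$nw, cfg$k, cfg$allow_leaky)
  w <- if (cfg$weighting == "eigen") dp$eigenvalues / sum(dp$eigenvalues)
       else rep(1 / cfg$k, cfg$k)

  starts <- (seq_len(n_windows) - 1L) * step
  seg <- matrix(x[outer(seq_len(nwin), starts, "+")], nrow = nwin)
  if (cfg$demean) seg <- sweep(seg, 2, colMeans(seg))

  nfreq <- nwin %/% 2 + 1L
  pow <- matrix(0, nrow = n_windows, ncol = nfreq)
  for (j in seq_len(cfg$k)) {
    F <- stats::mvfft(seg * dp$tapers[j, ])
    pow <- pow + w[j] * t(Mod(F[seq_len(nfreq), , drop = FALSE])^2)
  }
  pow <- pow / fs
  one_sided <- rep(2, nfreq); one_sided[1] <- 1
  if (nwin %% 2 == 0) one_sided[nfreq] <- 1
  pow <- sweep(pow, 2, one_sided, "*")

  structure(list(
    power = pow,
    freqs_hz = (seq_len(nfreq) - 1) * fs / nwin,
    window_times_s = starts / fs + nwin / (2 * fs),
    config = cfg, channel = channel, fs = fs
  ), class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %s: %d windows x %d freqs (0-%.1f Hz), nw=%g k=%d\n",
              x$channel, nrow(x$power), ncol(x$power), max(x$freqs_hz),
              x$config$nw, x$config$k))
  invisible(x)
}

#' Element-wise group-median spectrogram
#'
#' Aggregates per-animal spectrograms into a group density spectral array
#' by taking the median of power at every time-frequency cell; with an
#' odd number of animals every cell holds an observed value. All inputs
#' must share the same frequency and window-time grids.
#'
#' @param specs List of `spectrogram` objects on identical grids.
#' @return A `spectrogram` whose `power` is the cellwise median.
#' @export
group_median_spectrogram <- function(specs) {
  stopifnot(length(specs) >= 1, all(vapply(specs, inherits, TRUE, "spectrogram")))
  ref <- specs[[1]]
  for (s in specs[-1]) {
    if (!isTRUE(all.equal(s$freqs_hz, ref$freqs_hz)))
      stop("spectrogram grid mismatch on the frequency axis")
    if (!isTRUE(all.equal(s$window_times_s, ref$window_times_s)))
      stop("spectrogram grid mismatch on the time axis")
  }
  if (length(specs) > 1) {
    arr <- simplify2array(lapply(specs, function(s) s$power))
    ref$power <- apply(arr, c(1, 2), stats::median)
  }
  ref$channel <- paste0("median(", length(specs), " animals)")
  ref
}

#' Band-integrated power per spectrogram window
#'
#' Trapezoidal integral of the spectral density over the frequency bins
#' whose centers lie inside `[low_hz, high_hz]` (bounds inclusive), per
#' window. At the default 0.5 Hz resolution the 4-8 Hz theta band spans
#' the bins 4.0, 4.5, ..., 8.0.
#'
#' @param spec A `spectrogram`.
#' @param band A [band_spec()].
#' @return Numeric vector, one band power (unit^2) per window.
#' @export
band_power <- function(spec, band = band_spec()) {
  stopifnot(inherits(spec, "spectrogram"), inherits(band, "band_spec"))
  if (band$high_hz > max(spec$freqs_hz) + 1e-9)
    stop("band upper edge exceeds the Nyquist frequency")
  sel <- which(spec$freqs_hz >= band$low_hz - 1e-9 &
               spec$freqs_hz <= band$high_hz + 1e-9)
  if (length(sel) < 2)
    stop("band contains fewer than two frequency bins")
  df <- spec$freqs_hz[2] - spec$freqs_hz[1]
  v <- spec$power[, sel, drop = FALSE]
  df * (rowSums(v) - 0.5 * (v[, 1] + v[, ncol(v)]))
}

#' Frequency-band specification
#' @param low_hz,high_hz Band edges in Hz (default 4 and 8, the theta band).
#' @return A `band_spec` object.
#' @export
band_spec <- function(low_hz = 4, high_hz = 8) {
  stopifnot(low_hz >= 0, high_hz > low_hz)
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "band_spec")
}

#' Export a spectrogram as a long CSV table
#' @param spec A `spectrogram`.
#' @param path Output CSV (columns `time_s`, `freq_hz`, `power`).
#' @param max_freq_hz Optional cap on exported frequencies.
#' @export
write_spectrogram_csv <- function(spec, path, max_freq_hz = Inf) {
  keep <- spec$freqs_hz <= max_freq_hz
  df <- expand.grid(time_s = spec$window_times_s,
                    freq_hz = spec$freqs_hz[keep])
  df$power <- as.vector(spec$power[, keep, drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
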