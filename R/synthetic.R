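#' Strain-level generator parameters
#'
#' Collects everything the synthetic cohort generator needs to emulate one
#' mouse strain: the concentration-response of burst suppression (a
#' logistic link with midpoint `bs_ec50` and steepness `bs_slope`, gated
#' to exactly zero below `bs_ec50 - 3/bs_slope` so sub-threshold steps
#' produce no suppression events at all), burst/suppression dwell-time
#' scales, the theta-band amplitude profile over the montage with its
#' concentration-driven anteriorward redistribution, the suppression-floor
#' noise level, and the behavioral thresholds feeding the staircase
#' protocols.
#'
#' @param bs_ec50 Concentration (vol%) of 50% stationary suppression.
#' @param bs_slope Logistic steepness (per vol%).
#' @param mean_suppression_dur_s Mean suppression dwell (s). Kept well
#'   above the 0.5 s detection minimum (default 5 s, ten times the
#'   minimum) so segmentation resolution does not confound recovery.
#' @param mean_burst_dur_s Burst dwell scale (s); the realized burst dwell
#'   at concentration c is `mean_suppression_dur_s * (1-p)/p` so the
#'   stationary suppression fraction equals the logistic link exactly;
#'   `mean_burst_dur_s` itself sets the phase-reset interval on steps
#'   below the suppression floor (pure-burst steps).
#' @param theta_amp_by_site Named amplitudes (recording units) of the
#'   theta carrier per signal site at the lowest step: posterior-dominant
#'   by default, with every site at least 1.6x the 5 mV amplitude
#'   criterion so burst content stays reliably supra-threshold against
#'   background excursions.
#' @param theta_shift_rate Anteriorward redistribution rate (per vol%):
#'   the amplitude profile interpolates from the base (posterior-dominant)
#'   profile to its front/back mirror with weight
#'   `min(1, theta_shift_rate * (c - c_first))`.
#' @param noise_sd SD of the Gaussian floor noise (recording units).
#'   Default `5/3.29`, i.e. a 5 mV amplitude criterion is exceeded by a
#'   single floor sample with probability about 0.001.
#' @param true_mac True immobility threshold (vol%): a deterministic agent
#'   moves on tail clamp iff concentration < `true_mac`.
#' @param true_rr True righting threshold (vol%): a deterministic agent
#'   rights itself iff concentration <= `true_rr`.
#' @param behavioral_sd SD (vol%) of the Gaussian psychometric functions
#'   around the behavioral thresholds; 0 gives deterministic agents.
#' @param strain_tag Free-text tag copied into generated recordings.
#' @return A `strain_params` object.
#' @seealso [b6_params()], [btbr_params()] for the two shipped presets.
#' @export
strain_params <- function(bs_ec50, bs_slope,
                          mean_suppression_dur_s = 5,
                          mean_burst_dur_s = 5,
                          theta_amp_by_site = c(F1 = 8, F2 = 8, C1 = 11,
                                                C2 = 11, P1 = 15, P2 = 15),
                          theta_shift_rate = 1,
                          noise_sd = 5 / 3.29,
                          true_mac = 2.67, true_rr = 1.65,
                          behavioral_sd = 0.1,
                          strain_tag = "synthetic") {
  stopifnot(mean_suppression_dur_s > 0, mean_burst_dur_s > 0,
            all(theta_amp_by_site >= 0), noise_sd > 0, bs_slope > 0,
            behavioral_sd >= 0)
  structure(list(
    bs_ec50 = bs_ec50, bs_slope = bs_slope,
    mean_suppression_dur_s = mean_suppression_dur_s,
    mean_burst_dur_s = mean_burst_dur_s,
    theta_amp_by_site = theta_amp_by_site,
    theta_shift_rate = theta_shift_rate,
    noise_sd = noise_sd, true_mac = true_mac, true_rr = true_rr,
    behavioral_sd = behavioral_sd, strain_tag = strain_tag
  ), class = "strain_params")
}

#' Shipped strain presets
#'
#' `b6_params()` emulates a sevoflurane-resistant control-like strain:
#' suppression midpoint above 2.4 vol% (first suppression events appear at
#' the 2.4% step), slow theta anteriorization, righting threshold 1.65
#' vol%. `btbr_params()` emulates a sensitive autism-model-like strain:
#' suppression midpoint just above 2.0 vol% (events already present at the
#' 2.0% step), fast anteriorization, righting threshold 1.10 vol%. Both
#' share the immobility threshold near 2.7 vol%. The logistic steepness of
#' 15/vol% places the gating floor one 0.2% step below each midpoint, so
#' onset concentrations are separated by two protocol steps as programmed.
#'
#' @return A [strain_params()] object.
#' @export
b6_params <- function() {
  strain_params(bs_ec50 = 2.45, bs_slope = 15, theta_shift_rate = 0.8,
                true_mac = 2.67, true_rr = 1.65, behavioral_sd = 0.08,
                strain_tag = "B6-like")
}

#' @rdname b6_params
#' @export
btbr_params <- function() {
  strain_params(bs_ec50 = 2.05, bs_slope = 15, theta_shift_rate = 2.5,
                true_mac = 2.68, true_rr = 1.10, behavioral_sd = 0.10,
                strain_tag = "BTBR-like")
}

#' Stationary suppression probability at a concentration
#'
#' The logistic link `1/(1 + exp(-bs_slope * (c - bs_ec50)))`, gated to
#' exactly 0 below the floor concentration `bs_ec50 - 3/bs_slope` so that
#' low steps generate no suppression events at all.
#'
#' @param params A [strain_params()].
#' @param concentration Concentration(s), vol%.
#' @return Suppression probability in `[0, 1)`.
#' @export
suppression_probability <- function(params, concentration) {
  floor_c <- params$bs_ec50 - 3 / params$bs_slope
  p <- stats::plogis(params$bs_slope * (concentration - params$bs_ec50))
  p[concentration < floor_c] <- 0
  p
}

#' Expected per-step suppression fraction under a protocol
#' @param params A [strain_params()].
#' @param protocol A [conc_protocol()].
#' @return Named numeric vector, one entry per step.
#' @export
expected_suppression_fraction <- function(params, protocol) {
  p <- suppression_probability(params, protocol$concentration)
  names(p) <- format(protocol$concentration)
  p
}

# theta amplitude per site at concentration c: linear morph from the base
# profile toward its anterior-posterior mirror (F<->P swapped, C fixed)
theta_profile_at <- function(params, concentration, c_first) {
  base <- params$theta_amp_by_site
  mirror <- base
  swap <- function(a, b) { tmp <- mirror[a]; mirror[a] <<- unname(mirror[b]); mirror[b] <<- unname(tmp) }
  if (all(c("F1", "P1") %in% names(base))) swap("F1", "P1")
  if (all(c("F2", "P2") %in% names(base))) swap("F2", "P2")
  w <- min(1, max(0, params$theta_shift_rate * (concentration - c_first)))
  (1 - w) * base + w * mirror
}

# run expr with a private RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# alternating-renewal state sequence for one step: exponential dwells,
# stationary start (memorylessness makes the realized fraction unbiased)
renewal_mask <- function(n, fs, p, mu_s) {
  if (p <= 0) return(rep(FALSE, n))
  if (p >= 1) return(rep(TRUE, n))
  mu_b <- mu_s * (1 - p) / p
  state <- stats::runif(1) < p       # TRUE = suppression
  mask <- logical(n)
  t0 <- 0
  while (t0 < n / fs) {
    dwell <- stats::rexp(1, rate = 1 / (if (state) mu_s else mu_b))
    i0 <- floor(t0 * fs) + 1L
    i1 <- min(n, floor((t0 + dwell) * fs))
    if (i1 >= i0) mask[i0:i1] <- state
    t0 <- t0 + dwell
    state <- !state
  }
  mask
}

# segment boundaries (sample indices) of TRUE runs in a logical vector
run_bounds <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Simulate one stepped-concentration EEG recording with ground truth
#'
#' Per concentration step, brain state follows an alternating renewal
#' (two-state semi-Markov) process with exponential dwell times whose
#' stationary suppression fraction equals
#' [suppression_probability()] at that step's concentration. Burst periods
#' carry a 6 Hz theta oscillation (random phase per burst, shared across
#' channels; per-site amplitude from [strain_params()]'s profile morphed
#' anteriorward with concentration) plus a low-frequency AR(1) background
#' approximating a 1/f spectrum; suppression periods carry only the
#' Gaussian floor noise.
#'
#' @param params A [strain_params()].
#' @param protocol A [conc_protocol()].
#' @param fs Sampling rate, samples/s (>= 32 so the theta band is
#'   representable).
#' @param seed Integer; fixes all randomness (same seed, same bits).
#' @param channels Channels to synthesize (default all six montage signal
#'   sites; restrict for speed when only one channel is analyzed).
#' @param background_ar_sd,background_ar_phi Stationary SD and pole of the
#'   AR(1) burst background.
#' @param subject_id Identifier stamped on the recording.
#' @return A list with elements `recording` (an [eeg_recording()]) and
#'   `ground_truth` (class `ground_truth`: `suppression_mask` — logical
#'   per sample, shared across channels since the simulated state is
#'   global; `per_step_suppression_fraction` — realized mask mean per
#'   step; `theta_site_amplitudes` — the programmed per-site amplitudes
#'   per step).
#' @export
simulate_recording <- function(params, protocol = conc_protocol(), fs = 500,
                               seed = 1,
                               channels = signal_labels(mouse_montage()),
                               background_ar_sd = 1,
                               background_ar_phi = 0.98,
                               subject_id = "sim") {
  stopifnot(inherits(params, "strain_params"), inherits(protocol, "conc_protocol"))
  if (fs < 32) stop("fs too low to represent the 4-8 Hz theta band (need fs >= 32)")
  n_steps <- nrow(protocol)
  c_first <- protocol$concentration[1]
  total_n <- floor((protocol$start_s[n_steps] + protocol$duration_s[n_steps]) * fs)

  with_seed(seed, {
    mask <- logical(total_n)
    samples <- matrix(0, nrow = length(channels), ncol = total_n)
    rownames(samples) <- channels
    frac <- numeric(n_steps)
    amps_by_step <- vector("list", n_steps)

    for (s in seq_len(n_steps)) {
      i0 <- floor(protocol$start_s[s] * fs) + 1L
      i1 <- floor((protocol$start_s[s] + protocol$duration_s[s]) * fs)
      n <- i1 - i0 + 1L
      conc <- protocol$concentration[s]
      p <- suppression_probability(params, conc)
      m <- renewal_mask(n, fs, p, params$mean_suppression_dur_s)
      mask[i0:i1] <- m
      frac[s] <- mean(m)
      amp <- theta_profile_at(params, conc, c_first)
      amps_by_step[[s]] <- amp

      # floor noise everywhere
      for (ch in channels)
        samples[ch, i0:i1] <- stats::rnorm(n, sd = params$noise_sd)

      # burst content: shared-phase theta carrier + per-channel AR(1) background
      burst <- !m
      if (any(burst)) {
        # phase resets at burst onsets; on pure-burst steps additionally
        # every ~mean_burst_dur_s so the carrier is not one endless tone
        b <- run_bounds(burst)
        segs <- list()
        for (k in seq_len(nrow(b))) {
          len_s <- (b[k, 2] - b[k, 1] + 1L) / fs
          n_sub <- max(1L, stats::rpois(1, len_s / params$mean_burst_dur_s))
          cuts <- unique(c(b[k, 1],
                           sort(sample(b[k, 1]:b[k, 2], n_sub - 1L, replace = TRUE)),
                           b[k, 2] + 1L))
          for (j in seq_len(length(cuts) - 1L))
            segs[[length(segs) + 1L]] <- c(cuts[j], cuts[j + 1L] - 1L)
        }
        tt <- (seq_len(n) - 1) / fs
        carrier <- numeric(n)
        for (seg in segs) {
          if (seg[2] < seg[1]) next
          phase <- stats::runif(1, 0, 2 * pi)
          idx <- seg[1]:seg[2]
          carrier[idx] <- sin(2 * pi * 6 * tt[idx] + phase)
        }
        for (ch in channels) {
          ar <- as.numeric(stats::filter(
            stats::rnorm(n, sd = background_ar_sd * sqrt(1 - background_ar_phi^2)),
            background_ar_phi, method = "recursive"))
          add <- amp[[ch]] * carrier + ar
          add[m] <- 0
          samples[ch, i0:i1] <- samples[ch, i0:i1] + add
        }
      }
    }
  })

  names(frac) <- format(protocol$concentration)
  names(amps_by_step) <- format(protocol$concentration)
  rec <- eeg_recording(samples, fs = fs, channel_labels = channels,
                       unit = "mV", subject_id = subject_id,
                       strain_tag = params$strain_tag)
  gt <- structure(list(
    suppression_mask = mask,
    per_step_suppression_fraction = frac,
    theta_site_amplitudes = amps_by_step
  ), class = "ground_truth")
  list(recording = rec, ground_truth = gt)
}

#' Simulate a cohort of recordings
#'
#' Each subject gets an independent seed derived from the master seed (via
#' one `sample.int()` draw under the master seed — reproducible without
#' seed reuse) and an independent multiplicative Gaussian jitter on
#' `bs_ec50` with coefficient of variation `jitter_cv`.
#'
#' @inheritParams simulate_recording
#' @param n_subjects Number of subjects (>= 1).
#' @param jitter_cv Coefficient of variation of the per-subject `bs_ec50`
#'   jitter (0 disables it).
#' @param ... Passed to [simulate_recording()].
#' @return A list of per-subject results, each as returned by
#'   [simulate_recording()], with `params` attached.
#' @export
simulate_cohort <- function(params, n_subjects, protocol = conc_protocol(),
                            fs = 500, seed = 1, jitter_cv = 0.05, ...) {
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n_subjects),
    jitter = stats::rnorm(n_subjects, 1, jitter_cv)
  ))
  lapply(seq_len(n_subjects), function(i) {
    p_i <- params
    p_i$bs_ec50 <- params$bs_ec50 * (if (jitter_cv > 0) draws$jitter[i] else 1)
    out <- simulate_recording(p_i, protocol, fs, seed = draws$seeds[i],
                              subject_id = sprintf("%s-%02d", params$strain_tag, i),
                              ...)
    out$params <- p_i
    out
  })
}

# private uniform stream: draws don't disturb (and aren't disturbed by)
# the caller's RNG
rng_stream <- function(seed) {
  state <- with_seed(seed, get(".Random.seed", envir = globalenv()))
  function(n = 1) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", state, envir = globalenv())
    u <- stats::runif(n)
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    u
  }
}

#' Create a stochastic behavioral responder
#'
#' Returns a function `responder(concentration, endpoint)` emulating one
#' animal's binary responses on the staircase grids. Response probability
#' is a Gaussian-CDF psychometric function of concentration:
#' * `endpoint = "mac"`: probability of movement on tail clamp is
#'   `1 - pnorm(c, true_mac, behavioral_sd)` (decreasing in c);
#' * `endpoint = "rr"`: probability of righting is
#'   `pnorm(true_rr - c, 0, behavioral_sd)` (increasing as c decreases).
#'
#' With `behavioral_sd = 0` the agent is a deterministic threshold
#' crossing: movement iff `c < true_mac`, righting iff `c <= true_rr`.
#' The agent carries a private RNG stream, so the same seed reproduces the
#' same trial sequence regardless of surrounding RNG use.
#'
#' @param params A [strain_params()].
#' @param seed Integer seed for the agent's private stream.
#' @return `function(concentration, endpoint = c("mac", "rr"))` returning
#'   a logical response.
#' @export
behavioral_agent <- function(params, seed = 1) {
  stopifnot(inherits(params, "strain_params"))
  draw <- rng_stream(seed)
  function(concentration, endpoint = c("mac", "rr")) {
    endpoint <- match.arg(endpoint)
    sd <- params$behavioral_sd
    if (endpoint == "mac") {
      pr <- if (sd == 0) as.numeric(concentration < params$true_mac)
            else 1 - stats::pnorm(concentration, params$true_mac, sd)
    } else {
      pr <- if (sd == 0) as.numeric(concentration <= params$true_rr)
            else stats::pnorm(params$true_rr - concentration, 0, sd)
    }
    if (pr >= 1) TRUE else if (pr <= 0) FALSE else draw(1) < pr
  }
}
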