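# Independent oracles and small fixture builders used across the suite.

# Brute-force per-sample suppression scan: an explicit imperative walk,
# deliberately independent of the rle-based implementation.
brute_force_suppression_mask <- function(x, fs, thr, min_dur, merge_gap = 0) {
  sub <- abs(x) < thr
  n <- length(x)
  if (merge_gap > 0) {
    i <- 1L
    while (i <= n) {
      if (!sub[i]) {
        j <- i
        while (j <= n && !sub[j]) j <- j + 1L
        if (i > 1L && j <= n && (j - i) / fs <= merge_gap + 1e-12)
          sub[i:(j - 1L)] <- TRUE
        i <- j
      } else i <- i + 1L
    }
  }
  supp <- logical(n)
  i <- 1L
  while (i <= n) {
    if (sub[i]) {
      j <- i
      while (j <= n && sub[j]) j <- j + 1L
      if ((j - i) / fs > min_dur + 1e-9) supp[i:(j - 1L)] <- TRUE
      i <- j
    } else i <- i + 1L
  }
  supp
}

# per-sample mask from a segmentation's interval table
segmentation_to_mask <- function(seg, fs, n) {
  supp <- logical(n)
  iv <- seg$intervals[seg$intervals$label == "suppression", , drop = FALSE]
  for (k in seq_len(nrow(iv))) {
    i0 <- round(iv$start_s[k] * fs) + 1L
    i1 <- round(iv$end_s[k] * fs)
    supp[i0:i1] <- TRUE
  }
  supp
}

# Exact Mann-Whitney two-sided p by explicit enumeration of group-label
# assignments (combn), independent of the DP implementation.
mw_permutation_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(length(pooled), na)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - na * (na + 1) / 2)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# single-channel recording from a numeric vector
vec_recording <- function(x, fs = 500, channel = "F1", unit = "mV") {
  eeg_recording(matrix(x, nrow = 1), fs, channel, unit = unit)
}

# dense sinc-kernel concentration matrix (DPSS eigen-oracle)
sinc_kernel <- function(n, W) {
  d <- outer(0:(n - 1), 0:(n - 1), "-")
  S <- sin(2 * pi * W * d) / (pi * d)
  diag(S) <- 2 * W
  S
}

# detection criteria used in generator-recovery experiments: bridges
# supra-threshold gaps up to 10 ms so isolated floor-noise spikes do not
# fragment suppression runs (see the methods vignette)
recovery_criteria <- function() suppression_criteria(merge_gap_s = 0.01)
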