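test_that("degenerate signals produce the expected segmentations", {
  fs <- 500
  # all-zero signal: one suppression interval spanning everything
  seg <- detect_suppression(vec_recording(rep(0, 300 * fs), fs = fs))
  expect_equal(nrow(seg$intervals), 1)
  expect_identical(seg$intervals$label, "suppression")
  expect_equal(seg$intervals$start_s, 0)
  expect_equal(seg$intervals$end_s, 300)
  expect_equal(seg$bsr_percent, 100)
  # a 6 Hz sinusoid at twice the threshold never stays sub-threshold long
  # enough (one third of a 1/6 s cycle << 0.5 s)
  tt <- (0:(60 * fs - 1)) / fs
  seg2 <- detect_suppression(vec_recording(10 * sin(2 * pi * 6 * tt), fs = fs))
  expect_equal(seg2$bsr_percent, 0)
  expect_equal(seg2$suppression_time_s, 0)
})

test_that("the duration rule is strict: runs of 0.5 s or less are never suppression", {
  fs <- 500
  mk <- function(low_s) {
    x <- rep(10, 5 * fs)
    x[(2 * fs + 1):(2 * fs + round(low_s * fs))] <- 0
    vec_recording(x, fs = fs)
  }
  expect_equal(detect_suppression(mk(0.4))$suppression_time_s, 0)
  expect_equal(detect_suppression(mk(0.5))$suppression_time_s, 0)
  expect_equal(detect_suppression(mk(0.6))$suppression_time_s, 0.6)
})

test_that("BSR arithmetic follows the mask: 30 s of 300 s is 10%", {
  fs <- 100
  x <- rep(10, 300 * fs)
  x[1001:(1000 + 30 * fs)] <- 0
  seg <- detect_suppression(vec_recording(x, fs = fs))
  expect_equal(seg$suppression_time_s, 30)
  expect_equal(seg$bsr_percent, 10)
})

test_that("per-step BSR localizes suppression to the right step", {
  fs <- 100
  prot <- conc_protocol()
  x <- rep(10, 1500 * fs)
  x[(900 * fs + 1):(1200 * fs)] <- 0      # step 4 fully suppressed
  tab <- bsr_by_step(vec_recording(x, fs = fs), "F1", prot)
  expect_equal(tab$bsr_percent, c(0, 0, 0, 100, 0))
  expect_equal(tab$suppression_time_s, c(0, 0, 0, 300, 0))
})

test_that("intervals partition the recording and labels alternate", {
  set.seed(77)
  fs <- 250
  for (rep in 1:10) {
    x <- rnorm(20 * fs, sd = 4)   # hovers around the threshold
    seg <- detect_suppression(vec_recording(x, fs = fs))
    iv <- seg$intervals
    expect_equal(iv$start_s[1], 0)
    expect_equal(iv$end_s[nrow(iv)], seg$total_s)
    if (nrow(iv) > 1) {
      expect_equal(iv$start_s[-1], iv$end_s[-nrow(iv)])
      expect_true(all(iv$label[-1] != iv$label[-nrow(iv)]))
    }
    expect_equal(sum(iv$end_s - iv$start_s), seg$total_s)
    expect_gte(seg$bsr_percent, 0); expect_lte(seg$bsr_percent, 100)
  }
})

test_that("segmentation equals the brute-force per-sample scan", {
  set.seed(123)
  fs <- 200
  for (rep in 1:20) {
    n <- sample(2000:10000, 1)
    # piecewise quiet/loud signal with noise, exercising both labels
    x <- rnorm(n, sd = sample(c(1, 3, 8), 1))
    quiet <- sort(sample(n, 2))
    x[quiet[1]:quiet[2]] <- rnorm(quiet[2] - quiet[1] + 1, sd = 1)
    gap <- runif(1, 0, 0.05)
    crit <- suppression_criteria(merge_gap_s = gap)
    seg <- detect_suppression(vec_recording(x, fs = fs), criteria = crit)
    oracle <- brute_force_suppression_mask(x, fs, 5, 0.5, gap)
    expect_identical(segmentation_to_mask(seg, fs, n), oracle)
  }
})

test_that("BSR is monotone in the criteria", {
  set.seed(9)
  fs <- 200
  x <- rnorm(30 * fs, sd = 4)
  bsr <- function(thr, dur) detect_suppression(
    vec_recording(x, fs = fs),
    criteria = suppression_criteria(thr, min_duration_s = dur))$bsr_percent
  # raising the amplitude threshold never lowers BSR
  thr_grid <- c(2, 4, 6, 10, 20)
  expect_true(all(diff(vapply(thr_grid, bsr, 0, dur = 0.5)) >= 0))
  # raising the minimum duration never raises BSR
  dur_grid <- c(0.1, 0.3, 0.5, 1, 2)
  expect_true(all(diff(vapply(dur_grid, bsr, 0, thr = 5)) <= 0))
})

test_that("unit mismatches and empty input fail loudly", {
  rec_uv <- vec_recording(rnorm(1000), fs = 100, unit = "uV")
  expect_error(detect_suppression(rec_uv), "unit mismatch")
  expect_error(detect_suppression(rec_uv, criteria = suppression_criteria(unit = "uV")),
               NA)
  expect_error(detect_suppression(vec_recording(rnorm(100), fs = 100), "P1"),
               "not present")
})

test_that("onset concentration picks the lowest step with suppression", {
  tab <- data.frame(concentration = c(2.0, 2.2, 2.4, 2.6),
                    bsr_percent = c(0, 0, 5, 20))
  expect_equal(onset_concentration(tab), 2.4)
  expect_equal(onset_concentration(tab, epsilon = 10), 2.6)
  none <- data.frame(concentration = c(2.0, 2.2), bsr_percent = c(0, 0))
  expect_identical(onset_concentration(none), NA_real_)
  expect_error(onset_concentration(none[0, ]), "empty")
})

test_that("a sensitive strain shows at least the resistant strain's BSR at mid steps", {
  sens <- strain_params(bs_ec50 = 2.1, bs_slope = 10)
  resi <- strain_params(bs_ec50 = 2.5, bs_slope = 10)
  prot <- conc_protocol(c(2.2, 2.4), duration_s = 60)
  wins <- vapply(1:50, function(s) {
    b_s <- bsr_by_step(simulate_recording(sens, prot, 125, seed = s,
                                          channels = "F1")$recording,
                       "F1", prot, recovery_criteria())
    b_r <- bsr_by_step(simulate_recording(resi, prot, 125, seed = s + 1000,
                                          channels = "F1")$recording,
                       "F1", prot, recovery_criteria())
    all(b_s$bsr_percent >= b_r$bsr_percent)
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})
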