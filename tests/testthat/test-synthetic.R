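test_that("the same seed reproduces a recording bit for bit", {
  p <- btbr_params()
  prot <- conc_protocol(c(2.0, 2.4), duration_s = 20)
  a <- simulate_recording(p, prot, fs = 250, seed = 42)
  b <- simulate_recording(p, prot, fs = 250, seed = 42)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_recording(p, prot, fs = 250, seed = 43)
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("ground-truth fractions equal mask means per step by construction", {
  prot <- conc_protocol(duration_s = 30)
  out <- simulate_recording(btbr_params(), prot, fs = 125, seed = 3,
                            channels = "F1")
  m <- out$ground_truth$suppression_mask
  fs <- 125
  for (i in seq_len(nrow(prot))) {
    idx <- (floor(prot$start_s[i] * fs) + 1):floor((prot$start_s[i] + prot$duration_s[i]) * fs)
    expect_identical(mean(m[idx]),
                     unname(out$ground_truth$per_step_suppression_fraction[i]))
  }
})

test_that("a near-step sigmoid gives all-or-nothing suppression around its midpoint", {
  p <- strain_params(bs_ec50 = 2.3, bs_slope = 200)
  prot <- conc_protocol(c(2.2, 2.4), duration_s = 30)
  out <- simulate_recording(p, prot, fs = 125, seed = 9, channels = "F1")
  frac <- out$ground_truth$per_step_suppression_fraction
  expect_identical(unname(frac[1]), 0)       # below the gating floor: no events
  expect_gt(frac[2], 0.95)
})

test_that("suppression probability is gated to exactly zero below the floor", {
  p <- strain_params(bs_ec50 = 2.4, bs_slope = 8)
  expect_identical(suppression_probability(p, 2.0), 0)  # 2.0 < 2.4 - 3/8
  expect_equal(suppression_probability(p, 2.4), 0.5)
  expect_gt(suppression_probability(p, 2.2), 0)
})

test_that("realized per-step suppression fractions are unbiased for the sigmoid", {
  p <- strain_params(bs_ec50 = 2.4, bs_slope = 8)
  prot <- conc_protocol(duration_s = 60)
  expected <- unname(expected_suppression_fraction(p, prot))
  fracs <- vapply(1:200, function(s) {
    out <- simulate_recording(p, prot, fs = 64, seed = s, channels = "F1")
    unname(out$ground_truth$per_step_suppression_fraction)
  }, numeric(5))
  m <- rowMeans(fracs)
  se <- apply(fracs, 1, stats::sd) / sqrt(200)
  expect_identical(m[1], 0)                  # gated step: never any suppression
  for (i in 2:5)
    expect_lt(abs(m[i] - expected[i]), 3 * pmax(se[i], 1e-6))
})

test_that("cohorts are reproducible, distinct across subjects, and share expectations at zero jitter", {
  p <- btbr_params()
  prot <- conc_protocol(c(2.0, 2.4), duration_s = 10)
  co <- simulate_cohort(p, 8, prot, fs = 125, seed = 5, jitter_cv = 0)
  co2 <- simulate_cohort(p, 8, prot, fs = 125, seed = 5, jitter_cv = 0)
  expect_length(co, 8)
  expect_identical(co[[3]]$recording$samples, co2[[3]]$recording$samples)
  expect_false(identical(co[[1]]$recording$samples, co[[2]]$recording$samples))
  exps <- lapply(co, function(s) expected_suppression_fraction(s$params, prot))
  for (i in 2:8) expect_identical(exps[[i]], exps[[1]])
  # with jitter, per-subject midpoints differ
  coj <- simulate_cohort(p, 4, prot, fs = 125, seed = 5, jitter_cv = 0.05)
  expect_gt(stats::sd(vapply(coj, function(s) s$params$bs_ec50, 0)), 0)
  expect_error(simulate_cohort(p, 0, prot), "at least 1")
})

test_that("ec50 jitter propagates into onset-concentration spread", {
  p <- strain_params(bs_ec50 = 2.4, bs_slope = 30)
  prot <- conc_protocol(duration_s = 60)
  co <- simulate_cohort(p, 24, prot, fs = 125, seed = 17, jitter_cv = 0.05,
                        channels = "F1")
  onsets <- vapply(co, function(s) {
    fr <- s$ground_truth$per_step_suppression_fraction
    oc <- which(fr > 0)
    if (length(oc) == 0) NA_real_ else prot$concentration[oc[1]]
  }, 0)
  # jitter sd on the midpoint is 0.12 vol%; the 0.2 grid must show spread
  expect_gt(stats::sd(onsets, na.rm = TRUE), 0)
  expect_gt(length(unique(onsets)), 1)
})

test_that("too low a sampling rate is refused", {
  expect_error(simulate_recording(btbr_params(), conc_protocol(2.0, duration_s = 5),
                                  fs = 20, seed = 1), "fs")
})

test_that("deterministic behavioral agents are exact threshold crossings", {
  p <- strain_params(bs_ec50 = 2.4, bs_slope = 10, true_mac = 2.65,
                     true_rr = 1.12, behavioral_sd = 0)
  ag <- behavioral_agent(p, 1)
  expect_true(ag(2.6, "mac"))    # still moves below threshold
  expect_false(ag(2.7, "mac"))   # immobile above it
  expect_false(ag(1.2, "rr"))
  expect_true(ag(1.1, "rr"))     # first rights at the grid value below 1.12
})

test_that("stochastic agents are seed-reproducible and follow the psychometric curve", {
  p <- strain_params(bs_ec50 = 2.4, bs_slope = 10, true_mac = 2.65,
                     behavioral_sd = 0.1)
  a1 <- behavioral_agent(p, 7); a2 <- behavioral_agent(p, 7)
  seq1 <- vapply(rep(2.65, 20), a1, TRUE, endpoint = "mac")
  seq2 <- vapply(rep(2.65, 20), a2, TRUE, endpoint = "mac")
  expect_identical(seq1, seq2)
  # response rate at the threshold is ~50%
  a3 <- behavioral_agent(p, 99)
  rate <- mean(vapply(rep(2.65, 400), a3, TRUE, endpoint = "mac"))
  expect_lt(abs(rate - 0.5), 0.1)
})

test_that("the programmed theta profile shifts anteriorward with concentration", {
  p <- btbr_params()   # shift rate 2.5 per vol%
  prot <- conc_protocol(c(2.0, 2.2, 2.4), duration_s = 5)
  out <- simulate_recording(p, prot, fs = 125, seed = 1)
  amps <- out$ground_truth$theta_site_amplitudes
  expect_gt(amps[[1]][["P1"]], amps[[1]][["F1"]])   # posterior-dominant at 2.0
  expect_gt(amps[[3]][["F1"]], amps[[3]][["P1"]])   # anterior-dominant at 2.4
  fr <- vapply(amps, function(a) a[["F1"]], 0)
  expect_true(all(diff(fr) > 0))
})
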