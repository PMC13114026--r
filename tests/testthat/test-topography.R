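make_cohort_tables <- function(params, n, prot, fs = 200, seed = 1) {
  co <- simulate_cohort(params, n, prot, fs, seed = seed, jitter_cv = 0)
  lapply(co, function(s) theta_site_power(s$recording, prot))
}

test_that("band power selects the tone channel over matched-variance noise", {
  fs <- 200
  n <- fs * 30
  tt <- (0:(n - 1)) / fs
  set.seed(2)
  tone <- sqrt(2) * sin(2 * pi * 6 * tt)      # variance 1
  noise <- rnorm(n)                            # variance 1
  rec <- eeg_recording(rbind(tone, noise), fs, c("F1", "P1"))
  p_tone <- stats::median(band_power(multitaper_spectrogram(rec, "F1")))
  p_noise <- stats::median(band_power(multitaper_spectrogram(rec, "P1")))
  expect_gt(p_tone, 5 * p_noise)
})

test_that("all-zero channels yield zero site power everywhere", {
  prot <- conc_protocol(c(2.0, 2.2), duration_s = 10)
  rec <- eeg_recording(matrix(0, 6, 20 * 100), 100,
                       c("F1", "F2", "C1", "C2", "P1", "P2"))
  sp <- theta_site_power(rec, prot)
  expect_true(all(sp$power == 0))
})

test_that("theta power scales as amplitude squared across sites", {
  a <- 12
  p <- strain_params(bs_ec50 = 99, bs_slope = 15, theta_shift_rate = 0,
                     theta_amp_by_site = c(F1 = a / sqrt(2), F2 = a / sqrt(2),
                                           C1 = a, C2 = a, P1 = a, P2 = a))
  prot <- conc_protocol(2.0, duration_s = 40)
  ratios <- vapply(1:6, function(s) {
    out <- simulate_recording(p, prot, fs = 200, seed = s)
    sp <- theta_site_power(out$recording, prot)
    sp$power[sp$channel == "P1"] / sp$power[sp$channel == "F1"]
  }, 0)
  expect_lt(abs(mean(ratios) - 2), 0.3)
})

test_that("missing montage channels are reported", {
  prot <- conc_protocol(2.0, duration_s = 5)
  rec <- vec_recording(rnorm(500), fs = 100)
  expect_error(theta_site_power(rec, prot), "missing montage signal")
})

test_that("group maps are linear in site power and honor the sites", {
  prot <- conc_protocol(2.0, duration_s = 5)
  base <- data.frame(concentration = 2.0,
                     channel = c("F1", "F2", "C1", "C2", "P1", "P2"),
                     power = c(1, 2, 3, 4, 5, 6))
  triple <- base; triple$power <- 3 * base$power
  maps <- group_topomap(list(base, triple))
  expect_equal(unname(maps[["2"]]$site_power[base$channel]), 2 * base$power)
  # interpolated field is exact at electrode positions
  m <- mouse_montage()
  sig <- m[m$role == "signal", ]
  at_sites <- idw_interpolate(sig$ap_mm, sig$ml_mm,
                              maps[["2"]]$site_power[sig$label],
                              sig$ap_mm, sig$ml_mm)
  expect_lt(max(abs(at_sites - maps[["2"]]$site_power[sig$label])), 1e-6)
  # single-animal grid peaks at (or interpolates toward) the strongest site
  one <- group_topomap(list(base))
  peak <- which(one[["2"]]$grid$z == max(one[["2"]]$grid$z), arr.ind = TRUE)
  peak_ap <- one[["2"]]$grid$ap_mm[peak[1]]
  expect_lt(abs(peak_ap - sig$ap_mm[sig$label == "P2"]), 0.5)
})

test_that("incomplete animals are excluded under the default policy", {
  full <- data.frame(concentration = 2.0,
                     channel = c("F1", "F2", "C1", "C2", "P1", "P2"),
                     power = rep(2, 6))
  partial <- full[1:4, ]
  expect_message(maps <- group_topomap(list(full, partial)), "excluded")
  expect_equal(maps[["2"]]$n_animals, 1)
  maps2 <- suppressMessages(
    group_topomap(list(full, partial), missing_policy = "exclude_site"))
  expect_setequal(names(maps2[["2"]]$site_power), partial$channel)
})

test_that("the anteriorization index is a scale-invariant frontal/parietal contrast", {
  uni <- c(F1 = 3, F2 = 3, C1 = 3, C2 = 3, P1 = 3, P2 = 3)
  expect_equal(anteriorization_index(uni), 1)
  expect_equal(anteriorization_index(c(F1 = 4, F2 = 4, C1 = 1, C2 = 9,
                                       P1 = 2, P2 = 2)), 2)
  expect_identical(anteriorization_index(uni), anteriorization_index(17 * uni))
  expect_warning(val <- anteriorization_index(c(F1 = 1, F2 = 1, C1 = 1,
                                                C2 = 1, P1 = 0, P2 = 0)),
                 "infinite")
  expect_identical(val, Inf)
  expect_error(anteriorization_index(c(F1 = 1, F2 = 1)), "P1")
})

test_that("posterior-dominant cohorts put P1/P2 on top of the group map at 2.0%", {
  p <- btbr_params(); p$bs_ec50 <- 99   # pre-onset regime
  prot <- conc_protocol(c(2.0, 2.2), duration_s = 20)
  tabs <- make_cohort_tables(p, 3, prot, seed = 21)
  maps <- group_topomap(tabs)
  top2 <- names(sort(maps[["2"]]$site_power, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("P1", "P2"))
})

test_that("permuting animals leaves the group map unchanged", {
  p <- b6_params(); p$bs_ec50 <- 99
  prot <- conc_protocol(2.0, duration_s = 10)
  tabs <- make_cohort_tables(p, 3, prot, seed = 4)
  m1 <- group_topomap(tabs)
  m2 <- group_topomap(tabs[c(3, 1, 2)])
  expect_equal(m1[["2"]]$site_power, m2[["2"]]$site_power)
})

test_that("contaminated steps are flagged against the BSR table", {
  sp <- data.frame(concentration = rep(c(2.0, 2.4), each = 6),
                   channel = rep(c("F1", "F2", "C1", "C2", "P1", "P2"), 2),
                   power = 1)
  bsr <- data.frame(concentration = c(2.0, 2.4), bsr_percent = c(0, 40))
  ant <- anteriorization_by_step(sp, bsr = bsr)
  expect_identical(ant$bsr_flagged, c(FALSE, TRUE))
})
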