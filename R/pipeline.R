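#' Full-pipeline configuration
#'
#' Bundles every sub-configuration of the end-to-end reproduction run.
#' Defaults describe the two-strain study design: behavioral staircase
#' cohorts for both endpoints plus stepped-concentration EEG cohorts
#' analyzed for burst suppression, group-median density spectral arrays,
#' and theta topography.
#'
#' @param strains Named list of [strain_params()] (default the two
#'   shipped presets).
#' @param n_behavioral Subjects per strain per behavioral endpoint.
#' @param n_eeg Subjects per strain in the EEG cohort.
#' @param protocol EEG [conc_protocol()].
#' @param fs Sampling rate for simulated recordings.
#' @param spectral A [spectral_config()].
#' @param criteria A [suppression_criteria()].
#' @param band A [band_spec()].
#' @param bsr_channel Channel used for burst-suppression quantification.
#' @param seed Master seed; every random draw in the run derives from it.
#' @param jitter_cv Per-subject `bs_ec50` jitter CV in the EEG cohorts.
#' @return A `pipeline_config` object (a validated list).
#' @export
pipeline_config <- function(strains = list(B6 = b6_params(), BTBR = btbr_params()),
                            n_behavioral = 8, n_eeg = 5,
                            protocol = conc_protocol(),
                            fs = 500,
                            spectral = spectral_config(),
                            criteria = suppression_criteria(),
                            band = band_spec(),
                            bsr_channel = "F1",
                            seed = 1, jitter_cv = 0.05) {
  stopifnot(length(strains) >= 1, !is.null(names(strains)),
            all(vapply(strains, inherits, TRUE, "strain_params")),
            n_behavioral >= 1, n_eeg >= 1)
  structure(list(strains = strains, n_behavioral = n_behavioral,
                 n_eeg = n_eeg, protocol = protocol, fs = fs,
                 spectral = spectral, criteria = criteria, band = band,
                 bsr_channel = bsr_channel, seed = seed,
                 jitter_cv = jitter_cv),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Executes the two-cohort design end to end and writes every result as a
#' CSV table plus a JSON manifest sufficient to re-run:
#' * behavioral cohorts per strain for both endpoints, with group
#'   summaries and the gated two-sample comparison between strains
#'   (`endpoints.csv`, `endpoint_summary.csv`, `endpoint_tests.csv`);
#' * EEG cohorts per strain: per-subject, per-step BSR and suppression
#'   time (`bsr.csv`), suppression-onset concentrations with group
#'   medians (`onset.csv`), group-median density spectral array of the
#'   BSR channel (`dsa_<strain>.csv`, frequencies up to 30 Hz), per-site
#'   theta power, group topographic site means, and anteriorization
#'   indices with suppression-contamination flags (`theta_sites.csv`,
#'   `anteriorization.csv`).
#'
#' The run is deterministic: the same config and seed produce
#' byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(outdir, name),
                                           row.names = FALSE)
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, 4))

  ## behavioral cohorts -------------------------------------------------------
  endpoints <- list(); summaries <- list(); tests <- list()
  for (ep in c("mac", "rr")) {
    spec <- staircase_spec(ep)
    per_strain <- lapply(seq_along(config$strains), function(i) {
      cohort_endpoints(config$strains[[i]], config$n_behavioral, spec,
                       seed = seeds[1] + i + 31L * match(ep, c("mac", "rr")))
    })
    names(per_strain) <- names(config$strains)
    for (s in names(per_strain)) {
      e <- per_strain[[s]]
      endpoints[[length(endpoints) + 1L]] <-
        cbind(strain = s, endpoint = ep, e$estimates)
      summaries[[length(summaries) + 1L]] <-
        data.frame(strain = s, endpoint = ep, mean = e$mean, sd = e$sd,
                   n = e$n)
    }
    if (length(per_strain) >= 2) {
      gt <- gated_compare(per_strain[[1]]$estimates$value,
                          per_strain[[2]]$estimates$value)
      tests[[length(tests) + 1L]] <- data.frame(
        endpoint = ep,
        group_a = names(per_strain)[1], group_b = names(per_strain)[2],
        test = gt$test_name, statistic = gt$statistic,
        df = if (is.null(gt$df)) NA_real_ else gt$df, p_value = gt$p_value)
    }
  }
  w(do.call(rbind, endpoints), "endpoints.csv")
  w(do.call(rbind, summaries), "endpoint_summary.csv")
  if (length(tests) > 0) w(do.call(rbind, tests), "endpoint_tests.csv")

  ## EEG cohorts --------------------------------------------------------------
  bsr_rows <- list(); onset_rows <- list(); theta_rows <- list()
  ant_rows <- list()
  for (si in seq_along(config$strains)) {
    sname <- names(config$strains)[si]
    cohort <- simulate_cohort(config$strains[[si]], config$n_eeg,
                              config$protocol, config$fs,
                              seed = seeds[2] + si,
                              jitter_cv = config$jitter_cv)
    specs <- list(); site_tabs <- list()
    for (j in seq_along(cohort)) {
      rec <- cohort[[j]]$recording
      tab <- bsr_by_step(rec, config$bsr_channel, config$protocol,
                         config$criteria)
      bsr_rows[[length(bsr_rows) + 1L]] <- cbind(strain = sname,
                                                 subject = j, tab)
      onset_rows[[length(onset_rows) + 1L]] <- data.frame(
        strain = sname, subject = j,
        onset_concentration = onset_concentration(tab))
      specs[[j]] <- multitaper_spectrogram(rec, config$bsr_channel,
                                           config$spectral)
      site_tabs[[j]] <- theta_site_power(rec, config$protocol, config$band,
                                         config$spectral)
      theta_rows[[length(theta_rows) + 1L]] <- cbind(strain = sname,
                                                     subject = j,
                                                     site_tabs[[j]])
      ant <- anteriorization_by_step(site_tabs[[j]], bsr = tab)
      ant_rows[[length(ant_rows) + 1L]] <- cbind(strain = sname,
                                                 subject = j, ant)
    }
    med <- group_median_spectrogram(specs)
    write_spectrogram_csv(med, file.path(outdir, paste0("dsa_", sname, ".csv")),
                          max_freq_hz = 30)
  }
  w(do.call(rbind, bsr_rows), "bsr.csv")
  onset <- do.call(rbind, onset_rows)
  w(onset, "onset.csv")
  onset_med <- stats::aggregate(onset_concentration ~ strain, onset,
                                stats::median, na.action = stats::na.pass)
  names(onset_med)[2] <- "median_onset"
  w(onset_med, "onset_median.csv")
  w(do.call(rbind, theta_rows), "theta_sites.csv")
  w(do.call(rbind, ant_rows), "anteriorization.csv")

  manifest <- list(
    package = "sevoEEG",
    version = as.character(utils::packageVersion("sevoEEG")),
    seed = config$seed,
    n_behavioral = config$n_behavioral, n_eeg = config$n_eeg, fs = config$fs,
    protocol = as.data.frame(config$protocol),
    strains = lapply(config$strains, function(p)
      p[c("bs_ec50", "bs_slope", "mean_suppression_dur_s", "theta_shift_rate",
          "noise_sd", "true_mac", "true_rr", "behavioral_sd")]),
    criteria = unclass(config$criteria),
    spectral = unclass(config$spectral),
    band = unclass(config$band)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(onset = onset, manifest = manifest, outdir = outdir))
}
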