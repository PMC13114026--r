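#' Staircase protocol specification
#'
#' Two bracketing designs are supported:
#' * `"mac"` — ascending immobility staircase: start at 2.5 vol%, tail
#'   clamp at the end of each dwell, increase by one step after every
#'   positive (movement) response, stop at the first negative.
#' * `"rr"` — descending righting staircase: after a pre-exposure,
#'   decrease by one step per dwell until the animal first rights itself.
#'
#' Dwell and pre-exposure times are bookkeeping (no pharmacokinetic
#' equilibration is modeled); they are recorded in the log for realism.
#'
#' @param endpoint `"mac"` or `"rr"`.
#' @param start_conc Starting concentration (vol%); defaults 2.5 (mac)
#'   and 2.0 (rr).
#' @param step Concentration step (vol%), default 0.1.
#' @param dwell_s Dwell per concentration (s), default 600.
#' @param pre_exposure_s Pre-exposure before the first trial (s); default
#'   1200 for rr, 0 for mac.
#' @param max_steps Safety bound on the number of trials, default 50.
#' @return A `staircase_spec` object.
#' @export
staircase_spec <- function(endpoint = c("mac", "rr"), start_conc = NULL,
                           step = 0.1, dwell_s = 600, pre_exposure_s = NULL,
                           max_steps = 50) {
  endpoint <- match.arg(endpoint)
  start_conc <- start_conc %||% if (endpoint == "mac") 2.5 else 2.0
  pre_exposure_s <- pre_exposure_s %||% if (endpoint == "rr") 1200 else 0
  stopifnot(step > 0, start_conc > 0, start_conc <= 8, max_steps >= 1)
  structure(list(endpoint = endpoint, start_conc = start_conc, step = step,
                 dwell_s = dwell_s, pre_exposure_s = pre_exposure_s,
                 max_steps = max_steps),
            class = "staircase_spec")
}

#' Run a staircase protocol against a responder
#'
#' Queries the agent on the concentration grid until the terminating
#' response: for the ascending MAC-type design, the first absent movement
#' response; for the descending RR-type design, the first righting. If
#' `max_steps` trials pass without termination the log is returned with
#' its `truncated` flag set (and [estimate_endpoint()] will refuse it).
#'
#' @param agent A responder `function(concentration, endpoint)` as built
#'   by [behavioral_agent()].
#' @param spec A [staircase_spec()].
#' @return A [staircase_log()].
#' @export
run_staircase <- function(agent, spec = staircase_spec("mac")) {
  stopifnot(is.function(agent), inherits(spec, "staircase_spec"))
  conc <- spec$start_conc
  concs <- numeric(0); resps <- logical(0)
  terminated <- FALSE
  for (i in seq_len(spec$max_steps)) {
    r <- isTRUE(agent(conc, spec$endpoint))
    concs <- c(concs, conc); resps <- c(resps, r)
    if (spec$endpoint == "mac") {
      if (!r) { terminated <- TRUE; break }   # movement gone: stop
      conc <- round(conc + spec$step, 10)
    } else {
      if (r) { terminated <- TRUE; break }    # righting returned: stop
      conc <- round(conc - spec$step, 10)
      if (conc <= 0) break
    }
  }
  staircase_log(concs, resps,
                direction = if (spec$endpoint == "mac") "ascending" else "descending",
                step_size = spec$step, dwell_s = spec$dwell_s,
                truncated = !terminated)
}

#' Estimate the behavioral endpoint from a staircase log
#'
#' MAC-type (ascending): the concentration of the first trial without
#' movement — the lowest tested concentration that prevented the
#' response. RR-type (descending): the concentration of the first trial
#' with righting. For a deterministic agent these are, provably, the grid
#' ceiling of the true immobility threshold and the grid floor of the
#' true righting threshold.
#'
#' @param log A [staircase_log()].
#' @return An `endpoint_estimate`: `value` (vol%), `n_trials`, `log`.
#' @export
estimate_endpoint <- function(log) {
  stopifnot(inherits(log, "staircase_log"))
  if (log$truncated)
    stop("staircase log is truncated: no terminating response to estimate from")
  term <- if (log$direction == "ascending") which(!log$trials$response)
          else which(log$trials$response)
  if (length(term) == 0)
    stop("staircase log has no terminating response")
  structure(list(value = log$trials$concentration[term[1]],
                 n_trials = nrow(log$trials), log = log),
            class = "endpoint_estimate")
}

#' @export
print.endpoint_estimate <- function(x, ...) {
  cat(sprintf("<endpoint_estimate> %.2f vol%% after %d trial(s) (%s)\n",
              x$value, x$n_trials, x$log$direction))
  invisible(x)
}

#' Run a staircase cohort and summarize it
#'
#' Applies [behavioral_agent()] + [run_staircase()] + [estimate_endpoint()]
#' to `n` subjects drawn from one strain's parameters, with per-subject
#' seeds derived from the master seed.
#'
#' @param params A [strain_params()].
#' @param n Number of subjects.
#' @param spec A [staircase_spec()].
#' @param seed Master seed.
#' @return A list: `estimates` (data frame `subject`, `value`), `mean`,
#'   `sd`, `n`, `endpoint`.
#' @export
cohort_endpoints <- function(params, n, spec = staircase_spec("mac"), seed = 1) {
  stopifnot(n >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  vals <- vapply(seq_len(n), function(i) {
    agent <- behavioral_agent(params, seed = seeds[i])
    estimate_endpoint(run_staircase(agent, spec))$value
  }, 0)
  list(estimates = data.frame(subject = seq_len(n), value = vals),
       mean = mean(vals), sd = stats::sd(vals), n = n,
       endpoint = spec$endpoint)
}

#' Exact distribution of an ascending-staircase estimate
#'
#' Enumerates the trial-sequence probabilities of the ascending design on
#' a finite grid under a Gaussian psychometric agent: the estimate lands
#' on grid value `c_k` with probability
#' `prod_{j<k} P(move | c_j) * P(no move | c_k)`. Used as the independent
#' check of staircase estimator bias.
#'
#' @param true_mac,behavioral_sd Psychometric parameters.
#' @param spec A [staircase_spec()] (`endpoint = "mac"`).
#' @param n_grid Number of grid points enumerated.
#' @return Data frame `value`, `prob`, plus attribute `residual` — the
#'   probability mass beyond the enumerated grid.
#' @export
staircase_mac_distribution <- function(true_mac, behavioral_sd,
                                       spec = staircase_spec("mac"),
                                       n_grid = 10) {
  grid <- round(spec$start_conc + (seq_len(n_grid) - 1) * spec$step, 10)
  p_move <- if (behavioral_sd == 0) as.numeric(grid < true_mac)
            else 1 - stats::pnorm(grid, true_mac, behavioral_sd)
  cum <- cumprod(c(1, p_move[-n_grid]))
  prob <- cum * (1 - p_move)
  structure(data.frame(value = grid, prob = prob),
            residual = 1 - sum(prob))
}
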