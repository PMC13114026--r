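new_test_result <- function(test_name, statistic, df, p_value, gate = NULL,
                            note = NULL) {
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, gate = gate, note = note),
            class = "gated_test")
}

#' @export
print.gated_test <- function(x, ...) {
  lab <- c(student_t = "Student's t-test (pooled variance)",
           mann_whitney = "Mann-Whitney test")[x$test_name]
  cat(sprintf("<gated_test> %s\n", lab))
  cat(sprintf("  statistic = %.4f%s, p = %.4g\n", x$statistic,
              if (!is.null(x$df) && !is.na(x$df)) sprintf(", df = %g", x$df) else "",
              x$p_value))
  if (!is.null(x$gate))
    cat(sprintf("  gates: normal_a=%s normal_b=%s equal_var=%s\n",
                x$gate$normal_a, x$gate$normal_b, x$gate$equal_var))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

shapiro_gate <- function(x, alpha) {
  ok <- tryCatch(stats::shapiro.test(x)$p.value > alpha,
                 error = function(e) FALSE)  # constant samples fail the gate
  isTRUE(ok)
}

#' Gated two-sample comparison
#'
#' The decision rule used throughout the package for group comparisons:
#' each sample is tested for normality (Shapiro-Wilk) and the pair for
#' homogeneity of variance (F-ratio test, or Brown-Forsythe/Levene by
#' flag); if all three gates pass at `alpha_gate`, a two-sided
#' pooled-variance Student's t-test is run, otherwise a two-sided
#' Mann-Whitney test (exact enumeration of the rank-sum null when both
#' groups have at most 8 observations and the pooled size is at most 25;
#' tie-corrected normal approximation otherwise). Constant samples fail
#' the normality gate by convention and fall through to Mann-Whitney.
#'
#' @param a,b Numeric samples, each of size >= 3.
#' @param alpha_gate Gate significance level, default 0.05.
#' @param var_gate `"f"` (F-ratio, default) or `"levene"`
#'   (Brown-Forsythe: ANOVA on absolute deviations from medians).
#' @return A `gated_test` with fields `test_name`, `statistic`, `df`
#'   (t only), `p_value`, and `gate` (the three gate outcomes).
#' @export
gated_compare <- function(a, b, alpha_gate = 0.05, var_gate = c("f", "levene")) {
  var_gate <- match.arg(var_gate)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3)
    stop("each sample needs at least 3 observations")
  normal_a <- shapiro_gate(a, alpha_gate)
  normal_b <- shapiro_gate(b, alpha_gate)
  equal_var <- tryCatch({
    p <- if (var_gate == "f") stats::var.test(a, b)$p.value
    else {
      g <- factor(rep(1:2, c(length(a), length(b))))
      z <- c(abs(a - stats::median(a)), abs(b - stats::median(b)))
      stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1]
    }
    p > alpha_gate
  }, error = function(e) FALSE)
  gate <- list(normal_a = normal_a, normal_b = normal_b, equal_var = equal_var)

  if (normal_a && normal_b && equal_var) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    new_test_result("student_t", unname(tt$statistic), unname(tt$parameter),
                    tt$p.value, gate)
  } else if (length(a) <= 8 && length(b) <= 8 && length(a) + length(b) <= 25) {
    res <- mann_whitney_exact(a, b)
    res$gate <- gate
    res
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    new_test_result("mann_whitney", unname(wt$statistic), NA_real_,
                    wt$p.value, gate, note = "normal approximation (tie-corrected)")
  }
}

#' Pooled-variance Student's t-test from printed summaries
#'
#' Reconstructs the classic two-sided pooled-variance t-test from group
#' means, SDs and sizes — the form needed to reproduce a reported p-value
#' when only summary statistics are printed.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries (`sd > 0`,
#'   `n >= 2`).
#' @return A `gated_test` (`test_name = "student_t"`).
#' @export
t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (sd_a <= 0 || sd_b <= 0) stop("standard deviations must be positive")
  if (n_a < 2 || n_b < 2) stop("group sizes must be at least 2")
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  p <- 2 * stats::pt(-abs(t), df)
  new_test_result("student_t", t, df, p)
}

# distribution of the group-a rank sum over all C(n, n_a) label
# assignments, by dynamic programming over doubled mid-ranks (ties exact)
ranksum_null_counts <- function(ranks2, n_a) {
  S <- sum(ranks2)
  # f[j+1, s+1] = number of size-j subsets with doubled rank sum s
  f <- matrix(0, nrow = n_a + 1, ncol = S + 1)
  f[1, 1] <- 1
  for (r in ranks2) {
    jmax <- n_a
    for (j in jmax:1) {
      nz <- which(f[j, ] > 0)
      if (length(nz) > 0)
        f[j + 1, nz + r] <- f[j + 1, nz + r] + f[j, nz]
    }
  }
  f[n_a + 1, ]
}

#' Exact two-sided Mann-Whitney test
#'
#' The U statistic with mid-rank tie handling, and a two-sided p-value
#' from the *exact* null distribution of the rank sum over all
#' `choose(n_a + n_b, n_a)` group-label assignments of the observed
#' pooled values (computed by dynamic programming, so ties are handled
#' exactly). The two-sided p is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#' Pooled sizes above 25 fall back to the tie-corrected normal
#' approximation with a note.
#'
#' @param a,b Numeric samples, each of size >= 3.
#' @return A `gated_test` (`test_name = "mann_whitney"`, `statistic` = U
#'   of the first sample).
#' @export
mann_whitney_exact <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n_a <- length(a); n_b <- length(b)
  if (n_a < 3 || n_b < 3) stop("each sample needs at least 3 observations")
  r <- rank(c(a, b))
  Ra <- sum(r[seq_len(n_a)])
  U <- Ra - n_a * (n_a + 1) / 2

  if (n_a + n_b > 25) {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    return(new_test_result("mann_whitney", U, NA_real_, wt$p.value,
                           note = "pooled n > 25: normal approximation"))
  }
  ranks2 <- as.integer(round(2 * r))
  counts <- ranksum_null_counts(ranks2, n_a)
  total <- choose(n_a + n_b, n_a)
  s_obs <- as.integer(round(2 * Ra))
  p_le <- sum(counts[seq_len(s_obs + 1)]) / total
  p_ge <- sum(counts[(s_obs + 1):length(counts)]) / total
  p <- min(1, 2 * min(p_le, p_ge))
  new_test_result("mann_whitney", U, NA_real_, p)
}
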