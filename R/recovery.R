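#' Headline pattern-frequency summaries of a classified cohort
#'
#' Percentages of evaluable subjects that are regular (R), involve any
#' cervico-thoracic shift (CT, CT_LS, CT_TL, CT_TL_LS), combine
#' cervico-thoracic and thoraco-lumbar shifts (CT_TL, CT_TL_LS), or shift
#' all three boundaries (CT_TL_LS).
#'
#' @param classified classification tibble with a `pattern` column.
#' @return named numeric vector of percentages (`pct_R`,
#'   `pct_CT_involving`, `pct_CT_TL`, `pct_three_boundaries`) with an
#'   `n` attribute.
#' @export
pattern_frequencies <- function(classified) {
  pat <- classified$pattern[!is.na(classified$pattern)]
  n <- length(pat)
  if (n == 0L) stop("no evaluable subjects")
  out <- c(
    pct_R = 100 * mean(pat == "R"),
    pct_CT_involving = 100 * mean(pat %in%
      c("CT", "CT_LS", "CT_TL", "CT_TL_LS")),
    pct_CT_TL = 100 * mean(pat %in% c("CT", "CT_LS", "CT_TL", "CT_TL_LS") &
                             pat %in% c("CT_TL", "CT_TL_LS")),
    pct_three_boundaries = 100 * mean(pat == "CT_TL_LS")
  )
  attr(out, "n") <- n
  out
}

#' Parameter-recovery simulation for a severity slope
#'
#' Simulates `reps` cohorts of size `n`: severities are drawn from the
#' pattern multinomial, a Bernoulli outcome is generated logit-linear in
#' severity with the given generating slope and an intercept calibrated
#' so the expected case count matches `target_n`, and the severity GLM is
#' refitted by IRLS each replicate. The mean recovered slope and its
#' Monte-Carlo standard error quantify estimator bias at study scale.
#'
#' @param slope generating log-odds slope on severity.
#' @param target_n expected affected case count per cohort.
#' @param n cohort size per replicate.
#' @param reps number of replicates.
#' @param pattern_probs pattern-class simplex for the severity
#'   distribution.
#' @param seed integer seed.
#' @return list with `mean_slope`, `mc_se` (standard error of the mean
#'   over replicates), `sd`, `reps`, `n`, `slopes` (per-replicate
#'   estimates), and the generating `slope` and `intercept`.
#' @export
simulate_slope_recovery <- function(slope, target_n, n = 1062L,
                                    reps = 200L,
                                    pattern_probs = default_pattern_probs(),
                                    seed = 1L) {
  a <- calibrate_intercept(slope, target_n, n, pattern_probs)
  sev_values <- severity_scale()[names(pattern_probs)]
  set.seed(seed)
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    sev <- sample(sev_values, n, replace = TRUE, prob = pattern_probs)
    y <- stats::rbinom(n, 1L, stats::plogis(a + slope * sev))
    # rare degenerate replicate (all 0 or all 1): redraw
    while (sum(y) == 0L || sum(y) == n) {
      y <- stats::rbinom(n, 1L, stats::plogis(a + slope * sev))
    }
    X <- cbind(`(Intercept)` = 1, severity = sev)
    fit <- glm_logit_irls(X, y)
    est[r] <- fit$coefficients$estimate[2]
  }
  list(mean_slope = mean(est), mc_se = stats::sd(est) / sqrt(reps),
       sd = stats::sd(est), reps = reps, n = n, slopes = est,
       slope = slope, intercept = a)
}
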