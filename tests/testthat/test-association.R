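sim_logit <- function(n, a, b, sev_values = c(0, 1, 3, 4, 6, 7, 8, 9)) {
  sev <- sample(sev_values, n, replace = TRUE)
  y <- stats::rbinom(n, 1, stats::plogis(a + b * sev))
  data.frame(severity = sev, y = y)
}

test_that("IRLS reproduces the reference ML fit and a Newton oracle", {
  set.seed(31)
  dat <- sim_logit(300, -2, 0.25)
  X <- stats::model.matrix(~ severity, dat)
  fit <- glm_logit_irls(X, dat$y)
  ref <- stats::glm(y ~ severity, binomial(), dat)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  expect_equal(fit$deviance, deviance(ref), tolerance = 1e-8)
  # brute-force likelihood maximization as an independent oracle
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(dat$y * eta - log1p(exp(eta)))
  }
  opt <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(reltol = 1e-14))
  expect_equal(fit$coefficients$estimate, opt$par, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$separation)
})

test_that("two-severity designs recover the closed-form slope", {
  # saturated logistic MLE: slope = [logit(p1) - logit(p0)] / 6
  sev <- rep(c(0, 6), each = 400)
  set.seed(32)
  y <- stats::rbinom(800, 1, ifelse(sev == 0, 0.15, 0.45))
  p0 <- mean(y[sev == 0]); p1 <- mean(y[sev == 6])
  fit <- glm_logit_irls(cbind(1, severity = sev), y)
  expect_equal(fit$coefficients$estimate[2],
               (stats::qlogis(p1) - stats::qlogis(p0)) / 6,
               tolerance = 1e-8)
})

test_that("the null slope is near zero and separation is flagged", {
  set.seed(33)
  dat <- sim_logit(4000, -1, 0)
  fit <- fit_severity_glm(dat, "y", "severity")
  expect_lt(abs(fit$slope$estimate), 4 * fit$slope$se)
  # perfectly separated data diverge and get flagged
  sep <- data.frame(severity = c(0, 0, 9, 9), y = c(0, 0, 1, 1))
  expect_warning(fit_sep <- fit_severity_glm(sep, "y", "severity"),
                 "separation")
  expect_true(fit_sep$separation)
  expect_error(glm_logit_irls(cbind(1, 0:3), rep(0, 4)), "no events")
  expect_error(glm_logit_irls(cbind(1, 0:3), rep(1, 4)), "no non-events")
})

test_that("non-available outcomes are excluded per outcome", {
  set.seed(34)
  dat <- sim_logit(500, -1.5, 0.2)
  dat$y[1:100] <- NA
  fit <- fit_severity_glm(dat, "y", "severity")
  expect_equal(fit$n, 400L)
})

test_that("Wald p values are uniform under the null", {
  set.seed(35)
  reps <- 1200
  pv <- numeric(reps)
  sevs <- c(0, 1, 3, 4, 6, 7, 8, 9)
  for (r in seq_len(reps)) {
    dat <- sim_logit(150, -0.5, 0)
    X <- cbind(1, dat$severity)
    f <- glm_logit_irls(X, dat$y)
    pv[r] <- f$coefficients$p[2]
  }
  ks <- stats::ks.test(pv, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("overdispersion diagnosis separates binomial from contaminated data", {
  set.seed(36)
  dat <- sim_logit(2000, -1, 0.2)
  fit <- fit_severity_glm(dat, "y", "severity")
  chk <- overdispersion_check(fit)
  expect_equal(chk$ratio, 1, tolerance = 0.15)
  expect_equal(chk$verdict, "ok")
  # beta-binomial style contamination: clusters share a random logit
  m <- 250; size <- 20
  sev <- sample(c(0, 1, 3, 4, 6, 7, 8, 9), m, replace = TRUE)
  cluster <- rep(seq_len(m), each = size)
  mk <- function(sd_re) {
    p <- stats::plogis(-1 + 0.2 * sev + stats::rnorm(m, 0, sd_re))
    data.frame(severity = rep(sev, each = size),
               y = stats::rbinom(m * size, 1, rep(p, each = size)))
  }
  dd <- mk(1.5)
  fit2 <- fit_severity_glm(dd, "y", "severity")
  chk2 <- overdispersion_check(fit2, groups = cluster)
  expect_equal(chk2$verdict, "overdispersed")
  expect_gt(chk2$ratio, 1.5)
  # the same grouped check stays near 1 for clean binomial data
  d0 <- mk(0)
  fit0 <- fit_severity_glm(d0, "y", "severity")
  chk0 <- overdispersion_check(fit0, groups = cluster)
  expect_equal(chk0$ratio, 1, tolerance = 0.25)
  # no residual degrees of freedom: undefined
  tiny <- suppressWarnings(
    glm_logit_irls(cbind(1, c(0, 9)), c(0, 1), max_iter = 3))
  expect_error(overdispersion_check(tiny), "degrees of freedom")
})

test_that("slope comparisons are symmetric and null at equality", {
  set.seed(37)
  d1 <- sim_logit(800, -2, 0.3); d1$group <- "a"
  d2 <- d1; d2$group <- "b"  # identical groups: difference exactly 0
  cmp0 <- compare_slopes(rbind(d1, d2), "y", "severity", "group")
  expect_equal(cmp0$diff, 0, tolerance = 1e-8)
  d3 <- sim_logit(800, -2, 0.05); d3$group <- "b"
  cmp <- compare_slopes(rbind(d1, d3), "y", "severity", "group")
  d1s <- d1; d1s$group <- "b"; d3s <- d3; d3s$group <- "a"
  cmp_sw <- compare_slopes(rbind(d1s, d3s), "y", "severity", "group")
  expect_equal(cmp$statistic, -cmp_sw$statistic, tolerance = 1e-6)
  expect_equal(cmp$p, cmp_sw$p, tolerance = 1e-8)
  # non-overlapping severity support warns
  lo <- sim_logit(100, -1, 0, sev_values = c(0, 1))
  hi <- sim_logit(100, -1, 0, sev_values = c(8, 9))
  lo$group <- "a"; hi$group <- "b"
  expect_warning(compare_slopes(rbind(lo, hi), "y", "severity", "group"),
                 "non-overlapping")
})

test_that("slope comparison has power at study-like effect sizes", {
  # generating slopes 0.39 vs 0.16 at study-like case numbers
  set.seed(38)
  probs <- default_pattern_probs()
  sevs <- severity_scale()[names(probs)]
  a1 <- calibrate_intercept(0.39, 65, 1062, probs)
  a2 <- calibrate_intercept(0.16, 92, 1062, probs)
  hits <- 0L
  reps <- 60
  for (r in seq_len(reps)) {
    sev <- sample(sevs, 1062, replace = TRUE, prob = probs)
    d <- rbind(
      data.frame(severity = sev, group = "seg",
                 y = stats::rbinom(1062, 1, stats::plogis(a1 + 0.39 * sev))),
      data.frame(severity = sev, group = "lr",
                 y = stats::rbinom(1062, 1, stats::plogis(a2 + 0.16 * sev))))
    cmp <- compare_slopes(d, "y", "severity", "group")
    hits <- hits + (cmp$p < 0.05)
  }
  expect_gt(hits / reps, 0.5)
})

test_that("interaction LRT has the factor-level degrees of freedom", {
  set.seed(39)
  d <- do.call(rbind, lapply(c("endo", "meso", "ecto"), function(g) {
    dd <- sim_logit(400, -1.5, 0.15); dd$group <- g; dd
  }))
  res <- interaction_lrt(d, "y", "severity", "group")
  expect_equal(res$df, 2L)
  expect_gte(res$chisq, 0)
  expect_true(res$p >= 0 && res$p <= 1)
  # empty level dropped with warning
  d$group <- factor(d$group, levels = c("endo", "meso", "ecto", "ghost"))
  expect_warning(interaction_lrt(d, "y", "severity", "group"), "empty")
})

test_that("interaction LRT keeps its type-I error near nominal", {
  set.seed(40)
  reps <- 120
  rej <- 0L
  for (r in seq_len(reps)) {
    d <- do.call(rbind, lapply(c("a", "b", "c"), function(g) {
      dd <- sim_logit(150, -1, 0.2); dd$group <- g; dd
    }))
    res <- interaction_lrt(d, "y", "severity", "group")
    rej <- rej + (res$p < 0.05)
  }
  # binomial(120, 0.05): 3 SE band around 6
  expect_lt(abs(rej - reps * 0.05), 3 * sqrt(reps * 0.05 * 0.95) + 1e-9)
})

test_that("frequency trends behave like a Pearson correlation should", {
  expect_lt(freq_trend(c(0.5, 0.4, 0.32, 0.2, 0.1))$r, 0)
  lin <- freq_trend(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(abs(lin$r), 1, tolerance = 1e-12)
  expect_error(freq_trend(c(0.2, 0.2, 0.2)), "zero variance")
  expect_error(freq_trend(c(0.1, 0.2)), "at least 3")
})

test_that("pattern-by-covariate chi-square detects only real structure", {
  cls <- tibble::tibble(pattern = rep(pattern_levels(), each = 40))
  determ <- rep(c("x", "y"), each = 160)
  res <- pattern_covariate_chisq(cls, determ)
  expect_lt(res$p, 1e-10)
  set.seed(41)
  indep <- sample(c("x", "y"), 320, replace = TRUE)
  res2 <- pattern_covariate_chisq(cls, indep)
  expect_gt(res2$p, 1e-4)
  # small expected counts trigger the simulated p value
  small <- tibble::tibble(pattern = rep(pattern_levels(), 2))
  expect_warning(res3 <- pattern_covariate_chisq(
    small, rep(c("x", "y"), each = 8)), "simulated")
  expect_true(!is.null(res3$p_simulated))
})
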