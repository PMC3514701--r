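#' Logistic regression by iteratively reweighted least squares
#'
#' Fits a Bernoulli GLM with logit link by IRLS, iterating weighted
#' least-squares solves of the working response until the relative change
#' in deviance falls below `tol` (default 1e-8) or `max_iter` iterations.
#' Reports Wald standard errors from the inverse Fisher information at
#' the final iterate, the residual deviance, the Pearson chi-square and
#' the dispersion ratio (Pearson chi-square over residual degrees of
#' freedom). Fits with diverging coefficients (|beta| above
#' `separation_bound`) or that fail to converge are flagged as separated.
#'
#' @param X model matrix (n x p, including intercept column).
#' @param y 0/1 response vector.
#' @param tol relative deviance convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @param separation_bound coefficient magnitude treated as evidence of
#'   (quasi-)separation.
#' @return object of class `glm_fit`: list with `coefficients` tibble
#'   (`term`, `estimate`, `se`, `z`, `p`), `deviance`, `null_deviance`,
#'   `pearson`, `df_residual`, `dispersion`, `n`, `converged`,
#'   `iterations`, `separation`, `fitted`, `vcov`, `loglik`.
#' @export
glm_logit_irls <- function(X, y, tol = 1e-8, max_iter = 100L,
                           separation_bound = 15) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (sum(y) == 0) stop("no events: cannot fit a logistic model")
  if (sum(y) == length(y)) stop("no non-events: cannot fit a logistic model")
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  beta <- numeric(p)
  dev <- Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      drop(solve(XtW %*% X, XtW %*% z)),
      error = function(e) stop("singular information matrix in IRLS: ",
                               conditionMessage(e))
    )
    mu_new <- stats::plogis(drop(X %*% beta_new))
    mu_new <- pmin(pmax(mu_new, 1e-15), 1 - 1e-15)
    dev_new <- -2 * sum(y * log(mu_new) + (1 - y) * log(1 - mu_new))
    beta <- beta_new
    if (abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
    if (iter >= max_iter) break
  }

  eta <- drop(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-15), 1 - 1e-15)
  w <- mu * (1 - mu)
  info <- t(X * w) %*% X
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(diag(vc))
  zstat <- beta / se
  pval <- 2 * stats::pnorm(-abs(zstat))
  pearson <- sum((y - mu)^2 / w)
  df_res <- n - p
  pbar <- mean(y)
  null_dev <- -2 * sum(y * log(pbar) + (1 - y) * log(1 - pbar))
  separation <- !converged || any(abs(beta) > separation_bound)
  if (separation) {
    warning("possible separation or non-convergence: coefficient ",
            "estimates may diverge; consider a penalized refit")
  }

  structure(list(
    coefficients = tibble::tibble(term = colnames(X),
                                  estimate = unname(beta),
                                  se = unname(se), z = unname(zstat),
                                  p = unname(pval)),
    deviance = dev, null_deviance = null_dev, pearson = pearson,
    df_residual = df_res,
    dispersion = if (df_res > 0) pearson / df_res else NA_real_,
    n = n, converged = converged, iterations = iter,
    separation = separation, fitted = mu, y = y, vcov = vc,
    loglik = -dev / 2
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, digits = 4, ...) {
  cat("Logit-link binomial GLM (IRLS), n =", x$n,
      if (x$converged) sprintf("- converged in %d iterations", x$iterations)
      else "- NOT converged", "\n")
  print(as.data.frame(lapply(x$coefficients, function(col) {
    if (is.numeric(col)) signif(col, digits) else col
  })))
  cat("Deviance:", format(x$deviance, digits = digits),
      " Dispersion (Pearson X2/df):", format(x$dispersion, digits = digits),
      "\n")
  invisible(x)
}

#' Fit the severity-association GLM for one outcome
#'
#' Regresses a per-subject binary outcome on the numeric severity score
#' (values in \{0, 1, 3, 4, 6, 7, 8, 9\}), optionally adjusted for sex
#' and gestational-age band as factors. Subjects with a missing
#' (non-available) outcome are excluded from the fit; the severity slope
#' is the single coefficient of interest.
#'
#' @param data data frame holding the variables.
#' @param outcome name of the 0/1 (or logical) outcome column; `NA`
#'   entries are dropped.
#' @param severity name of the numeric severity column.
#' @param covariates optional character vector of factor covariate names
#'   (e.g. `c("sex", "age_band")`).
#' @param ... passed to [glm_logit_irls()].
#' @return `glm_fit` with a `slope` element (estimate, se, z, p of the
#'   severity term).
#' @export
fit_severity_glm <- function(data, outcome, severity = "severity",
                             covariates = NULL, ...) {
  data <- as.data.frame(data)
  y <- as.numeric(data[[outcome]])
  keep <- !is.na(y) & !is.na(data[[severity]])
  for (v in covariates) keep <- keep & !is.na(data[[v]])
  dat <- data[keep, , drop = FALSE]
  y <- y[keep]
  fml <- stats::as.formula(paste(
    "~", paste(c(severity, covariates), collapse = " + ")))
  X <- stats::model.matrix(fml, data = dat)
  fit <- glm_logit_irls(X, y, ...)
  sl <- fit$coefficients[fit$coefficients$term == severity, ]
  fit$slope <- as.list(sl[, c("estimate", "se", "z", "p")])
  fit$outcome <- outcome
  fit
}

#' Overdispersion check for a fitted binomial GLM
#'
#' Without `groups` this is the Pearson chi-square over the residual
#' degrees of freedom of the Bernoulli fit. Extra-binomial variation in
#' ungrouped 0/1 data is only visible after aggregation, so when `groups`
#' is supplied (e.g. covariate classes or litter/cluster labels) the
#' check pools observed and expected events per group:
#' `sum_g (y_g - mu_g)^2 / v_g` with `y_g` the group event count, `mu_g`
#' the summed fitted probabilities and `v_g` the summed binomial
#' variances, on `#groups - p` degrees of freedom.
#'
#' @param fit a `glm_fit`.
#' @param threshold dispersion ratio above which the data are called
#'   overdispersed relative to the binomial model.
#' @param groups optional grouping vector (length `fit$n`).
#' @return list with `ratio`, `df` and `verdict`
#'   (`"overdispersed"`/`"ok"`).
#' @export
overdispersion_check <- function(fit, threshold = 1.5, groups = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  p <- nrow(fit$coefficients)
  if (is.null(groups)) {
    if (fit$df_residual <= 0) {
      stop("no residual degrees of freedom: overdispersion undefined")
    }
    ratio <- fit$pearson / fit$df_residual
    df <- fit$df_residual
  } else {
    stopifnot(length(groups) == fit$n)
    g <- factor(groups)
    df <- nlevels(g) - p
    if (df <= 0) {
      stop("no residual degrees of freedom: overdispersion undefined")
    }
    yg <- tapply(fit$y, g, sum)
    mug <- tapply(fit$fitted, g, sum)
    vg <- tapply(fit$fitted * (1 - fit$fitted), g, sum)
    ratio <- sum((yg - mug)^2 / vg) / df
  }
  list(ratio = ratio, df = df,
       verdict = if (ratio > threshold) "overdispersed" else "ok")
}

#' Compare severity slopes between two outcome groups
#'
#' Stacks the two groups' observations, fits a joint model
#' `outcome ~ severity * group`, and reads the slope difference off the
#' interaction coefficient with its Wald statistic. Swapping the group
#' labels flips the sign of the statistic but not the p value.
#'
#' @param data stacked data frame.
#' @param outcome name of the 0/1 outcome column.
#' @param severity name of the numeric severity column.
#' @param group name of the two-level group column.
#' @return list of class `slope_comparison`: `groups`, `diff`, `se`,
#'   `statistic`, `p`.
#' @export
compare_slopes <- function(data, outcome, severity = "severity",
                           group = "group") {
  data <- as.data.frame(data)
  g <- factor(data[[group]])
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  s1 <- unique(data[[severity]][g == levels(g)[1]])
  s2 <- unique(data[[severity]][g == levels(g)[2]])
  if (length(intersect(s1, s2)) == 0L) {
    warning("groups have non-overlapping severity support; the slope ",
            "comparison is an extrapolation")
  }
  y <- as.numeric(data[[outcome]])
  keep <- !is.na(y) & !is.na(data[[severity]]) & !is.na(g)
  dat <- data.frame(sev = data[[severity]][keep], grp = g[keep])
  X <- stats::model.matrix(~ sev * grp, data = dat)
  fit <- glm_logit_irls(X, y[keep])
  term <- paste0("sev:grp", levels(g)[2])
  row <- fit$coefficients[fit$coefficients$term == term, ]
  structure(list(groups = levels(g), diff = row$estimate, se = row$se,
                 statistic = row$z, p = row$p, fit = fit),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Slope difference (%s vs %s): %.4g (SE %.4g), z = %.3f, p = %.4g\n",
              x$groups[2], x$groups[1], x$diff, x$se, x$statistic, x$p))
  invisible(x)
}

#' Likelihood-ratio test of a severity-by-factor interaction
#'
#' Tests whether the severity slope differs across the levels of a
#' factor (e.g. germ layer of origin) by comparing the deviances of
#' `outcome ~ severity * factor` and `outcome ~ severity + factor`;
#' the chi-square statistic has `levels - 1` degrees of freedom. Empty
#' factor levels are dropped with a warning.
#'
#' @param data stacked data frame (one row per subject-level
#'   combination).
#' @param outcome name of the 0/1 outcome column.
#' @param severity name of the numeric severity column.
#' @param factor_var name of the factor column (>= 2 levels).
#' @return list with `chisq`, `df`, `p`, and the two fits.
#' @export
interaction_lrt <- function(data, outcome, severity = "severity",
                            factor_var = "group") {
  data <- as.data.frame(data)
  f <- data[[factor_var]]
  if (!is.factor(f)) f <- factor(f)
  if (any(table(f) == 0L)) {
    warning("dropping empty level(s) of ", factor_var)
    f <- droplevels(f)
  }
  if (nlevels(f) < 2L) stop(factor_var, " needs at least two levels")
  y <- as.numeric(data[[outcome]])
  keep <- !is.na(y) & !is.na(data[[severity]]) & !is.na(f)
  dat <- data.frame(sev = data[[severity]][keep], fac = f[keep])
  y <- y[keep]
  X_full <- stats::model.matrix(~ sev * fac, data = dat)
  X_red <- stats::model.matrix(~ sev + fac, data = dat)
  fit_full <- glm_logit_irls(X_full, y)
  fit_red <- glm_logit_irls(X_red, y)
  chisq <- fit_red$deviance - fit_full$deviance
  df <- nlevels(dat$fac) - 1L
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       fit_full = fit_full, fit_reduced = fit_red)
}

#' Pearson correlation of frequencies against an ordered band index
#'
#' Trend test for e.g. the frequency of the regular vertebral pattern
#' across bands of the number of affected organ systems.
#'
#' @param frequencies numeric vector of band frequencies.
#' @param index ordinal band index (defaults to 1..length).
#' @return list of class `trend_result`: `r`, `p`, `n`.
#' @export
freq_trend <- function(frequencies, index = seq_along(frequencies)) {
  stopifnot(length(frequencies) == length(index))
  if (length(frequencies) < 3L) stop("need at least 3 points for a trend")
  if (stats::sd(frequencies) == 0 || stats::sd(index) == 0) {
    stop("zero variance: trend correlation undefined")
  }
  ct <- stats::cor.test(frequencies, index, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n = length(frequencies)),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Pearson trend: R = %.3f, p = %.4g (n = %d points)\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Chi-square test of pattern class against a covariate
#'
#' Tests whether the distribution of vertebral pattern classes varies
#' with a covariate such as sex or gestational-age band. With small
#' expected counts a warning is raised and a simulated p value is
#' reported alongside the asymptotic one.
#'
#' @param classified classification tibble with a `pattern` column.
#' @param covariate vector (same length/order as `classified` rows) of
#'   covariate values, or the name of a column in `classified`.
#' @param simulate_threshold minimum expected cell count below which a
#'   Monte-Carlo p value is added.
#' @return list with `chisq`, `df`, `p`, optionally `p_simulated`.
#' @export
pattern_covariate_chisq <- function(classified, covariate,
                                    simulate_threshold = 5) {
  if (is.character(covariate) && length(covariate) == 1L &&
      covariate %in% names(classified)) {
    covariate <- classified[[covariate]]
  }
  keep <- !is.na(classified$pattern) & !is.na(covariate)
  tab <- table(classified$pattern[keep], covariate[keep])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- list(chisq = unname(ct$statistic), df = unname(ct$parameter),
              p = ct$p.value)
  if (any(ct$expected < simulate_threshold)) {
    warning("expected counts below ", simulate_threshold,
            "; simulated p value added")
    sim <- stats::chisq.test(tab, simulate.p.value = TRUE, B = 2000)
    out$p_simulated <- sim$p.value
  }
  out
}
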