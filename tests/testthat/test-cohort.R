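test_that("pattern sampling is a faithful seeded multinomial", {
  probs <- default_pattern_probs()
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  # degenerate simplex
  p1 <- stats::setNames(c(1, rep(0, 7)), pattern_levels())
  set.seed(1)
  expect_true(all(sample_patterns(500, p1) == "R"))
  # determinism
  set.seed(99); a <- sample_patterns(1000, probs)
  set.seed(99); b <- sample_patterns(1000, probs)
  expect_identical(a, b)
  # convergence to the simplex (3 binomial SEs at n = 4000)
  set.seed(5)
  draws <- sample_patterns(4000, probs)
  for (k in pattern_levels()) {
    se <- sqrt(probs[k] * (1 - probs[k]) / 4000)
    expect_lt(abs(mean(draws == k) - probs[k]), 3 * se + 1e-12)
  }
})

test_that("morphology synthesis is class-exact for all eight patterns", {
  cfg <- cohort_config()
  set.seed(42)
  for (pat in pattern_levels()) {
    for (r in 1:50) {
      rows <- synthesize_morphology(pat, "s", cfg)
      col <- as_vertebral_column(rows)
      got <- suppressWarnings(pattern_class(detect_shifts(col)))
      expect_equal(got, pat, info = sprintf("pattern %s rep %d", pat, r))
    }
  }
})

test_that("synthesized columns conserve regional counts exactly", {
  cfg <- cohort_config()
  set.seed(7)
  for (r in 1:100) {
    pat <- sample(pattern_levels(), 1)
    col <- as_vertebral_column(synthesize_morphology(pat, "s", cfg))
    rc <- suppressWarnings(regional_counts(col))
    expect_identical(rc$cervical + rc$thoracic + rc$lumbar,
                     as.numeric(rc$presacral))
    expect_true(all(c(rc$cervical, rc$thoracic, rc$lumbar) >= 0))
  }
})

test_that("intercept calibration hits the target expected count", {
  probs <- default_pattern_probs()
  sev <- severity_scale()[names(probs)]
  for (par in list(c(0.36, 64), c(-0.11, 357), c(0.07, 121))) {
    a <- calibrate_intercept(par[1], par[2], 1062, probs)
    expect_equal(1062 * sum(probs * stats::plogis(a + par[1] * sev)),
                 par[2], tolerance = 1e-6)
  }
  # with missingness the available-case count is matched
  a <- calibrate_intercept(0.2, 100, 1062, probs, missingness = 0.2)
  expect_equal(0.8 * 1062 * sum(probs * stats::plogis(a + 0.2 * sev)),
               100, tolerance = 1e-6)
  expect_error(calibrate_intercept(0.1, 2000, 1062, probs), "target_n")
})

test_that("malformation events follow the generating logistic curve", {
  cfg <- cohort_config(n_subjects = 6000, seed = 3)
  # flat system: prevalence independent of severity
  cfg$system_params <- tibble::tibble(system = "CV", slope = 0,
                                      target_n = 200L)
  sev <- rep(c(0L, 9L), each = 3000)
  set.seed(11)
  ev <- sample_malformations(sev, cfg)
  p_lo <- mean(ev[sev == 0, "CV"]); p_hi <- mean(ev[sev == 9, "CV"])
  expect_lt(abs(p_lo - p_hi), 4 * sqrt(0.04 / 3000))

  # positive slope: empirical prevalence tracks the closed-form curve
  cfg$system_params <- tibble::tibble(system = "CF", slope = 0.36,
                                      target_n = 64L)
  a <- calibrate_intercept(0.36, 64, cfg$reference_n,
                           cfg$pattern_probs, cfg$missingness[["CF"]])
  sev2 <- rep(c(0L, 4L, 9L), each = 2000)
  set.seed(12)
  ev2 <- sample_malformations(sev2, cfg)
  for (s in c(0, 4, 9)) {
    p_hat <- mean(ev2[sev2 == s, "CF"])
    p_true <- stats::plogis(a + 0.36 * s)
    expect_lt(abs(p_hat - p_true),
              4 * sqrt(p_true * (1 - p_true) / 2000))
  }
  expect_true(mean(ev2[sev2 == 9, "CF"]) > mean(ev2[sev2 == 0, "CF"]))
})

test_that("cohort generation is reproducible and schema-complete", {
  cfg <- cohort_config(n_subjects = 60, seed = 123)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$morphology, c2$morphology)
  expect_identical(c1$findings, c2$findings)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$truth, c2$truth)
  # a different seed changes the draw
  c3 <- generate_cohort(cohort_config(n_subjects = 60, seed = 124))
  expect_false(identical(c1$truth$pattern, c3$truth$pattern))
  # truth rows 1:1 with subjects; findings only for available systems
  expect_equal(nrow(c1$truth), 60L)
  expect_equal(nrow(c1$subjects), 60L)
  avail <- c1$subjects[, paste0("avail_", organ_systems())]
  for (i in seq_len(nrow(c1$findings))) {
    s <- c1$findings$raw_system[i]
    j <- match(c1$findings$subject_id[i], c1$subjects$subject_id)
    expect_equal(avail[[paste0("avail_", s)]][j], 1L)
  }
})

test_that("written cohorts are byte-identical under one seed", {
  cfg <- cohort_config(n_subjects = 25, seed = 9)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in c("morphology.csv", "findings.csv", "subjects.csv",
              "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("an empty cohort yields empty tables with headers", {
  coh <- generate_cohort(cohort_config(n_subjects = 0, seed = 1))
  expect_equal(nrow(coh$morphology), 0L)
  expect_equal(nrow(coh$truth), 0L)
  expect_true(all(c("subject_id", "rib_state") %in%
                    names(coh$morphology)))
  d <- file.path(tempdir(), "coh0")
  write_cohort(coh, d)
  expect_equal(length(readLines(file.path(d, "morphology.csv"))), 1L)
})

test_that("invalid generator configs are rejected", {
  expect_error(cohort_config(pattern_probs = c(R = 0.5, LS = 0.6)),
               "named by the eight")
  bad <- default_pattern_probs(); bad["R"] <- bad["R"] + 0.01
  expect_error(cohort_config(pattern_probs = bad), "sum to 1")
  expect_error(cohort_config(bilateral_prob = 1.4), "0, 1")
})

test_that("sex and gestational age are independent of pattern class", {
  cc <- cached_cohort(2000, 77)
  dat <- dplyr::inner_join(cc$classified, cc$cohort$subjects,
                           by = "subject_id")
  res <- suppressWarnings(pattern_covariate_chisq(dat, dat$sex))
  expect_gt(res$p, 0.001)
  band <- cut(dat$ga_weeks, c(0, 28, Inf))
  res2 <- suppressWarnings(pattern_covariate_chisq(dat, as.character(band)))
  expect_gt(res2$p, 0.001)
})

test_that("config YAML loads back to the default generator settings", {
  path <- system.file("extdata", "default_config.yaml",
                      package = "homeovert")
  cfg <- read_cohort_config(path)
  def <- cohort_config()
  expect_equal(cfg$pattern_probs, def$pattern_probs, tolerance = 1e-12)
  expect_equal(as.data.frame(cfg$system_params),
               as.data.frame(def$system_params))
  expect_equal(cfg$missingness, def$missingness)
  # unknown keys are named in the error
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_subjects = 5, not_a_key = 1), tmp)
  expect_error(read_cohort_config(tmp), "not_a_key")
})
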