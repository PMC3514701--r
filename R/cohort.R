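#' Draw pattern classes from the generator multinomial
#'
#' @param n number of subjects.
#' @param probs named simplex over [pattern_levels()].
#' @return character vector of pattern classes.
#' @export
sample_patterns <- function(n, probs = default_pattern_probs()) {
  stopifnot(abs(sum(probs) - 1) < 1e-9)
  if (n == 0L) return(character())
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# substream seeds: deterministic function of the root seed and a stage
# index, kept inside 32-bit integer range
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 1000003) %%
               (.Machine$integer.max - 1L)) + 1L
}

runif1 <- function(lo, hi) stats::runif(1L, lo, hi)

#' Synthesize a concrete vertebral column realizing a pattern class
#'
#' Emits long-format morphology rows whose classification by
#' [detect_shifts()] and [pattern_class()] returns exactly the requested
#' class. Within a class the generator randomizes the anterior/posterior
#' realisation of each shifted boundary, laterality, rudimentary versus
#' absent boundary ribs, the cervical-rib presentation (free rib,
#' qualifying enlarged transverse process, or the rare full thoracic
#' identity), and the lumbo-sacral realisation (23 or 25 presacral
#' vertebrae, or an observer-flagged transitional vertebra at 24).
#'
#' @param pattern one of [pattern_levels()].
#' @param subject_id subject identifier for the emitted rows.
#' @param config a [cohort_config()].
#' @return data frame of long-format morphology rows (two per vertebra).
#' @export
synthesize_morphology <- function(pattern, subject_id,
                                  config = cohort_config()) {
  parts <- strsplit(pattern, "_")[[1]]
  stopifnot(pattern %in% pattern_levels())
  ct <- "CT" %in% parts
  tl <- "TL" %in% parts
  ls <- "LS" %in% parts

  tl_dir <- if (tl) {
    if (stats::runif(1) < config$tl_anterior_prob) "anterior" else "posterior"
  } else "none"

  ls_mode <- "none"
  if (ls) {
    modes <- config$ls_mode_probs
    if (tl_dir == "posterior") {
      # a full lumbar rib already consumes one lumbar position; keep at
      # least four lumbar vertebrae by not also dropping one
      modes <- modes[c("plus", "flag")] / sum(modes[c("plus", "flag")])
    }
    ls_mode <- sample(names(modes), 1L, prob = modes)
  }
  n <- switch(ls_mode, minus = 23L, plus = 25L, 24L)

  side_pick <- function() {
    if (stats::runif(1) < config$bilateral_prob) c("left", "right")
    else sample(c("left", "right"), 1L)
  }

  # baseline: ribs on vertebrae 8..19, nothing elsewhere
  state <- matrix("absent", nrow = n, ncol = 2,
                  dimnames = list(NULL, c("left", "right")))
  ratio <- matrix(NA_real_, nrow = n, ncol = 2,
                  dimnames = list(NULL, c("left", "right")))
  tp_x <- matrix(FALSE, nrow = n, ncol = 2,
                 dimnames = list(NULL, c("left", "right")))
  for (i in 8:19) {
    state[i, ] <- "present"
    ratio[i, ] <- stats::runif(2, 0.8, 1.2)
  }

  if (ct) {
    if (stats::runif(1) < config$ct_anterior_prob) {
      sides <- side_pick()
      if (stats::runif(1) < config$tp_enlarged_prob) {
        state[7L, sides] <- "tp_enlarged"
        tp_x[7L, sides] <- TRUE
      } else {
        state[7L, sides] <- "present"
        if (stats::runif(1) < config$thoracic_identity_prob) {
          ratio[7L, sides] <- stats::runif(length(sides), 0.55, 0.9)
        } else {
          ratio[7L, sides] <- stats::runif(length(sides), 0.1, 0.5)
        }
      }
    } else {
      sides <- side_pick()
      if (stats::runif(1) < config$rudimentary_vs_absent_prob) {
        ratio[8L, sides] <- stats::runif(length(sides), 0.05, 0.45)
      } else {
        state[8L, sides] <- "absent"
        ratio[8L, sides] <- NA_real_
      }
    }
  }

  if (tl_dir == "anterior") {
    sides <- side_pick()
    if (stats::runif(1) < config$rudimentary_vs_absent_prob) {
      ratio[19L, sides] <- stats::runif(length(sides), 0.05, 0.45)
    } else {
      state[19L, sides] <- "absent"
      ratio[19L, sides] <- NA_real_
    }
  } else if (tl_dir == "posterior") {
    sides <- side_pick()
    state[20L, sides] <- "present"
    if (stats::runif(1) < config$rudimentary_vs_absent_prob) {
      ratio[20L, sides] <- stats::runif(length(sides), 0.05, 0.45)
    } else {
      ratio[20L, sides] <- stats::runif(length(sides), 0.8, 1.1)
    }
  }

  ls_flag <- integer(n)
  if (ls_mode == "flag") ls_flag[n] <- 1L

  data.frame(
    subject_id = subject_id,
    vertebra_ordinal = rep(seq_len(n), each = 2L),
    side = rep(c("left", "right"), n),
    rib_state = as.vector(t(state)),
    length_ratio = as.vector(t(ratio)),
    tp_exceeds_t1 = as.integer(as.vector(t(tp_x))),
    sacral_attached = 0L,
    ls_transitional_flag = rep(ls_flag, each = 2L),
    quality = "evaluable",
    stringsAsFactors = FALSE
  )
}

#' Draw per-system malformation events for given severities
#'
#' For each organ system `s` the event indicator is Bernoulli with
#' probability `plogis(a_s + b_s * severity)`, the generating slope `b_s`
#' taken from the config and the intercept `a_s` calibrated so the
#' expected affected count among available subjects matches the config's
#' target count at the reference cohort size.
#'
#' @param severity integer vector of severity scores.
#' @param config a [cohort_config()].
#' @return 0/1 matrix, one row per subject, one column per organ system.
#' @export
sample_malformations <- function(severity, config = cohort_config()) {
  sp <- config$system_params
  n <- length(severity)
  events <- matrix(0L, nrow = n, ncol = nrow(sp),
                   dimnames = list(NULL, sp$system))
  for (k in seq_len(nrow(sp))) {
    a <- calibrate_intercept(sp$slope[k], sp$target_n[k],
                             config$reference_n, config$pattern_probs,
                             config$missingness[[sp$system[k]]])
    p <- stats::plogis(a + sp$slope[k] * severity)
    events[, k] <- stats::rbinom(n, 1L, p)
  }
  events
}

#' Generate a full synthetic cohort
#'
#' Draws latent pattern classes, synthesizes class-exact morphology,
#' draws per-system malformation events logit-linear in severity,
#' materialises events as findings with terms sampled from the coding
#' map, and applies independent per-system missingness. Sex and
#' gestational age are drawn independently of pattern class. One root
#' seed drives per-stage substreams, so each stage is reproducible in
#' isolation.
#'
#' @param config a [cohort_config()].
#' @param map coding map used to sample finding terms.
#' @return list of class `cohort_tables` with tibbles `morphology`,
#'   `findings`, `subjects` (sex, gestational age, per-system
#'   availability), and `truth` (latent pattern, severity, pre-missingness
#'   event indicators).
#' @export
generate_cohort <- function(config = cohort_config(),
                            map = default_coding_map()) {
  validate_cohort_config(config)
  n <- config$n_subjects
  ids <- sprintf("S%05d", seq_len(n))

  set.seed(stage_seed(config$seed, 1L))
  patterns <- sample_patterns(n, config$pattern_probs)
  sev <- severity_score(patterns)
  sex <- if (n > 0L) {
    sample(names(config$sex_probs), n, replace = TRUE,
           prob = config$sex_probs)
  } else character()
  ga <- numeric(n)
  if (n > 0L) {
    lo <- config$ga_range[1]; hi <- config$ga_range[2]
    ga <- stats::rnorm(n, config$ga_mean, config$ga_sd)
    while (any(bad <- ga < lo | ga > hi)) {
      ga[bad] <- stats::rnorm(sum(bad), config$ga_mean, config$ga_sd)
    }
    ga <- round(ga, 1)
  }

  set.seed(stage_seed(config$seed, 2L))
  morph <- if (n > 0L) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      synthesize_morphology(patterns[i], ids[i], config)
    }))
  } else synthesize_morphology("R", "S00001", config)[0, ]

  set.seed(stage_seed(config$seed, 3L))
  events <- sample_malformations(sev, config)
  systems <- organ_systems()
  frows <- list()
  if (n > 0L) {
    for (s in systems) {
      terms <- map$term[map$primary == s]
      hit <- which(events[, s] == 1L)
      if (length(hit) > 0L) {
        frows[[s]] <- data.frame(
          subject_id = ids[hit],
          term = sample(terms, length(hit), replace = TRUE),
          raw_system = s,
          cause_context = "",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  findings <- dplyr::bind_rows(frows)
  if (nrow(findings) == 0L) {
    findings <- data.frame(subject_id = character(), term = character(),
                           raw_system = character(),
                           cause_context = character(),
                           stringsAsFactors = FALSE)
  }

  set.seed(stage_seed(config$seed, 4L))
  avail <- matrix(1L, nrow = n, ncol = length(systems),
                  dimnames = list(NULL, systems))
  for (s in systems) {
    avail[, s] <- stats::rbinom(n, 1L, 1 - config$missingness[[s]])
  }
  if (nrow(findings) > 0L) {
    keep <- avail[cbind(match(findings$subject_id, ids),
                        match(findings$raw_system, systems))] == 1L
    findings <- findings[keep, , drop = FALSE]
  }
  findings <- findings[order(match(findings$subject_id, ids)), ,
                       drop = FALSE]

  subjects <- tibble::tibble(subject_id = ids, sex = sex,
                             ga_weeks = ga)
  for (s in systems) subjects[[paste0("avail_", s)]] <- avail[, s]

  truth <- tibble::tibble(subject_id = ids, pattern = patterns,
                          severity = sev)
  for (s in systems) truth[[paste0("event_", s)]] <- events[, s]
  truth$n_affected <- as.integer(rowSums(events))

  structure(list(morphology = tibble::as_tibble(morph),
                 findings = tibble::as_tibble(findings),
                 subjects = subjects, truth = truth,
                 config = config),
            class = "cohort_tables")
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat("<cohort_tables>", nrow(x$truth), "subjects,",
      nrow(x$findings), "findings, seed", x$config$seed, "\n")
  invisible(x)
}

#' Write cohort tables to CSV files
#'
#' Writes `morphology.csv`, `findings.csv`, `subjects.csv` and
#' `truth.csv` (RFC-4180, UTF-8) into `dir`.
#'
#' @param cohort a `cohort_tables` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("morphology.csv", "findings.csv",
                            "subjects.csv", "truth.csv"))
  readr::write_csv(cohort$morphology, paths[1], na = "")
  readr::write_csv(cohort$findings, paths[2], na = "")
  readr::write_csv(cohort$subjects, paths[3], na = "")
  readr::write_csv(cohort$truth, paths[4], na = "")
  invisible(paths)
}
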