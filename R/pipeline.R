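#' Assemble per-subject analysis data from pipeline stages
#'
#' Joins the classification, coding and subject tables into one analysis
#' frame with per-system 0/1/NA outcomes (NA = non-available), the
#' no-malformation indicator, germ-layer and process indicators, the
#' affected-system band, and optional sex/gestational-age covariates.
#'
#' @param classified output of [classify_cohort()].
#' @param coded output of [code_findings()].
#' @param subjects optional subjects tibble with `sex` and `ga_weeks`.
#' @param age_breaks breaks (weeks) for the gestational-age band factor;
#'   default splits at 28 weeks. The banding is a configuration choice,
#'   not an inference.
#' @return analysis tibble, evaluable subjects only.
#' @export
assemble_analysis_data <- function(classified, coded, subjects = NULL,
                                   age_breaks = c(0, 28, Inf)) {
  dat <- dplyr::inner_join(classified, coded, by = "subject_id")
  dat <- dat[!is.na(dat$pattern), , drop = FALSE]
  for (s in organ_systems()) {
    dat[[paste0("out_", s)]] <- ifelse(dat[[s]] == "non_available",
                                       NA_real_,
                                       as.numeric(dat[[s]] == "affected"))
  }
  dat$out_no_malformation <- ifelse(dat$all_non_available, NA_real_,
                                    as.numeric(dat$n_systems_affected == 0L))
  for (l in germ_layers()) {
    dat[[paste0("out_layer_", l)]] <- as.numeric(dat[[l]])
  }
  for (p in morphogenetic_processes()) {
    dat[[paste0("out_proc_", p)]] <- as.numeric(dat[[p]])
  }
  if (!is.null(subjects)) {
    dat <- dplyr::left_join(
      dat, subjects[, intersect(c("subject_id", "sex", "ga_weeks"),
                                names(subjects))],
      by = "subject_id")
    if ("ga_weeks" %in% names(dat)) {
      dat$age_band <- cut(dat$ga_weeks, breaks = age_breaks,
                          right = FALSE)
    }
  }
  dat
}

#' Run the full association analysis on a classified, coded cohort
#'
#' Reproduces the study's analysis plan on any cohort: contingency
#' tables in both groupings with their correspondence analyses and
#' first-axis interpretations; severity GLMs for each organ system, the
#' no-malformation indicator, each germ layer, each morphogenetic
#' process and each affected-system band; overdispersion checks; a
#' likelihood-ratio test of the severity-by-germ-layer interaction;
#' pairwise slope comparisons between processes; trend correlations of
#' the regular and most-abnormal pattern frequencies across
#' affected-system bands; and chi-square checks of pattern against sex
#' and age band. Outcomes whose fit is impossible (no events, or no
#' severity variance) are skipped with a notice in `skipped`.
#'
#' @inheritParams assemble_analysis_data
#' @param adjust optional covariates for the GLMs (e.g. `c("sex",
#'   "age_band")` when `subjects` is given); default unadjusted.
#' @return list of class `cohort_report`.
#' @export
analyze_cohort <- function(classified, coded, subjects = NULL,
                           adjust = NULL, age_breaks = c(0, 28, Inf)) {
  dat <- assemble_analysis_data(classified, coded, subjects, age_breaks)
  if (nrow(dat) == 0L) stop("no evaluable subjects to analyze")
  report <- list()
  report$n <- nrow(dat)

  report$contingency <- list(
    eight_level = build_contingency(classified, coded, "eight_level"),
    four_level = build_contingency(classified, coded, "four_level")
  )
  report$ca <- lapply(report$contingency, function(tab) {
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    tryCatch({
      res <- correspondence_analysis(tab)
      list(result = res, axis = interpret_axis(res))
    }, error = function(e) {
      list(result = NULL, note = paste("skipped:", conditionMessage(e)))
    })
  })

  outcomes <- c(stats::setNames(paste0("out_", organ_systems()),
                                organ_systems()),
                no_malformation = "out_no_malformation",
                stats::setNames(paste0("out_layer_", germ_layers()),
                                paste0("layer_", germ_layers())),
                stats::setNames(
                  paste0("out_proc_", morphogenetic_processes()),
                  paste0("process_", morphogenetic_processes())))
  bands <- levels(n_affected_band(0))
  for (b in bands) {
    col <- paste0("out_band_", b)
    dat[[col]] <- ifelse(dat$all_non_available, NA_real_,
                         as.numeric(dat$n_band == b))
    outcomes[paste0("band_", b)] <- col
  }

  if (stats::sd(dat$severity) == 0) {
    report$skipped <- "all severity values identical: GLMs skipped"
    report$fits <- list()
    class(report) <- "cohort_report"
    return(report)
  }

  fits <- list()
  skipped <- character()
  for (nm in names(outcomes)) {
    col <- outcomes[[nm]]
    y <- dat[[col]]
    if (sum(y == 1, na.rm = TRUE) == 0L ||
        sum(y == 0, na.rm = TRUE) == 0L) {
      skipped <- c(skipped, paste0(nm, ": outcome has no variation"))
      next
    }
    fits[[nm]] <- fit_severity_glm(dat, col, "severity",
                                   covariates = adjust)
  }
  report$fits <- fits
  report$skipped <- skipped
  report$slopes <- dplyr::bind_rows(lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    tibble::tibble(outcome = nm,
                   n_cases = sum(dat[[outcomes[[nm]]]] == 1, na.rm = TRUE),
                   n_used = f$n,
                   slope = f$slope$estimate, se = f$slope$se,
                   z = f$slope$z, p = f$slope$p,
                   dispersion = f$dispersion,
                   overdispersed =
                     overdispersion_check(f)$verdict == "overdispersed")
  }))

  # severity-by-germ-layer interaction (stacked indicators)
  layer_stack <- dplyr::bind_rows(lapply(germ_layers(), function(l) {
    tibble::tibble(outcome = dat[[paste0("out_layer_", l)]],
                   severity = dat$severity, group = l)
  }))
  report$germ_layer_interaction <- tryCatch(
    interaction_lrt(layer_stack, "outcome", "severity", "group"),
    error = function(e) paste("skipped:", conditionMessage(e)))

  # pairwise process slope comparisons
  procs <- morphogenetic_processes()
  pairs <- utils::combn(procs, 2, simplify = FALSE)
  report$process_comparisons <- dplyr::bind_rows(lapply(pairs, function(pr) {
    stack <- dplyr::bind_rows(lapply(pr, function(p) {
      tibble::tibble(outcome = dat[[paste0("out_proc_", p)]],
                     severity = dat$severity, group = p)
    }))
    cmp <- tryCatch(compare_slopes(stack, "outcome", "severity", "group"),
                    error = function(e) NULL)
    if (is.null(cmp)) return(NULL)
    tibble::tibble(group_a = pr[1], group_b = pr[2], diff = cmp$diff,
                   se = cmp$se, statistic = cmp$statistic, p = cmp$p)
  }))

  # pattern-frequency trends across affected-system bands
  band_dat <- dat[!dat$all_non_available, , drop = FALSE]
  band_tab <- table(band_dat$n_band)
  if (all(band_tab >= 1L)) {
    f_reg <- vapply(bands, function(b) {
      mean(band_dat$pattern[band_dat$n_band == b] == "R")
    }, numeric(1))
    f_worst <- vapply(bands, function(b) {
      mean(band_dat$pattern[band_dat$n_band == b] == "CT_TL_LS")
    }, numeric(1))
    report$trend_regular <- tryCatch(freq_trend(f_reg),
                                     error = function(e) NULL)
    report$trend_most_abnormal <- tryCatch(freq_trend(f_worst),
                                           error = function(e) NULL)
    report$band_frequencies <- tibble::tibble(
      band = bands, n = as.integer(band_tab[bands]),
      freq_regular = f_reg, freq_most_abnormal = f_worst)
  }

  if (!is.null(subjects)) {
    if ("sex" %in% names(dat)) {
      report$sex_chisq <- pattern_covariate_chisq(dat, dat$sex)
    }
    if ("age_band" %in% names(dat)) {
      report$age_chisq <- pattern_covariate_chisq(dat,
                                                  as.character(dat$age_band))
    }
  }

  class(report) <- "cohort_report"
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>", x$n, "evaluable subjects;",
      length(x$fits), "severity GLMs fitted",
      if (length(x$skipped)) paste0("(", length(x$skipped), " skipped)"),
      "\n")
  if (!is.null(x$slopes)) print(as.data.frame(x$slopes), digits = 3)
  invisible(x)
}

#' Write a report bundle as TSV files
#'
#' Emits `slopes.tsv`, `process_comparisons.tsv`, `band_frequencies.tsv`
#' and per-grouping CA tables (`ca_<grouping>_inertia.tsv`,
#' `..._row_coords.tsv`, `..._col_coords.tsv`), each with a header line
#' recording the seed when one is supplied.
#'
#' @param report a `cohort_report`.
#' @param dir output directory.
#' @param seed optional seed to record in the file headers.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  hdr <- function(path) {
    if (!is.null(seed)) {
      writeLines(paste0("# seed: ", seed), path)
    }
  }
  emit <- function(tbl, name) {
    path <- file.path(dir, name)
    hdr(path)
    readr::write_tsv(tbl, path, append = !is.null(seed),
                     col_names = TRUE)
    paths <<- c(paths, path)
  }
  if (!is.null(report$slopes)) emit(report$slopes, "slopes.tsv")
  if (!is.null(report$process_comparisons) &&
      nrow(report$process_comparisons) > 0) {
    emit(report$process_comparisons, "process_comparisons.tsv")
  }
  if (!is.null(report$band_frequencies)) {
    emit(report$band_frequencies, "band_frequencies.tsv")
  }
  for (g in names(report$ca)) {
    res <- report$ca[[g]]$result
    emit(tibble::tibble(dimension = seq_len(res$ndim),
                        inertia = res$inertia, percent = res$percent),
         paste0("ca_", g, "_inertia.tsv"))
    emit(tibble::as_tibble(res$row_coords, rownames = "label"),
         paste0("ca_", g, "_row_coords.tsv"))
    emit(tibble::as_tibble(res$col_coords, rownames = "label"),
         paste0("ca_", g, "_col_coords.tsv"))
  }
  invisible(paths)
}
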