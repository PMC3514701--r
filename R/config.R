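#' Default pattern-class probabilities of the generator
#'
#' Eight-class multinomial over the pattern classes, reproducing the
#' reported cohort frequencies: 20.6% regular, 3.4% isolated lumbo-sacral
#' shifts, 8.6% thoraco-lumbar shifts with or without a lumbo-sacral
#' change, and 67.4% cervico-thoracic involvement, of which 33.4% also
#' shift the thoraco-lumbar boundary and 10.6% all three boundaries.
#' Composite frequencies (TL with TL_LS; CT with CT_LS) are split between
#' their two classes with `composite_split` (default 50:50), the only
#' free choice the printed marginals leave open.
#'
#' @param composite_split fraction of each composite frequency assigned
#'   to the class without the `_LS` suffix.
#' @return named probability vector over [pattern_levels()], summing to 1.
#' @export
default_pattern_probs <- function(composite_split = 0.5) {
  stopifnot(composite_split >= 0, composite_split <= 1)
  tl_total <- 0.086
  ct_involving <- 0.674
  ct_tl_total <- 0.334
  three <- 0.106
  ct_only_total <- ct_involving - ct_tl_total  # CT + CT_LS
  p <- c(
    R = 0.206,
    LS = 0.034,
    TL = tl_total * composite_split,
    TL_LS = tl_total * (1 - composite_split),
    CT = ct_only_total * composite_split,
    CT_LS = ct_only_total * (1 - composite_split),
    CT_TL = ct_tl_total - three,
    CT_TL_LS = three
  )
  p[pattern_levels()]
}

#' Per-system severity-association parameters of the generator
#'
#' For each organ system the generating log-odds slope on the numeric
#' severity score and the target number of affected cases among available
#' subjects in a cohort of the default size; intercepts are calibrated at
#' generation time with [calibrate_intercept()] so the expected case
#' count matches the target. Values default to the reported per-system
#' associations. `no_malformation` is not generated directly (it is the
#' complement of all system events) but its reported slope and count are
#' kept here for parameter-recovery simulations.
#'
#' @return tibble with `system`, `slope`, `target_n`.
#' @export
default_system_params <- function() {
  tibble::tibble(
    system = c("BP", "CV", "CF", "DS", "LD", "MS", "NS", "SK", "UG", "VBW"),
    slope = c(0.12, 0.12, 0.36, 0.19, 0.17, 0.11, 0.07, 0.31, 0.11, 0.18),
    target_n = c(68L, 216L, 64L, 110L, 146L, 28L, 121L, 115L, 168L, 23L)
  )
}

#' @rdname default_system_params
#' @export
no_malformation_params <- function() {
  list(slope = -0.11, target_n = 357L)
}

#' Generator configuration for a synthetic cohort
#'
#' Bundles every tunable of the synthetic cohort generator with defaults
#' matching the study's reported structure: cohort size 1062 (the number
#' of analysable columns), the eight-class pattern multinomial, per-system
#' logistic severity associations, independent per-system missingness,
#' rib-synthesis probabilities, and sex/gestational age distributions
#' with no effect on pattern class.
#'
#' @param n_subjects cohort size.
#' @param reference_n study-scale cohort size at which the per-system
#'   `target_n` case counts define prevalences; intercept calibration
#'   uses this reference so that smaller or larger cohorts keep the same
#'   generating prevalence structure.
#' @param pattern_probs named simplex over [pattern_levels()].
#' @param system_params tibble as [default_system_params()].
#' @param missingness per-system probability that an organ system is
#'   scored non-available (maceration / no autopsy); scalar or named
#'   vector over [organ_systems()].
#' @param ct_anterior_prob probability that a cervico-thoracic shift is
#'   anterior (cervical rib) rather than posterior (rudimentary/absent
#'   first rib); default 0.855 = 1 - 9.8/67.4, the reported share of
#'   first-rib cases among cervico-thoracic shifts.
#' @param tl_anterior_prob probability that a thoraco-lumbar shift is
#'   anterior (rudimentary/absent twelfth rib, the usual finding) rather
#'   than posterior (lumbar rib).
#' @param bilateral_prob probability that a rib anomaly is bilateral.
#' @param rudimentary_vs_absent_prob probability that an anomalous
#'   boundary rib is rudimentary rather than absent.
#' @param tp_enlarged_prob probability that an anterior cervico-thoracic
#'   shift presents as a qualifying enlarged transverse process instead
#'   of a free cervical rib.
#' @param thoracic_identity_prob probability that a cervical rib is
#'   longer than half the adjacent thoracic rib (rare full thoracic
#'   identity of the seventh vertebra).
#' @param ls_mode_probs probabilities that a lumbo-sacral shift realises
#'   as 23 presacral vertebrae, 25 presacral vertebrae, or an
#'   observer-flagged transitional lumbo-sacral vertebra at 24.
#' @param sex_probs named probabilities for male/female/unknown; defaults
#'   to the reported 589/460/13 split.
#' @param ga_mean,ga_sd,ga_range gestational age distribution in weeks
#'   (truncated normal; reported mean 26.6, SD 10.4, range 13-92).
#' @param seed integer root seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 1062L,
                          reference_n = 1062L,
                          pattern_probs = default_pattern_probs(),
                          system_params = default_system_params(),
                          missingness = 0.12,
                          ct_anterior_prob = 0.855,
                          tl_anterior_prob = 0.8,
                          bilateral_prob = 0.5,
                          rudimentary_vs_absent_prob = 0.6,
                          tp_enlarged_prob = 0.1,
                          thoracic_identity_prob = 0.02,
                          ls_mode_probs = c(minus = 0.45, plus = 0.35,
                                            flag = 0.20),
                          sex_probs = c(male = 589, female = 460,
                                        unknown = 13) / 1062,
                          ga_mean = 26.6, ga_sd = 10.4,
                          ga_range = c(13, 92),
                          seed = 1L) {
  if (length(missingness) == 1L) {
    missingness <- stats::setNames(rep(missingness, 10L), organ_systems())
  }
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects),
    reference_n = as.integer(reference_n),
    pattern_probs = pattern_probs,
    system_params = system_params,
    missingness = missingness,
    ct_anterior_prob = ct_anterior_prob,
    tl_anterior_prob = tl_anterior_prob,
    bilateral_prob = bilateral_prob,
    rudimentary_vs_absent_prob = rudimentary_vs_absent_prob,
    tp_enlarged_prob = tp_enlarged_prob,
    thoracic_identity_prob = thoracic_identity_prob,
    ls_mode_probs = ls_mode_probs,
    sex_probs = sex_probs,
    ga_mean = ga_mean, ga_sd = ga_sd, ga_range = ga_range,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  p <- cfg$pattern_probs
  if (!setequal(names(p), pattern_levels())) {
    stop("pattern_probs must be named by the eight pattern classes")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("pattern_probs must sum to 1 (off by ",
         format(sum(p) - 1), ")")
  }
  probs <- c(p, cfg$missingness, cfg$ct_anterior_prob,
             cfg$tl_anterior_prob, cfg$bilateral_prob,
             cfg$rudimentary_vs_absent_prob, cfg$tp_enlarged_prob,
             cfg$thoracic_identity_prob, cfg$ls_mode_probs, cfg$sex_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$ls_mode_probs) - 1) > 1e-9 ||
      abs(sum(cfg$sex_probs) - 1) > 1e-9) {
    stop("ls_mode_probs and sex_probs must each sum to 1")
  }
  if (cfg$n_subjects < 0L) stop("n_subjects must be nonnegative")
  cfg
}

#' Read a generator configuration from YAML
#'
#' Any field of [cohort_config()] may be overridden; `system_params`
#' is given as a list of `{system, slope, target_n}` entries. Unknown
#' keys raise an error naming the key.
#'
#' @param path YAML file.
#' @return `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$coding_map <- NULL  # may share a file with the coding map
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$pattern_probs)) {
    raw$pattern_probs <- unlist(raw$pattern_probs)
  }
  if (!is.null(raw$system_params)) {
    raw$system_params <- dplyr::bind_rows(lapply(raw$system_params,
                                                 tibble::as_tibble))
  }
  for (key in c("missingness", "ls_mode_probs", "sex_probs", "ga_range")) {
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  }
  do.call(cohort_config, raw)
}

#' Calibrate a logistic intercept to an expected case count
#'
#' Root-finds the intercept `a` such that the expected number of affected
#' cases among available subjects equals `target_n`, given the severity
#' distribution implied by `pattern_probs`, the generating slope, cohort
#' size and missingness: `(1 - miss) * n * sum_k p_k * plogis(a + b *
#' s_k) = target_n`, with `s_k` the severity value of class `k`.
#'
#' @param slope generating log-odds slope on severity.
#' @param target_n expected affected count among available subjects.
#' @param n_subjects cohort size.
#' @param pattern_probs pattern-class simplex.
#' @param missingness probability the system is non-available.
#' @return intercept (log-odds at severity 0).
#' @export
calibrate_intercept <- function(slope, target_n, n_subjects = 1062L,
                                pattern_probs = default_pattern_probs(),
                                missingness = 0) {
  sev <- severity_scale()[names(pattern_probs)]
  denom <- (1 - missingness) * n_subjects
  stopifnot(denom > 0, target_n > 0, target_n < denom)
  f <- function(a) {
    sum(pattern_probs * stats::plogis(a + slope * sev)) - target_n / denom
  }
  stats::uniroot(f, c(-40, 40), tol = 1e-12)$root
}
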