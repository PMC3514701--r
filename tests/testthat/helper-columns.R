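# Build a column from a compact spec: n vertebrae, baseline ribs on 8..19,
# per-vertebra-side overrides as "ordinal.side" = list(state, ratio).
make_column_rows <- function(sid, n = 24L, mods = list(),
                             tp_mods = list(), ls_flag_at = integer(),
                             quality = "evaluable") {
  rows <- vector("list", n * 2L)
  k <- 0L
  for (i in seq_len(n)) {
    for (s in c("left", "right")) {
      st <- if (i >= 8L && i <= 19L) "present" else "absent"
      ra <- if (st == "present") 1.0 else NA_real_
      key <- paste0(i, ".", s)
      if (!is.null(mods[[key]])) {
        st <- mods[[key]]$state
        ra <- mods[[key]]$ratio
      }
      tp <- if (!is.null(tp_mods[[key]])) 1L else 0L
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = sid, vertebra_ordinal = i, side = s,
        rib_state = st, length_ratio = ra, tp_exceeds_t1 = tp,
        sacral_attached = 0L,
        ls_transitional_flag = as.integer(i %in% ls_flag_at),
        quality = quality, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

make_column <- function(...) as_vertebral_column(make_column_rows(...))

rib <- function(state, ratio = NA_real_) list(state = state, ratio = ratio)

# cached cohorts shared across test files (built once per test run)
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(n, seed) {
  key <- paste0("n", n, "_s", seed)
  if (is.null(.cohort_cache[[key]])) {
    coh <- generate_cohort(cohort_config(n_subjects = n, seed = seed))
    cls <- suppressWarnings(classify_cohort(coh$morphology))
    .cohort_cache[[key]] <- list(cohort = coh, classified = cls)
  }
  .cohort_cache[[key]]
}
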