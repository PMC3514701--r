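#!/usr/bin/env Rscript
# Stage 3: malformation coding.
#
# Codes the findings table into per-subject primary organ-system flags
# (primary/secondary causal rules), derives germ-layer and
# morphogenetic-process involvement from the shipped coding map, and
# writes results/coded.csv.

suppressPackageStartupMessages(library(homeovert))

findings <- readr::read_csv("results/cohort/findings.csv",
                            show_col_types = FALSE,
                            col_types = readr::cols(
                              cause_context = readr::col_character()))
findings$cause_context[is.na(findings$cause_context)] <- ""
subjects <- readr::read_csv("results/cohort/subjects.csv",
                            show_col_types = FALSE)
coded <- code_findings(findings, subjects)
readr::write_csv(coded, "results/coded.csv", na = "")

n <- nrow(coded)
cat("Coded", n, "subjects\n")
cat("Affected per organ system (% of available):\n")
for (s in organ_systems()) {
  avail <- coded[[s]] != "non_available"
  cat(sprintf("  %-4s %5.1f %% (n = %d of %d available)\n", s,
              100 * mean(coded[[s]][avail] == "affected"),
              sum(coded[[s]] == "affected"), sum(avail)))
}
cat(sprintf("No malformations: %d (%.1f %%)\n",
            sum(coded$n_systems_affected == 0 & !coded$all_non_available),
            100 * mean(coded$n_systems_affected == 0 &
                         !coded$all_non_available)))
cat("Affected-system bands:\n")
print(table(coded$n_band))
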