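#!/usr/bin/env Rscript
# Step 2 — univariate candidate screening.
#
# Normality-gated ANOVA / Kruskal-Wallis per metabolite against each
# pregnancy endpoint, Bonferroni-adjusted, with bull-breed and Day-6-stage
# fixed-effect checks. CM is screened as one aggregate cohort; plasma is
# screened within the AV and Holstein breed blocks (crossbred excluded),
# following the breed separation seen in Day-0 plasma.

suppressMessages(library(bovipreg))

coh <- read_cohort("results/cohort_discovery")
rec <- coh$et_records

subset_mm <- function(mm, ids) {
  mm$values <- mm$values[rownames(mm$values) %in% ids, , drop = FALSE]
  mm
}

blocks <- list(CM_aggregate = coh$cm)
for (br in c("AV", "Holstein")) {
  ids <- rec$et_id[rec$breed == br]
  blocks[[paste0("plasma_d0_", br)]] <- subset_mm(coh$plasma_d0, ids)
  blocks[[paste0("plasma_d7_", br)]] <- subset_mm(coh$plasma_d7, ids)
}

out <- list()
for (ep in c("d40", "d62", "birth")) {
  for (bl in names(blocks)) {
    scr <- screen_matrix(blocks[[bl]], rec, ep)
    scr$block <- bl
    out[[paste(ep, bl)]] <- scr
  }
}
candidates <- do.call(rbind, unname(out))
dir.create("results", showWarnings = FALSE)
write.table(candidates, "results/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

hits <- candidates[candidates$candidate_flag, ]
cat("screened", nrow(candidates), "metabolite x endpoint x block tests;",
    nrow(hits), "candidates after Bonferroni:\n")
print(hits[, c("metabolite", "block", "endpoint", "p_value", "p_adjusted",
               "fch", "test_used")], row.names = FALSE)
cat("written to results/candidates.tsv\n")
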