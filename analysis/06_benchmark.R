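#!/usr/bin/env Rscript
# Step 6 — null and power characterisation of the whole procedure.
#
# Two simulation scenarios: a global null (no effects) measuring the
# screen's type-I error, the family-wise error after Bonferroni, and the
# selection inflation of the all-pairs F1 scan; and a planted scenario
# (log2FC = 2 on one CM and one Day-0 plasma metabolite, published group
# sizes) measuring recovery of the planted pair. Replicate counts are kept
# moderate here; the test suite runs the same benchmarks at full size.

suppressMessages(library(bovipreg))

null_bm <- run_benchmark(cohort_config(), n_reps = 50, scenario = "null",
                         seed = 20210419)
eff <- rbind(
  data.frame(metabolite = "CM_01", compartment = "CM", endpoint = "birth",
             log2fc = 2),
  data.frame(metabolite = "P_01", compartment = "plasma_d0",
             endpoint = "birth", log2fc = 2))
planted_bm <- run_benchmark(
  cohort_config(effect_table = eff,
                fixed_outcome_counts = c(d40 = 23, d62 = 21, birth = 19)),
  n_reps = 50, scenario = "planted",
  planted_pair = list(cm = "CM_01", plasma = "P_01", plasma_day = "d0"),
  seed = 20210419)

dir.create("results", showWarnings = FALSE)
write.table(null_bm$per_rep, "results/benchmark_null.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(planted_bm$per_rep, "results/benchmark_planted.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("null scenario (50 replicates):\n")
print(null_bm$summary, row.names = FALSE)
cat("-> the best-pair p < 0.05 rate shows the selection optimism of",
    "scanning ~2600 pairs; single-pair p-values must not be read at face",
    "value after selection.\n")
cat("planted scenario (50 replicates):\n")
print(planted_bm$summary, row.names = FALSE)
cat("written to results/benchmark_null.tsv and results/benchmark_planted.tsv\n")
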