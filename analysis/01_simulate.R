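#!/usr/bin/env Rscript
# Step 1 — simulate the study cohorts.
#
# Builds a 36-ET discovery cohort (37 CM metabolites, 71 plasma metabolites,
# breed block AV 13 / Holstein 17 / cross 6, one uncollected Day-0 plasma
# sample) and an independent 19-ET Holstein validation cohort in absolute
# units. Four metabolites carry planted open/pregnant effects standing in
# for the birth-predictive signals of the real study: two embryo-side (CM)
# metabolites with log2 fold changes above 2, two recipient-side (Day-0
# plasma) metabolites with smaller shifts — the embryo/recipient effect-size
# contrast the discovery tables show.

suppressMessages(library(bovipreg))

seed <- 20210416
effects <- rbind(
  data.frame(metabolite = "CM_05", compartment = "CM", endpoint = "birth",
             log2fc = 2.2),
  data.frame(metabolite = "CM_11", compartment = "CM", endpoint = "birth",
             log2fc = 2.0),
  data.frame(metabolite = "P_03", compartment = "plasma_d0",
             endpoint = "birth", log2fc = 1.6),
  data.frame(metabolite = "P_17", compartment = "plasma_d0",
             endpoint = "birth", log2fc = -1.4)   # higher in pregnant
)

cfg <- cohort_config(effect_table = effects,
                     fixed_outcome_counts = c(d40 = 23, d62 = 21, birth = 19),
                     seed = seed)
discovery <- generate_cohort(cfg)
validation <- generate_validation_cohort(cfg, discovery_effects = effects)

write_cohort(discovery, "results/cohort_discovery")
write_cohort(validation, "results/cohort_validation")

cat("discovery cohort: ", nrow(discovery$et_records), "ETs; CM ",
    paste(dim(discovery$cm$values), collapse = "x"), "; plasma Day-0 ",
    paste(dim(discovery$plasma_d0$values), collapse = "x"), "\n", sep = "")
cat("outcomes (d40/d62/birth): ",
    paste(colSums(discovery$et_records[, c("pregnant_d40", "pregnant_d62",
                                           "birth")]), collapse = "/"), "\n",
    sep = "")
cat("validation cohort: ", nrow(validation$et_records),
    " Holstein ETs, absolute units\n", sep = "")
cat(discovery$log, sep = "\n")
cat("written to results/cohort_discovery and results/cohort_validation\n")
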