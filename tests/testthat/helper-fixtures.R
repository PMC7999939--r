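# Shared fixtures: all synthetic, built in code at test time.

# Small planted-effect configuration: one CM and one Day-0 plasma metabolite
# shifted at birth, everything else null.
planted_effects <- function(log2fc = 2, cm = "CM_01", plasma = "P_01") {
  rbind(
    data.frame(metabolite = cm, compartment = "CM", endpoint = "birth",
               log2fc = log2fc, stringsAsFactors = FALSE),
    data.frame(metabolite = plasma, compartment = "plasma_d0",
               endpoint = "birth", log2fc = log2fc, stringsAsFactors = FALSE)
  )
}

# Tiny cohort config for fast loops: panel sizes cut down, structure intact
small_config <- function(seed, effect_table = NULL, n_cm = 4L, n_plasma = 6L) {
  cohort_config(n_cm_metabolites = n_cm, n_plasma_metabolites = n_plasma,
                effect_table = effect_table, seed = seed)
}

# Brute-force AUC by between-class pair counting, ties count one half.
# Independent of the rank-based implementation.
brute_auc <- function(values, pregnant) {
  vp <- values[pregnant]
  vo <- values[!pregnant]
  tot <- 0
  for (a in vp) for (b in vo) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  raw <- tot / (length(vp) * length(vo))
  max(raw, 1 - raw)
}

# Exhaustive optimal-cutoff search over all midpoints and infinities,
# replicating the corner-distance criterion independently.
brute_cutoff <- function(values, pregnant, orientation) {
  v <- sort(unique(values))
  cuts <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  best <- NULL
  for (cut in cuts) {
    pred <- if (orientation == "pregnant_high") values > cut else values < cut
    sens <- sum(pred & pregnant) / sum(pregnant)
    spec <- sum(!pred & !pregnant) / sum(!pregnant)
    d <- sqrt((1 - sens)^2 + (1 - spec)^2)
    j <- sens + spec - 1
    cand <- list(cutoff = cut, sens = sens, spec = spec, d = d, j = j)
    if (is.null(best) || d < best$d - 1e-12 ||
        (abs(d - best$d) <= 1e-12 && j > best$j + 1e-12) ||
        (abs(d - best$d) <= 1e-12 && abs(j - best$j) <= 1e-12 && cut < best$cutoff)) {
      best <- cand
    }
  }
  best
}

# Named vector helpers for pair scoring
named_col <- function(mm, nm) stats::setNames(mm$values[, nm], rownames(mm$values))
named_outcome <- function(rec, endpoint) {
  stats::setNames(bovipreg:::endpoint_outcome(rec, endpoint), rec$et_id)
}
named_stage <- function(rec) stats::setNames(rec$day6_stage, rec$et_id)

# Yates-corrected chi-square of one confusion 2x2, via stats::chisq.test
yates_chi2 <- function(cc) {
  m <- matrix(c(cc$tp, cc$fn, cc$fp, cc$tn), 2, 2)
  suppressWarnings(unname(stats::chisq.test(m, correct = TRUE)$statistic))
}

# The 200-replicate null benchmark is used by two separate calibration
# checks; run it once per session and cache the result.
.bench_cache <- new.env(parent = emptyenv())
cached_null_benchmark <- function() {
  if (is.null(.bench_cache$null)) {
    .bench_cache$null <- run_benchmark(cohort_config(), n_reps = 200,
                                       scenario = "null", seed = 20210416)
  }
  .bench_cache$null
}
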