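#' Choose between ANOVA and Kruskal-Wallis via a normality gate
#'
#' Applies Shapiro-Wilk to the within-group residuals of each outcome group:
#' the parametric one-way ANOVA is used only when normality is not rejected
#' (at `alpha`) in both groups; otherwise the Kruskal-Wallis rank test is
#' used. This mirrors the common metabolomics practice of gating the
#' parametric test on a per-metabolite normality check, since metabolite
#' concentrations are frequently skewed.
#'
#' @param values numeric concentrations (`NA` dropped).
#' @param groups logical or two-level factor splitting the samples.
#' @param alpha significance level of the normality gate.
#' @return list with `test` (`"anova"` or `"kruskal_wallis"`) and
#'   `shapiro_p`, the per-group Shapiro-Wilk p-values.
#' @export
choose_test <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.factor(groups[keep])
  if (nlevels(droplevels(groups)) != 2L) {
    stop_data("need exactly two groups for the normality-gated test")
  }
  split_vals <- split(values, droplevels(groups))
  if (any(vapply(split_vals, length, 1L) < 3L)) {
    stop_data("insufficient data: each group needs at least 3 values")
  }
  if (stats::var(values) == 0 ||
      any(vapply(split_vals, stats::var, 1.0) == 0)) {
    stop_data("insufficient variance: constant-valued metabolite")
  }
  shapiro_p <- vapply(split_vals, function(v) {
    stats::shapiro.test(v - mean(v))$p.value
  }, 1.0)
  test <- if (all(shapiro_p > alpha)) "anova" else "kruskal_wallis"
  list(test = test, shapiro_p = shapiro_p)
}

#' Log2 fold change of group means (open over pregnant)
#'
#' The reported fold change is `log2(mean(open) / mean(pregnant))`, so a
#' positive value means higher concentrations in recipients that did not
#' reach the endpoint.
#'
#' @param open_values,pregnant_values concentrations per group (`NA` dropped).
#' @return log2 fold change (dimensionless).
#' @export
fold_change <- function(open_values, pregnant_values) {
  mo <- mean(open_values, na.rm = TRUE)
  mp <- mean(pregnant_values, na.rm = TRUE)
  if (!is.finite(mo) || !is.finite(mp) || mo <= 0 || mp <= 0) {
    stop_data("undefined fold change: group means must be positive")
  }
  log2(mo / mp)
}

#' Multiplicity adjustment of p-values
#'
#' Thin, validated wrapper over [stats::p.adjust()]: `bonferroni` gives
#' `min(1, m * p)`, `bh` the Benjamini-Hochberg step-up adjusted values.
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @param method `"bonferroni"` (default, the stricter criterion used for
#'   candidate calling) or `"bh"`.
#' @return adjusted p-values, same length and order as the input.
#' @export
adjust_pvalues <- function(p_values, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  bad <- !is.na(p_values) & (p_values < 0 | p_values > 1)
  if (any(bad)) stop_data("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = if (method == "bh") "BH" else "bonferroni")
}

#' Remove gross outliers by a fold-over-mean rule
#'
#' A value is removed when it exceeds `threshold_fold` times the mean of the
#' remaining values (e.g. a single sample at 1200x the mean of the rest).
#' The rule is evaluated in one pass against each value's leave-one-out
#' mean; removals are reported, never silent.
#'
#' @param values named (or unnamed) numeric vector.
#' @param threshold_fold removal threshold, must exceed 1; default 100.
#' @return list with `values` (retained) and `removed` (names or indices of
#'   removed samples; empty when nothing is removed).
#' @export
remove_outliers <- function(values, threshold_fold = 100) {
  if (threshold_fold <= 1) stop_config("threshold_fold must exceed 1")
  ids <- names(values)
  if (is.null(ids)) {
    ids <- as.character(seq_along(values))
    names(values) <- ids
  }
  present <- which(!is.na(values))
  flag <- logical(length(values))
  for (i in present) {
    others <- values[setdiff(present, i)]
    if (length(others) > 0 && mean(others) > 0 &&
        values[i] > threshold_fold * mean(others)) {
      flag[i] <- TRUE
    }
  }
  list(values = values[!flag], removed = ids[flag])
}

two_group_p <- function(values, groups, test) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) return(NA_real_)
  if (test == "anova") {
    summary(stats::aov(values ~ groups))[[1]][["Pr(>F)"]][1]
  } else {
    stats::kruskal.test(values, groups)$p.value
  }
}

#' Univariate test of one metabolite against a pregnancy endpoint
#'
#' Runs the normality-gated test ([choose_test()]) of concentrations against
#' the open/pregnant outcome, reports group means with standard errors, the
#' log2 fold change (open/pregnant) and, when covariates are supplied, the
#' same test applied to each fixed effect (bull breed, Day-6 embryonic
#' stage) separately.
#'
#' @param values concentrations for one metabolite (`NA` dropped pairwise).
#' @param pregnant logical outcome at the endpoint under study.
#' @param covariates optional named list with elements `bull_breed` and/or
#'   `day6_stage` (factors aligned with `values`).
#' @param outlier_threshold `NULL` to disable outlier removal, otherwise
#'   passed to [remove_outliers()].
#' @return one-row data.frame with test used, p-values, group summaries,
#'   fold change and the ids of removed outliers (comma-separated).
#' @export
test_metabolite <- function(values, pregnant, covariates = NULL,
                            outlier_threshold = NULL) {
  ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_along(values))
  names(values) <- ids
  removed <- character(0)
  if (!is.null(outlier_threshold)) {
    out <- remove_outliers(values, outlier_threshold)
    removed <- out$removed
    keep_ids <- setdiff(ids, removed)
  } else {
    keep_ids <- ids
  }
  keep <- ids %in% keep_ids & !is.na(values) & !is.na(pregnant)
  v <- values[keep]
  g <- pregnant[keep]
  open_v <- v[!g]
  preg_v <- v[g]
  gate <- choose_test(v, g)
  p_value <- two_group_p(v, g, gate$test)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  p_bb <- p_d6 <- NA_real_
  if (!is.null(covariates$bull_breed)) {
    p_bb <- two_group_p(v, covariates$bull_breed[keep], gate$test)
  }
  if (!is.null(covariates$day6_stage)) {
    p_d6 <- two_group_p(v, covariates$day6_stage[keep], gate$test)
  }
  data.frame(
    test_used = gate$test,
    p_value = p_value,
    mean_open = mean(open_v), se_open = se(open_v),
    mean_pregnant = mean(preg_v), se_pregnant = se(preg_v),
    fch = fold_change(open_v, preg_v),
    p_bull_breed = p_bb, p_day6_stage = p_d6,
    n_open = length(open_v), n_pregnant = length(preg_v),
    outliers_removed = paste(removed, collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Screen all metabolites of one matrix at one endpoint
#'
#' Applies [test_metabolite()] to every metabolite, adjusts the p-values
#' across the panel ([adjust_pvalues()]) and flags candidates: a metabolite
#' is a biomarker candidate when both its raw and adjusted p-values fall
#' below `alpha`. Metabolites that cannot be tested (all-missing, constant,
#' or a group below 3 observations after missing-value handling) are skipped
#' with a logged warning and carry `NA` results.
#'
#' @param mm a [metabolite_matrix()].
#' @param et_records the cohort metadata (`et_id`, outcomes, covariates).
#' @param endpoint `"d40"`, `"d62"` or `"birth"`.
#' @param alpha candidate-calling significance level.
#' @param adjust multiplicity method for the candidate flag.
#' @param covariates if `TRUE`, also test bull breed and Day-6 stage.
#' @param outlier_threshold passed to [test_metabolite()]; `NULL` disables.
#' @return data.frame, one row per metabolite, with a `candidate_flag`
#'   column; skipped metabolites are listed in `attr(, "skipped")`.
#' @export
screen_matrix <- function(mm, et_records, endpoint,
                          alpha = 0.05, adjust = c("bonferroni", "bh"),
                          covariates = TRUE, outlier_threshold = 100) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(mm, "metabolite_matrix"))
  idx <- match(rownames(mm$values), et_records$et_id)
  if (anyNA(idx)) stop_data("matrix contains samples absent from et_records")
  rec <- et_records[idx, , drop = FALSE]
  pregnant <- endpoint_outcome(rec, endpoint)
  covs <- if (isTRUE(covariates)) {
    list(bull_breed = factor(rec$bull_breed), day6_stage = factor(rec$day6_stage))
  }
  rows <- vector("list", ncol(mm$values))
  skipped <- character(0)
  for (j in seq_len(ncol(mm$values))) {
    nm <- colnames(mm$values)[j]
    res <- tryCatch(
      test_metabolite(stats::setNames(mm$values[, j], rownames(mm$values)),
                      pregnant, covariates = covs,
                      outlier_threshold = outlier_threshold),
      bovipreg_data_error = function(e) {
        warning(sprintf("skipping %s: %s", nm, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) {
      skipped <- c(skipped, nm)
      res <- data.frame(test_used = NA_character_, p_value = NA_real_,
                        mean_open = NA_real_, se_open = NA_real_,
                        mean_pregnant = NA_real_, se_pregnant = NA_real_,
                        fch = NA_real_, p_bull_breed = NA_real_,
                        p_day6_stage = NA_real_, n_open = NA_integer_,
                        n_pregnant = NA_integer_, outliers_removed = "",
                        stringsAsFactors = FALSE)
    }
    rows[[j]] <- cbind(data.frame(metabolite = nm,
                                  compartment = mm$compartment,
                                  endpoint = endpoint,
                                  stringsAsFactors = FALSE), res)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p_value, adjust)
  out$candidate_flag <- !is.na(out$p_value) &
    out$p_value < alpha & out$p_adjusted < alpha
  attr(out, "skipped") <- skipped
  out
}
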