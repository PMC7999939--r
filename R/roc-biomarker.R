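#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' Computes `U / (n1 * n0)` where `U` counts between-class pairs in which
#' the pregnant sample has the larger value, with ties counted one half.
#' Orientation is auto-detected: when the raw statistic falls below 0.5 the
#' metabolite discriminates with pregnant animals on the LOW side, and the
#' reported AUC is flipped above 0.5 with `orientation = "pregnant_low"`.
#'
#' @param values concentrations (`NA` dropped).
#' @param pregnant logical class labels.
#' @return list with `auc` (>= 0.5) and `orientation` (`"pregnant_high"` or
#'   `"pregnant_low"`).
#' @export
roc_auc <- function(values, pregnant) {
  keep <- !is.na(values) & !is.na(pregnant)
  values <- values[keep]
  pregnant <- pregnant[keep]
  n1 <- sum(pregnant)
  n0 <- sum(!pregnant)
  if (n1 < 2L || n0 < 2L) {
    stop_data("degenerate labels: need at least 2 samples per class")
  }
  r <- rank(values)
  auc_raw <- (sum(r[pregnant]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (auc_raw >= 0.5) {
    list(auc = auc_raw, orientation = "pregnant_high")
  } else {
    list(auc = 1 - auc_raw, orientation = "pregnant_low")
  }
}

# All candidate thresholds: midpoints of adjacent distinct sorted values,
# plus the two infinities (classify-all / classify-none).
candidate_cutoffs <- function(values) {
  v <- sort(unique(values))
  mids <- if (length(v) > 1L) (v[-1] + v[-length(v)]) / 2 else numeric(0)
  c(-Inf, mids, Inf)
}

# Predicted "pregnant" side of a cutoff under an orientation
call_pregnant <- function(values, cutoff, orientation) {
  if (orientation == "pregnant_high") values > cutoff else values < cutoff
}

#' Optimal ROC cutoff: closest to the perfect-classification corner
#'
#' Scans all candidate thresholds (midpoints of adjacent distinct values
#' plus the infinities) and returns the one minimising the Euclidean
#' distance to the corner of perfect classification (sensitivity 1,
#' specificity 1). Ties are broken by maximal Youden J (sens + spec - 1),
#' then by the lower threshold.
#'
#' @inheritParams roc_auc
#' @param orientation from [roc_auc()].
#' @return list with `cutoff`, `sens`, `spec`.
#' @export
optimal_cutoff <- function(values, pregnant, orientation) {
  keep <- !is.na(values) & !is.na(pregnant)
  values <- values[keep]
  pregnant <- pregnant[keep]
  if (sum(pregnant) < 1L || sum(!pregnant) < 1L) {
    stop_data("degenerate labels: both classes must be present")
  }
  cuts <- candidate_cutoffs(values)
  best <- NULL
  for (cut in cuts) {
    pred <- call_pregnant(values, cut, orientation)
    sens <- sum(pred & pregnant) / sum(pregnant)
    spec <- sum(!pred & !pregnant) / sum(!pregnant)
    d <- sqrt((1 - sens)^2 + (1 - spec)^2)
    j <- sens + spec - 1
    if (is.null(best) ||
        d < best$d - 1e-12 ||
        (abs(d - best$d) <= 1e-12 && j > best$j + 1e-12) ||
        (abs(d - best$d) <= 1e-12 && abs(j - best$j) <= 1e-12 && cut < best$cutoff)) {
      best <- list(cutoff = cut, sens = sens, spec = spec, d = d, j = j)
    }
  }
  best[c("cutoff", "sens", "spec")]
}

#' Per-class correct counts at a cutoff
#'
#' Counts the open samples on the open side and the pregnant samples on the
#' pregnant side of the cutoff, with each class's denominator (group size
#' after missing-value handling) — the "correctly identified / total"
#' numbers of the discovery tables.
#'
#' @inheritParams optimal_cutoff
#' @param cutoff from [optimal_cutoff()].
#' @return list with `correct_open = c(k, n_open)` and
#'   `correct_pregnant = c(m, n_pregnant)`.
#' @export
class_counts <- function(values, pregnant, cutoff, orientation) {
  keep <- !is.na(values) & !is.na(pregnant)
  values <- values[keep]
  pregnant <- pregnant[keep]
  pred <- call_pregnant(values, cutoff, orientation)
  list(
    correct_open = c(sum(!pred & !pregnant), sum(!pregnant)),
    correct_pregnant = c(sum(pred & pregnant), sum(pregnant))
  )
}

#' Stratified percentile bootstrap confidence interval for the AUC
#'
#' Resamples within each class (so both classes are always represented) and
#' recomputes the AUC under the orientation fixed by the full sample, so
#' that resampled values may fall below 0.5 and overlapping small groups
#' yield intervals spanning chance.
#'
#' @inheritParams roc_auc
#' @param n_boot number of bootstrap resamples (a warning is logged below
#'   100).
#' @param seed integer seed for reproducibility.
#' @param conf confidence level.
#' @return numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(values, pregnant, n_boot = 1000L, seed = 1L,
                         conf = 0.95) {
  if (n_boot < 100L) {
    warning("n_boot below 100: interval will be unstable", call. = FALSE)
  }
  keep <- !is.na(values) & !is.na(pregnant)
  values <- values[keep]
  pregnant <- pregnant[keep]
  vp <- values[pregnant]
  vo <- values[!pregnant]
  orientation <- roc_auc(values, pregnant)$orientation
  raw_auc <- function(p, o) {
    r <- rank(c(p, o))
    (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
      (length(p) * length(o))
  }
  set.seed(seed)
  aucs <- vapply(seq_len(n_boot), function(b) {
    a <- raw_auc(sample(vp, replace = TRUE), sample(vo, replace = TRUE))
    if (orientation == "pregnant_high") a else 1 - a
  }, 1.0)
  a <- (1 - conf) / 2
  unname(stats::quantile(aucs, c(a, 1 - a), type = 7))
}

#' Single-biomarker ROC evaluation of one metabolite
#'
#' Bundles the oriented AUC, its bootstrap interval, the
#' closest-to-corner optimal cutoff with per-class correct counts, the
#' Welch t-test p-value on untransformed concentrations, and the selection
#' flag of the single-biomarker rule (AUC above `auc_threshold` and t-test
#' p below `p_threshold`).
#'
#' @inheritParams roc_auc
#' @param auc_threshold selection threshold on the AUC (default 0.650).
#' @param p_threshold reporting threshold for the t-test p-value.
#' @param n_boot,seed bootstrap settings, see [bootstrap_ci()].
#' @param pooled_var if `TRUE` use the pooled-variance t-test instead of
#'   Welch's.
#' @return one-row data.frame (AUC, CI, orientation, cutoff, sens, spec,
#'   correct counts and denominators, p_ttest, selected).
#' @export
roc_biomarker <- function(values, pregnant, auc_threshold = 0.650,
                          p_threshold = 0.05, n_boot = 1000L, seed = 1L,
                          pooled_var = FALSE) {
  a <- roc_auc(values, pregnant)
  ci <- bootstrap_ci(values, pregnant, n_boot = n_boot, seed = seed)
  oc <- optimal_cutoff(values, pregnant, a$orientation)
  cc <- class_counts(values, pregnant, oc$cutoff, a$orientation)
  keep <- !is.na(values) & !is.na(pregnant)
  p_t <- stats::t.test(values[keep][!pregnant[keep]],
                       values[keep][pregnant[keep]],
                       var.equal = pooled_var)$p.value
  data.frame(
    auc = a$auc, ci_low = min(ci[1], a$auc), ci_high = max(ci[2], a$auc),
    orientation = a$orientation,
    cutoff = oc$cutoff, sens = oc$sens, spec = oc$spec,
    correct_open = cc$correct_open[1], n_open = cc$correct_open[2],
    correct_pregnant = cc$correct_pregnant[1], n_pregnant = cc$correct_pregnant[2],
    p_ttest = p_t,
    selected = a$auc > auc_threshold & p_t < p_threshold,
    stringsAsFactors = FALSE
  )
}

#' ROC biomarker table for a whole matrix at one endpoint
#'
#' Applies [roc_biomarker()] per metabolite and adds the
#' "correctly identified / total" display columns of the discovery tables.
#'
#' @param mm a [metabolite_matrix()].
#' @param et_records cohort metadata.
#' @param endpoint `"d40"`, `"d62"` or `"birth"`.
#' @param metabolites optional subset of metabolite names (default: all).
#' @param ... passed to [roc_biomarker()].
#' @return data.frame, one row per metabolite, with `open_counts` and
#'   `pregnant_counts` formatted as "k/n".
#' @export
roc_table <- function(mm, et_records, endpoint, metabolites = NULL, ...) {
  stopifnot(inherits(mm, "metabolite_matrix"))
  if (is.null(metabolites)) metabolites <- colnames(mm$values)
  idx <- match(rownames(mm$values), et_records$et_id)
  pregnant <- endpoint_outcome(et_records[idx, , drop = FALSE], endpoint)
  rows <- lapply(metabolites, function(nm) {
    res <- roc_biomarker(mm$values[, nm], pregnant, ...)
    cbind(data.frame(metabolite = nm, compartment = mm$compartment,
                     endpoint = endpoint, stringsAsFactors = FALSE),
          res,
          data.frame(open_counts = format_counts(res$correct_open, res$n_open),
                     pregnant_counts = format_counts(res$correct_pregnant,
                                                     res$n_pregnant),
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
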