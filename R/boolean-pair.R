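#' Pregnant range of a metabolite
#'
#' The inclusive `[min, max]` interval of the metabolite's concentrations
#' among recipients that reached the endpoint ("pregnant range"). An
#' optional symmetric percentile trim is available for robustness studies;
#' the default is the plain min/max interval.
#'
#' @param values concentrations (named by sample id; `NA` allowed).
#' @param pregnant logical labels aligned with `values`.
#' @param trim `NULL` for min/max, or a single proportion `q` for the
#'   `[q, 1-q]` percentile interval of the pregnant values.
#' @return numeric `c(range_low, range_high)`.
#' @export
pregnant_range <- function(values, pregnant, trim = NULL) {
  pv <- values[pregnant & !is.na(values)]
  if (length(pv) < 2L) {
    stop_data("insufficient data: need at least 2 pregnant values for a range")
  }
  if (is.null(trim)) {
    c(min(pv), max(pv))
  } else {
    unname(stats::quantile(pv, c(trim, 1 - trim), type = 7))
  }
}

#' Boolean pregnant-range calls
#'
#' Marks each sample `TRUE` when its concentration lies within the pregnant
#' range, inclusive at both ends. Missing concentrations yield missing
#' calls, and such samples are excluded from pair scoring downstream.
#'
#' @param values concentrations.
#' @param range `c(range_low, range_high)` from [pregnant_range()].
#' @return logical vector (with `NA` for missing inputs); attributes
#'   `range` and `n_true`.
#' @export
boolean_calls <- function(values, range) {
  if (range[1] > range[2]) stop_data("range_low must not exceed range_high")
  calls <- values >= range[1] & values <= range[2]
  structure(calls, range = range, n_true = sum(calls, na.rm = TRUE))
}

#' OR-combination of two Boolean call vectors
#'
#' Combines an embryo (CM) call vector with a recipient (plasma) call
#' vector: the combined call is `TRUE` when either member calls the sample
#' within its pregnant range. If either member's call is missing the
#' combined call is missing (the sample drops out of scoring).
#'
#' @param calls_cm,calls_plasma logical vectors over the same samples.
#' @return logical vector of combined calls.
#' @export
combine_or <- function(calls_cm, calls_plasma) {
  if (length(calls_cm) != length(calls_plasma)) {
    stop_data("call vectors must cover the same samples")
  }
  out <- as.logical(calls_cm) | as.logical(calls_plasma)
  out[is.na(calls_cm) | is.na(calls_plasma)] <- NA
  out
}

#' Confusion counts of calls against outcomes
#'
#' Pregnancy is the positive class: `tp` = pregnant and called within range,
#' `tn` = open and called outside, `fp` = open called within, `fn` =
#' pregnant called outside. Samples with missing calls are excluded.
#'
#' @param calls logical call vector.
#' @param pregnant logical outcomes.
#' @return list with `tp`, `fp`, `fn`, `tn`.
#' @export
pair_confusion <- function(calls, pregnant) {
  keep <- !is.na(calls) & !is.na(pregnant)
  calls <- calls[keep]
  pregnant <- pregnant[keep]
  list(tp = sum(calls & pregnant), fp = sum(calls & !pregnant),
       fn = sum(!calls & pregnant), tn = sum(!calls & !pregnant))
}

sum_confusion <- function(confusions) {
  Reduce(function(a, b) Map(`+`, a, b), confusions)
}

#' F1 score from confusion counts
#'
#' `2 tp / (2 tp + fp + fn)`, the harmonic mean of precision and recall with
#' pregnancy as the positive class. Undefined (NA) when `tp + fp + fn = 0`.
#'
#' @param confusion list with `tp`, `fp`, `fn` (and `tn`, unused).
#' @return F1 in \[0, 1\], or `NA` when undefined.
#' @export
f1_score <- function(confusion) {
  denom <- 2 * confusion$tp + confusion$fp + confusion$fn
  if (denom == 0) return(NA_real_)
  2 * confusion$tp / denom
}

#' Mantel-Haenszel chi-square over stratified 2x2 tables
#'
#' Each stratum is a calls-by-outcome 2x2 table summarised as confusion
#' counts. The statistic is
#' `(|sum_i (a_i - E a_i)| - 1/2)^2 / sum_i Var(a_i)` with `a_i = tp_i`,
#' expectation from the margins and, by default, the Cochran form of the
#' variance (`r1 r2 c1 c2 / N^3`), under which the single-stratum statistic
#' reduces exactly to the Yates-corrected 2x2 chi-square. The classical
#' hypergeometric variance (`r1 r2 c1 c2 / (N^2 (N-1))`, as in
#' `stats::mantelhaen.test`) is available via `variance`. Strata with a
#' zero margin carry no information and are dropped (and reported).
#'
#' @param per_stratum list of confusion-count lists (`tp`, `fp`, `fn`, `tn`).
#' @param correct apply the 0.5 continuity correction (default `TRUE`).
#' @param variance `"cochran"` (default) or `"hypergeometric"`.
#' @return list with `chi2`, `p` (1 df), and `dropped` (indices of
#'   zero-margin strata).
#' @export
mh_chi_square <- function(per_stratum, correct = TRUE,
                          variance = c("cochran", "hypergeometric")) {
  variance <- match.arg(variance)
  if (length(per_stratum) < 1L) stop_data("need at least one stratum")
  num <- 0
  den <- 0
  dropped <- integer(0)
  for (i in seq_along(per_stratum)) {
    s <- per_stratum[[i]]
    r1 <- s$tp + s$fn   # pregnant
    r2 <- s$fp + s$tn   # open
    c1 <- s$tp + s$fp   # called true
    c2 <- s$fn + s$tn   # called false
    n <- r1 + r2
    if (min(r1, r2, c1, c2) == 0) {
      dropped <- c(dropped, i)
      next
    }
    num <- num + (s$tp - r1 * c1 / n)
    den <- den + if (variance == "cochran") {
      r1 * r2 * c1 * c2 / n^3
    } else {
      r1 * r2 * c1 * c2 / (n^2 * (n - 1))
    }
  }
  if (den == 0) {
    stop_data("undefined test: all strata are degenerate (zero margin)")
  }
  dev <- abs(num)
  if (correct) dev <- max(0, dev - 0.5)
  chi2 <- dev^2 / den
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       dropped = dropped)
}

#' ND (not-determined) rule for a metabolite pair
#'
#' A pair is reported as ND when its combined correct-call count falls
#' below the best correct-call count of its member metabolites taken
#' singly at the same endpoint and mode.
#'
#' @param pair_true_count correct calls (`tp + tn`) of the pair.
#' @param single_true_counts correct calls of each member alone.
#' @return logical: `TRUE` means not determined.
#' @export
nd_rule <- function(pair_true_count, single_true_counts) {
  pair_true_count < max(single_true_counts)
}

# Calls + solo confusion for one metabolite within one sample subset
solo_calls <- function(values, pregnant, trim = NULL) {
  rng <- pregnant_range(values, pregnant, trim = trim)
  boolean_calls(values, rng)
}

#' Score one CM-by-plasma metabolite pair
#'
#' The combined-biomarker procedure for a single pair: pregnant-range
#' Boolean calls per member, OR-combination, confusion against the outcome,
#' F1 and the Mantel-Haenszel chi-square p-value, plus the ND flag. All
#' quantities are computed on the samples with both members measured
#' (inner join on sample id).
#'
#' Two modes: `aggregate` derives one range per member over the pooled
#' cohort and tests a single stratum; `stratified_b_m` re-derives the
#' ranges, calls and confusion within each Day-6 embryonic stage (early
#' blastocyst / morula), pools the per-stratum confusions for F1 and the
#' correct-call count, and tests across the stage strata. Stage strata
#' that cannot support a range (fewer than 2 pregnant samples) are
#' dropped and reported.
#'
#' @param cm_values,plasma_values named concentration vectors for the two
#'   members (names = sample ids).
#' @param pregnant named logical outcome vector.
#' @param stage named Day-6 stage vector (required for stratified mode).
#' @param mode `"aggregate"` or `"stratified_b_m"`.
#' @param shared_range in stratified mode, derive one pooled range instead
#'   of per-stratum ranges.
#' @param trim percentile trim for [pregnant_range()].
#' @param correct continuity correction for [mh_chi_square()].
#' @return list of class `pair_f1`: pooled `confusion`, `per_stratum`
#'   confusions, `true_count` (tp + tn), `n_scored`, `f1`, `chi2`, `p`,
#'   `nd`, `single_true_counts`, `mode`, `dropped_strata`.
#' @export
score_pair <- function(cm_values, plasma_values, pregnant, stage = NULL,
                       mode = c("aggregate", "stratified_b_m"),
                       shared_range = FALSE, trim = NULL, correct = TRUE) {
  mode <- match.arg(mode)
  ids <- intersect(names(cm_values), names(plasma_values))
  ids <- ids[!is.na(cm_values[ids]) & !is.na(plasma_values[ids]) &
             !is.na(pregnant[ids])]
  if (length(ids) == 0L) stop_data("no samples shared by the two metabolites")
  cm <- cm_values[ids]
  pl <- plasma_values[ids]
  pr <- pregnant[ids]

  score_stratum <- function(cm_s, pl_s, pr_s, rng_cm = NULL, rng_pl = NULL) {
    if (is.null(rng_cm)) rng_cm <- pregnant_range(cm_s, pr_s, trim = trim)
    if (is.null(rng_pl)) rng_pl <- pregnant_range(pl_s, pr_s, trim = trim)
    calls_cm <- boolean_calls(cm_s, rng_cm)
    calls_pl <- boolean_calls(pl_s, rng_pl)
    list(pair = pair_confusion(combine_or(calls_cm, calls_pl), pr_s),
         cm = pair_confusion(calls_cm, pr_s),
         pl = pair_confusion(calls_pl, pr_s))
  }

  dropped_strata <- character(0)
  if (mode == "aggregate") {
    strata <- list(pooled = score_stratum(cm, pl, pr))
  } else {
    if (is.null(stage)) stop_data("stratified mode needs the Day-6 stage")
    st <- stage[ids]
    rng_cm <- rng_pl <- NULL
    if (shared_range) {
      rng_cm <- pregnant_range(cm, pr, trim = trim)
      rng_pl <- pregnant_range(pl, pr, trim = trim)
    }
    strata <- list()
    for (lev in unique(st)) {
      sel <- st == lev
      res <- tryCatch(
        score_stratum(cm[sel], pl[sel], pr[sel], rng_cm, rng_pl),
        bovipreg_data_error = function(e) NULL)
      if (is.null(res)) dropped_strata <- c(dropped_strata, lev)
      else strata[[lev]] <- res
    }
    if (length(strata) == 0L) {
      stop_data("no Day-6 stage stratum supports a pregnant range")
    }
  }

  per_stratum <- lapply(strata, `[[`, "pair")
  pooled <- sum_confusion(per_stratum)
  singles <- c(
    cm = with(sum_confusion(lapply(strata, `[[`, "cm")), tp + tn),
    plasma = with(sum_confusion(lapply(strata, `[[`, "pl")), tp + tn)
  )
  true_count <- pooled$tp + pooled$tn
  mh <- tryCatch(mh_chi_square(per_stratum, correct = correct),
                 bovipreg_data_error = function(e) list(chi2 = NA_real_,
                                                        p = NA_real_,
                                                        dropped = integer(0)))
  structure(list(
    confusion = pooled,
    per_stratum = per_stratum,
    true_count = true_count,
    n_scored = with(pooled, tp + fp + fn + tn),
    f1 = f1_score(pooled),
    chi2 = mh$chi2, p = mh$p,
    nd = nd_rule(true_count, singles),
    single_true_counts = singles,
    mode = mode, dropped_strata = dropped_strata
  ), class = "pair_f1")
}

#' Score all CM-by-plasma candidate pairs
#'
#' Cartesian product of candidate CM metabolites and candidate plasma
#' metabolites over the requested plasma days, each scored with
#' [score_pair()], ranked by F1 (descending) then p (ascending).
#'
#' @param cm_mm CM [metabolite_matrix()].
#' @param plasma_mms named list of plasma matrices, e.g.
#'   `list(d0 = ..., d7 = ...)`.
#' @param et_records cohort metadata.
#' @param endpoint `"d40"`, `"d62"` or `"birth"`.
#' @param cm_candidates character vector of CM metabolite names.
#' @param plasma_candidates character vector (applied to every day) or a
#'   named list per plasma day.
#' @param mode,trim,correct passed to [score_pair()].
#' @param breed optional breed filter: only recipients of these breeds are
#'   scored (ranges re-derived within the subset).
#' @return data.frame of scored pairs, sorted by `f1` descending then `p`
#'   ascending; ND pairs carry `NA` in `f1_report`/`p_report` but keep the
#'   underlying numbers for audit.
#' @export
score_all_pairs <- function(cm_mm, plasma_mms, et_records, endpoint,
                            cm_candidates, plasma_candidates,
                            mode = c("aggregate", "stratified_b_m"),
                            breed = NULL, trim = NULL, correct = TRUE) {
  mode <- match.arg(mode)
  rec <- et_records
  if (!is.null(breed)) rec <- rec[rec$breed %in% breed, , drop = FALSE]
  pregnant <- stats::setNames(endpoint_outcome(rec, endpoint), rec$et_id)
  stage <- stats::setNames(rec$day6_stage, rec$et_id)

  col_named <- function(mm, nm) {
    ids <- intersect(rownames(mm$values), rec$et_id)
    stats::setNames(mm$values[ids, nm], ids)
  }
  if (!is.list(plasma_candidates)) {
    plasma_candidates <- stats::setNames(
      rep(list(plasma_candidates), length(plasma_mms)), names(plasma_mms))
  }
  rows <- list()
  for (day in names(plasma_mms)) {
    pl_mm <- plasma_mms[[day]]
    pl_cands <- plasma_candidates[[day]]
    if (length(pl_cands) == 0L || length(cm_candidates) == 0L) next
    ids <- Reduce(intersect, list(rownames(cm_mm$values),
                                  rownames(pl_mm$values), rec$et_id))
    cmM <- cm_mm$values[ids, cm_candidates, drop = FALSE]
    plM <- pl_mm$values[ids, pl_cands, drop = FALSE]
    day_rows <- if (!anyNA(cmM) && !anyNA(plM)) {
      pair_scan(cmM, plM, pregnant[ids], stage[ids], mode = mode,
                trim = trim, correct = correct)
    } else {
      pair_scan_slow(cmM, plM, pregnant[ids], stage[ids], mode = mode,
                     trim = trim, correct = correct)
    }
    if (is.null(day_rows) || nrow(day_rows) == 0L) next
    day_rows$plasma_day <- day
    day_rows$endpoint <- endpoint
    rows[[day]] <- day_rows
  }
  if (length(rows) == 0L) {
    warning("no scorable candidate pairs", call. = FALSE)
    return(data.frame())
  }
  out <- do.call(rbind, unname(rows))
  out <- out[order(-out$f1, out$p), , drop = FALSE]
  rownames(out) <- NULL
  # ND rows withhold F1/p from the primary report; audit keeps the numbers
  out$f1_report <- ifelse(out$nd, NA_real_, round_half_up(out$f1, 3))
  out$p_report <- ifelse(out$nd, NA_real_, out$p)
  out$true_report <- format_counts(out$true_count, out$n_scored)
  out
}

# Vectorised all-pairs scan on complete data. Equivalent to looping
# score_pair over the Cartesian product (verified by a property test);
# confusion counts come from matrix cross-products of the complemented
# call matrices.
pair_scan <- function(cmM, plM, pregnant, stage, mode, trim = NULL,
                      correct = TRUE) {
  strata_idx <- if (mode == "aggregate") {
    list(pooled = seq_along(pregnant))
  } else {
    split(seq_along(pregnant), stage)
  }
  # a stratum must hold at least 2 pregnant samples to support a range
  strata_idx <- Filter(function(ix) sum(pregnant[ix]) >= 2L, strata_idx)
  if (length(strata_idx) == 0L) return(NULL)

  mc <- ncol(cmM)
  mp <- ncol(plM)
  tp <- fp <- fn <- tn <- matrix(0, mc, mp)
  num <- den <- matrix(0, mc, mp)
  cm_true <- numeric(mc)
  pl_true <- numeric(mp)
  n_scored <- 0L

  col_calls <- function(M, y) {
    pv <- M[y, , drop = FALSE]
    if (is.null(trim)) {
      lo <- apply(pv, 2, min)
      hi <- apply(pv, 2, max)
    } else {
      lo <- apply(pv, 2, stats::quantile, probs = trim, type = 7)
      hi <- apply(pv, 2, stats::quantile, probs = 1 - trim, type = 7)
    }
    sweep(M, 2, lo, ">=") & sweep(M, 2, hi, "<=")
  }

  for (ix in strata_idx) {
    y <- pregnant[ix]
    n1 <- sum(y)
    n0 <- sum(!y)
    n_scored <- n_scored + length(ix)
    C <- col_calls(cmM[ix, , drop = FALSE], y)
    P <- col_calls(plM[ix, , drop = FALSE], y)
    A <- 1 - C    # complement: !called
    B <- 1 - P
    fn_s <- crossprod(A[y, , drop = FALSE], B[y, , drop = FALSE])
    tn_s <- if (n0 > 0) crossprod(A[!y, , drop = FALSE], B[!y, , drop = FALSE])
            else matrix(0, mc, mp)
    tp_s <- n1 - fn_s
    fp_s <- n0 - tn_s
    tp <- tp + tp_s; fp <- fp + fp_s; fn <- fn + fn_s; tn <- tn + tn_s
    cm_true <- cm_true + colSums(C[y, , drop = FALSE]) +
      (if (n0 > 0) colSums(1 - C[!y, , drop = FALSE]) else 0)
    pl_true <- pl_true + colSums(P[y, , drop = FALSE]) +
      (if (n0 > 0) colSums(1 - P[!y, , drop = FALSE]) else 0)
    # Mantel-Haenszel components; zero-margin strata contribute nothing
    nS <- n1 + n0
    c1 <- tp_s + fp_s
    c2 <- fn_s + tn_s
    ok <- (n1 > 0) & (n0 > 0) & (c1 > 0) & (c2 > 0)
    num <- num + ifelse(ok, tp_s - n1 * c1 / nS, 0)
    den <- den + ifelse(ok, n1 * n0 * c1 * c2 / nS^3, 0)
  }

  dev <- abs(num)
  if (correct) dev <- pmax(0, dev - 0.5)
  chi2 <- ifelse(den > 0, dev^2 / den, NA_real_)
  pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), NA_real_)
  true_count <- tp + tn
  nd <- true_count < outer(cm_true, pl_true, pmax)

  grid <- expand.grid(ci = seq_len(mc), pi = seq_len(mp))
  data.frame(
    cm_metabolite = colnames(cmM)[grid$ci],
    plasma_metabolite = colnames(plM)[grid$pi],
    mode = mode,
    tp = tp[cbind(grid$ci, grid$pi)], fp = fp[cbind(grid$ci, grid$pi)],
    fn = fn[cbind(grid$ci, grid$pi)], tn = tn[cbind(grid$ci, grid$pi)],
    true_count = true_count[cbind(grid$ci, grid$pi)],
    n_scored = n_scored,
    f1 = f1[cbind(grid$ci, grid$pi)],
    chi2 = chi2[cbind(grid$ci, grid$pi)],
    p = pval[cbind(grid$ci, grid$pi)],
    nd = nd[cbind(grid$ci, grid$pi)],
    stringsAsFactors = FALSE
  )
}

# Per-pair fallback (handles missing values by pairwise exclusion)
pair_scan_slow <- function(cmM, plM, pregnant, stage, mode, trim = NULL,
                           correct = TRUE) {
  pregnant <- stats::setNames(pregnant, rownames(cmM))
  stage <- stats::setNames(stage, rownames(cmM))
  rows <- list()
  for (cm_nm in colnames(cmM)) {
    cm_v <- stats::setNames(cmM[, cm_nm], rownames(cmM))
    for (pl_nm in colnames(plM)) {
      pl_v <- stats::setNames(plM[, pl_nm], rownames(plM))
      res <- tryCatch(
        score_pair(cm_v, pl_v, pregnant, stage = stage, mode = mode,
                   trim = trim, correct = correct),
        bovipreg_data_error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cm_metabolite = cm_nm, plasma_metabolite = pl_nm, mode = mode,
        tp = res$confusion$tp, fp = res$confusion$fp,
        fn = res$confusion$fn, tn = res$confusion$tn,
        true_count = res$true_count, n_scored = res$n_scored,
        f1 = res$f1, chi2 = res$chi2, p = res$p, nd = res$nd,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}
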