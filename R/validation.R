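#' Below-detection-limit exclusion filter
#'
#' Flags metabolites whose measurements sit too close to the detection
#' limit to be trusted in a targeted assay: a metabolite is excluded when
#' more than `lod_fraction` of its non-missing values fall below `lod`.
#'
#' @param values concentrations.
#' @param lod declared limit of detection (same units as `values`).
#' @param lod_fraction exclusion threshold on the below-LOD fraction.
#' @return logical: `TRUE` means exclude.
#' @export
below_lod <- function(values, lod, lod_fraction = 0.5) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) return(TRUE)
  mean(v < lod) > lod_fraction
}

#' Validate selected metabolite pairs in an independent cohort
#'
#' Re-applies discovery-selected CM-by-plasma pairs to an independent
#' (targeted, typically absolute-quantification) cohort and produces a
#' validation report with both the stage-stratified and the aggregate mode,
#' each with its own ND flag.
#'
#' Two range policies: `refit_in_validation` (default) re-derives the
#' pregnant ranges within the validation cohort, which is invariant to the
#' unit change between semi-quantitative discovery data and absolute
#' validation data; `frozen_from_discovery` carries numeric discovery
#' ranges over and therefore refuses to run across incompatible units.
#'
#' @param selected_pairs data.frame with columns `cm_metabolite`,
#'   `plasma_metabolite`, `plasma_day` (from [score_all_pairs()] or
#'   hand-picked).
#' @param validation_cohort an `et_cohort` (e.g. from
#'   [generate_validation_cohort()] or [read_cohort()]).
#' @param endpoint pregnancy endpoint to validate at (default `"birth"`).
#' @param range_policy `"refit_in_validation"` or `"frozen_from_discovery"`.
#' @param discovery_ranges for the frozen policy: named list
#'   `ranges[[compartment]][[metabolite]] = c(low, high)`.
#' @param discovery_units units of the discovery data (checked against the
#'   validation matrices under the frozen policy).
#' @param lod optional detection limit applied to CM metabolites (with
#'   `lod_fraction`) before scoring; excluded members yield flagged rows.
#' @param lod_fraction see [below_lod()].
#' @param trim,correct passed to [score_pair()].
#' @return data.frame of class `validation_report`: one row per pair and
#'   mode with `true_report` ("k/n"), `f1`, `p`, `nd` (ND rows carry `NA`
#'   f1/p in the report columns) and a `status` column (`scored`,
#'   `not_measured`, `below_lod`).
#' @export
validate_pairs <- function(selected_pairs, validation_cohort,
                           endpoint = "birth",
                           range_policy = c("refit_in_validation",
                                            "frozen_from_discovery"),
                           discovery_ranges = NULL, discovery_units = NULL,
                           lod = NULL, lod_fraction = 0.5,
                           trim = NULL, correct = TRUE) {
  range_policy <- match.arg(range_policy)
  coh <- validation_cohort
  stopifnot(inherits(coh, "et_cohort"))
  rec <- coh$et_records
  pregnant <- stats::setNames(endpoint_outcome(rec, endpoint), rec$et_id)
  stage <- stats::setNames(rec$day6_stage, rec$et_id)

  if (range_policy == "frozen_from_discovery") {
    if (is.null(discovery_ranges)) {
      stop_config("frozen_from_discovery requires discovery_ranges")
    }
    units <- unique(c(coh$cm$units, coh$plasma_d0$units, coh$plasma_d7$units))
    if (!is.null(discovery_units) && !all(units == discovery_units)) {
      stop_data(paste("unit mismatch: frozen discovery ranges (%s) cannot be",
                      "applied to a %s-unit validation cohort"),
                discovery_units, paste(units, collapse = "/"))
    }
  }

  pick_plasma <- function(day) {
    switch(day, d0 = coh$plasma_d0, d7 = coh$plasma_d7,
           stop_config("unknown plasma day %s", day))
  }
  named_col <- function(mm, nm) {
    stats::setNames(mm$values[, nm], rownames(mm$values))
  }

  rows <- list()
  for (i in seq_len(nrow(selected_pairs))) {
    cm_nm <- selected_pairs$cm_metabolite[i]
    pl_nm <- selected_pairs$plasma_metabolite[i]
    day <- selected_pairs$plasma_day[i]
    pl_mm <- pick_plasma(day)
    status <- "scored"
    if (!cm_nm %in% colnames(coh$cm$values) ||
        !pl_nm %in% colnames(pl_mm$values)) {
      status <- "not_measured"
    } else if (!is.null(lod) && below_lod(coh$cm$values[, cm_nm], lod,
                                          lod_fraction)) {
      status <- "below_lod"
    }
    for (mode in c("stratified_b_m", "aggregate")) {
      if (status != "scored") {
        rows[[length(rows) + 1L]] <- data.frame(
          cm_metabolite = cm_nm, plasma_metabolite = pl_nm, plasma_day = day,
          mode = mode, status = status, true_report = NA_character_,
          f1 = NA_real_, p = NA_real_, nd = NA, stringsAsFactors = FALSE)
        next
      }
      cm_v <- named_col(coh$cm, cm_nm)
      pl_v <- named_col(pl_mm, pl_nm)
      res <- if (range_policy == "refit_in_validation") {
        score_pair(cm_v, pl_v, pregnant, stage = stage, mode = mode,
                   trim = trim, correct = correct)
      } else {
        score_pair_frozen(cm_v, pl_v, pregnant, stage = stage, mode = mode,
                          rng_cm = discovery_ranges[["CM"]][[cm_nm]],
                          rng_pl = discovery_ranges[[paste0("plasma_", day)]][[pl_nm]],
                          correct = correct)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cm_metabolite = cm_nm, plasma_metabolite = pl_nm, plasma_day = day,
        mode = mode, status = status,
        true_report = format_counts(res$true_count, res$n_scored),
        f1 = if (res$nd) NA_real_ else round_half_up(res$f1, 3),
        p = if (res$nd) NA_real_ else res$p,
        nd = res$nd, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "cohort") <- list(n = nrow(rec),
                              breed = unique(rec$breed),
                              endpoint = endpoint,
                              range_policy = range_policy)
  class(out) <- c("validation_report", class(out))
  out
}

# Frozen-range variant of score_pair: ranges fixed from discovery, calls
# and confusion computed in the validation cohort.
score_pair_frozen <- function(cm_values, plasma_values, pregnant, stage,
                              mode, rng_cm, rng_pl, correct = TRUE) {
  if (is.null(rng_cm) || is.null(rng_pl)) {
    stop_config("frozen ranges missing for one of the pair members")
  }
  ids <- intersect(names(cm_values), names(plasma_values))
  ids <- ids[!is.na(cm_values[ids]) & !is.na(plasma_values[ids]) &
             !is.na(pregnant[ids])]
  if (length(ids) == 0L) stop_data("no samples shared by the two metabolites")
  calls <- combine_or(boolean_calls(cm_values[ids], rng_cm),
                      boolean_calls(plasma_values[ids], rng_pl))
  calls_cm <- boolean_calls(cm_values[ids], rng_cm)
  calls_pl <- boolean_calls(plasma_values[ids], rng_pl)
  pr <- pregnant[ids]
  per_stratum <- if (mode == "aggregate") {
    list(pooled = pair_confusion(calls, pr))
  } else {
    st <- stage[ids]
    lapply(split(seq_along(ids), st), function(sel) {
      pair_confusion(calls[sel], pr[sel])
    })
  }
  pooled <- sum_confusion(per_stratum)
  singles <- c(cm = with(pair_confusion(calls_cm, pr), tp + tn),
               plasma = with(pair_confusion(calls_pl, pr), tp + tn))
  mh <- tryCatch(mh_chi_square(per_stratum, correct = correct),
                 bovipreg_data_error = function(e) list(chi2 = NA_real_,
                                                        p = NA_real_))
  true_count <- pooled$tp + pooled$tn
  structure(list(confusion = pooled, per_stratum = per_stratum,
                 true_count = true_count,
                 n_scored = with(pooled, tp + fp + fn + tn),
                 f1 = f1_score(pooled), chi2 = mh$chi2, p = mh$p,
                 nd = nd_rule(true_count, singles),
                 single_true_counts = singles, mode = mode,
                 dropped_strata = character(0)),
            class = "pair_f1")
}
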