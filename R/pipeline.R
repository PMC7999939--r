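#' End-to-end discovery run
#'
#' Orchestrates the discovery pipeline on one cohort, mirroring the study's
#' breed-block strategy: culture-medium metabolites are analysed as one
#' aggregate cohort, plasma metabolites separately within the AV and
#' Holstein breed blocks, and crossbred recipients are excluded from the
#' plasma analyses (with the exclusion count logged). For every endpoint it
#' produces the univariate candidate table, the single-biomarker ROC table
#' for candidates, and the ranked CM-by-plasma pair table.
#'
#' @param cohort an `et_cohort` (or a [cohort_config()], which is generated
#'   first).
#' @param endpoints subset of `c("d40", "d62", "birth")`.
#' @param alpha candidate-calling level.
#' @param adjust multiplicity method for the screen.
#' @param auc_threshold single-biomarker AUC selection threshold.
#' @param member_rule how pair members qualify: `"either"` (screen
#'   candidate or ROC-selected, default), `"screen"`, `"roc"`.
#' @param pair_modes modes to score pairs under; stratified scoring is run
#'   only within the Holstein block (the larger block), as stage strata in
#'   smaller blocks are too thin.
#' @param n_boot bootstrap resamples per ROC interval.
#' @param outdir optional directory: tab-separated tables and a JSON audit
#'   are written when given.
#' @param seed seed for the bootstrap intervals.
#' @return list of class `discovery_bundle`: `candidates`, `roc`, `pairs`
#'   (data.frames), `log`, `config_hash`, `endpoints`, and the selection
#'   settings.
#' @export
run_discovery <- function(cohort, endpoints = c("d40", "d62", "birth"),
                          alpha = 0.05, adjust = "bonferroni",
                          auc_threshold = 0.650,
                          member_rule = c("either", "screen", "roc"),
                          pair_modes = c("aggregate", "stratified_b_m"),
                          n_boot = 200L, outdir = NULL, seed = 1L) {
  member_rule <- match.arg(member_rule)
  if (inherits(cohort, "cohort_config")) cohort <- generate_cohort(cohort)
  stopifnot(inherits(cohort, "et_cohort"))
  if (length(endpoints) == 0L) stop_config("endpoint set must be non-empty")
  rec <- cohort$et_records
  log <- cohort$log
  n_cross <- sum(rec$breed == "cross")
  log <- c(log, sprintf("excluded %d crossbred recipients from plasma analyses",
                        n_cross))

  subset_mm <- function(mm, ids) {
    mm2 <- mm
    mm2$values <- mm$values[rownames(mm$values) %in% ids, , drop = FALSE]
    mm2
  }
  plasma_breeds <- intersect(c("AV", "Holstein"), unique(rec$breed))

  candidates <- list()
  roc <- list()
  pairs <- list()

  for (ep in endpoints) {
    blocks <- list(list(label = "CM_aggregate", mm = cohort$cm, breed = NA))
    for (br in plasma_breeds) {
      ids <- rec$et_id[rec$breed == br]
      blocks <- c(blocks,
                  list(list(label = paste0("plasma_d0_", br),
                            mm = subset_mm(cohort$plasma_d0, ids), breed = br),
                       list(label = paste0("plasma_d7_", br),
                            mm = subset_mm(cohort$plasma_d7, ids), breed = br)))
    }
    members <- list()
    for (blk in blocks) {
      scr <- tryCatch(
        screen_matrix(blk$mm, rec, ep, alpha = alpha, adjust = adjust),
        bovipreg_data_error = function(e) NULL)
      if (is.null(scr)) next
      scr$block <- blk$label
      scr$breed <- blk$breed
      candidates[[paste(ep, blk$label)]] <- scr
      pre <- scr$metabolite[!is.na(scr$p_value) & scr$p_value < alpha]
      if (length(pre) > 0L) {
        rt <- roc_table(blk$mm, rec, ep, metabolites = pre,
                        auc_threshold = auc_threshold, n_boot = n_boot,
                        seed = seed)
        rt$block <- blk$label
        rt$breed <- blk$breed
        roc[[paste(ep, blk$label)]] <- rt
        sel_roc <- rt$metabolite[rt$selected]
      } else {
        sel_roc <- character(0)
      }
      sel_screen <- scr$metabolite[scr$candidate_flag]
      members[[blk$label]] <- switch(member_rule,
        screen = sel_screen,
        roc = sel_roc,
        either = union(sel_screen, sel_roc))
    }
    cm_members <- members[["CM_aggregate"]] %||% character(0)
    for (br in plasma_breeds) {
      pl_cands <- list(
        d0 = members[[paste0("plasma_d0_", br)]] %||% character(0),
        d7 = members[[paste0("plasma_d7_", br)]] %||% character(0))
      if (length(cm_members) == 0L ||
          (length(pl_cands$d0) + length(pl_cands$d7)) == 0L) next
      modes <- pair_modes
      if (br != "Holstein") modes <- setdiff(modes, "stratified_b_m")
      for (mode in modes) {
        pt <- score_all_pairs(cohort$cm,
                              list(d0 = cohort$plasma_d0,
                                   d7 = cohort$plasma_d7),
                              rec, ep, cm_members, pl_cands,
                              mode = mode, breed = br)
        if (nrow(pt) == 0L) next
        pt$breed <- br
        pairs[[paste(ep, br, mode)]] <- pt
      }
    }
  }

  bind <- function(lst) if (length(lst)) do.call(rbind, unname(lst)) else data.frame()
  bundle <- structure(list(
    candidates = bind(candidates), roc = bind(roc), pairs = bind(pairs),
    log = log, config_hash = cohort$config_hash, endpoints = endpoints,
    alpha = alpha, auc_threshold = auc_threshold, member_rule = member_rule
  ), class = "discovery_bundle")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  wr(bundle$candidates, "candidates.tsv")
  wr(bundle$roc, "biomarkers.tsv")
  wr(bundle$pairs, "pairs.tsv")
  jsonlite::write_json(
    list(config_hash = bundle$config_hash, endpoints = bundle$endpoints,
         alpha = bundle$alpha, auc_threshold = bundle$auc_threshold,
         member_rule = bundle$member_rule, log = bundle$log),
    file.path(outdir, "audit.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' Validation run over a discovery bundle
#'
#' Scores the discovery-selected pairs (Day-0 plasma preferred, matching
#' the interest in selecting recipients a week before transfer) in an
#' independent validation cohort and writes a validation report linked to
#' the discovery run by its configuration hash.
#'
#' @param bundle a `discovery_bundle` from [run_discovery()], or a
#'   data.frame of pairs (`cm_metabolite`, `plasma_metabolite`,
#'   `plasma_day`).
#' @param validation_cohort an `et_cohort`.
#' @param endpoint endpoint to validate at.
#' @param top_n number of top discovery pairs taken forward (by rank).
#' @param plasma_day restrict carried-forward pairs to one plasma day
#'   (default `"d0"`); `NULL` keeps both.
#' @param outdir optional output directory.
#' @param ... passed to [validate_pairs()].
#' @return a `validation_report` (see [validate_pairs()]) with the
#'   discovery `config_hash` attached as an attribute.
#' @export
run_validation <- function(bundle, validation_cohort, endpoint = "birth",
                           top_n = 6L, plasma_day = "d0", outdir = NULL, ...) {
  if (inherits(bundle, "discovery_bundle")) {
    pairs <- bundle$pairs
    hash <- bundle$config_hash
  } else {
    pairs <- bundle
    hash <- NA_character_
  }
  if (is.null(pairs) || nrow(pairs) == 0L) {
    warning("empty selected-pair list: empty validation report", call. = FALSE)
    out <- data.frame()
    class(out) <- c("validation_report", class(out))
    return(out)
  }
  if (!is.null(plasma_day)) {
    pairs <- pairs[pairs$plasma_day %in% plasma_day, , drop = FALSE]
  }
  key <- paste(pairs$cm_metabolite, pairs$plasma_metabolite, pairs$plasma_day)
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  pairs <- utils::head(pairs, top_n)
  report <- validate_pairs(pairs, validation_cohort, endpoint = endpoint, ...)
  attr(report, "discovery_hash") <- hash
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report, file.path(outdir, "validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    jsonlite::write_json(c(attr(report, "cohort"),
                           list(discovery_hash = hash)),
                         file.path(outdir, "validation_audit.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' Null / planted-signal benchmark of the discovery procedure
#'
#' Characterises the pipeline by simulation. The `null` scenario measures
#' the univariate screen's per-metabolite type-I error, the family-wise
#' error after correction, and the selection inflation of the pair scan
#' (distribution of the maximum F1 and the frequency of a best-pair
#' p < 0.05 over many scored pairs). The `planted` scenario measures
#' recovery: how often the planted CM-by-plasma pair ranks first and how
#' often each planted member passes the single-biomarker rule.
#'
#' @param config a [cohort_config()]; the planted scenario requires its
#'   `effect_table` to contain the planted pair.
#' @param n_reps number of simulation replicates (a warning is logged
#'   below 50).
#' @param scenario `"null"` or `"planted"`.
#' @param endpoint endpoint analysed.
#' @param planted_pair for `"planted"`: list with `cm`, `plasma`,
#'   `plasma_day` naming the planted members.
#' @param pair_panel for `"null"`: list with `cm` and `plasma` metabolite
#'   names over which the pair scan runs (all-by-all, no candidate
#'   filtering — the point is the selection effect itself).
#' @param alpha screening level.
#' @param seed root seed; each replicate derives its own substream.
#' @return list with `per_rep` (one row per replicate) and `summary`.
#' @export
run_benchmark <- function(config, n_reps = 100L,
                          scenario = c("null", "planted"),
                          endpoint = "birth", planted_pair = NULL,
                          pair_panel = NULL, alpha = 0.05, seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_reps < 50L) warning("fewer than 50 replicates", call. = FALSE)
  per_rep <- vector("list", n_reps)

  for (rep in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- substream_seed(seed, "benchmark", scenario, rep)
    coh <- generate_cohort(cfg)
    rec <- coh$et_records
    if (scenario == "null") {
      scr_cm <- screen_matrix(coh$cm, rec, endpoint, alpha = alpha,
                              covariates = FALSE, outlier_threshold = NULL)
      scr_pl <- screen_matrix(coh$plasma_d0, rec, endpoint, alpha = alpha,
                              covariates = FALSE, outlier_threshold = NULL)
      p_all <- c(scr_cm$p_value, scr_pl$p_value)
      panel <- pair_panel %||% list(cm = colnames(coh$cm$values),
                                    plasma = colnames(coh$plasma_d0$values))
      pt <- score_all_pairs(coh$cm, list(d0 = coh$plasma_d0), rec, endpoint,
                            panel$cm, panel$plasma, mode = "aggregate")
      per_rep[[rep]] <- data.frame(
        rep = rep,
        reject_rate = mean(p_all < alpha, na.rm = TRUE),
        n_tests = sum(!is.na(p_all)),
        fwer_cm = any(scr_cm$candidate_flag),
        fwer_plasma = any(scr_pl$candidate_flag),
        max_f1 = max(pt$f1, na.rm = TRUE),
        best_p = pt$p[1],
        best_p_sig = !is.na(pt$p[1]) && pt$p[1] < 0.05)
    } else {
      if (is.null(planted_pair)) {
        stop_config("planted scenario requires planted_pair")
      }
      scr_cm <- screen_matrix(coh$cm, rec, endpoint, alpha = alpha,
                              covariates = FALSE, outlier_threshold = NULL)
      pl_mm <- if (planted_pair$plasma_day == "d0") coh$plasma_d0 else coh$plasma_d7
      scr_pl <- screen_matrix(pl_mm, rec, endpoint, alpha = alpha,
                              covariates = FALSE, outlier_threshold = NULL)
      cm_cand <- scr_cm$metabolite[scr_cm$candidate_flag]
      pl_cand <- scr_pl$metabolite[scr_pl$candidate_flag]
      member_ok <- function(mm, nm) {
        if (!nm %in% colnames(mm$values)) return(FALSE)
        y <- endpoint_outcome(rec[match(rownames(mm$values), rec$et_id), ],
                              endpoint)
        r <- roc_biomarker(mm$values[, nm], y, n_boot = 100L, seed = cfg$seed)
        isTRUE(r$selected)
      }
      top_hit <- FALSE
      if (planted_pair$cm %in% cm_cand && planted_pair$plasma %in% pl_cand) {
        pt <- score_all_pairs(coh$cm,
                              stats::setNames(list(pl_mm),
                                              planted_pair$plasma_day),
                              rec, endpoint, cm_cand, pl_cand,
                              mode = "aggregate")
        top_hit <- nrow(pt) > 0 &&
          pt$cm_metabolite[1] == planted_pair$cm &&
          pt$plasma_metabolite[1] == planted_pair$plasma
      }
      per_rep[[rep]] <- data.frame(
        rep = rep, top_hit = top_hit,
        cm_selected = member_ok(coh$cm, planted_pair$cm),
        plasma_selected = member_ok(pl_mm, planted_pair$plasma))
    }
  }
  per_rep <- do.call(rbind, per_rep)
  summary <- if (scenario == "null") {
    data.frame(
      mean_reject_rate = mean(per_rep$reject_rate),
      fwer_cm = mean(per_rep$fwer_cm),
      fwer_plasma = mean(per_rep$fwer_plasma),
      mean_max_f1 = mean(per_rep$max_f1),
      best_p_sig_rate = mean(per_rep$best_p_sig))
  } else {
    data.frame(
      top_hit_rate = mean(per_rep$top_hit),
      cm_selected_rate = mean(per_rep$cm_selected),
      plasma_selected_rate = mean(per_rep$plasma_selected))
  }
  list(per_rep = per_rep, summary = summary, scenario = scenario,
       n_reps = n_reps, seed = seed)
}
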