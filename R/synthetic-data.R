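#' Configuration for a synthetic embryo-transfer cohort
#'
#' Defines the structure and statistical assumptions of a simulated
#' embryo-transfer (ET) study: one spent culture-medium (CM) sample per
#' embryo and two recipient plasma samples (Day-0, Day-7), with nested binary
#' pregnancy outcomes at gestational Day-40, Day-62 and birth. Defaults mirror
#' a 36-ET discovery cohort with 37 CM and 71 plasma metabolites, a recipient
#' breed block of 13 Asturiana de los Valles (AV), 17 Holstein and 6
#' crossbred animals, and one uncollected Day-0 plasma sample.
#'
#' Concentrations are lognormal, parameterised on the log2 scale: a
#' metabolite's log2-concentration is its baseline plus group shifts plus
#' Gaussian noise with standard deviation `noise_sdlog` (log2 units). Group
#' effects in `effect_table` are log2 fold changes (open/pregnant), so a
#' positive value means higher concentrations in recipients that did not
#' reach the endpoint. Outcomes follow a Markov chain over endpoints
#' (Day-40 -> Day-62 -> birth), which enforces the nesting invariant
#' birth => Day-62 => Day-40 by construction.
#'
#' @param n_et number of embryo transfers (samples).
#' @param breed_counts named integer vector of recipients per breed; must sum
#'   to `n_et`. Names are a subset of `AV`, `Holstein`, `cross`.
#' @param n_cm_metabolites,n_plasma_metabolites panel sizes for the CM and
#'   plasma matrices.
#' @param stage_probs named probabilities for the Day-6 embryonic stage,
#'   `c(morula = , early_blastocyst = )`; must sum to 1.
#' @param endpoint_rates named probabilities `d40` (pregnancy at Day-40),
#'   `d62_given_d40` and `birth_given_d62` (conditional continuation).
#' @param fixed_outcome_counts `NULL` (outcomes drawn from
#'   `endpoint_rates`) or named counts `c(d40 = , d62 = , birth = )` fixing
#'   the exact number of pregnancies at each endpoint (non-increasing,
#'   nested by construction); use to reproduce a study's printed group
#'   sizes exactly.
#' @param effect_table `NULL` (global null) or a data.frame with columns
#'   `metabolite`, `compartment` (`CM`, `plasma_d0`, `plasma_d7`),
#'   `endpoint` (`d40`, `d62`, `birth`), `log2fc` (open/pregnant), and
#'   optionally `breeds` (comma-separated breed restriction, `NA` = all).
#' @param noise_sdlog per-metabolite noise standard deviation on the log2
#'   scale (recycled across metabolites).
#' @param baseline_log2_range range the per-metabolite baseline
#'   log2-concentration is drawn from (uniform), spanning the magnitudes seen
#'   in internal-standard response-ratio data.
#' @param breed_effect_d0 optional log2 shift added to AV recipients in the
#'   Day-0 plasma matrix only, emulating the near-significant breed
#'   separation seen in Day-0 plasma but not in CM or Day-7 plasma.
#' @param missing_day0 number of Day-0 plasma samples to drop (uncollected).
#' @param units concentration units flag, `is_ratio` (semi-quantitative
#'   internal-standard response ratios) or `absolute`.
#' @param seed root integer seed; all randomness is drawn from named
#'   substreams derived from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_et = 36L,
                          breed_counts = c(AV = 13L, Holstein = 17L, cross = 6L),
                          n_cm_metabolites = 37L,
                          n_plasma_metabolites = 71L,
                          stage_probs = c(morula = 0.5, early_blastocyst = 0.5),
                          endpoint_rates = c(d40 = 0.65, d62_given_d40 = 0.9,
                                             birth_given_d62 = 0.9),
                          fixed_outcome_counts = NULL,
                          effect_table = NULL,
                          noise_sdlog = 1.0,
                          baseline_log2_range = c(6, 14),
                          breed_effect_d0 = 0,
                          missing_day0 = 1L,
                          units = c("is_ratio", "absolute"),
                          seed = 1L) {
  units <- match.arg(units)
  if (length(n_et) != 1L || is.na(n_et) || n_et < 1) {
    stop_config("n_et must be a positive count, got %s", format(n_et))
  }
  if (any(breed_counts < 0) || sum(breed_counts) != n_et) {
    stop_config("breed_counts must be nonnegative and sum to n_et (%d), got %d",
                n_et, sum(breed_counts))
  }
  if (!all(names(breed_counts) %in% c("AV", "Holstein", "cross"))) {
    stop_config("breed_counts names must be among AV, Holstein, cross")
  }
  for (nm in c("n_cm_metabolites", "n_plasma_metabolites")) {
    v <- get(nm)
    if (v < 1) stop_config("%s must be a positive count, got %s", nm, format(v))
  }
  if (any(stage_probs < 0 | stage_probs > 1) ||
      abs(sum(stage_probs) - 1) > 1e-8) {
    stop_config("stage_probs must be probabilities summing to 1")
  }
  if (!all(c("morula", "early_blastocyst") %in% names(stage_probs))) {
    stop_config("stage_probs must name morula and early_blastocyst")
  }
  if (any(endpoint_rates < 0 | endpoint_rates > 1)) {
    stop_config("endpoint_rates must lie in [0, 1]")
  }
  if (!all(c("d40", "d62_given_d40", "birth_given_d62") %in% names(endpoint_rates))) {
    stop_config("endpoint_rates must name d40, d62_given_d40, birth_given_d62")
  }
  if (!is.null(fixed_outcome_counts)) {
    if (!all(c("d40", "d62", "birth") %in% names(fixed_outcome_counts))) {
      stop_config("fixed_outcome_counts must name d40, d62, birth")
    }
    k <- fixed_outcome_counts[c("d40", "d62", "birth")]
    if (any(k < 0) || any(k > n_et) || k[["d40"]] < k[["d62"]] ||
        k[["d62"]] < k[["birth"]]) {
      stop_config("fixed_outcome_counts must be nested: n_et >= d40 >= d62 >= birth >= 0")
    }
  }
  if (missing_day0 < 0 || missing_day0 >= n_et) {
    stop_config("missing_day0 must be in [0, n_et), got %s", format(missing_day0))
  }
  if (!is.null(effect_table)) {
    effect_table <- as.data.frame(effect_table)
    need <- c("metabolite", "compartment", "endpoint", "log2fc")
    if (!all(need %in% names(effect_table))) {
      stop_config("effect_table must have columns %s", paste(need, collapse = ", "))
    }
    if (!all(effect_table$compartment %in% c("CM", "plasma_d0", "plasma_d7"))) {
      stop_config("effect_table compartment must be CM, plasma_d0 or plasma_d7")
    }
    if (!all(effect_table$endpoint %in% c("d40", "d62", "birth"))) {
      stop_config("effect_table endpoint must be d40, d62 or birth")
    }
    if (is.null(effect_table$breeds)) effect_table$breeds <- NA_character_
  }
  structure(list(
    n_et = as.integer(n_et),
    breed_counts = breed_counts,
    n_cm_metabolites = as.integer(n_cm_metabolites),
    n_plasma_metabolites = as.integer(n_plasma_metabolites),
    stage_probs = stage_probs,
    endpoint_rates = endpoint_rates,
    fixed_outcome_counts = fixed_outcome_counts,
    effect_table = effect_table,
    noise_sdlog = noise_sdlog,
    baseline_log2_range = baseline_log2_range,
    breed_effect_d0 = breed_effect_d0,
    missing_day0 = as.integer(missing_day0),
    units = units,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' A samples-by-metabolites concentration matrix for one compartment
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   metabolites in columns (colnames = metabolite names); nonnegative,
#'   `NA` allowed.
#' @param compartment one of `CM`, `plasma_d0`, `plasma_d7`.
#' @param units `is_ratio` or `absolute`.
#' @return an object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(values,
                              compartment = c("CM", "plasma_d0", "plasma_d7"),
                              units = c("is_ratio", "absolute")) {
  compartment <- match.arg(compartment)
  units <- match.arg(units)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop_data("sample ids (rownames) must be present and unique")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop_data("metabolite names (colnames) must be present and unique")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_data("concentrations must be nonnegative")
  }
  structure(list(values = values, compartment = compartment, units = units),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("<metabolite_matrix> %s: %d samples x %d metabolites (%s units), %d missing\n",
              x$compartment, nrow(x$values), ncol(x$values), x$units,
              sum(is.na(x$values))))
  invisible(x)
}

# One metabolite column: per-metabolite named substream provides the
# baseline draw and the noise, so panels can grow without perturbing
# existing columns or other matrices.
generate_column <- function(cfg, prefix, compartment, name, shift_log2) {
  with_substream(cfg$seed, prefix, compartment, name, expr = {
    mu <- stats::runif(1, cfg$baseline_log2_range[1], cfg$baseline_log2_range[2])
    z <- stats::rnorm(length(shift_log2))
    2^(mu + shift_log2 + cfg$noise_sdlog * z)
  })
}

# log2 shift per sample for one metabolite in one compartment: sum of
# matching effect rows, applied to samples that are OPEN at the row's
# endpoint (log2fc is open/pregnant), optionally restricted by breed.
effect_shift <- function(cfg, compartment, name, records) {
  shift <- numeric(nrow(records))
  et <- cfg$effect_table
  if (is.null(et)) return(shift)
  rows <- et[et$metabolite == name & et$compartment == compartment, , drop = FALSE]
  if (nrow(rows) == 0L) return(shift)
  open_at <- function(ep) switch(ep,
    d40 = !records$pregnant_d40,
    d62 = !records$pregnant_d62,
    birth = !records$birth)
  for (i in seq_len(nrow(rows))) {
    idx <- open_at(rows$endpoint[i])
    if (!is.na(rows$breeds[i])) {
      allowed <- trimws(strsplit(rows$breeds[i], ",")[[1]])
      idx <- idx & records$breed %in% allowed
    }
    shift[idx] <- shift[idx] + rows$log2fc[i]
  }
  shift
}

generate_records <- function(cfg, prefix) {
  with_substream(cfg$seed, prefix, "meta", expr = {
    n <- cfg$n_et
    breed <- sample(rep(names(cfg$breed_counts), cfg$breed_counts))
    bull_breed <- sample(c("AV", "Holstein"), n, replace = TRUE)
    day6_stage <- sample(names(cfg$stage_probs), n, replace = TRUE,
                         prob = cfg$stage_probs)
    if (is.null(cfg$fixed_outcome_counts)) {
      r <- cfg$endpoint_rates
      pregnant_d40 <- stats::runif(n) < r[["d40"]]
      pregnant_d62 <- pregnant_d40 & (stats::runif(n) < r[["d62_given_d40"]])
      birth <- pregnant_d62 & (stats::runif(n) < r[["birth_given_d62"]])
    } else {
      # nested by assigning the deepest endpoint first within a random order
      k <- cfg$fixed_outcome_counts
      ord <- sample.int(n)
      birth <- pregnant_d62 <- pregnant_d40 <- logical(n)
      birth[ord[seq_len(k[["birth"]])]] <- TRUE
      pregnant_d62[ord[seq_len(k[["d62"]])]] <- TRUE
      pregnant_d40[ord[seq_len(k[["d40"]])]] <- TRUE
    }
    data.frame(
      et_id = sprintf("ET%02d", seq_len(n)),
      breed = breed, bull_breed = bull_breed, day6_stage = day6_stage,
      pregnant_d40 = pregnant_d40, pregnant_d62 = pregnant_d62, birth = birth,
      stringsAsFactors = FALSE
    )
  })
}

generate_matrix <- function(cfg, prefix, compartment, names, records) {
  vals <- matrix(NA_real_, nrow(records), length(names),
                 dimnames = list(records$et_id, names))
  for (nm in names) {
    shift <- effect_shift(cfg, compartment, nm, records)
    if (compartment == "plasma_d0" && cfg$breed_effect_d0 != 0) {
      shift <- shift + ifelse(records$breed == "AV", cfg$breed_effect_d0, 0)
    }
    vals[, nm] <- generate_column(cfg, prefix, compartment, nm, shift)
  }
  metabolite_matrix(vals, compartment, cfg$units)
}

generate_cohort_impl <- function(cfg, prefix) {
  records <- generate_records(cfg, prefix)
  cm_names <- sprintf("CM_%02d", seq_len(cfg$n_cm_metabolites))
  pl_names <- sprintf("P_%02d", seq_len(cfg$n_plasma_metabolites))
  cm <- generate_matrix(cfg, prefix, "CM", cm_names, records)
  d0 <- generate_matrix(cfg, prefix, "plasma_d0", pl_names, records)
  d7 <- generate_matrix(cfg, prefix, "plasma_d7", pl_names, records)
  log <- character(0)
  if (cfg$missing_day0 > 0L) {
    drop <- with_substream(cfg$seed, prefix, "missing_day0", expr = {
      sample(records$et_id, cfg$missing_day0)
    })
    d0$values <- d0$values[!rownames(d0$values) %in% drop, , drop = FALSE]
    log <- c(log, sprintf("dropped uncollected Day-0 plasma sample(s): %s",
                          paste(drop, collapse = ", ")))
  }
  structure(list(et_records = records, cm = cm, plasma_d0 = d0, plasma_d7 = d7,
                 config = cfg, log = log, config_hash = config_hash(unclass(cfg))),
            class = "et_cohort")
}

#' Generate a synthetic discovery cohort
#'
#' Draws recipient metadata, nested pregnancy outcomes and the three
#' concentration matrices (CM, Day-0 plasma, Day-7 plasma) under the
#' configured effect structure. Reproducible: the same configuration and
#' seed yield bitwise-identical output.
#'
#' @param config a [cohort_config()].
#' @return an object of class `et_cohort`: a list with `et_records`
#'   (data.frame of per-ET metadata and outcomes), `cm`, `plasma_d0`,
#'   `plasma_d7` ([metabolite_matrix()] objects), the `config`, an exclusion
#'   `log`, and a `config_hash`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 1))
#' dim(coh$cm$values)        # 36 x 37
#' dim(coh$plasma_d0$values) # 35 x 71 (one Day-0 sample uncollected)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  generate_cohort_impl(config, "discovery")
}

#' Generate an independent Holstein validation cohort
#'
#' Emulates the targeted validation stage: an independent cohort of Holstein
#' recipients (default N = 19) measured in absolute units, with the same
#' effect structure as discovery but an independent random stream.
#'
#' @param config a [cohort_config()] (its seed is the root; the validation
#'   stream is independent of the discovery stream by construction).
#' @param discovery_effects effect table to carry over (possibly the
#'   discovery configuration's); `NULL` for a null validation cohort.
#' @param n_et validation cohort size.
#' @return an `et_cohort` with all-Holstein recipients and `absolute` units.
#' @export
generate_validation_cohort <- function(config, discovery_effects = NULL,
                                       n_et = 19L) {
  stopifnot(inherits(config, "cohort_config"))
  vcfg <- cohort_config(
    n_et = n_et,
    breed_counts = c(Holstein = as.integer(n_et)),
    n_cm_metabolites = config$n_cm_metabolites,
    n_plasma_metabolites = config$n_plasma_metabolites,
    stage_probs = config$stage_probs,
    endpoint_rates = config$endpoint_rates,
    effect_table = discovery_effects,
    noise_sdlog = config$noise_sdlog,
    baseline_log2_range = config$baseline_log2_range,
    breed_effect_d0 = 0,
    missing_day0 = 0L,
    units = "absolute",
    seed = config$seed
  )
  generate_cohort_impl(vcfg, "validation")
}

#' Write a cohort to tab-separated files
#'
#' Writes `metadata.tsv` (one row per ET), one `<compartment>.tsv` per
#' matrix (samples as rows, metabolite names as header, empty cell =
#' missing) and `manifest.json` recording the seed and configuration hash.
#'
#' @param cohort an `et_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "et_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$et_records, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (comp in c("cm", "plasma_d0", "plasma_d7")) {
    mm <- cohort[[comp]]
    df <- data.frame(sample_id = rownames(mm$values), mm$values,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(comp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  manifest <- list(seed = cohort$config$seed, config_hash = cohort$config_hash,
                   units = cohort$config$units, log = cohort$log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `metadata.tsv` and the matrix files.
#' @param units units flag for the matrices read back.
#' @return an `et_cohort` (without a generating config).
#' @export
read_cohort <- function(dir, units = c("is_ratio", "absolute")) {
  units <- match.arg(units)
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stop_data("no metadata.tsv under %s", dir)
  records <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  read_mm <- function(comp, compartment) {
    path <- file.path(dir, paste0(comp, ".tsv"))
    if (!file.exists(path)) stop_data("missing matrix file %s", path)
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    rownames(vals) <- df[[1]]
    metabolite_matrix(vals, compartment, units)
  }
  structure(list(
    et_records = records,
    cm = read_mm("cm", "CM"),
    plasma_d0 = read_mm("plasma_d0", "plasma_d0"),
    plasma_d7 = read_mm("plasma_d7", "plasma_d7"),
    config = NULL, log = character(0), config_hash = NA_character_
  ), class = "et_cohort")
}

# Outcome column for an endpoint
endpoint_outcome <- function(records, endpoint = c("d40", "d62", "birth")) {
  endpoint <- match.arg(endpoint)
  switch(endpoint,
         d40 = records$pregnant_d40,
         d62 = records$pregnant_d62,
         birth = records$birth)
}
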