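test_that("pregnant range is the inclusive min/max of the pregnant group", {
  v <- c(a = 3, b = 5, c = 9, d = 1, e = 20)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(pregnant_range(v, y), c(3, 9))
  expect_equal(pregnant_range(c(7, 7, 1), c(T, T, F)), c(7, 7))
  expect_error(pregnant_range(c(7, 1), c(T, F)), "insufficient",
               class = "bovipreg_data_error")
  # an upstream-removed gross outlier no longer widens the range
  v2 <- c(p1 = 3, p2 = 5, p3 = 9, p4 = 12000, o1 = 1)
  y2 <- setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE), names(v2))
  kept <- remove_outliers(v2, 100)
  expect_equal(kept$removed, "p4")
  expect_equal(pregnant_range(kept$values, y2[names(kept$values)]), c(3, 9))
})

test_that("boolean calls are inclusive at both ends and preserve missingness", {
  calls <- boolean_calls(c(3, 2.999, 9, 9.001, NA), c(3, 9))
  expect_identical(as.logical(calls), c(TRUE, FALSE, TRUE, FALSE, NA))
  expect_equal(attr(calls, "n_true"), 2)
  # vector form equals a naive per-element loop
  set.seed(2)
  v <- runif(50, 0, 10)
  rng <- c(2.5, 7.5)
  naive <- vapply(v, function(x) x >= rng[1] && x <= rng[2], TRUE)
  expect_identical(as.logical(boolean_calls(v, rng)), naive)
})

test_that("OR-combination reproduces the stated truth table and disjunction", {
  expect_identical(combine_or(c(F, T, F, T), c(F, F, T, T)), c(F, T, T, T))
  set.seed(3)
  for (i in 1:20) {
    a <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    b <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    expect_identical(combine_or(a, b), a | b)
    expect_identical(combine_or(a, rep(FALSE, 50)), a)   # identity element
    expect_identical(combine_or(a, b), combine_or(b, a)) # commutative
    expect_identical(combine_or(a, a), a)                # idempotent
    c3 <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    expect_identical(combine_or(combine_or(a, b), c3),
                     combine_or(a, combine_or(b, c3)))   # associative
  }
  # a missing member call removes the sample, even against TRUE
  expect_identical(combine_or(c(NA, TRUE), c(TRUE, NA)), c(NA, NA))
})

test_that("confusion counts and F1 match hand tallies and the closed form", {
  expect_equal(pair_confusion(c(T, T, F, F), c(T, T, F, F)),
               list(tp = 2, fp = 0, fn = 0, tn = 2))
  expect_equal(pair_confusion(rep(TRUE, 5), c(T, T, F, F, F)),
               list(tp = 2, fp = 3, fn = 0, tn = 0))
  set.seed(4)
  calls <- sample(c(TRUE, FALSE, NA), 60, replace = TRUE, prob = c(.45, .45, .1))
  y <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  cc <- pair_confusion(calls, y)
  expect_equal(cc$tp, sum(calls & y, na.rm = TRUE))
  expect_equal(cc$tn, sum(!calls & !y, na.rm = TRUE))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, sum(!is.na(calls)))

  expect_equal(f1_score(list(tp = 5, fp = 0, fn = 0, tn = 3)), 1.0)
  expect_equal(f1_score(list(tp = 14, fp = 3, fn = 2, tn = 0)), 28 / 33)
  expect_true(is.na(f1_score(list(tp = 0, fp = 0, fn = 0, tn = 4))))
  # F1 = 1 iff no false calls
  expect_lt(f1_score(list(tp = 10, fp = 1, fn = 0, tn = 0)), 1)
})

test_that("single-stratum MH equals the Yates chi-square; multi-stratum matches mantelhaen.test", {
  set.seed(6)
  for (i in 1:200) {
    cc <- list(tp = rpois(1, 6) + 1, fp = rpois(1, 4) + 1,
               fn = rpois(1, 4) + 1, tn = rpois(1, 6) + 1)
    mh <- mh_chi_square(list(cc))
    expect_equal(mh$chi2, yates_chi2(cc), tolerance = 1e-12)
  }
  # hypergeometric variance reproduces stats::mantelhaen.test across strata
  for (i in 1:50) {
    strata <- lapply(1:2, function(k) {
      list(tp = rpois(1, 6) + 1, fp = rpois(1, 4) + 1,
           fn = rpois(1, 4) + 1, tn = rpois(1, 6) + 1)
    })
    arr <- array(unlist(lapply(strata, function(s) c(s$tp, s$fn, s$fp, s$tn))),
                 dim = c(2, 2, 2))
    ref <- stats::mantelhaen.test(arr, correct = TRUE)
    mh <- mh_chi_square(strata, variance = "hypergeometric")
    # mantelhaen.test does not clamp the corrected deviation at zero
    # (chisq.test does); compare only where the statistic is informative
    if (mh$chi2 > 0) {
      expect_equal(mh$chi2, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mh$p, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("MH is calibrated under a two-stratum null; correction is conservative", {
  set.seed(8)
  p_unc <- p_cor <- numeric(400)
  for (i in seq_len(400)) {
    strata <- lapply(1:2, function(k) {
      n <- 60
      pair_confusion(runif(n) < 0.5, runif(n) < 0.5)
    })
    p_unc[i] <- mh_chi_square(strata, correct = FALSE)$p
    p_cor[i] <- mh_chi_square(strata, correct = TRUE)$p
  }
  band <- qbinom(c(.025, .975), 400, 0.05) / 400
  expect_gte(mean(p_unc < 0.05), band[1])
  expect_lte(mean(p_unc < 0.05), band[2])
  expect_lte(mean(p_cor < 0.05), band[2])  # conservative by construction
})

test_that("zero-margin strata are dropped; all-degenerate input errors", {
  ok <- list(tp = 5, fp = 2, fn = 2, tn = 5)
  deg <- list(tp = 7, fp = 7, fn = 0, tn = 0)  # all called true
  mh <- mh_chi_square(list(ok, deg))
  expect_equal(mh$dropped, 2L)
  expect_equal(mh$chi2, mh_chi_square(list(ok))$chi2)
  expect_error(mh_chi_square(list(deg)), "degenerate",
               class = "bovipreg_data_error")
})

test_that("ND rule compares the pair to the best single member", {
  expect_false(nd_rule(14, c(13, 12)))
  expect_true(nd_rule(12, c(13, 12)))
  expect_false(nd_rule(13, c(13, 13)))
})

test_that("a perfectly separating pair forces F1 = 1 with p < 0.001", {
  # open values sit entirely outside each member's pregnant range, so the
  # OR calls reproduce the outcome exactly (the confusion is forced)
  ids <- sprintf("S%02d", 1:20)
  y <- setNames(rep(c(TRUE, FALSE), each = 10), ids)
  cm <- setNames(c(seq(1, 2, length.out = 10), seq(5, 6, length.out = 10)), ids)
  pl <- setNames(c(seq(10, 12, length.out = 10), seq(20, 22, length.out = 10)), ids)
  res <- score_pair(cm, pl, y, mode = "aggregate")
  expect_equal(res$f1, 1.0)
  expect_lt(res$p, 0.001)
  expect_equal(res$confusion$fp + res$confusion$fn, 0)
  expect_false(res$nd)
})

test_that("two null members drift toward the all-true F1 baseline", {
  # wide ranges call nearly everything true; F1 approaches
  # 2 n_preg / (2 n_preg + n_open)
  set.seed(9)
  f1s <- replicate(50, {
    ids <- sprintf("S%02d", 1:36)
    y <- setNames(sample(rep(c(TRUE, FALSE), c(19, 17))), ids)
    cm <- setNames(rlnorm(36), ids)
    pl <- setNames(rlnorm(36), ids)
    score_pair(cm, pl, y, mode = "aggregate")$f1
  })
  baseline <- 2 * 19 / (2 * 19 + 17)
  expect_lt(abs(mean(f1s) - baseline), 0.08)
})

test_that("stage-specific ranges let stratified mode beat aggregate on a shifted fixture", {
  # morulae and blastocysts occupy disjoint concentration bands; pooled
  # ranges swallow open samples that per-stage ranges exclude
  ids <- sprintf("S%02d", 1:24)
  stage <- setNames(rep(c("morula", "early_blastocyst"), each = 12), ids)
  y <- setNames(rep(c(TRUE, FALSE), 12), ids)
  base <- ifelse(stage == "morula", 0, 100)
  cm <- setNames(base + ifelse(y, runif(24, 1, 2), runif(24, 2.5, 3.5)), ids)
  pl <- setNames(base + ifelse(y, runif(24, 1, 2), runif(24, 2.5, 3.5)), ids)
  agg <- score_pair(cm, pl, y, stage = stage, mode = "aggregate")
  str <- score_pair(cm, pl, y, stage = stage, mode = "stratified_b_m")
  expect_gte(str$true_count, agg$true_count)
  # pooled confusion equals the sum of the per-stratum confusions
  expect_equal(str$confusion,
               bovipreg:::sum_confusion(str$per_stratum))
})

test_that("widening the pregnant range never decreases the true-call count", {
  set.seed(10)
  v <- runif(40, 0, 10)
  rng <- c(4, 6)
  base_true <- attr(boolean_calls(v, rng), "n_true")
  for (pad in seq(0.5, 4, by = 0.5)) {
    wide <- attr(boolean_calls(v, rng + c(-pad, pad)), "n_true")
    expect_gte(wide, base_true)
    base_true <- wide
  }
})

test_that("pair scan covers the Cartesian product, sorted by F1 then p", {
  eff <- planted_effects(2)
  coh <- generate_cohort(small_config(14, eff, n_cm = 4, n_plasma = 6))
  pt <- score_all_pairs(coh$cm, list(d0 = coh$plasma_d0, d7 = coh$plasma_d7),
                        coh$et_records, "birth",
                        c("CM_01", "CM_02"), c("P_01", "P_02", "P_03"))
  expect_equal(nrow(pt), 12L)  # 2 CM x 3 plasma x 2 days
  expect_true(all(diff(pt$f1) <= 1e-12))
  expect_true(all(is.na(pt$f1_report[pt$nd])))
  expect_match(pt$true_report, "^\\d+/\\d+$")
  # fast matrix path agrees with the per-pair reference on the same input
  ids <- rownames(coh$cm$values)
  keep <- intersect(ids, rownames(coh$plasma_d7$values))
  slow <- bovipreg:::pair_scan_slow(
    coh$cm$values[keep, c("CM_01", "CM_02")],
    coh$plasma_d7$values[keep, c("P_01", "P_02", "P_03")],
    named_outcome(coh$et_records, "birth")[keep],
    named_stage(coh$et_records)[keep], mode = "stratified_b_m")
  fast <- bovipreg:::pair_scan(
    coh$cm$values[keep, c("CM_01", "CM_02")],
    coh$plasma_d7$values[keep, c("P_01", "P_02", "P_03")],
    named_outcome(coh$et_records, "birth")[keep],
    named_stage(coh$et_records)[keep], mode = "stratified_b_m")
  ord <- function(d) d[order(d$cm_metabolite, d$plasma_metabolite),
                       c("tp", "fp", "fn", "tn", "f1", "chi2", "p", "nd")]
  expect_equal(ord(fast), ord(slow), ignore_attr = TRUE)
})
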