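test_that("AUC handles separation, ties and the hand-computable cases", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c(F, F, T, T))$auc, 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 1, 2, 3), c(F, F, F, T, T, T))$auc, 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(F, F, T, T))$auc, 1.0)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(F, F, T, T))$auc, 0.75)
  # orientation flips when pregnant animals sit low
  r <- roc_auc(c(10, 11, 1, 2), c(F, F, T, T))
  expect_equal(r$auc, 1.0)
  expect_equal(r$orientation, "pregnant_low")
  expect_error(roc_auc(1:5, rep(TRUE, 5)), class = "bovipreg_data_error")
})

test_that("rank AUC equals brute-force pair counting and is rank-invariant", {
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(2:15, 1)
    n0 <- sample(2:15, 1)
    v <- c(rnorm(n1), rnorm(n0, sample(c(0, 1), 1)))
    if (runif(1) < 0.3) v <- round(v)  # induce ties
    y <- c(rep(TRUE, n1), rep(FALSE, n0))
    expect_equal(roc_auc(v, y)$auc, brute_auc(v, y), tolerance = 1e-12)
    # strictly increasing transform leaves the AUC unchanged
    expect_equal(roc_auc(exp(v), y)$auc, roc_auc(v, y)$auc, tolerance = 1e-12)
  }
})

test_that("optimal cutoff is closest to the perfect-classification corner", {
  # clean separation: open {1,2} vs pregnant {10,11} -> midpoint 6, perfect
  oc <- optimal_cutoff(c(1, 2, 10, 11), c(F, F, T, T), "pregnant_high")
  expect_equal(oc$cutoff, 6)
  expect_equal(oc$sens, 1)
  expect_equal(oc$spec, 1)

  # values shared across the classes: no cutoff beats chance at any
  # threshold, so the tie-break path runs
  vi <- c(1, 2, 3, 4, 1, 2, 3, 4)
  yi <- rep(c(FALSE, TRUE), each = 4)
  oci <- optimal_cutoff(vi, yi, "pregnant_high")
  expect_equal(oci$sens + oci$spec - 1, 0, tolerance = 1e-12)

  # overlapping fixture vs exhaustive search oracle
  v <- c(1, 2, 3, 8, 4, 6, 7, 9)
  y <- c(F, F, F, F, T, T, T, T)
  ref <- brute_cutoff(v, y, "pregnant_high")
  oc2 <- optimal_cutoff(v, y, "pregnant_high")
  expect_equal(oc2$cutoff, ref$cutoff)
  expect_equal(oc2$sens, ref$sens)
  expect_equal(oc2$spec, ref$spec)
})

test_that("no other threshold dominates the chosen cutoff (random scan)", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    v <- rnorm(n)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(y) < 1 || sum(!y) < 1) next
    ori <- if (runif(1) < 0.5) "pregnant_high" else "pregnant_low"
    oc <- optimal_cutoff(v, y, ori)
    ref <- brute_cutoff(if (ori == "pregnant_high") v else v, y, ori)
    expect_equal(sqrt((1 - oc$sens)^2 + (1 - oc$spec)^2),
                 sqrt((1 - ref$sens)^2 + (1 - ref$spec)^2), tolerance = 1e-12)
  }
})

test_that("class counts tally correctly against a brute-force confusion", {
  cc <- class_counts(c(1, 2, 10, 11), c(F, F, T, T), 6, "pregnant_high")
  expect_equal(cc$correct_open, c(2, 2))
  expect_equal(cc$correct_pregnant, c(2, 2))

  v <- c(1, 2, 3, 8, 4, 6, 7, 9)
  y <- c(F, F, F, F, T, T, T, T)
  oc <- optimal_cutoff(v, y, "pregnant_high")
  cc2 <- class_counts(v, y, oc$cutoff, "pregnant_high")
  pred <- v > oc$cutoff
  expect_equal(cc2$correct_open[1], sum(!pred & !y))
  expect_equal(cc2$correct_pregnant[1], sum(pred & y))
})

test_that("bootstrap interval is seeded, tight under separation, wide at n=3", {
  v <- c(rnorm(15, 0), rnorm(15, 10))
  y <- rep(c(FALSE, TRUE), each = 15)
  ci <- bootstrap_ci(v, y, n_boot = 1000, seed = 9)
  expect_identical(ci, bootstrap_ci(v, y, n_boot = 1000, seed = 9))
  expect_gte(ci[1], 0.9)

  v3 <- c(1, 3, 5, 2, 4, 6)
  y3 <- rep(c(FALSE, TRUE), each = 3)
  ci3 <- bootstrap_ci(v3, y3, n_boot = 1000, seed = 9)
  expect_lte(ci3[1], 0.5)
  expect_gte(ci3[2], 0.5)
  expect_warning(bootstrap_ci(v, y, n_boot = 50, seed = 1), "unstable")
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:25) {
    n <- sample(10:30, 1)
    v <- rnorm(n)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.5, 0.5))
    if (sum(y) < 2 || sum(!y) < 2) next
    ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, v, quiet = TRUE))))
    expect_equal(roc_auc(v, y)$auc, max(ref, 1 - ref), tolerance = 1e-12)
  }
})

test_that("single-biomarker rule selects on AUC > 0.650 and t-test p", {
  eff <- data.frame(metabolite = "CM_01", compartment = "CM",
                    endpoint = "birth", log2fc = 2.5)
  coh <- generate_cohort(cohort_config(n_cm_metabolites = 2,
                                       effect_table = eff, seed = 31))
  y <- coh$et_records$birth
  hit <- roc_biomarker(coh$cm$values[, "CM_01"], y, n_boot = 200, seed = 1)
  expect_true(hit$selected)
  expect_gt(hit$auc, 0.65)
  expect_true(hit$ci_low <= hit$auc && hit$auc <= hit$ci_high)
  expect_equal(hit$n_open + hit$n_pregnant, 36)
  tbl <- roc_table(coh$cm, coh$et_records, "birth", n_boot = 100, seed = 1)
  expect_match(tbl$open_counts, "^\\d+/\\d+$")
  expect_match(tbl$pregnant_counts, "^\\d+/\\d+$")
})
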