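test_that("normality gate picks ANOVA for Gaussian data, KW under gross outliers", {
  set.seed(101)
  g <- rep(c(FALSE, TRUE), each = 15)
  v <- rnorm(30, mean = 10, sd = 1)
  expect_equal(choose_test(v, g)$test, "anova")

  # a 1200x-the-mean outlier left in place wrecks within-group normality;
  # cross-checked against the Shapiro-Wilk p on the fixed vector
  v_out <- v
  v_out[1] <- 1200 * mean(v[-1])
  gate <- choose_test(v_out, g)
  expect_equal(gate$test, "kruskal_wallis")
  ref_p <- shapiro.test(v_out[!g] - mean(v_out[!g]))$p.value
  expect_equal(unname(gate$shapiro_p[1]), ref_p, tolerance = 1e-12)
  expect_lt(ref_p, 0.05)

  expect_error(choose_test(rep(5, 30), g), "variance",
               class = "bovipreg_data_error")
  expect_error(choose_test(v[c(1:2, 16:17)], g[c(1:2, 16:17)]), "insufficient",
               class = "bovipreg_data_error")
})

test_that("fold change is log2 of the open/pregnant mean ratio", {
  expect_equal(fold_change(c(2, 4), c(2, 4)), 0)
  expect_equal(fold_change(c(8, 8), c(2, 2)), 2)
  expect_equal(fold_change(2454, 940), log2(2454 / 940), tolerance = 1e-12)
  expect_equal(round(fold_change(2454, 940), 3), 1.384)
  expect_error(fold_change(c(0, 0), c(1, 2)), "positive",
               class = "bovipreg_data_error")
})

test_that("p-value adjustment matches the closed forms and orderings", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  # BH step-up by hand: p_(i) * m / i, cummin from the top -> all 0.03
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"), rep(0.03, 3))
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "bovipreg_data_error")

  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    bon <- adjust_pvalues(p, "bonferroni")
    bh <- adjust_pvalues(p, "bh")
    expect_true(all(bon >= p))
    expect_true(all(bh <= bon + 1e-15))
  }
})

test_that("outlier rule removes only values exceeding the fold threshold", {
  v <- c(a = 10, b = 12, c = 9, d = 11, e = 12600)  # e is ~1200x the rest
  out <- remove_outliers(v, threshold_fold = 100)
  expect_equal(out$removed, "e")
  expect_equal(sort(names(out$values)), c("a", "b", "c", "d"))

  expect_equal(remove_outliers(c(5, 6, 5, 6))$removed, character(0))

  # two mutually supporting extremes: each is under the threshold relative
  # to the mean of the others (which includes the other extreme)
  v2 <- c(x = 1, y = 1, z = 40, w = 41)
  expect_equal(remove_outliers(v2, threshold_fold = 100)$removed, character(0))
  expect_error(remove_outliers(v, threshold_fold = 1),
               class = "bovipreg_config_error")
})

test_that("planted effect is detected; permuted labels give uniform p", {
  eff <- data.frame(metabolite = "CM_01", compartment = "CM",
                    endpoint = "birth", log2fc = 3)
  coh <- generate_cohort(cohort_config(n_cm_metabolites = 2,
                                       effect_table = eff, seed = 21))
  v <- setNames(coh$cm$values[, "CM_01"], rownames(coh$cm$values))
  y <- coh$et_records$birth
  res <- test_metabolite(v, y,
                         covariates = list(bull_breed = factor(coh$et_records$bull_breed),
                                           day6_stage = factor(coh$et_records$day6_stage)))
  expect_lt(res$p_value, 0.05)
  expect_gt(res$fch, 0)  # open higher by construction
  expect_false(is.na(res$p_bull_breed))
  expect_false(is.na(res$p_day6_stage))
  expect_equal(res$n_open + res$n_pregnant, 36L)

  set.seed(33)
  vn <- setNames(coh$cm$values[, "CM_02"], rownames(coh$cm$values))
  pp <- replicate(200, test_metabolite(vn, sample(y))$p_value)
  expect_gt(suppressWarnings(ks.test(pp, "punif")$p.value), 0.01)
})

test_that("screen results are invariant to sample order and unit rescaling", {
  coh <- generate_cohort(small_config(8))
  v <- setNames(coh$cm$values[, 1], rownames(coh$cm$values))
  y <- coh$et_records$birth
  base <- test_metabolite(v, y)
  perm <- sample(length(v))
  shuffled <- test_metabolite(v[perm], y[perm])
  expect_equal(shuffled$p_value, base$p_value, tolerance = 1e-12)
  rescaled <- test_metabolite(v * 1000, y)
  expect_equal(rescaled$p_value, base$p_value, tolerance = 1e-10)
  expect_equal(rescaled$fch, base$fch, tolerance = 1e-10)
})

test_that("matrix screen flags candidates by raw AND adjusted p, skips degenerates", {
  eff <- data.frame(metabolite = "CM_01", compartment = "CM",
                    endpoint = "birth", log2fc = 3)
  coh <- generate_cohort(cohort_config(n_cm_metabolites = 6,
                                       effect_table = eff, seed = 12))
  coh$cm$values[, "CM_03"] <- 7  # constant metabolite -> skipped
  scr <- suppressWarnings(screen_matrix(coh$cm, coh$et_records, "birth"))
  expect_equal(nrow(scr), 6L)
  expect_true(all(scr$p_adjusted >= scr$p_value, na.rm = TRUE))
  expect_true(scr$candidate_flag[scr$metabolite == "CM_01"])
  expect_true(is.na(scr$p_value[scr$metabolite == "CM_03"]))
  expect_false(scr$candidate_flag[scr$metabolite == "CM_03"])
  expect_equal(attr(scr, "skipped"), "CM_03")
  # group summaries come in the mean +/- SE layout of the candidate tables
  expect_true(all(c("mean_open", "se_open", "mean_pregnant", "se_pregnant",
                    "fch", "p_bull_breed", "p_day6_stage") %in% names(scr)))
})
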