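test_that("standardisation uses within-table moments only", {
  tab <- generate_feature_table(50, 5, seed = 1)
  std <- standardize(tab)
  for (f in sprintf("feature_%02d", 1:5)) {
    expect_lt(abs(mean(std[[f]])), 1e-10)
    expect_lt(abs(var(std[[f]]) - 1), 1e-10)
  }
  expect_equal(standardize(std), std, tolerance = 1e-10)  # idempotent

  # a location-shifted "external" table must be scaled with its own moments
  shifted <- tab
  shifted$feature_01 <- shifted$feature_01 + 100
  std_ext <- standardize(shifted)
  expect_lt(abs(mean(std_ext$feature_01)), 1e-10)

  const <- dplyr::mutate(tab, feature_03 = 2)
  expect_error(standardize(const), "feature_03")
})

test_that("mean imputation fills gaps without moving observed means", {
  tab <- tibble::tibble(subject_id = c("a", "b", "c"), label = c(0L, 1L, 0L),
                        f1 = c(1, NA, 3), f2 = c(2, 4, 6))
  imp <- impute_mean(tab)
  expect_equal(imp$f1, c(1, 2, 3))
  expect_identical(imp$f2, tab$f2)  # no missing: identity
  expect_equal(mean(imp$f1), mean(tab$f1, na.rm = TRUE))
  expect_error(impute_mean(dplyr::mutate(tab, f2 = NA_real_)), "f2")
})

test_that("AUROC matches exhaustive pairwise concordance", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 75)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 100)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(1, 1, 0, 0)), 25)  # flipped
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    sc <- round(runif(n), 2)  # ties likely
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    pos <- sc[lb == 1]; neg <- sc[lb == 0]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(auroc(sc, lb), 100 * mean(pairs))
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "Both classes")
})

test_that("classification metrics reproduce the worked confusion ratios", {
  # 38/40 positives and 58/60 negatives correct
  scores <- c(rep(0.9, 38), rep(0.1, 2), rep(0.1, 58), rep(0.9, 2))
  labels <- c(rep(1, 40), rep(0, 60))
  m <- classification_metrics(scores, labels)
  expect_equal(m$sensitivity, 95.00)
  expect_equal(m$specificity, 96.67, tolerance = 1e-4)
  expect_equal(m$balanced_accuracy, 95.83, tolerance = 1e-4)
  expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)

  expect_equal(classification_metrics(scores, labels, threshold = 0)$sensitivity, 100)
  expect_equal(classification_metrics(scores, labels, threshold = 1)$specificity, 100)
})

test_that("paired AUROC comparison behaves at both extremes", {
  a <- c(90, 91, 92, 93)
  expect_equal(compare_auroc(a, a), 1)
  set.seed(2)
  b <- rnorm(200, 90, 0.5)
  expect_lt(compare_auroc(b + 5, b), 0.001)
  expect_equal(compare_auroc(b + 5, b), compare_auroc(b, b + 5))  # two-sided
  expect_lt(compare_auroc(b + 5, b, method = "bootstrap"), 0.01)
  expect_error(compare_auroc(1:3, 1:4), "equal length")
})

test_that("bootstrap-LASSO shrinks fully under a huge penalty and is reproducible", {
  tab <- standardize(generate_feature_table(80, 6, planted = list(c(1, 2)),
                                            seed = 3))
  res <- bootstrap_lasso(tab, n_boot = 10, seed = 4, lambda = c(1e4, 5e3))
  expect_true(all(res$selection$selection_probability == 0))
  expect_true(all(is.na(res$selection$mean_coefficient)))

  r1 <- bootstrap_lasso(tab, n_boot = 15, seed = 7)
  r2 <- bootstrap_lasso(tab, n_boot = 15, seed = 7)
  expect_identical(r1$selection, r2$selection)
  expect_identical(r1$replicates$auroc, r2$replicates$auroc)
  expect_identical(r1$score_mode, "oob")
  expect_true(all(r1$replicates$auroc >= 0 & r1$replicates$auroc <= 100,
                  na.rm = TRUE))
})

test_that("bootstrap-LASSO recovers a planted discriminative feature", {
  tab <- standardize(generate_feature_table(
    250, 10, planted = list(c(4, 2.5)), seed = 11))
  res <- bootstrap_lasso(tab, n_boot = 40, seed = 12)
  sel <- res$selection
  expect_gte(sel$selection_probability[sel$feature == "feature_04"], 0.9)
  top <- rank_features(res, 1)
  expect_identical(top, "feature_04")
  noise <- sel$selection_probability[sel$feature != "feature_04"]
  expect_lte(stats::median(noise), 0.35)

  # ranking contract
  expect_identical(rank_features(res, 0), character(0))
  expect_identical(sort(rank_features(res, 10)), sort(sel$feature))
  expect_error(rank_features(res, 99), "exceeds")
})

test_that("selection probability of noise features drops as n grows", {
  small <- standardize(generate_feature_table(60, 8, planted = list(c(1, 2)),
                                              seed = 13))
  large <- standardize(generate_feature_table(600, 8, planted = list(c(1, 2)),
                                              seed = 13))
  rs <- bootstrap_lasso(small, n_boot = 25, seed = 14)
  rl <- bootstrap_lasso(large, n_boot = 25, seed = 14)
  noise_small <- mean(rs$selection$selection_probability[-1])
  noise_large <- mean(rl$selection$selection_probability[-1])
  expect_lte(noise_large, noise_small + 0.05)
  expect_gt(rl$selection$selection_probability[1], 0.95)
})

test_that("simplified models expose coefficients and handle separation", {
  tab <- standardize(generate_feature_table(120, 5, planted = list(c(2, 3)),
                                            seed = 15))
  fit <- fit_simplified(tab, c("feature_02", "feature_03", "feature_05"))
  expect_identical(length(fit$coefficients), 4L)
  expect_identical(names(fit$coefficients)[1], "(Intercept)")
  expect_identical(fit$features, c("feature_02", "feature_03", "feature_05"))

  # permutation invariance of the fit
  perm <- tab[sample(nrow(tab)), ]
  fit2 <- fit_simplified(perm, fit$features)
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-6)

  # a feature equal to the label separates perfectly: ridge fallback
  sep <- tab
  sep$feature_01 <- as.numeric(sep$label)
  expect_warning(fsep <- fit_simplified(sep, "feature_01"), "separation")
  expect_true(fsep$fallback_ridge)
  p <- predict(fsep, sep)
  expect_true(all(p[sep$label == 1] >= 0.99))

  expect_error(fit_simplified(tab, "nope"), "not in table")
  ev <- evaluate_model(fit, tab)
  expect_s3_class(ev, "evaluation_report")
  expect_gt(ev$auroc, 90)
  expect_equal(ev$balanced_accuracy, (ev$sensitivity + ev$specificity) / 2)
})

test_that("tidiers return well-formed tibbles", {
  tab <- standardize(generate_feature_table(80, 4, planted = list(c(1, 2)),
                                            seed = 16))
  res <- bootstrap_lasso(tab, n_boot = 8, seed = 17)
  td <- tidy(res)
  expect_identical(names(td), c("feature", "selection_probability",
                                "mean_coefficient"))
  expect_true(!is.unsorted(rev(td$selection_probability)))
  gl <- glance(res)
  expect_identical(gl$n_boot, 8L)
  fit <- fit_simplified(tab, "feature_01")
  expect_identical(nrow(tidy(fit)), 2L)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
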