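test_that("phantom generation is deterministic and respects its invariants", {
  spec <- phantom_spec(denervation_severity = 0.5, gradient_strength = 0.8)
  a <- generate_phantom(spec, 123)
  b <- generate_phantom(spec, 123)
  expect_identical(a$volume$suv, b$volume$suv)     # bit-identical
  expect_identical(a$label, 1L)
  expect_identical(generate_phantom(phantom_spec(), 1)$label, 0L)

  # noise-free symmetric phantom is mirror-symmetric about the mid-sagittal
  sym <- generate_phantom(phantom_spec(noise_sd = 0, denervation_severity = 0.3,
                                       asymmetry = 0, gradient_strength = 0.5),
                          1)
  arr <- sym$volume$suv
  expect_equal(arr, arr[rev(seq_len(dim(arr)[1])), , ], tolerance = 1e-12)

  expect_error(phantom_spec(grid_shape = c(20, 20, 8)), "too small")
  expect_error(phantom_spec(denervation_severity = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(voxel_spacing_mm = c(1, 0, 1)), "positive")
})

test_that("putaminal uptake decreases strictly with severity before noise", {
  geo <- striatomics:::striatal_geometry()
  put_mean <- function(sev) {
    ph <- generate_phantom(phantom_spec(denervation_severity = sev,
                                        gradient_strength = 0.5,
                                        noise_sd = 0), 1)
    v <- ph$volume
    dm <- dim(v$suv)
    xs <- (seq_len(dm[1]) - (dm[1] + 1) / 2) * v$spacing[1]
    ys <- (seq_len(dm[2]) - (dm[2] + 1) / 2) * v$spacing[2]
    zs <- (seq_len(dm[3]) - (dm[3] + 1) / 2) * v$spacing[3]
    pm <- geo$putamen
    inside <- outer(outer(((xs - pm$centre[1]) / pm$semi[1])^2,
                          ((ys - pm$centre[2]) / pm$semi[2])^2, `+`),
                    ((zs - pm$centre[3]) / pm$semi[3])^2, `+`) <= 1
    mean(v$suv[inside])
  }
  vals <- vapply(c(0, 0.25, 0.5, 0.75, 1), put_mean, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("positive phantoms have lower putaminal uptake and larger VOIs", {
  coh <- generate_cohort(60, 0.5, phantom_spec(), seed = 9)
  labs <- vapply(coh, `[[`, integer(1), "label")
  geo <- striatomics:::striatal_geometry()
  stats <- vapply(coh, function(s) {
    v <- s$volume
    dm <- dim(v$suv)
    xs <- (seq_len(dm[1]) - (dm[1] + 1) / 2) * v$spacing[1]
    ys <- (seq_len(dm[2]) - (dm[2] + 1) / 2) * v$spacing[2]
    zs <- (seq_len(dm[3]) - (dm[3] + 1) / 2) * v$spacing[3]
    pm <- geo$putamen
    inside_r <- outer(outer(((xs - pm$centre[1]) / pm$semi[1])^2,
                            ((ys - pm$centre[2]) / pm$semi[2])^2, `+`),
                      ((zs - pm$centre[3]) / pm$semi[3])^2, `+`) <= 1
    inside <- inside_r | inside_r[rev(seq_len(dm[1])), , ]
    seg <- segment_striatum(v)
    c(put = mean(v$suv[inside]) / s$truth$striatal_peak_suv,
      vol = (seg$left$volume_mL + seg$right$volume_mL) / 2)
  }, numeric(2))
  expect_lt(mean(stats["put", labs == 1]), mean(stats["put", labs == 0]))
  # relative-threshold volumes stochastically larger in positives
  expect_lt(stats::wilcox.test(stats["vol", labs == 1],
                               stats["vol", labs == 0],
                               alternative = "greater")$p.value, 0.05)
})

test_that("cohorts reproduce the requested composition and are reproducible", {
  coh <- generate_cohort(100, 0.4, phantom_spec(), seed = 2)
  labs <- vapply(coh, `[[`, integer(1), "label")
  expect_identical(sum(labs), 40L)
  expect_identical(length(labs), 100L)
  for (s in coh) {
    expect_identical(s$label, as.integer(s$truth$denervation_severity > 0))
  }
  coh0 <- generate_cohort(10, 0, phantom_spec(), seed = 2)
  expect_true(all(vapply(coh0, `[[`, integer(1), "label") == 0L))
  expect_error(generate_cohort(0, 0.5, phantom_spec(), seed = 1), "positive")

  small_a <- generate_cohort(4, 0.5, phantom_spec(), seed = 2)
  small_b <- generate_cohort(4, 0.5, phantom_spec(), seed = 2)
  expect_identical(small_a[[2]]$volume$suv, small_b[[2]]$volume$suv)
  expect_identical(cohort_manifest(small_a), cohort_manifest(small_b))
  man <- cohort_manifest(coh0)
  expect_identical(nrow(man), 10L)
  expect_true(all(man$severity == 0))
})

test_that("planted feature tables carry exactly the requested signal", {
  # no planted effect: class-wise mean differences are pure sampling noise
  tab <- generate_feature_table(300, 30, planted = list(), seed = 5)
  pvals <- vapply(sprintf("feature_%02d", 1:30), function(f) {
    stats::t.test(tab[[f]] ~ tab$label)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.001), 0.99)

  # a 3 SD planted effect is nearly perfectly discriminative
  tab2 <- generate_feature_table(400, 10, planted = list(c(3, 3)), seed = 6)
  expect_gt(auroc(tab2$feature_03, tab2$label), 95)

  empty <- generate_feature_table(0, 5)
  expect_identical(nrow(empty), 0L)
  expect_identical(ncol(empty), 7L)
  expect_error(generate_feature_table(10, 5, planted = list(c(9, 1))),
               "indices")
})

test_that("clinical tables respect the item scale and missingness contract", {
  tab <- generate_clinical_table(200, effect = 0.2, missing_rate = 0, seed = 3)
  items <- as.matrix(tab[, grep("^item_", names(tab))])
  expect_identical(ncol(items), 25L)
  expect_false(anyNA(items))
  expect_true(all(items %in% 0:4))
  expect_true(all(rowSums(items) <= 100))
  # a subject scoring 4 everywhere reaches the scale maximum of 100
  expect_equal(max(rowSums(array(4L, dim(items)))), 100)

  miss <- generate_clinical_table(300, missing_rate = 0.1, seed = 3)
  m <- as.matrix(miss[, grep("^item_", names(miss))])
  expect_gt(mean(is.na(m)), 0.07); expect_lt(mean(is.na(m)), 0.13)
})

test_that("uninformative clinical tables yield chance-level models", {
  tab <- generate_clinical_table(400, effect = 0, missing_rate = 0.05, seed = 8)
  prep <- standardize(impute_mean(tab))
  res <- bootstrap_lasso(prep, n_boot = 30, seed = 8)
  expect_gt(res$auroc_mean, 40)
  expect_lt(res$auroc_mean, 60)
})
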