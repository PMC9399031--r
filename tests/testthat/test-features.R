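slab_voi <- function(values, n_levels = 2) {
  # values given as grey levels; encode as SUV bin representatives
  arr <- array((values - 0.5) * 10 / n_levels, dim = dim(values))
  quantize_voi(arr, array(TRUE, dim(values)), c(1, 1, 1), n_levels)
}

test_that("GLCM matrix matches hand enumeration on the 2x2 slab", {
  q <- slab_voi(array(c(1, 2, 1, 2), c(2, 2, 1)))
  g <- glcm_matrix(q, c(1, 0, 0), 1)
  expect_equal(g$P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(g$mu_i, 1.5)
  expect_equal(g$sigma_i^2, 0.25)
  # Correlation along this single direction is exactly -1
  f <- glcm_features(q, 1, directions = c(1, 0, 0))
  expect_equal(unname(f["GLCM_Correlation"]), -1)

  # constant VOI: single diagonal entry, Correlation 1 by convention
  qc <- slab_voi(array(2, c(3, 3, 1)))
  gc <- glcm_matrix(qc, c(1, 0, 0), 1)
  expect_equal(sum(gc$P), 1)
  expect_equal(gc$P[2, 2], 1)
  expect_equal(unname(glcm_features(qc, 1)["GLCM_Correlation"]), 1)

  expect_error(glcm_matrix(q, c(0, 0, 1), 1), class = "striatomics_empty_glcm")
})

test_that("texture builders agree with exhaustive oracles on random VOIs", {
  set.seed(7)
  dirs <- dirs13_oracle()
  for (i in 1:40) {
    q <- random_voi(c(4, 4, 4), n_levels = 4)
    n_vox <- sum(q$mask)
    # GLCM against pair enumeration, every direction, distance 1 and 2
    for (dist in c(1, 2)) {
      for (k in sample(nrow(dirs), 4)) {
        P_or <- oracle_glcm(q$levels, 4, dirs[k, ], dist)
        got <- tryCatch(glcm_matrix(q, dirs[k, ], dist)$P,
                        error = function(e) NULL)
        if (is.null(P_or)) expect_null(got) else expect_equal(got, P_or)
      }
    }
    # GLRLM: full 13-direction feature average against the walking oracle
    feats <- vapply(seq_len(nrow(dirs)), function(k) {
      rl_oracle_features(oracle_glrlm(q$levels, 4, dirs[k, ]), 4, n_vox)
    }, numeric(11))
    expect_equal(unname(glrlm_features(q)), unname(rowMeans(feats)),
                 tolerance = 1e-12)
    # GLZLM zones against flood fill
    z_or <- oracle_zones(q$levels)
    expect_equal(unname(glzlm_features(q)),
                 unname(rl_oracle_features(z_or, 4, n_vox)), tolerance = 1e-12)
    # NGLDM accumulators against the per-voxel oracle
    nd <- oracle_ngldm(q$levels, 4)
    got_nd <- ngldm_features(q)
    N <- sum(nd$n); p <- nd$n / N
    pres <- which(p > 0); Ng <- length(pres)
    expect_equal(unname(got_nd["NGLDM_Coarseness"]),
                 min(1 / sum(p * nd$s), 1e6), tolerance = 1e-9)
    if (Ng > 1) {
      contr <- sum(outer(p[pres], p[pres]) * outer(pres, pres, `-`)^2) /
        (Ng * (Ng - 1)) * sum(nd$s) / N
      ipi <- pres * p[pres]
      busy <- sum(p * nd$s) / sum(abs(outer(ipi, ipi, `-`)))
      expect_equal(unname(got_nd["NGLDM_Contrast"]), contr, tolerance = 1e-9)
      expect_equal(unname(got_nd["NGLDM_Busyness"]), busy, tolerance = 1e-9)
    }
  }
})

test_that("run and zone counts on the uniform cube match hand counts", {
  q <- slab_voi(array(1, c(3, 3, 3)), n_levels = 2)
  # 9 axis runs of length 3 over 27 voxels: RP = 1/3 along any axis
  runs <- striatomics:::glrlm_matrix_one(which(q$mask, arr.ind = TRUE),
                                         q$levels[q$mask], c(1L, 0L, 0L))
  expect_identical(length(runs$len), 9L)
  expect_true(all(runs$len == 3L))
  expect_equal(9 / 27, rl_oracle_features(cbind(runs$grey, runs$len), 2, 27)[["RP"]])
  # single zone of 27 voxels: ZP = 1/27
  expect_equal(unname(glzlm_features(q)["GLZLM_ZP"]), 1 / 27)
})

test_that("first-order features follow the moment definitions", {
  vals <- c(1, 1, 1, 5)
  arr <- array((vals - 0.5) * 10 / 8, c(4, 1, 1))
  q <- quantize_voi(arr, array(TRUE, c(4, 1, 1)), c(1, 1, 1), 8)
  expect_identical(q$levels[q$mask], as.integer(vals))
  h <- histogram_features(q, arr[q$mask])
  expect_equal(unname(h["Skewness"]), 6 / 3^1.5, tolerance = 1e-4)
  expect_equal(unname(h["Kurtosis"]), mean((vals - 2)^4) / 3^2)

  symm <- c(1, 2, 3)
  q2 <- quantize_voi(array((symm - 0.5) * 10 / 4, c(3, 1, 1)),
                     array(TRUE, c(3, 1, 1)), c(1, 1, 1), 4)
  expect_equal(unname(histogram_features(q2, symm)["Skewness"]), 0)

  # TVU: 1000 voxels at 2 mm isotropic with SUVmean 2 -> 2 * 8 mL = 16
  big <- array(2, c(10, 10, 10))
  qb <- quantize_voi(big, array(TRUE, dim(big)), c(2, 2, 2), 32)
  hb <- histogram_features(qb, big[qb$mask])
  expect_equal(unname(hb["TVU"]), 16)
  expect_equal(unname(hb["SUVmean"]), 2)
  expect_equal(unname(hb["Skewness"]), 0)  # zero-variance convention
})

test_that("shape features: unit voxel, analytic cube, digital sphere", {
  m1 <- array(TRUE, c(1, 1, 1))
  s1 <- shape_features(m1, spacing = c(1, 1, 1))
  expect_equal(unname(s1["Volume_mL"]), 1e-3)
  expect_equal(unname(s1["Surface_mm2"]), 6)

  # digital cube of side 5 at 1 mm: V = 125, A = 150 exactly
  mc <- array(TRUE, c(5, 5, 5))
  sc <- shape_features(mc, spacing = c(1, 1, 1))
  expect_equal(unname(sc["Surface_mm2"]), 150)
  expect_equal(unname(sc["Sphericity"]), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  expect_equal(unname(sc["Compacity"]), 125 / (sqrt(pi) * 150^1.5))

  # digital sphere: face-count surface overestimates the continuous area
  # by about 3/2, so sphericity plateaus near 0.67 rather than 1
  r <- 20
  dmn <- rep(2 * r + 5, 3)
  ctr <- (dmn + 1) / 2
  sph <- array(outer(outer((seq_len(dmn[1]) - ctr[1])^2,
                           (seq_len(dmn[2]) - ctr[2])^2, `+`),
                     (seq_len(dmn[3]) - ctr[3])^2, `+`) <= r^2, dmn)
  ss <- shape_features(sph, spacing = c(1, 1, 1))
  expect_gt(unname(ss["Sphericity"]), 0.60)
  expect_lt(unname(ss["Sphericity"]), 0.75)
})

test_that("direction-averaged texture features are rotation invariant", {
  set.seed(11)
  q <- random_voi(c(5, 4, 4), n_levels = 4)
  rot <- function(a) aperm(a[, rev(seq_len(dim(a)[2])), , drop = FALSE],
                           c(2, 1, 3))  # 90 degrees about z
  qr <- structure(list(levels = rot(q$levels), n_levels = 4L,
                       spacing = c(1, 1, 1), mask = rot(q$mask)),
                  class = "quantized_voi")
  expect_equal(glcm_features(q, 1), glcm_features(qr, 1), tolerance = 1e-12)
  expect_equal(glrlm_features(q), glrlm_features(qr), tolerance = 1e-12)
  expect_equal(glzlm_features(q), glzlm_features(qr), tolerance = 1e-12)
  expect_equal(ngldm_features(q), ngldm_features(qr), tolerance = 1e-12)
})

test_that("GLCM Correlation is bounded and near zero for shuffled patterns", {
  set.seed(3)
  # axis-aligned ramp: strong linear dependency
  ramp <- array(rep(1:8, each = 8), c(8, 8, 4))
  qr <- quantize_voi(ramp, array(TRUE, dim(ramp)), c(1, 1, 1), 8,
                     bounds = c(0, 9))
  corr_ramp <- abs(glcm_features(qr, 1)["GLCM_Correlation"])
  shuffled <- vapply(1:40, function(i) {
    v <- ramp; v[] <- sample(as.vector(ramp))
    qs <- quantize_voi(v, array(TRUE, dim(v)), c(1, 1, 1), 8, bounds = c(0, 9))
    abs(glcm_features(qs, 1)["GLCM_Correlation"])
  }, numeric(1))
  expect_lt(mean(shuffled), corr_ramp)
  for (i in 1:20) {
    q <- random_voi(c(4, 4, 4), n_levels = 4)
    co <- glcm_features(q, 1)["GLCM_Correlation"]
    expect_gte(co, -1 - 1e-12); expect_lte(co, 1 + 1e-12)
  }
})

test_that("per-scan extraction yields 43 side-averaged features", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0), seed = 1)
  fv <- extract_features(ph$volume, parameter_set(32, 1, "iso2mm"))
  expect_identical(names(fv), feature_names())
  expect_identical(length(fv), 43L)
  expect_true(all(is.finite(fv)))
  expect_identical(nrow(feature_families()), 43L)
  expect_identical(as.integer(table(feature_families()$family)[
    c("shape", "first_order", "glcm", "glrlm", "ngldm", "glzlm")]),
    c(5L, 7L, 6L, 11L, 3L, 11L))

  # left/right swap leaves the bilaterally averaged vector unchanged
  flip <- ph$volume$suv[rev(seq_len(dim(ph$volume$suv)[1])), , ]
  vflip <- scan_volume(flip, ph$volume$spacing)
  fv2 <- extract_features(vflip, parameter_set(32, 1, "iso2mm"))
  expect_equal(fv, fv2, tolerance = 1e-9)
})

test_that("intensity rescaling acts only on SUV-scaled features", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0), seed = 2)
  k <- 1.5
  scaled <- scan_volume(ph$volume$suv * k, ph$volume$spacing)
  p <- parameter_set(64, 1, "iso2mm")
  f1 <- extract_features(ph$volume, p)
  f2 <- extract_features(scaled, p)
  suv_feats <- c("SUVmin", "SUVmean", "SUVmax", "SUVsd", "TVU")
  expect_equal(unname(f2[suv_feats]), unname(k * f1[suv_feats]),
               tolerance = 1e-9)
  shape_feats <- c("Volume_mL", "Volume_vx", "Surface_mm2", "Sphericity",
                   "Compacity")
  expect_equal(f2[shape_feats], f1[shape_feats], tolerance = 1e-12)
})

test_that("cohort tables preserve subject order and share work across sets", {
  coh <- generate_cohort(4, 0.5, phantom_spec(), seed = 5)
  grid <- parameter_grid()
  sub <- grid[grid$name %in% c("32-1-222", "32-2-222", "64-2-222"), ]
  tabs <- extract_all_sets(coh, sub)
  expect_identical(sort(names(tabs)), sort(sub$name))
  for (tb in tabs) {
    expect_identical(tb$subject_id, sprintf("S%04d", 1:4))
    expect_identical(tb$label, vapply(coh, `[[`, integer(1), "label"))
    expect_identical(ncol(tb), 45L)
  }
  # distance-sharing consistency: direct extraction matches the batched path
  direct <- extract_features(coh[[2]]$volume, parameter_set(64, 2, "iso2mm"))
  expect_equal(unlist(tabs[["64-2-222"]][2, feature_names()]), direct,
               tolerance = 1e-12)
  # re-running is deterministic
  tabs2 <- extract_all_sets(coh, sub)
  expect_identical(tabs[["32-2-222"]], tabs2[["32-2-222"]])
})
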