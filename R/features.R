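#' The 43-feature registry
#'
#' Names of the 43 per-VOI biomarkers in canonical order, grouped as five
#' shape descriptors, seven first-order statistics and the GLCM (6),
#' GLRLM (11), NGLDM (3) and GLZLM (11) texture families.
#'
#' @return Character vector of 43 feature names.
#' @export
feature_names <- function() {
  c(
    "Volume_mL", "Volume_vx", "Surface_mm2", "Sphericity", "Compacity",
    "SUVmin", "SUVmean", "SUVmax", "SUVsd", "TVU", "Skewness", "Kurtosis",
    "GLCM_Homogeneity", "GLCM_Energy", "GLCM_Contrast", "GLCM_Correlation",
    "GLCM_Entropy", "GLCM_Dissimilarity",
    "GLRLM_SRE", "GLRLM_LRE", "GLRLM_LGRE", "GLRLM_HGRE", "GLRLM_SRLGE",
    "GLRLM_SRHGE", "GLRLM_LRLGE", "GLRLM_LRHGE", "GLRLM_GLNU", "GLRLM_RLNU",
    "GLRLM_RP",
    "NGLDM_Coarseness", "NGLDM_Contrast", "NGLDM_Busyness",
    "GLZLM_SZE", "GLZLM_LZE", "GLZLM_LGZE", "GLZLM_HGZE", "GLZLM_SZLGE",
    "GLZLM_SZHGE", "GLZLM_LZLGE", "GLZLM_LZHGE", "GLZLM_GLNUz", "GLZLM_ZLNU",
    "GLZLM_ZP"
  )
}

#' @rdname feature_names
#' @return `feature_families()`: a tibble mapping each feature to its
#'   family (`shape`, `first_order`, `glcm`, `glrlm`, `ngldm`, `glzlm`).
#' @export
feature_families <- function() {
  tibble(
    feature = feature_names(),
    family = rep(c("shape", "first_order", "glcm", "glrlm", "ngldm", "glzlm"),
                 times = c(5L, 7L, 6L, 11L, 3L, 11L))
  )
}

#' The eight conventional (non-textural) features
#'
#' The baseline feature list used by the conventional model series:
#' SUV statistics, total volume uptake and the shape descriptors.
#'
#' @return Character vector of 8 feature names.
#' @export
conventional_features <- function() {
  c("SUVmin", "SUVmean", "SUVmax", "TVU", "Volume_mL", "Surface_mm2",
    "Sphericity", "Compacity")
}

#' Shape descriptors of a VOI
#'
#' Volume in voxels and millilitres, surface area as the total area of
#' mask faces adjacent to background (exposed voxel faces, not a fitted
#' mesh), sphericity `pi^(1/3) (6V)^(2/3) / A` and the dimensionless
#' compacity `V / (sqrt(pi) A^(3/2))`. On digital masks the face-count
#' surface overestimates the continuous area, so the sphericity of a
#' voxelised sphere plateaus below 1 (around 0.67 for large radii).
#'
#' @param voi a [voi_mask()] (or logical array with `spacing` given).
#' @param spacing voxel spacing in mm, required when `voi` is a bare array.
#' @return Named numeric vector of 5 features.
#' @export
shape_features <- function(voi, spacing = NULL) {
  if (inherits(voi, "voi_mask")) {
    mask <- voi$mask; spacing <- voi$spacing
  } else {
    mask <- voi
    if (is.null(spacing)) abort("`spacing` is required for a bare mask.")
  }
  n <- sum(mask)
  if (n == 0L) abort("Empty mask.")
  dm <- dim(mask)
  shifted <- function(by, axis) {
    # mask translated by `by` along `axis`, FALSE outside the grid
    out <- array(FALSE, dm)
    lo <- max(1L, 1L + by); hi <- min(dm[axis], dm[axis] + by)
    if (lo > hi) return(out)  # single-slice axis: everything exposed
    src <- lo:hi
    from <- lapply(dm, seq_len); from[[axis]] <- src
    to <- lapply(dm, seq_len); to[[axis]] <- src - by
    out[to[[1]], to[[2]], to[[3]]] <- mask[from[[1]], from[[2]], from[[3]]]
    out
  }
  area <- 0
  for (a in 1:3) {
    face <- prod(spacing[-a])
    exposed <- sum(mask & !shifted(1L, a)) + sum(mask & !shifted(-1L, a))
    area <- area + exposed * face
  }
  V <- n * prod(spacing)           # mm^3
  c(
    Volume_mL = V / 1000,
    Volume_vx = as.numeric(n),
    Surface_mm2 = area,
    Sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / area,
    Compacity = V / (sqrt(pi) * area^1.5)
  )
}

#' First-order (histogram) features
#'
#' SUVmin, SUVmean, SUVmax and SUVsd (sample standard deviation) are
#' computed on the raw SUV values of the VOI; TVU (total volume uptake) is
#' SUVmean times the VOI volume in millilitres. Skewness and Kurtosis use
#' Fisher--Pearson moment definitions (Kurtosis non-excess) on the
#' discretised grey levels; a zero-variance VOI reports both as 0 by
#' convention.
#'
#' @param q a [quantize_voi()] object.
#' @param raw_suv numeric vector of raw SUV values inside the VOI, in mask
#'   order.
#' @return Named numeric vector of 7 features.
#' @export
histogram_features <- function(q, raw_suv) {
  stopifnot(inherits(q, "quantized_voi"))
  n <- sum(q$mask)
  if (length(raw_suv) != n) abort("`raw_suv` length must match the VOI size.")
  vol_mL <- n * prod(q$spacing) / 1000
  g <- as.numeric(q$levels[q$mask])
  m <- mean(g)
  m2 <- mean((g - m)^2)
  if (m2 > 0) {
    skew <- mean((g - m)^3) / m2^1.5
    kurt <- mean((g - m)^4) / m2^2
  } else {
    skew <- 0; kurt <- 0
  }
  mu <- mean(raw_suv)
  c(
    SUVmin = min(raw_suv), SUVmean = mu, SUVmax = max(raw_suv),
    SUVsd = if (n > 1) sd(raw_suv) else 0,
    TVU = mu * vol_mL,
    Skewness = skew, Kurtosis = kurt
  )
}

apply_voxel_policy <- function(scan, voxel_policy) {
  switch(voxel_policy,
    default = scan,
    iso1mm = resample_isotropic(scan, 1),
    iso2mm = resample_isotropic(scan, 2),
    abort(sprintf("Unknown voxel policy: %s", voxel_policy))
  )
}

side_feature_vector <- function(suv, voi, n_grey, distance, bounds = c(0, 10)) {
  raw <- suv[voi$mask]
  q <- quantize_voi(suv, voi$mask, voi$spacing, n_grey, bounds)
  c(
    shape_features(voi),
    histogram_features(q, raw),
    glcm_features(q, distance),
    glrlm_features(q),
    ngldm_features(q),
    glzlm_features(q)
  )
}

#' Extract the 43-feature vector for one scan
#'
#' Applies the full per-scan pipeline for one pre-processing parameter
#' set: resample the volume per the voxel policy, segment each side with
#' the 40\% SUVmax isocontour (largest component kept), discretise, and
#' compute all six feature families per side; the left- and right-side
#' vectors are averaged entrywise into a single per-subject vector.
#'
#' @param scan a [scan_volume()].
#' @param params a [parameter_set()].
#' @param fraction isocontour fraction, default 0.40.
#' @return Named numeric vector of 43 features.
#' @export
extract_features <- function(scan, params, fraction = 0.40) {
  stopifnot(inherits(scan, "scan_volume"), inherits(params, "parameter_set"))
  v <- apply_voxel_policy(scan, params$voxel_policy)
  seg <- segment_striatum(v, fraction)
  vecs <- lapply(seg, function(voi) {
    side_feature_vector(v$suv, voi, params$n_grey_levels,
                        params$glcm_distance, params$bounds)
  })
  out <- (vecs$left + vecs$right) / 2
  out[feature_names()]
}

# Shared-work extraction across several parameter sets for one scan:
# resampling and segmentation depend only on the voxel policy, the
# non-GLCM families additionally on the grey-level count, and only the
# GLCM family on the co-occurrence distance.
extract_scan_sets <- function(scan, sets_tbl, fraction = 0.40) {
  out <- list()
  for (pol in unique(sets_tbl$voxel_policy)) {
    sub_pol <- sets_tbl[sets_tbl$voxel_policy == pol, ]
    v <- apply_voxel_policy(scan, pol)
    seg <- segment_striatum(v, fraction)
    for (gl in unique(sub_pol$n_grey_levels)) {
      sub_gl <- sub_pol[sub_pol$n_grey_levels == gl, ]
      base <- lapply(seg, function(voi) {
        raw <- v$suv[voi$mask]
        q <- quantize_voi(v$suv, voi$mask, voi$spacing, gl)
        list(
          q = q,
          fixed = c(shape_features(voi), histogram_features(q, raw),
                    glrlm_features(q), ngldm_features(q), glzlm_features(q))
        )
      })
      for (d in unique(sub_gl$glcm_distance)) {
        vecs <- lapply(base, function(b) c(b$fixed, glcm_features(b$q, d)))
        avg <- (vecs$left + vecs$right) / 2
        nm <- sub_gl$name[sub_gl$glcm_distance == d][1]
        out[[nm]] <- avg[feature_names()]
      }
    }
  }
  out
}

#' Extract a feature table for a cohort
#'
#' One row per subject with its binary label and the 43 bilaterally
#' averaged features. Subjects whose extraction fails (e.g. unsegmentable
#' scans) are dropped with a warning naming the subject, never silently.
#'
#' @param cohort a list of labelled scans from [generate_cohort()], or any
#'   list whose elements have `volume` (a `scan_volume`), `label` and
#'   optionally `subject_id`.
#' @param params a [parameter_set()].
#' @param fraction isocontour fraction.
#' @return A tibble with columns `subject_id`, `label` and the 43 features.
#' @export
extract_table <- function(cohort, params, fraction = 0.40) {
  tabs <- extract_all_sets(cohort, sets = tibble_one_set(params),
                           fraction = fraction)
  tabs[[1]]
}

tibble_one_set <- function(params) {
  tibble(
    name = params$name,
    n_grey_levels = params$n_grey_levels,
    glcm_distance = params$glcm_distance,
    voxel_policy = params$voxel_policy,
    params = list(params)
  )
}

#' Extract feature tables for many parameter sets
#'
#' Runs the extraction for every row of `sets` (default: the full
#' 21-combination grid), sharing segmentation and texture-matrix work
#' between sets that differ only in co-occurrence distance.
#'
#' @inheritParams extract_table
#' @param sets a tibble as returned by [parameter_grid()] (or a subset of
#'   its rows).
#' @return A named list of feature tibbles, keyed by compact set name.
#' @export
extract_all_sets <- function(cohort, sets = parameter_grid(), fraction = 0.40) {
  if (length(cohort) == 0L) abort("`cohort` must be non-empty.")
  ids <- vapply(seq_along(cohort), function(i) {
    sid <- cohort[[i]]$subject_id
    if (is.null(sid)) sprintf("S%03d", i) else as.character(sid)
  }, character(1))
  labels <- vapply(cohort, function(s) as.integer(s$label), integer(1))
  rows <- vector("list", length(cohort))
  ok <- rep(TRUE, length(cohort))
  for (i in seq_along(cohort)) {
    rows[[i]] <- tryCatch(
      extract_scan_sets(cohort[[i]]$volume, sets, fraction),
      error = function(e) {
        warn(sprintf("Dropping subject %s: %s", ids[i], conditionMessage(e)))
        NULL
      }
    )
    if (is.null(rows[[i]])) ok[i] <- FALSE
  }
  rows <- rows[ok]; ids <- ids[ok]; labels <- labels[ok]
  if (length(rows) == 0L) abort("Extraction failed for every subject.")
  out <- list()
  for (nm in sets$name) {
    mat <- do.call(rbind, lapply(rows, `[[`, nm))
    out[[nm]] <- dplyr::bind_cols(
      tibble(subject_id = ids, label = labels),
      as_tibble(mat)
    )
  }
  out
}
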