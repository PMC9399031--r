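#' Specification of a synthetic striatal phantom
#'
#' Describes one synthetic FDOPA scan: a uniform background with two
#' comma-shaped striatal uptake foci (per side, a caudate-head ellipsoid
#' fused with an elongated putaminal ellipsoid), optionally "denervated".
#' Axis conventions follow [scan_volume()]: axis 1 left--right, axis 2
#' antero--posterior (high indices anterior), axis 3 inferior--superior.
#'
#' Denervation with severity `s` scales the putaminal uptake down by
#' `0.45 * s` (the caudate by `0.3 * s`, reflecting its relative
#' sparing; the caps reflect FDOPA's compensatory under-reading of
#' denervation) and, on any denervated side, tilts the putamen along the
#' antero--posterior axis: a linear fall-off reaching
#' `gradient_strength * (0.4 + 0.6 s)` at the posterior tip with a mild
#' (7\% of the same factor) compensatory upregulation at the anterior
#' tip. Posterior-predominant loss and anterior compensation mark the
#' disease from its earliest stage, hence the severity floor of 0.4 on
#' the tilt. `asymmetry` shifts severity between sides: the left side
#' carries the full severity `s`, the right
#' `max(0, s * (1 - asymmetry))`, i.e. `asymmetry = 1` is strictly
#' unilateral (left) disease at severity `s`. A Gaussian point-spread blur of
#' `psf_fwhm_mm` is applied to the noiseless field, then additive Gaussian
#' voxel noise (`noise_sd`, clipped at zero) last.
#'
#' The default calibration (peak SUV, PSF, geometry) was tuned once so
#' that a default cohort reproduces the reference population statistics of
#' the segmented striatum (mean SUVmean approximately 2.61, SUVmax 4.56,
#' VOI volume 12.9 mL).
#'
#' @param grid_shape integer triple of voxel counts.
#' @param voxel_spacing_mm positive triple, defaults to the native PET grid
#'   0.709 x 0.709 x 2.00 mm.
#' @param background_suv uniform background SUV.
#' @param striatal_peak_suv pre-blur SUV of the striatal templates.
#' @param denervation_severity overall severity in `[0, 1]`; 0 = normal.
#' @param gradient_strength antero--posterior fall-off in `[0, 1]`.
#' @param asymmetry left/right severity imbalance in `[0, 1]`.
#' @param psf_fwhm_mm full width at half maximum of the PSF blur (mm).
#' @param noise_sd standard deviation of additive SUV noise.
#' @param template_scale positive length-3 multiplier on the template
#'   semi-axes, the anatomical size of this subject's striatum relative
#'   to the population template. Cohorts draw it per subject so normals
#'   overlap positives on shape and first-order features, as real
#'   populations do.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(104L, 96L, 28L),
                         voxel_spacing_mm = c(0.709, 0.709, 2.00),
                         background_suv = 1.15,
                         striatal_peak_suv = 5.2,
                         denervation_severity = 0,
                         gradient_strength = 0,
                         asymmetry = 0,
                         psf_fwhm_mm = 8,
                         noise_sd = 0.15,
                         template_scale = c(1, 1, 1)) {
  grid_shape <- as.integer(grid_shape)
  voxel_spacing_mm <- as.numeric(voxel_spacing_mm)
  if (length(grid_shape) != 3L || any(is.na(grid_shape)) || any(grid_shape < 2L)) {
    abort("`grid_shape` must be three integers >= 2.")
  }
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0)) {
    abort("`voxel_spacing_mm` must be three positive numbers.")
  }
  for (nmv in c("denervation_severity", "gradient_strength", "asymmetry")) {
    v <- get(nmv)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a single number in [0, 1].", nmv))
    }
  }
  if (background_suv <= 0 || striatal_peak_suv <= background_suv) {
    abort("Need 0 < background_suv < striatal_peak_suv.")
  }
  if (psf_fwhm_mm < 0 || noise_sd < 0) {
    abort("`psf_fwhm_mm` and `noise_sd` must be non-negative.")
  }
  template_scale <- as.numeric(template_scale)
  if (length(template_scale) == 1L) template_scale <- rep(template_scale, 3L)
  if (length(template_scale) != 3L || any(template_scale <= 0)) {
    abort("`template_scale` must be one or three positive numbers.")
  }
  spec <- structure(
    list(
      grid_shape = grid_shape, voxel_spacing_mm = voxel_spacing_mm,
      background_suv = background_suv, striatal_peak_suv = striatal_peak_suv,
      denervation_severity = denervation_severity,
      gradient_strength = gradient_strength, asymmetry = asymmetry,
      psf_fwhm_mm = psf_fwhm_mm, noise_sd = noise_sd,
      template_scale = template_scale
    ),
    class = "phantom_spec"
  )
  check_grid_fits(spec)
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %dx%dx%d @ %.3gx%.3gx%.3g mm, bg %.2f, peak %.2f\n",
    x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
    x$voxel_spacing_mm[1], x$voxel_spacing_mm[2], x$voxel_spacing_mm[3],
    x$background_suv, x$striatal_peak_suv
  ))
  cat(sprintf("  severity %.2f, gradient %.2f, asymmetry %.2f, PSF %.1f mm, noise sd %.2f\n",
              x$denervation_severity, x$gradient_strength, x$asymmetry,
              x$psf_fwhm_mm, x$noise_sd))
  invisible(x)
}

# Fixed striatal template geometry (mm, relative to grid centre).
# Semi-axes/offsets were frozen during calibration against the reference
# segmented-VOI statistics; only the printed population statistics
# constrain the geometry.
striatal_geometry <- function() {
  list(
    putamen = list(centre = c(21, -3, 0),   semi = c(8.8, 20, 10)),
    caudate = list(centre = c(12.5, 13, 3), semi = c(7, 10.8, 8.6)),
    taper = 0.45  # linear fall-off of uptake from core to ellipsoid edge
  )
}

check_grid_fits <- function(spec, margin_mm = 2) {
  geo <- striatal_geometry()
  geo$taper <- NULL
  half <- spec$grid_shape * spec$voxel_spacing_mm / 2
  for (st in geo) {
    need <- abs(st$centre) + st$semi * spec$template_scale + margin_mm
    if (any(need > half)) {
      abort(paste0(
        "Grid too small for the striatal templates: need half-extents of at ",
        "least (", paste(sprintf("%.1f", need), collapse = ", "), ") mm."
      ))
    }
  }
  invisible(TRUE)
}

# Separable Gaussian blur with zero padding and edge renormalisation.
gaussian_blur <- function(arr, sigma_vox) {
  dm <- dim(arr)
  norm_axes <- vector("list", 3L)
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s < 1e-6) { norm_axes[[a]] <- rep(1, dm[a]); next }
    r <- max(1L, as.integer(ceiling(3 * s)))
    w <- exp(-0.5 * ((-r:r) / s)^2)
    w <- w / sum(w)
    n <- dm[a]
    # convolution matrix applied along axis `a` via permutation to axis 1
    perm <- c(a, setdiff(1:3, a))
    x <- aperm(arr, perm)
    dim(x) <- c(n, prod(dm[perm[2:3]]))
    out <- matrix(0, n, ncol(x))
    ones <- numeric(n)
    for (k in -r:r) {
      src <- max(1L, 1L + k):min(n, n + k)
      dst <- src - k
      wk <- w[k + r + 1L]
      out[dst, ] <- out[dst, ] + wk * x[src, , drop = FALSE]
      ones[dst] <- ones[dst] + wk
    }
    dim(out) <- dm[perm]
    arr <- aperm(out, order(perm))
    norm_axes[[a]] <- ones
  }
  norm <- outer(outer(norm_axes[[1]], norm_axes[[2]]), norm_axes[[3]])
  dim(norm) <- dm
  arr / norm
}

noiseless_field <- function(spec) {
  dm <- spec$grid_shape; sp <- spec$voxel_spacing_mm
  xs <- (seq_len(dm[1]) - (dm[1] + 1) / 2) * sp[1]
  ys <- (seq_len(dm[2]) - (dm[2] + 1) / 2) * sp[2]
  zs <- (seq_len(dm[3]) - (dm[3] + 1) / 2) * sp[3]
  geo <- striatal_geometry()
  taper <- geo$taper; geo$taper <- NULL
  s <- spec$denervation_severity
  sev <- c(left = s, right = max(0, s * (1 - spec$asymmetry)))
  amp <- spec$striatal_peak_suv - spec$background_suv
  excess <- array(0, dm)
  for (side in c(-1, 1)) {
    side_name <- if (side < 0) "left" else "right"
    sv <- sev[[side_name]]
    for (st_name in names(geo)) {
      st <- geo[[st_name]]
      semi <- st$semi * spec$template_scale
      cx <- side * st$centre[1]; cy <- st$centre[2]; cz <- st$centre[3]
      qx <- ((xs - cx) / semi[1])^2
      qy <- ((ys - cy) / semi[2])^2
      qz <- ((zs - cz) / semi[3])^2
      Q <- outer(outer(qx, qy, `+`), qz, `+`)
      shape <- (Q <= 1) * (1 - taper * Q)  # peaked core, tapered edge
      if (st_name == "putamen") {
        # uniform loss capped at 45%: FDOPA under-reads denervation due
        # to compensatory decarboxylase upregulation
        base <- amp * (1 - 0.45 * sv)
        # antero-posterior tilt whenever this side is denervated:
        # posterior fall-off at full gradient strength plus a mild
        # compensatory anterior upregulation (posterior-predominant loss
        # and anterior compensation both mark the disease early)
        frac <- pmin(1, pmax(0, (cy + semi[2] - ys) / (2 * semi[2])))
        # present from the earliest stage (floor 0.4), deepening with
        # severity
        g_eff <- spec$gradient_strength * (sv > 0) * (0.4 + 0.6 * sv)
        a_y <- base * pmax(0, 1 + g_eff * (0.07 - 1.07 * frac))
        contrib <- shape * rep(rep(a_y, each = dm[1]), times = dm[3])
      } else {
        contrib <- shape * (amp * (1 - 0.3 * sv))
      }
      excess <- pmax(excess, contrib)
    }
  }
  spec$background_suv + excess
}

#' Generate one synthetic striatal scan
#'
#' Builds the noiseless uptake field described by `spec`, applies the
#' Gaussian PSF blur, then adds voxel noise (clipped at zero). The result
#' is deterministic for a fixed `(spec, seed)` pair.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the voxel noise.
#' @return A `labelled_scan`: list with `volume` (a [scan_volume()]),
#'   `label` (1 when `denervation_severity > 0`) and `truth` (the spec).
#' @export
generate_phantom <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  field <- noiseless_field(spec)
  sigma_vox <- spec$psf_fwhm_mm / (2 * sqrt(2 * log(2))) / spec$voxel_spacing_mm
  field <- gaussian_blur(field, sigma_vox)
  if (spec$noise_sd > 0) {
    noise <- with_seed(seed, rnorm(length(field), 0, spec$noise_sd))
    field <- field + noise
    field[field < 0] <- 0
  }
  dim(field) <- spec$grid_shape
  structure(
    list(volume = scan_volume(field, spec$voxel_spacing_mm),
         label = as.integer(spec$denervation_severity > 0),
         truth = spec,
         subject_id = NULL),
    class = "labelled_scan"
  )
}

#' Generate a labelled phantom cohort
#'
#' Draws `round(n * positive_fraction)` "denervated" subjects (severity,
#' gradient and asymmetry sampled uniformly from the given ranges) and the
#' rest normal, with per-subject global-uptake variability (log-normal,
#' mean-preserving, coefficient of variation `subject_sd`). Every subject
#' receives its own noise seed derived from `seed`, so the cohort is fully
#' reproducible and label order is a seeded permutation.
#'
#' @param n number of subjects (> 0).
#' @param positive_fraction fraction of denervated subjects, default 0.39
#'   (the reference positive/negative ratio).
#' @param spec baseline [phantom_spec()] (its own severity fields are
#'   ignored; they are drawn per subject).
#' @param seed master integer seed.
#' @param severity_range,gradient_range,asymmetry_range uniform sampling
#'   ranges for positive subjects; the lower severity bound of 0.15
#'   includes early, near-subclinical denervation so the class
#'   distributions of conventional features overlap substantially.
#' @param subject_sd between-subject log-normal uptake variability.
#' @param shape_sd per-axis log-normal variability of the striatal
#'   template size (anatomical heterogeneity).
#' @param psf_sd log-normal variability of the effective resolution;
#'   0 by default since reconstruction resolution is fixed within one
#'   scanner protocol (set > 0 to emulate motion-degraded scans).
#' @return A list of `labelled_scan` objects with `subject_id` set.
#' @export
generate_cohort <- function(n, positive_fraction = 0.39,
                            spec = phantom_spec(), seed = 1L,
                            severity_range = c(0.15, 0.9),
                            gradient_range = c(0.6, 1),
                            asymmetry_range = c(0, 0.4),
                            subject_sd = 0.2, shape_sd = 0.08,
                            psf_sd = 0) {
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) abort("`n` must be a positive integer.")
  if (positive_fraction < 0 || positive_fraction > 1) {
    abort("`positive_fraction` must lie in [0, 1].")
  }
  n_pos <- round(n * positive_fraction)
  draws <- with_seed(seed, {
    list(
      labels = sample(c(rep(1L, n_pos), rep(0L, n - n_pos))),
      sev = runif(n, severity_range[1], severity_range[2]),
      grad = runif(n, gradient_range[1], gradient_range[2]),
      asym = runif(n, asymmetry_range[1], asymmetry_range[2]),
      scale = exp(rnorm(n, 0, subject_sd) - subject_sd^2 / 2),
      shape = matrix(exp(rnorm(3L * n, 0, shape_sd)), n, 3L),
      psf = exp(rnorm(n, 0, psf_sd)),
      seeds = sample.int(2147483646L, n)
    )
  })
  lapply(seq_len(n), function(i) {
    pos <- draws$labels[i] == 1L
    spec_i <- phantom_spec(
      grid_shape = spec$grid_shape,
      voxel_spacing_mm = spec$voxel_spacing_mm,
      background_suv = spec$background_suv * draws$scale[i],
      striatal_peak_suv = spec$striatal_peak_suv * draws$scale[i],
      denervation_severity = if (pos) draws$sev[i] else 0,
      gradient_strength = if (pos) draws$grad[i] else 0,
      asymmetry = if (pos) draws$asym[i] else 0,
      psf_fwhm_mm = spec$psf_fwhm_mm * draws$psf[i],
      noise_sd = spec$noise_sd,
      template_scale = spec$template_scale * draws$shape[i, ]
    )
    out <- generate_phantom(spec_i, draws$seeds[i])
    out$subject_id <- sprintf("S%04d", i)
    out
  })
}

#' Cohort manifest
#'
#' @param cohort list of labelled scans from [generate_cohort()].
#' @return A tibble with subject id, label and the true generating
#'   parameters.
#' @export
cohort_manifest <- function(cohort) {
  tibble(
    subject_id = vapply(seq_along(cohort), function(i) {
      sid <- cohort[[i]]$subject_id
      if (is.null(sid)) sprintf("S%04d", i) else sid
    }, character(1)),
    label = vapply(cohort, function(s) as.integer(s$label), integer(1)),
    severity = vapply(cohort, function(s) s$truth$denervation_severity, numeric(1)),
    gradient = vapply(cohort, function(s) s$truth$gradient_strength, numeric(1)),
    asymmetry = vapply(cohort, function(s) s$truth$asymmetry, numeric(1)),
    peak_suv = vapply(cohort, function(s) s$truth$striatal_peak_suv, numeric(1))
  )
}

#' Synthetic feature table with planted class effects
#'
#' Generates `n_features` standardised-normal features for `n` subjects
#' with a binary label; features listed in `planted` are shifted by their
#' effect size (in SD units) in the positive class, all other features are
#' label-independent noise. Optional equicorrelation between features via
#' a shared latent factor.
#'
#' @param n number of subjects; `n = 0` yields an empty table with header.
#' @param n_features number of features.
#' @param planted list of `c(index, effect)` pairs (or a two-column
#'   matrix); indices must not exceed `n_features`.
#' @param seed integer seed.
#' @param positive_fraction fraction of positive labels.
#' @param feature_cor equicorrelation between features in `[0, 1)`.
#' @return A tibble with `subject_id`, `label` and features
#'   `feature_01`, ...
#' @export
generate_feature_table <- function(n, n_features = 20L, planted = list(),
                                   seed = 1L, positive_fraction = 0.5,
                                   feature_cor = 0) {
  n <- as.integer(n); n_features <- as.integer(n_features)
  if (n < 0L || n_features < 1L) abort("`n` >= 0 and `n_features` >= 1 required.")
  if (is.matrix(planted)) planted <- asplit(planted, 1)
  idx <- vapply(planted, function(p) as.integer(p[1]), integer(1))
  eff <- vapply(planted, function(p) as.numeric(p[2]), numeric(1))
  if (length(idx) && (any(idx < 1L) | any(idx > n_features))) {
    abort("Planted feature indices must lie in 1..n_features.")
  }
  nms <- sprintf("feature_%02d", seq_len(n_features))
  if (n == 0L) {
    empty <- c(list(subject_id = character(0), label = integer(0)),
               setNames(rep(list(numeric(0)), n_features), nms))
    return(as_tibble(empty))
  }
  n_pos <- round(n * positive_fraction)
  out <- with_seed(seed, {
    label <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    X <- matrix(rnorm(n * n_features), n, n_features)
    if (feature_cor > 0) {
      z <- rnorm(n)
      X <- sqrt(1 - feature_cor) * X + sqrt(feature_cor) * z
    }
    for (k in seq_along(idx)) {
      X[, idx[k]] <- X[, idx[k]] + eff[k] * label
    }
    colnames(X) <- nms
    dplyr::bind_cols(
      tibble(subject_id = sprintf("S%04d", seq_len(n)), label = label),
      as_tibble(X)
    )
  })
  out
}

#' Synthetic clinical item table
#'
#' Emulates a shortened clinical rating scale: 25 items scored 0--4
#' (maximum total 100), weakly associated with the label through a small
#' logit shift, with subject-level random severity and missing values
#' injected completely at random.
#'
#' @param n number of subjects.
#' @param effect logit shift of per-item expected score in positives;
#'   default small, emulating a near-uninformative clinical signal.
#' @param missing_rate probability in `[0, 1)` that an item is missing.
#' @param seed integer seed.
#' @param positive_fraction fraction of positive labels.
#' @return A tibble with `subject_id`, `label` and items `item_01` ...
#'   `item_25` (NA = missing).
#' @export
generate_clinical_table <- function(n, effect = 0.1, missing_rate = 0.05,
                                    seed = 1L, positive_fraction = 0.39) {
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) abort("`n` must be a positive integer.")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).")
  }
  n_items <- 25L
  with_seed(seed, {
    n_pos <- round(n * positive_fraction)
    label <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    u <- rnorm(n, 0, 0.6)
    base <- qlogis(0.22)  # mean item score about 0.88/4 in negatives
    M <- matrix(NA_integer_, n, n_items)
    for (j in seq_len(n_items)) {
      item_shift <- rnorm(1, 0, 0.3)
      p <- plogis(base + item_shift + effect * label + u)
      M[, j] <- rbinom(n, 4L, p)
    }
    if (missing_rate > 0) {
      M[matrix(runif(n * n_items) < missing_rate, n, n_items)] <- NA_integer_
    }
    colnames(M) <- sprintf("item_%02d", seq_len(n_items))
    dplyr::bind_cols(
      tibble(subject_id = sprintf("S%04d", seq_len(n)), label = label),
      as_tibble(M)
    )
  })
}
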