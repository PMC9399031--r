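#' Quantized volume of interest
#'
#' Applies absolute discretisation (see [discretise()]) to the SUV values
#' inside a VOI mask. The result stores an integer grey-level array with
#' `NA` outside the mask, which is the input to all texture-matrix
#' builders.
#'
#' @param suv numeric 3D array of SUV values.
#' @param mask logical 3D array (the VOI), same dimensions.
#' @param spacing voxel spacing in mm.
#' @param n_levels number of grey levels.
#' @param bounds absolute discretisation bounds, default SUV 0--10.
#' @return A `quantized_voi` object.
#' @export
quantize_voi <- function(suv, mask, spacing, n_levels, bounds = c(0, 10)) {
  stopifnot(is.array(suv), is.logical(mask), all(dim(suv) == dim(mask)))
  if (!any(mask)) abort("Empty VOI mask.")
  # crop to the mask bounding box: texture matrices only pair in-mask
  # voxels, so trimming background changes nothing and saves most work
  idx <- which(mask, arr.ind = TRUE)
  rng <- lapply(1:3, function(a) min(idx[, a]):max(idx[, a]))
  suv <- suv[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  mask <- mask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  lv <- array(NA_integer_, dim(suv))
  lv[mask] <- discretise(suv[mask], bounds, n_levels)
  structure(
    list(levels = lv, n_levels = as.integer(n_levels),
         spacing = as.numeric(spacing), mask = mask),
    class = "quantized_voi"
  )
}

# The 13 unique 3D directions (one representative per +/- pair).
directions_13 <- function() {
  offs <- connectivity_offsets(26L)
  offs[order(rowSums(abs(offs)), offs[, 1], offs[, 2], offs[, 3]), ,
       drop = FALSE]
}

# ---- GLCM ------------------------------------------------------------------

glcm_counts <- function(levels, n, offset) {
  rg <- shift_ranges(dim(levels), offset)
  if (is.null(rg)) return(NULL)
  a <- levels[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
  b <- levels[rg[[1]] + offset[1], rg[[2]] + offset[2], rg[[3]] + offset[3],
              drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  counts <- tabulate(a[ok] + n * (b[ok] - 1L), nbins = n * n)
  C <- matrix(counts, n, n)
  C + t(C)  # count each pair in both orders (symmetric matrix)
}

#' Grey-level co-occurrence matrix for one direction
#'
#' Counts all ordered in-mask voxel pairs separated by
#' `distance * direction` (both orientations), normalised to sum to one,
#' and returns the matrix together with its row/column marginal means and
#' standard deviations.
#'
#' @param q a [quantize_voi()] object.
#' @param direction integer length-3 vector with components in -1, 0, 1,
#'   not all zero.
#' @param distance co-occurrence distance in voxels (1, 2 or 5).
#' @return A `glcm_matrix` object with elements `P`, `mu_i`, `mu_j`,
#'   `sigma_i`, `sigma_j`. Errors with class `striatomics_empty_glcm` when
#'   the VOI admits no pair in this direction.
#' @export
glcm_matrix <- function(q, direction, distance = 1L) {
  stopifnot(inherits(q, "quantized_voi"))
  direction <- as.integer(direction)
  if (length(direction) != 3L || all(direction == 0L) ||
      any(abs(direction) > 1L)) {
    abort("`direction` must be a nonzero triple with components in {-1,0,1}.")
  }
  C <- glcm_counts(q$levels, q$n_levels, direction * as.integer(distance))
  if (is.null(C)) {
    abort("No voxel pair in this direction.", class = "striatomics_empty_glcm")
  }
  P <- C / sum(C)
  i <- seq_len(q$n_levels)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mu_i <- sum(i * pi_); mu_j <- sum(i * pj_)
  structure(
    list(P = P,
         mu_i = mu_i, mu_j = mu_j,
         sigma_i = sqrt(sum((i - mu_i)^2 * pi_)),
         sigma_j = sqrt(sum((i - mu_j)^2 * pj_))),
    class = "glcm_matrix"
  )
}

glcm_features_one <- function(P) {
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  d <- abs(i - j)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  lev <- seq_len(n)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj_)
  s_i <- sqrt(sum((lev - mu_i)^2 * pi_)); s_j <- sqrt(sum((lev - mu_j)^2 * pj_))
  corr <- if (s_i * s_j == 0) 1 else {
    sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j)
  }
  pos <- P > 0
  c(
    Homogeneity   = sum(P / (1 + d)),
    Energy        = sum(P^2),
    Contrast      = sum(d^2 * P),
    Correlation   = corr,
    Entropy       = -sum(P[pos] * log2(P[pos])),
    Dissimilarity = sum(d * P)
  )
}

#' GLCM texture features averaged over 13 directions
#'
#' Computes the six co-occurrence features (Homogeneity, Energy, Contrast,
#' Correlation, Entropy, Dissimilarity) per direction over the 13 unique
#' 3D directions and averages feature values over the directions with at
#' least one voxel pair. Correlation follows
#' `sum_ij (i - mu_i)(j - mu_j) P(i,j) / (sigma_i sigma_j)`; a constant
#' VOI (zero marginal variance) is assigned Correlation 1 by convention,
#' since a constant field is perfectly linearly dependent.
#'
#' @inheritParams glcm_matrix
#' @param directions integer matrix of direction triples (one per row);
#'   defaults to the 13 unique 3D directions.
#' @return Named numeric vector of 6 features (names `GLCM_*`).
#' @export
glcm_features <- function(q, distance = 1L, directions = NULL) {
  dirs <- if (is.null(directions)) directions_13() else
    matrix(as.integer(directions), ncol = 3)
  acc <- NULL; ndir <- 0L
  for (k in seq_len(nrow(dirs))) {
    C <- glcm_counts(q$levels, q$n_levels, dirs[k, ] * as.integer(distance))
    if (is.null(C)) next
    f <- glcm_features_one(C / sum(C))
    acc <- if (is.null(acc)) f else acc + f
    ndir <- ndir + 1L
  }
  if (ndir == 0L) abort("VOI too small: no pair in any of the 13 directions.")
  out <- acc / ndir
  names(out) <- paste0("GLCM_", names(out))
  out
}

# ---- GLRLM -----------------------------------------------------------------

# Run-length counting along one direction: voxels are grouped by the line
# they lie on (cross-product invariants), ordered along the line, and runs
# are breaks in (line, position step, grey level).
glrlm_matrix_one <- function(coords, g, dir) {
  t_ <- coords %*% dir
  k1 <- coords[, 1] * dir[2] - coords[, 2] * dir[1]
  k2 <- coords[, 1] * dir[3] - coords[, 3] * dir[1]
  k3 <- coords[, 2] * dir[3] - coords[, 3] * dir[2]
  key <- ((k1 + 2048) * 4096 + (k2 + 2048)) * 4096 + (k3 + 2048)
  ord <- order(key, t_)
  key <- key[ord]; t_ <- t_[ord]; go <- g[ord]
  step <- sum(dir^2)
  m <- length(go)
  same <- c(FALSE, key[-1] == key[-m] & t_[-1] == t_[-m] + step &
                   go[-1] == go[-m])
  run_id <- cumsum(!same)
  run_len <- tabulate(run_id)
  run_grey <- go[!same]
  list(grey = run_grey, len = run_len)
}

rl_features <- function(grey, len, n_levels, n_vox, zone = FALSE) {
  Nr <- length(grey)
  gi2 <- grey^2; li2 <- len^2
  gl_tab <- tabulate(grey, n_levels)
  len_tab <- tabulate(len)
  vals <- c(
    SRE   = sum(1 / li2) / Nr,
    LRE   = sum(li2) / Nr,
    LGRE  = sum(1 / gi2) / Nr,
    HGRE  = sum(gi2) / Nr,
    SRLGE = sum(1 / (gi2 * li2)) / Nr,
    SRHGE = sum(gi2 / li2) / Nr,
    LRLGE = sum(li2 / gi2) / Nr,
    LRHGE = sum(gi2 * li2) / Nr,
    GLNU  = sum(gl_tab^2) / Nr,
    RLNU  = sum(len_tab^2) / Nr,
    RP    = Nr / n_vox
  )
  if (zone) {
    names(vals) <- c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE",
                     "LZLGE", "LZHGE", "GLNUz", "ZLNU", "ZP")
  }
  vals
}

#' Run-length texture features averaged over 13 directions
#'
#' Counts maximal runs of equal grey level along each of the 13 unique 3D
#' directions (runs are confined to the VOI mask) and averages the 11
#' run-length features over directions.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of 11 features (names `GLRLM_*`).
#' @export
glrlm_features <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  n_vox <- sum(q$mask)
  if (n_vox < 2L) abort("VOI too small for run-length features.")
  coords <- which(q$mask, arr.ind = TRUE)
  g <- q$levels[q$mask]
  dirs <- directions_13()
  acc <- 0
  for (k in seq_len(nrow(dirs))) {
    runs <- glrlm_matrix_one(coords, g, dirs[k, ])
    acc <- acc + rl_features(runs$grey, runs$len, q$n_levels, n_vox)
  }
  out <- acc / nrow(dirs)
  names(out) <- paste0("GLRLM_", names(out))
  out
}

# ---- NGLDM -----------------------------------------------------------------

#' Neighbourhood grey-level difference features
#'
#' Coarseness, Contrast and Busyness computed from the 26-neighbourhood
#' grey-level difference matrix: for each VOI voxel with at least one
#' in-mask neighbour, the absolute difference between its grey level and
#' the mean grey level of its in-mask neighbours is accumulated per grey
#' level. Degenerate cases (constant VOI) return Contrast and Busyness 0,
#' and Coarseness is capped at 1e6.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of 3 features (names `NGLDM_*`).
#' @export
ngldm_features <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  lv <- q$levels
  dm <- dim(lv)
  val0 <- ifelse(is.na(lv), 0, lv)
  in_mask <- !is.na(lv)
  half <- connectivity_offsets(26L)
  offs <- rbind(half, -half)
  nsum <- array(0, dm); ncnt <- array(0L, dm)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    rg <- shift_ranges(dm, o)
    if (is.null(rg)) next
    nsum[rg[[1]], rg[[2]], rg[[3]]] <- nsum[rg[[1]], rg[[2]], rg[[3]]] +
      val0[rg[[1]] + o[1], rg[[2]] + o[2], rg[[3]] + o[3], drop = FALSE]
    ncnt[rg[[1]], rg[[2]], rg[[3]]] <- ncnt[rg[[1]], rg[[2]], rg[[3]]] +
      in_mask[rg[[1]] + o[1], rg[[2]] + o[2], rg[[3]] + o[3], drop = FALSE]
  }
  use <- in_mask & ncnt > 0L
  if (!any(use)) abort("VOI too small for neighbourhood difference features.")
  g <- lv[use]
  abar <- nsum[use] / ncnt[use]
  diffs <- abs(g - abar)
  N <- length(g)
  n_i <- tabulate(g, q$n_levels)
  s_i <- vapply(seq_len(q$n_levels),
                function(i) sum(diffs[g == i]), numeric(1))
  p_i <- n_i / N
  present <- which(p_i > 0)
  Ng <- length(present)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6
  if (Ng > 1) {
    ii <- matrix(present, Ng, Ng); jj <- t(ii)
    pp <- outer(p_i[present], p_i[present])
    contrast <- sum(pp * (ii - jj)^2) / (Ng * (Ng - 1)) * sum(s_i) / N
    ipi <- present * p_i[present]
    busy_den <- sum(abs(outer(ipi, ipi, `-`)))
    busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  } else {
    contrast <- 0; busyness <- 0
  }
  c(NGLDM_Coarseness = coarseness, NGLDM_Contrast = contrast,
    NGLDM_Busyness = busyness)
}

# ---- GLZLM -----------------------------------------------------------------

# Zones: 26-connected components of equal grey level within the VOI.
glzlm_zones <- function(q) {
  lv <- q$levels
  dm <- dim(lv)
  nvox <- sum(q$mask)
  idmap <- array(0L, dm)
  idmap[q$mask] <- seq_len(nvox)
  offs <- connectivity_offsets(26L)
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    rg <- shift_ranges(dm, o)
    if (is.null(rg)) next
    a <- idmap[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
    b <- idmap[rg[[1]] + o[1], rg[[2]] + o[2], rg[[3]] + o[3], drop = FALSE]
    la <- lv[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
    lb <- lv[rg[[1]] + o[1], rg[[2]] + o[2], rg[[3]] + o[3], drop = FALSE]
    ok <- a > 0L & b > 0L & !is.na(la) & !is.na(lb) & la == lb
    if (any(ok)) edges[[k]] <- rbind(a[ok], b[ok])
  }
  edges <- do.call(cbind, edges[!vapply(edges, is.null, logical(1))])
  g <- igraph::make_empty_graph(n = nvox, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)
  grey_by_vox <- lv[q$mask]
  zone_grey <- as.integer(tapply(grey_by_vox, comp$membership, `[`, 1))
  list(grey = zone_grey, size = as.integer(comp$csize))
}

#' Zone-length (size-zone) texture features
#'
#' The 11 zone features computed from 26-connected equal-grey-level zones
#' of the VOI; formulas parallel the run-length family with zone size in
#' place of run length.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of 11 features (names `GLZLM_*`).
#' @export
glzlm_features <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  n_vox <- sum(q$mask)
  if (n_vox < 2L) abort("VOI too small for zone features.")
  z <- glzlm_zones(q)
  out <- rl_features(z$grey, z$size, q$n_levels, n_vox, zone = TRUE)
  names(out) <- paste0("GLZLM_", names(out))
  out
}
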