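#' Scan volumes in SUV units
#'
#' A `scan_volume` bundles a 3D grid of standardised uptake values (SUV)
#' with its voxel spacing in millimetres and two axis-aligned striatal
#' search boxes (left and right). Axis conventions are fixed: axis 1 is
#' left--right (low indices = left), axis 2 is antero--posterior (high
#' indices = anterior), axis 3 is inferior--superior. Boxes use 0-based,
#' half-open voxel intervals `[lo, hi)`.
#'
#' @param suv numeric 3D array of SUV values; all entries must be finite.
#' @param spacing positive numeric length-3 vector, voxel edge lengths in mm.
#' @param side_boxes optional named list with elements `left` and `right`,
#'   each a `region_box()`. Defaults to the two halves of the grid split on
#'   axis 1.
#' @return An object of class `scan_volume`.
#' @seealso [region_box()], [read_volume()], [resample_isotropic()]
#' @export
scan_volume <- function(suv, spacing, side_boxes = NULL) {
  if (!is.array(suv) || length(dim(suv)) != 3L) {
    abort("`suv` must be a 3D array.")
  }
  if (!all(is.finite(suv))) abort("`suv` must contain only finite values.")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive numbers (mm).")
  }
  dm <- dim(suv)
  if (is.null(side_boxes)) {
    half <- dm[1] %/% 2L
    side_boxes <- list(
      left  = region_box(c(0L, 0L, 0L), c(half, dm[2], dm[3])),
      right = region_box(c(half, 0L, 0L), c(dm[1], dm[2], dm[3]))
    )
  }
  validate_side_boxes(side_boxes, dm)
  structure(
    list(suv = suv, spacing = spacing, side_boxes = side_boxes),
    class = "scan_volume"
  )
}

#' @export
print.scan_volume <- function(x, ...) {
  dm <- dim(x$suv)
  cat(sprintf(
    "<scan_volume> %d x %d x %d voxels, spacing %.3f x %.3f x %.3f mm\n",
    dm[1], dm[2], dm[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  SUV range [%.3f, %.3f]\n", min(x$suv), max(x$suv)))
  invisible(x)
}

#' @export
dim.scan_volume <- function(x) dim(x$suv)

#' Axis-aligned voxel box
#'
#' Half-open, 0-based voxel interval `[lo, hi)` on each axis, the coordinate
#' convention used for striatal search regions.
#'
#' @param lo,hi integer length-3 vectors with `lo < hi` componentwise.
#' @return A `region_box` object.
#' @export
region_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(is.na(lo)) || any(is.na(hi))) {
    abort("`lo` and `hi` must be integer vectors of length 3.")
  }
  if (any(lo < 0L) || any(hi <= lo)) {
    abort("Need 0 <= lo < hi on every axis.")
  }
  structure(list(lo = lo, hi = hi), class = "region_box")
}

validate_side_boxes <- function(side_boxes, dm) {
  if (!is.list(side_boxes) || !setequal(names(side_boxes), c("left", "right"))) {
    abort("`side_boxes` must be a named list with elements `left` and `right`.")
  }
  for (side in c("left", "right")) {
    b <- side_boxes[[side]]
    if (!inherits(b, "region_box")) abort("Each side box must be a `region_box`.")
    if (any(b$hi > dm)) abort(sprintf("`%s` box exceeds grid bounds.", side))
  }
  l <- side_boxes$left; r <- side_boxes$right
  overlap <- all(pmax(l$lo, r$lo) < pmin(l$hi, r$hi))
  if (overlap) abort("Side boxes must be disjoint.")
  invisible(TRUE)
}

box_slice <- function(arr, box) {
  arr[(box$lo[1] + 1L):box$hi[1],
      (box$lo[2] + 1L):box$hi[2],
      (box$lo[3] + 1L):box$hi[3], drop = FALSE]
}

# ---- NIfTI-1 I/O -----------------------------------------------------------
# Minimal single-file NIfTI-1 (.nii / .nii.gz) support: no R NIfTI reader is
# assumed to be installed. Little-endian only; data written as float32 with
# spacing in pixdim and a diagonal sform.

nifti_datatypes <- c(`2` = "uint8", `4` = "int16", `8` = "int32",
                     `16` = "float32", `64` = "float64", `512` = "uint16")

#' Read and write SUV volumes as NIfTI-1
#'
#' `read_volume()` reads a 3D single-file NIfTI-1 image (`.nii` or
#' `.nii.gz`) into a [scan_volume()]; voxel spacing is recovered from
#' `pixdim` and the slope/intercept scaling in the header is applied.
#' `write_volume()` writes a `scan_volume` as an uncompressed or gzipped
#' float32 NIfTI-1 file. Side boxes are not stored in the NIfTI header;
#' `read_volume()` assigns the default left/right halves unless
#' `side_boxes` is given.
#'
#' Only little-endian files are supported; 4D or higher-dimensional images
#' are rejected.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param side_boxes optional side boxes passed to [scan_volume()].
#' @return `read_volume()` returns a `scan_volume`; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path, side_boxes = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(sizeof_hdr, 348L)) {
    abort("Not a little-endian NIfTI-1 file (sizeof_hdr != 348).")
  }
  invisible(readBin(con, "raw", 36L))
  dim0 <- readBin(con, "integer", 8L, size = 2L, endian = "little")
  if (dim0[1] != 3L && !(dim0[1] > 3L && all(dim0[(dim0[1] + 1L):2] == 1L))) {
    abort(sprintf("Expected a 3D volume, got %dD.", dim0[1]))
  }
  invisible(readBin(con, "raw", 14L))  # intent_p1..p3, intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 4L))   # bitpix, slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = "little")
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  invisible(readBin(con, "raw", 348L - 120L))  # rest of header
  invisible(readBin(con, "raw", max(0L, as.integer(round(vox_offset)) - 348L)))
  nx <- dim0[2]; ny <- dim0[3]; nz <- dim0[4]
  n <- as.double(nx) * ny * nz
  key <- as.character(datatype)
  if (!key %in% names(nifti_datatypes)) {
    abort(sprintf("Unsupported NIfTI datatype code %d.", datatype))
  }
  vals <- switch(nifti_datatypes[[key]],
    uint8   = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    int16   = as.numeric(readBin(con, "integer", n, size = 2L, endian = "little")),
    uint16  = as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE,
                                 endian = "little")),
    int32   = as.numeric(readBin(con, "integer", n, size = 4L, endian = "little")),
    float32 = readBin(con, "numeric", n, size = 4L, endian = "little"),
    float64 = readBin(con, "numeric", n, size = 8L, endian = "little")
  )
  if (length(vals) != n) abort("Truncated NIfTI data section.")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("Missing or invalid voxel spacing in NIfTI header.")
  }
  scan_volume(array(vals, dim = c(nx, ny, nz)), spacing, side_boxes)
}

#' @param vol a `scan_volume`.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scan_volume"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  dm <- dim(vol$suv); sp <- vol$spacing
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(348L, 4L)
  writeBin(raw(36L), con)
  wi(c(3L, dm, 1L, 1L, 1L, 1L), 2L)                   # dim
  wf(c(0, 0, 0)); wi(0L, 2L)                          # intent
  wi(16L, 2L); wi(32L, 2L); wi(0L, 2L)                # float32
  wf(c(1, sp, 0, 0, 0, 0))                            # pixdim (qfac = 1)
  wf(352); wf(1); wf(0)                               # vox_offset, scl
  wi(0L, 2L)                                          # slice_end
  writeBin(as.raw(c(0L, 2L)), con)                    # slice_code, xyzt = mm
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4L)                # cal/glmax etc.
  writeBin(raw(104L), con)                            # descrip + aux_file
  wi(c(0L, 1L), 2L)                                   # qform 0, sform 1
  wf(rep(0, 6))                                       # quaternion + offsets
  wf(c(sp[1], 0, 0, 0)); wf(c(0, sp[2], 0, 0)); wf(c(0, 0, sp[3], 0))
  writeBin(raw(16L), con)                             # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)      # magic
  writeBin(raw(4L), con)                              # extension flag
  wf(as.numeric(vol$suv))
  invisible(path)
}

# ---- Isotropic resampling --------------------------------------------------

#' Resample a volume to isotropic voxels
#'
#' Trilinear interpolation of the SUV grid onto an isotropic grid with edge
#' `target_mm`, preserving the physical extent to within one voxel. Voxel
#' `i` (1-based) spans physical `[(i-1)*s, i*s)` mm on an axis; values are
#' interpolated at the new voxel centres, clamping at the border half-voxel.
#' Side boxes are mapped by converting their corners to mm and rounding
#' outward (floor/ceiling), so the striatal region is never truncated; if
#' outward rounding makes the two boxes touch-and-overlap, the overlap is
#' split at its midpoint to keep them disjoint.
#'
#' @param vol a [scan_volume()].
#' @param target_mm positive isotropic voxel edge in mm.
#' @return A `scan_volume` on the new grid.
#' @export
resample_isotropic <- function(vol, target_mm) {
  stopifnot(inherits(vol, "scan_volume"))
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0) {
    abort("`target_mm` must be a single positive number.")
  }
  dm <- dim(vol$suv); sp <- vol$spacing
  if (any(dm < 2L)) abort("Cannot resample a degenerate (single-slice) volume.")
  if (all(abs(sp - target_mm) < 1e-9)) return(vol)
  extent <- dm * sp
  newdim <- pmax(2L, as.integer(round(extent / target_mm)))
  # continuous 1-based input index of each output voxel centre, per axis
  idx <- lapply(1:3, function(a) {
    centre_mm <- (seq_len(newdim[a]) - 0.5) * target_mm
    ci <- centre_mm / sp[a] + 0.5
    pmin(pmax(ci, 1), dm[a])
  })
  i0 <- lapply(1:3, function(a) pmin(floor(idx[[a]]), dm[a] - 1L))
  fr <- lapply(1:3, function(a) idx[[a]] - i0[[a]])
  gx <- rep(i0[[1]], times = newdim[2] * newdim[3])
  gy <- rep(rep(i0[[2]], each = newdim[1]), times = newdim[3])
  gz <- rep(i0[[3]], each = newdim[1] * newdim[2])
  fx <- rep(fr[[1]], times = newdim[2] * newdim[3])
  fy <- rep(rep(fr[[2]], each = newdim[1]), times = newdim[3])
  fz <- rep(fr[[3]], each = newdim[1] * newdim[2])
  at <- function(ox, oy, oz) {
    vol$suv[cbind(gx + ox, gy + oy, gz + oz)]
  }
  out <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
    at(1, 1, 0) * fx       * fy       * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 0, 1) * fx       * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy       * fz +
    at(1, 1, 1) * fx       * fy       * fz
  dim(out) <- newdim
  boxes <- map_boxes_outward(vol$side_boxes, sp, target_mm, newdim)
  scan_volume(out, rep(target_mm, 3L), boxes)
}

map_boxes_outward <- function(side_boxes, sp, t, newdim) {
  mapb <- function(b) {
    lo <- pmax(0L, as.integer(floor(b$lo * sp / t + 1e-9)))
    hi <- pmin(newdim, as.integer(ceiling(b$hi * sp / t - 1e-9)))
    region_box(lo, pmax(hi, lo + 1L))
  }
  l <- mapb(side_boxes$left); r <- mapb(side_boxes$right)
  # split any overlap introduced by outward rounding at its midpoint
  for (a in 1:3) {
    olo <- max(l$lo[a], r$lo[a]); ohi <- min(l$hi[a], r$hi[a])
    others <- setdiff(1:3, a)
    if (olo < ohi &&
        all(pmax(l$lo[others], r$lo[others]) < pmin(l$hi[others], r$hi[others]))) {
      cut <- as.integer(round((olo + ohi) / 2))
      if (l$lo[a] < r$lo[a]) { l$hi[a] <- cut; r$lo[a] <- cut }
      else { r$hi[a] <- cut; l$lo[a] <- cut }
    }
  }
  list(left = l, right = r)
}

# ---- Absolute discretisation ----------------------------------------------

#' Absolute grey-level discretisation
#'
#' Maps SUV values to integer grey levels `1..n_levels` using fixed global
#' bounds rather than per-image extrema:
#' `GL(x) = min(n_levels, floor(n_levels * (x - lo) / (hi - lo)) + 1)`,
#' with values below `lo` mapped to level 1 and values at or above `hi`
#' clipped into the top bin. The map is monotone non-decreasing.
#'
#' @param values numeric vector of SUV values (finite).
#' @param bounds length-2 numeric `(lo, hi)`, `lo < hi`; default `c(0, 10)`.
#' @param n_levels integer number of grey levels, at least 2.
#' @return Integer vector of grey levels in `1..n_levels`.
#' @export
discretise <- function(values, bounds = c(0, 10), n_levels) {
  if (any(!is.finite(values))) abort("`values` must be finite.")
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
    abort("`bounds` must be an increasing pair (lo, hi).")
  }
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L) abort("`n_levels` must be >= 2.")
  gl <- floor(n_levels * (values - bounds[1]) / (bounds[2] - bounds[1])) + 1
  as.integer(pmin(n_levels, pmax(1, gl)))
}

# ---- Pre-processing parameter grid ----------------------------------------

#' A single pre-processing parameter set
#'
#' Combines the number of grey levels for absolute discretisation (bounds
#' fixed at SUV 0--10), the co-occurrence distance in voxels, and the voxel
#' size policy (`"default"` keeps the native grid, `"iso1mm"` / `"iso2mm"`
#' resample to 1 or 2 mm isotropic). Native (non-isotropic) voxels are only
#' combined with distance 1, matching the studied grid. Sets are named
#' compactly as `"<GL>-<d>-<vox>"`, e.g. `"64-5-111"` or `"32-1-default"`.
#'
#' @param n_grey_levels one of 32, 64, 128.
#' @param glcm_distance one of 1, 2, 5 (voxels).
#' @param voxel_policy one of `"default"`, `"iso1mm"`, `"iso2mm"`.
#' @return A `parameter_set` object.
#' @export
parameter_set <- function(n_grey_levels, glcm_distance, voxel_policy) {
  n_grey_levels <- as.integer(n_grey_levels)
  glcm_distance <- as.integer(glcm_distance)
  if (!n_grey_levels %in% c(32L, 64L, 128L)) {
    abort("`n_grey_levels` must be 32, 64 or 128.")
  }
  if (!glcm_distance %in% c(1L, 2L, 5L)) {
    abort("`glcm_distance` must be 1, 2 or 5.")
  }
  voxel_policy <- match.arg(voxel_policy, c("default", "iso1mm", "iso2mm"))
  if (voxel_policy == "default" && glcm_distance != 1L) {
    abort("Native (default) voxel size is only combined with distance 1.")
  }
  structure(
    list(
      n_grey_levels = n_grey_levels,
      glcm_distance = glcm_distance,
      voxel_policy = voxel_policy,
      bounds = c(0, 10),
      name = sprintf("%d-%d-%s", n_grey_levels, glcm_distance,
                     switch(voxel_policy, default = "default",
                            iso1mm = "111", iso2mm = "222"))
    ),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %s (GL=%d, d=%d, voxels=%s)\n",
              x$name, x$n_grey_levels, x$glcm_distance, x$voxel_policy))
  invisible(x)
}

#' The 21-combination pre-processing grid
#'
#' All studied combinations: three grey-level counts crossed with the
#' native grid and both isotropic grids at distance 1, plus the two
#' isotropic grids at distances 2 and 5 (native voxels are never used with
#' distance > 1), for 21 sets in total.
#'
#' @return A tibble with columns `name`, `n_grey_levels`, `glcm_distance`,
#'   `voxel_policy` and a list-column `params` of [parameter_set()] objects.
#' @export
parameter_grid <- function() {
  rows <- list()
  for (d in c(1L, 2L, 5L)) {
    policies <- if (d == 1L) c("default", "iso1mm", "iso2mm") else c("iso1mm", "iso2mm")
    for (pol in policies) {
      for (gl in c(32L, 64L, 128L)) {
        rows[[length(rows) + 1L]] <- parameter_set(gl, d, pol)
      }
    }
  }
  tibble(
    name = vapply(rows, `[[`, character(1), "name"),
    n_grey_levels = vapply(rows, `[[`, integer(1), "n_grey_levels"),
    glcm_distance = vapply(rows, `[[`, integer(1), "glcm_distance"),
    voxel_policy = vapply(rows, `[[`, character(1), "voxel_policy"),
    params = rows
  )
}

#' Parse a compact parameter-set name
#'
#' @param name compact name such as `"64-5-111"` or `"32-1-default"`.
#' @return A [parameter_set()].
#' @export
parse_set_name <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) != 3L) abort(sprintf("Malformed set name: %s", name))
  pol <- switch(parts[3], `111` = "iso1mm", `222` = "iso2mm",
                default = "default",
                abort(sprintf("Unknown voxel code in set name: %s", name)))
  parameter_set(as.integer(parts[1]), as.integer(parts[2]), pol)
}
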