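#' Relative-threshold isocontour mask
#'
#' Includes every voxel of the search box whose SUV is greater than or
#' equal to `fraction` times the maximum SUV *within that box* (inclusive
#' comparison, so the maximum voxel always belongs to the mask). Voxels
#' outside the box are never included. The mask is invariant to positive
#' rescaling of the intensities.
#'
#' @param vol a [scan_volume()].
#' @param side_box a [region_box()] within the grid.
#' @param fraction relative threshold in (0, 1); 0.40 reproduces the
#'   standard 40\% SUVmax isocontour.
#' @return A logical 3D array aligned with `vol`.
#' @export
isocontour_mask <- function(vol, side_box, fraction = 0.40) {
  stopifnot(inherits(vol, "scan_volume"), inherits(side_box, "region_box"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly between 0 and 1.")
  }
  if (any(side_box$hi > dim(vol$suv))) abort("`side_box` exceeds grid bounds.")
  sub <- box_slice(vol$suv, side_box)
  m <- max(sub)
  if (m <= 0) abort("Unsegmentable scan: no positive uptake in the search box.")
  mask <- array(FALSE, dim(vol$suv))
  mask[(side_box$lo[1] + 1L):side_box$hi[1],
       (side_box$lo[2] + 1L):side_box$hi[2],
       (side_box$lo[3] + 1L):side_box$hi[3]] <- sub >= fraction * m
  mask
}

# Source-voxel index ranges such that both a voxel and its neighbour at
# `offset` lie inside a grid of dimensions `dm`; NULL when no voxel does.
shift_ranges <- function(dm, offset) {
  out <- vector("list", 3L)
  for (a in 1:3) {
    lo <- max(1L, 1L - offset[a]); hi <- min(dm[a], dm[a] - offset[a])
    if (lo > hi) return(NULL)
    out[[a]] <- lo:hi
  }
  out
}

connectivity_offsets <- function(connectivity = 26L) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nn <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
    `6`  = offs[nn == 1, , drop = FALSE],
    `18` = offs[nn <= 2, , drop = FALSE],
    `26` = offs,
    abort("`connectivity` must be 6, 18 or 26.")
  )
  # keep one representative per +/- pair (first nonzero component positive)
  keep <- apply(offs, 1, function(o) { nz <- o[o != 0]; nz[1] > 0 })
  offs[keep, , drop = FALSE]
}

# Label connected components of a logical 3D mask. Returns an integer array
# (0 = background) plus component sizes. Edges are built by slicing the
# vertex-id array against itself shifted by each half-connectivity offset.
label_components <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  nvox <- sum(mask)
  if (nvox == 0L) abort("Empty mask: nothing to label.")
  idmap <- array(0L, dm)
  idmap[mask] <- seq_len(nvox)
  offs <- connectivity_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    rg <- shift_ranges(dm, o)
    if (is.null(rg)) next
    a <- idmap[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
    b <- idmap[rg[[1]] + o[1], rg[[2]] + o[2], rg[[3]] + o[3], drop = FALSE]
    ok <- a > 0L & b > 0L
    if (any(ok)) edges[[k]] <- rbind(a[ok], b[ok])
  }
  edges <- do.call(cbind, edges[!vapply(edges, is.null, logical(1))])
  g <- igraph::make_empty_graph(n = nvox, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)
  labels <- array(0L, dm)
  labels[mask] <- comp$membership
  list(labels = labels, sizes = as.integer(comp$csize))
}

#' Largest connected component of a mask
#'
#' Keeps the connected component with the most voxels under the requested
#' connectivity. Ties are broken deterministically in favour of the
#' component containing the smallest linear (column-major) voxel index.
#'
#' @param mask logical 3D array, non-empty.
#' @param connectivity 6, 18 or 26 (default) neighbourhood.
#' @return A logical 3D array containing a single connected component.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask)) {
    abort("`mask` must be a logical 3D array.")
  }
  lab <- label_components(mask, connectivity)
  best <- which(lab$sizes == max(lab$sizes))
  if (length(best) > 1L) {
    # component of the smallest member voxel index among the tied ones
    members <- lab$labels[mask]                 # in increasing linear index
    best <- best[which.min(match(best, members))]
  } else {
    best <- best[1]
  }
  lab$labels == best
}

#' Segmented striatal volume of interest
#'
#' @param mask logical 3D array (single connected component).
#' @param side `"left"` or `"right"`.
#' @param spacing voxel spacing in mm.
#' @param threshold absolute SUV threshold that produced the mask.
#' @return A `voi_mask` with voxel count and volume in mL precomputed.
#' @export
voi_mask <- function(mask, side, spacing, threshold = NA_real_) {
  side <- match.arg(side, c("left", "right"))
  n <- sum(mask)
  structure(
    list(
      mask = mask, side = side, spacing = as.numeric(spacing),
      threshold = threshold, n_voxels = n,
      volume_mL = n * prod(spacing) / 1000
    ),
    class = "voi_mask"
  )
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> side=%s, %d voxels, %.2f mL (threshold %.3f SUV)\n",
              x$side, x$n_voxels, x$volume_mL, x$threshold))
  invisible(x)
}

#' Segment both striatal sides
#'
#' Applies the relative-SUVmax isocontour independently within each side's
#' search box (each side uses its own box maximum), then retains the
#' largest connected component per side.
#'
#' @inheritParams isocontour_mask
#' @param connectivity component connectivity, default 26.
#' @return A list with `voi_mask` elements `left` and `right`.
#' @export
segment_striatum <- function(vol, fraction = 0.40, connectivity = 26L) {
  stopifnot(inherits(vol, "scan_volume"))
  out <- list()
  for (side in c("left", "right")) {
    box <- vol$side_boxes[[side]]
    res <- tryCatch({
      m <- isocontour_mask(vol, box, fraction)
      thr <- fraction * max(box_slice(vol$suv, box))
      voi_mask(largest_component(m, connectivity), side, vol$spacing, thr)
    }, error = function(e) {
      abort(sprintf("Segmentation failed on the %s side: %s", side,
                    conditionMessage(e)))
    })
    out[[side]] <- res
  }
  out
}

#' Write a VOI mask as NIfTI-1
#'
#' Stores the mask as a 0/1 volume with the VOI's spacing in the header.
#'
#' @param voi a [voi_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(voi, path) {
  stopifnot(inherits(voi, "voi_mask"))
  write_volume(scan_volume(voi$mask + 0, voi$spacing), path)
}

#' Per-scan segmentation summary
#'
#' @param vois the list returned by [segment_striatum()].
#' @return A tibble with one row per side: threshold used, voxel count and
#'   volume in mL.
#' @export
segmentation_report <- function(vois) {
  tibble(
    side = vapply(vois, `[[`, character(1), "side"),
    threshold_suv = vapply(vois, `[[`, numeric(1), "threshold"),
    n_voxels = vapply(vois, `[[`, numeric(1), "n_voxels"),
    volume_mL = vapply(vois, `[[`, numeric(1), "volume_mL")
  )
}
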