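# Independent brute-force oracles for the texture-matrix builders and
# connected components. Deliberately naive: plain loops over voxels,
# no shared code with the package internals.

all_26_offsets <- function() {
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
}

dirs13_oracle <- function() {
  o <- all_26_offsets()
  keep <- apply(o, 1, function(d) { nz <- d[d != 0]; nz[1] > 0 })
  o[keep, , drop = FALSE]
}

# GLCM by exhaustive voxel-pair enumeration (both orientations).
oracle_glcm <- function(levels, n, dir, dist) {
  dm <- dim(levels)
  C <- matrix(0, n, n)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    for (s in c(1, -1)) {
      p <- c(x, y, z) + s * dir * dist
      if (any(p < 1) || any(p > dm)) next
      b <- levels[p[1], p[2], p[3]]
      if (is.na(b)) next
      C[a, b] <- C[a, b] + 1
    }
  }
  if (sum(C) == 0) return(NULL)
  C / sum(C)
}

# Runs by walking each line voxel by voxel.
oracle_glrlm <- function(levels, n, dir) {
  dm <- dim(levels)
  runs <- list()
  inb <- function(p) all(p >= 1) && all(p <= dm)
  at <- function(p) levels[p[1], p[2], p[3]]
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    p <- c(x, y, z)
    a <- at(p)
    if (is.na(a)) next
    prev <- p - dir
    # start of a run: predecessor outside grid, outside mask, or different
    if (inb(prev) && !is.na(at(prev)) && at(prev) == a) next
    len <- 1
    nxt <- p + dir
    while (inb(nxt) && !is.na(at(nxt)) && at(nxt) == a) {
      len <- len + 1
      nxt <- nxt + dir
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  do.call(rbind, runs)  # columns: grey, length
}

# Neighbourhood difference accumulators over the 26-neighbourhood.
oracle_ngldm <- function(levels, n) {
  dm <- dim(levels)
  offs <- all_26_offsets()
  s_i <- numeric(n); n_i <- numeric(n)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (k in 1:nrow(offs)) {
      p <- c(x, y, z) + offs[k, ]
      if (any(p < 1) || any(p > dm)) next
      b <- levels[p[1], p[2], p[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  list(s = s_i, n = n_i)
}

# Zones by recursive flood fill over equal-grey 26-neighbours.
oracle_zones <- function(levels) {
  dm <- dim(levels)
  seen <- array(FALSE, dm)
  offs <- all_26_offsets()
  zones <- list()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    a <- levels[x, y, z]
    if (is.na(a) || seen[x, y, z]) next
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (k in 1:nrow(offs)) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > dm)) next
        if (seen[q[1], q[2], q[3]]) next
        b <- levels[q[1], q[2], q[3]]
        if (!is.na(b) && b == a) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  do.call(rbind, zones)  # columns: grey, size
}

# Connected components of a logical mask by flood fill; returns sizes of
# all components and the mask of the largest (ties: smallest linear index).
oracle_largest_component <- function(mask) {
  lv <- array(NA_integer_, dim(mask))
  lv[mask] <- 1L
  z <- oracle_zones(lv)  # grey always 1 -> components of the mask
  # rebuild membership to find the largest; redo fill tracking labels
  dm <- dim(mask)
  lab <- array(0L, dm)
  offs <- all_26_offsets()
  nextlab <- 0L
  for (i in which(mask)) {
    if (lab[i] > 0L) next
    nextlab <- nextlab + 1L
    pos <- arrayInd(i, dm)
    stack <- list(as.integer(pos))
    lab[i] <- nextlab
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in 1:nrow(offs)) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > dm)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nextlab
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))[1]  # first label = smallest seed index
  lab == best
}

# Random small masked quantized VOI for oracle comparisons.
random_voi <- function(dim3 = c(4, 4, 4), n_levels = 4, p_mask = 0.7) {
  repeat {
    mask <- array(runif(prod(dim3)) < p_mask, dim3)
    if (sum(mask) >= 2) break
  }
  suv <- array(runif(prod(dim3), 0, 10), dim3)
  quantize_voi(suv, mask, spacing = c(1, 1, 1), n_levels = n_levels)
}

# Feature-formula helpers shared by tests (direct formula evaluation).
rl_oracle_features <- function(tab, n_levels, n_vox) {
  g <- tab[, 1]; l <- tab[, 2]
  Nr <- nrow(tab)
  c(SRE = sum(1 / l^2) / Nr, LRE = sum(l^2) / Nr,
    LGRE = sum(1 / g^2) / Nr, HGRE = sum(g^2) / Nr,
    SRLGE = sum(1 / (g^2 * l^2)) / Nr, SRHGE = sum(g^2 / l^2) / Nr,
    LRLGE = sum(l^2 / g^2) / Nr, LRHGE = sum(g^2 * l^2) / Nr,
    GLNU = sum(tabulate(g, n_levels)^2) / Nr,
    RLNU = sum(tabulate(l)^2) / Nr,
    RP = Nr / n_vox)
}
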