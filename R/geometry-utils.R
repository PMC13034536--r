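# Internal geometry primitives shared by the surface-vector and profile code.
# All world-space quantities are in millimetres; voxel indices handed to the
# affine are 0-based (NIfTI convention), R array indices are 1-based.

# Apply a (d+1)x(d+1) homogeneous affine to an n x d matrix of 0-based voxel
# indices, returning n x d world-mm coordinates.
voxelToWorld <- function(idx0, affine) {
  idx0 <- as.matrix(idx0)
  d <- ncol(idx0)
  lin <- affine[seq_len(d), seq_len(d), drop = FALSE]
  off <- affine[seq_len(d), d + 1L]
  sweep(idx0 %*% t(lin), 2L, off, "+")
}

# Inverse map: world mm -> continuous 0-based voxel coordinates.
worldToVoxel <- function(world, affine) {
  world <- as.matrix(world)
  d <- ncol(world)
  lin <- affine[seq_len(d), seq_len(d), drop = FALSE]
  off <- affine[seq_len(d), d + 1L]
  t(solve(lin, t(sweep(world, 2L, off, "-"))))
}

# Default axis-aligned affine for a given voxel spacing (origin at voxel 0).
spacingAffine <- function(spacing) {
  d <- length(spacing)
  aff <- diag(c(spacing, 1))
  dimnames(aff) <- NULL
  aff
}

# Shift an array by an integer offset along each axis, padding with `fill`.
# offset[k] > 0 moves content toward higher indices on axis k.
arrayShift <- function(a, offset, fill = 0) {
  dm <- dim(a)
  d <- length(dm)
  src <- vector("list", d)
  dst <- vector("list", d)
  for (k in seq_len(d)) {
    o <- offset[k]
    if (abs(o) >= dm[k]) return(array(fill, dm))
    if (o >= 0) {
      src[[k]] <- seq_len(dm[k] - o)
      dst[[k]] <- seq.int(o + 1L, dm[k])
    } else {
      src[[k]] <- seq.int(-o + 1L, dm[k])
      dst[[k]] <- seq_len(dm[k] + o)
    }
  }
  out <- array(fill, dm)
  if (d == 2L) {
    out[dst[[1]], dst[[2]]] <- a[src[[1]], src[[2]]]
  } else {
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  }
  out
}

# Face-neighbour offsets (4-connectivity in 2D, 6-connectivity in 3D).
faceOffsets <- function(d) {
  out <- list()
  for (k in seq_len(d)) for (s in c(-1L, 1L)) {
    o <- integer(d); o[k] <- s
    out[[length(out) + 1L]] <- o
  }
  out
}

# Separable Gaussian smoothing with sigma in voxels (possibly per-axis),
# zero-padded. Used to orient normals from the mask indicator gradient.
gaussianSmoothArray <- function(a, sigma) {
  dm <- dim(a)
  d <- length(dm)
  if (length(sigma) == 1L) sigma <- rep(sigma, d)
  out <- a
  for (k in seq_len(d)) {
    r <- max(1L, ceiling(3 * sigma[k]))
    w <- exp(-((-r):r)^2 / (2 * sigma[k]^2))
    w <- w / sum(w)
    acc <- array(0, dm)
    for (j in seq_along(w)) {
      o <- integer(d); o[k] <- j - r - 1L
      acc <- acc + w[j] * arrayShift(out, o)
    }
    out <- acc
  }
  out
}

# Central-difference gradient of a scalar array in world mm.
# Returns list of d arrays. Uses the affine's linear part: for an axis-aligned
# affine this reduces to dividing by the signed spacing.
worldGradient <- function(a, affine) {
  dm <- dim(a)
  d <- length(dm)
  gidx <- vector("list", d)
  for (k in seq_len(d)) {
    fw <- integer(d); fw[k] <- 1L
    bw <- integer(d); bw[k] <- -1L
    gidx[[k]] <- (arrayShift(a, bw) - arrayShift(a, fw)) / 2
  }
  # chain rule: grad_world = A^{-T} grad_index
  lin <- affine[seq_len(d), seq_len(d), drop = FALSE]
  invT <- t(solve(lin))
  gw <- vector("list", d)
  for (i in seq_len(d)) {
    acc <- array(0, dm)
    for (j in seq_len(d)) if (invT[i, j] != 0) acc <- acc + invT[i, j] * gidx[[j]]
    gw[[i]] <- acc
  }
  gw
}

# Exact squared Euclidean distance transform (lower envelope of parabolas),
# applied separably. `mask` TRUE voxels are sources; distances in world units
# when spacing is given, voxel units otherwise.
distanceTransform <- function(mask, spacing = NULL) {
  dm <- dim(mask)
  d <- length(dm)
  if (is.null(spacing)) spacing <- rep(1, d)
  INF <- .Machine$double.xmax / 4
  f <- array(ifelse(mask, 0, INF), dm)
  for (k in seq_len(d)) {
    f <- aperm1d(f, k, function(line) edt1d(line, spacing[k]))
  }
  sqrt(f)
}

# Apply fn over every 1D line of array `a` along axis k.
aperm1d <- function(a, k, fn) {
  dm <- dim(a)
  d <- length(dm)
  perm <- c(k, setdiff(seq_len(d), k))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = dm[k])
  for (j in seq_len(ncol(m))) m[, j] <- fn(m[, j])
  ap <- array(m, dim(ap))
  aperm(ap, order(perm))
}

# 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
edt1d <- function(f, h) {
  n <- length(f)
  INF <- .Machine$double.xmax / 4
  if (all(f >= INF)) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -INF; z[2L] <- INF
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + (q * h)^2) - (f[p] + (p * h)^2)) / (2 * h^2 * (q - p))
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) { k <- 1L; v[1L] <- q; z[1L] <- -INF; z[2L] <- INF; break }
      } else {
        k <- k + 1L
        v[k] <- q
        z[k] <- s
        z[k + 1L] <- INF
        break
      }
    }
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    out[q] <- (h * (q - p))^2 + f[p]
  }
  out
}

# Multilinear (bilinear/trilinear) interpolation of `data` at continuous
# 0-based voxel coordinates `vox` (n x d). Points outside [0, dim-1] on any
# axis return NA (out-of-volume is 'missing', never zero-filled).
interpolateVoxel <- function(data, vox) {
  dm <- dim(data)
  d <- length(dm)
  vox <- as.matrix(vox)
  n <- nrow(vox)
  eps <- 1e-9
  inb <- rep(TRUE, n)
  for (k in seq_len(d)) inb <- inb & vox[, k] >= -eps & vox[, k] <= dm[k] - 1 + eps
  out <- rep(NA_real_, n)
  if (!any(inb)) return(out)
  v <- vox[inb, , drop = FALSE]
  i0 <- floor(v)
  for (k in seq_len(d)) {
    i0[, k] <- pmin(pmax(i0[, k], 0), dm[k] - 2)  # clamp so i0+1 stays in-grid
    if (dm[k] == 1L) i0[, k] <- 0
  }
  fr <- v - i0
  fr <- pmin(pmax(fr, 0), 1)
  acc <- numeric(nrow(v))
  corners <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
  mult <- cumprod(c(1, dm[-d]))
  for (ci in seq_len(nrow(corners))) {
    cr <- corners[ci, ]
    idx <- rep(1, nrow(v))
    w <- rep(1, nrow(v))
    for (k in seq_len(d)) {
      ik <- i0[, k] + if (dm[k] == 1L) 0 else cr[k]
      idx <- idx + ik * mult[k]
      wk <- if (cr[k] == 1) fr[, k] else 1 - fr[, k]
      if (dm[k] == 1L) wk <- if (cr[k] == 1) 0 else 1
      w <- w * wk
    }
    keep <- w > 0
    if (any(keep)) acc[keep] <- acc[keep] + w[keep] * data[idx[keep]]
  }
  out[inb] <- acc
  out
}

# Nearest containing voxel (1-based R index matrix) for continuous 0-based
# voxel coordinates; rows outside the grid get NA.
containingVoxel <- function(vox, dm) {
  vox <- as.matrix(vox)
  idx <- round(vox) + 1
  ok <- rep(TRUE, nrow(idx))
  for (k in seq_along(dm)) ok <- ok & idx[, k] >= 1 & idx[, k] <= dm[k]
  idx[!ok, ] <- NA_real_
  idx
}

# Linear (single) index into an array from a 1-based index matrix; NA rows
# propagate.
linearIndex <- function(idx, dm) {
  mult <- cumprod(c(1, dm[-length(dm)]))
  li <- rep(1, nrow(idx))
  for (k in seq_along(dm)) li <- li + (idx[, k] - 1) * mult[k]
  li
}
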