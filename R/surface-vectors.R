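#' @include AllClasses.R io.R morphology.R
NULL

#' Refine a tumour ROI mask
#'
#' Regularizes a binary ROI before boundary extraction: morphological
#' closing (Euclidean ball, radius in voxels), interior hole filling, then
#' connected-component selection. The default policy keeps every component
#' of at least `min_component_voxels` voxels, so multifocal disease is
#' retained.
#'
#' @param mask logical array (2D or 3D), nonempty.
#' @param closing_radius_vox closing radius in voxels (0 disables closing).
#' @param min_component_voxels minimum face-connected component size kept.
#' @return Logical array of the refined mask.
#' @export
refineROI <- function(mask, closing_radius_vox = 1, min_component_voxels = 5) {
  if (!any(mask)) stop("empty ROI")
  m <- binaryClose(mask, closing_radius_vox)
  m <- fillHoles(m)
  lab <- labelComponents(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_component_voxels)
  m <- array(lab %in% keep, dim(lab))
  if (!any(m)) stop("empty ROI after component-size filtering")
  m
}

#' Extract boundary voxels of a binary mask
#'
#' A voxel is a boundary voxel iff it belongs to the mask and has at least
#' one face-adjacent background neighbour (4-connectivity in 2D,
#' 6-connectivity in 3D); voxels on the grid edge count the outside as
#' background. Interior voxels are never returned.
#'
#' @param mask logical array (refined ROI).
#' @return data.frame of 1-based voxel indices (`i1`, `i2`, and `i3` in 3D)
#'   with a `component_id` column numbering face-connected components by
#'   decreasing size.
#' @export
extractBoundary <- function(mask) {
  if (!any(mask)) stop("empty ROI")
  d <- length(dim(mask))
  interior <- mask
  for (o in faceOffsets(d)) interior <- interior & (arrayShift(mask * 1L, o) > 0)
  bnd <- mask & !interior
  lab <- labelComponents(mask)
  idx <- which(bnd)
  coords <- arrayInd(idx, dim(mask))
  out <- as.data.frame(coords)
  names(out) <- paste0("i", seq_len(d))
  out$component_id <- lab[idx]
  out
}

#' Estimate unit outward surface normals by local eigen-decomposition
#'
#' For each boundary voxel, the local surface topology is sampled by a
#' fixed centred kernel (`kernel_vox` per axis, default 5x5 in 2D and
#' 5x5x5 in 3D): boundary voxels inside the kernel are converted to world
#' mm and the eigen-decomposition of their scatter about the centroid
#' yields the principal directions — tangential (largest eigenvalues) and
#' normal (smallest). The normal is oriented outward using the world-space
#' gradient of a Gaussian-smoothed (sigma = 1 voxel) mask indicator; where
#' that gradient vanishes the vector is pointed away from the component
#' centroid. Doing the decomposition in world mm keeps anisotropic grids
#' metrically correct.
#'
#' @param boundary data.frame from [extractBoundary()].
#' @param mask the refined mask the boundary came from.
#' @param kernel_vox odd kernel width in voxels, >= 3.
#' @param spacing,affine grid geometry (mm); default 1 mm isotropic.
#' @return A [SurfaceVectorField-class]; boundary voxels whose kernel holds
#'   fewer than 3 boundary points are skipped and counted in `nSkipped`.
#' @export
estimateNormals <- function(boundary, mask, kernel_vox = 5,
                            spacing = rep(1, length(dim(mask))),
                            affine = spacingAffine(spacing)) {
  if (nrow(boundary) == 0L) stop("empty boundary")
  if (kernel_vox < 3 || kernel_vox %% 2 != 1) stop("kernel must be odd and >= 3")
  dm <- dim(mask)
  d <- length(dm)
  h <- (kernel_vox - 1L) %/% 2L
  bnd <- array(FALSE, dm)
  coordCols <- paste0("i", seq_len(d))
  bmat <- as.matrix(boundary[coordCols])
  bnd[bmat] <- TRUE
  # outward orientation field: minus the gradient of the smoothed indicator
  sm <- gaussianSmoothArray(mask * 1.0, 1)
  gr <- worldGradient(sm, affine)
  lin <- affine[seq_len(d), seq_len(d), drop = FALSE]
  # component centroids in world mm (orientation fallback)
  centroids <- stats::aggregate(bmat, list(component_id = boundary$component_id),
                                mean)
  centW <- voxelToWorld(as.matrix(centroids[coordCols]) - 1, affine)
  rownames(centW) <- centroids$component_id
  n <- nrow(boundary)
  dirs <- matrix(NA_real_, n, d)
  skipped <- logical(n)
  for (v in seq_len(n)) {
    ctr <- bmat[v, ]
    lo <- pmax(ctr - h, 1L)
    hi <- pmin(ctr + h, dm)
    win <- if (d == 2L) bnd[lo[1]:hi[1], lo[2]:hi[2], drop = FALSE]
           else bnd[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    pts <- arrayInd(which(win), dim(win))
    if (nrow(pts) < 3L) { skipped[v] <- TRUE; next }
    pts <- sweep(pts, 2L, lo - 1L, "+")           # back to full-grid indices
    ptsW <- (pts - 1) %*% t(lin)                  # world (translation cancels)
    ctd <- colMeans(ptsW)
    sc <- crossprod(sweep(ptsW, 2L, ctd, "-"))
    eig <- eigen(sc, symmetric = TRUE)
    nv <- eig$vectors[, d]                        # smallest-eigenvalue vector
    # orient outward
    g <- vapply(gr, function(a) a[matrix(ctr, 1)], numeric(1))
    o <- -g
    if (sqrt(sum(o^2)) < 1e-12) {
      cw <- centW[as.character(boundary$component_id[v]), ]
      o <- voxelToWorld(matrix(ctr - 1, 1), affine)[1, ] - cw
    }
    if (sum(nv * o) < 0) nv <- -nv
    dirs[v, ] <- nv / sqrt(sum(nv^2))
  }
  keep <- !skipped
  baseW <- voxelToWorld(bmat[keep, , drop = FALSE] - 1, affine)
  vdf <- data.frame(id = seq_len(sum(keep)),
                    component_id = boundary$component_id[keep])
  vdf$x <- baseW[, 1]; vdf$y <- baseW[, 2]
  vdf$nx <- dirs[keep, 1]; vdf$ny <- dirs[keep, 2]
  if (d == 3L) { vdf$z <- baseW[, 3]; vdf$nz <- dirs[keep, 3] }
  new("SurfaceVectorField", vectors = vdf, gridDim = as.integer(dm),
      spacing = as.numeric(spacing), affine = affine,
      nSkipped = as.integer(sum(skipped)))
}

#' Vector-field overlap map
#'
#' Counts, per voxel, how many profile sample points fall inside it (same
#' window and rate as profile sampling), identifying regions of vector
#' overlap or multiple sampling.
#'
#' @param field a [SurfaceVectorField-class].
#' @param window_mm length-2 window relative to the boundary (mm).
#' @param rate_per_mm samples per mm.
#' @return A [ScalarVolume-class] of integer counts on the field's grid.
#' @export
overlapMap <- function(field, window_mm = c(-2, 6), rate_per_mm = 2) {
  v <- field@vectors
  dm <- field@gridDim
  d <- length(dm)
  if (nrow(v) == 0L)
    return(ScalarVolume(array(0, dm), spacing = field@spacing,
                        affine = field@affine, units = "arbitrary"))
  pts <- samplePoints(v, window_mm, rate_per_mm, d)
  vox <- worldToVoxel(pts$world, field@affine)
  idx <- containingVoxel(vox, dm)
  ok <- stats::complete.cases(idx)
  counts <- array(0, dm)
  li <- linearIndex(idx[ok, , drop = FALSE], dm)
  tab <- table(li)
  counts[as.numeric(names(tab))] <- as.numeric(tab)
  ScalarVolume(counts, spacing = field@spacing, affine = field@affine,
               units = "arbitrary")
}

# Sample-point layout shared by overlapMap and sampleProfiles: for each
# vector, positions window_start + k/rate, k = 0..(span*rate).
samplePoints <- function(vdf, window_mm, rate_per_mm, d) {
  arcs <- seq(window_mm[1], window_mm[2], by = 1 / rate_per_mm)
  base <- as.matrix(vdf[, c("x", "y", if (d == 3L) "z")])
  dirm <- as.matrix(vdf[, c("nx", "ny", if (d == 3L) "nz")])
  n <- nrow(vdf); m <- length(arcs)
  world <- base[rep(seq_len(n), each = m), , drop = FALSE] +
    dirm[rep(seq_len(n), each = m), , drop = FALSE] * rep(arcs, n)
  list(world = world, arcs = arcs,
       vector_id = rep(vdf$id, each = m), k = rep(seq_len(m), n))
}
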