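# Binary morphology on logical arrays (2D or 3D), identical code path for
# both dimensionalities. Structuring elements are Euclidean balls in voxel
# units; out-of-grid is treated as background throughout.

# Integer offsets within a Euclidean ball of radius r voxels.
ballOffsets <- function(r, d) {
  rr <- ceiling(r)
  ax <- (-rr):rr
  grid <- as.matrix(do.call(expand.grid, rep(list(ax), d)))
  keep <- rowSums(grid^2) <= r^2 + 1e-9
  grid[keep, , drop = FALSE]
}

binaryDilate <- function(mask, r) {
  if (r <= 0) return(mask)
  offs <- ballOffsets(r, length(dim(mask)))
  out <- array(FALSE, dim(mask))
  m <- mask * 1L
  for (i in seq_len(nrow(offs))) {
    out <- out | (arrayShift(m, offs[i, ]) > 0)
  }
  out
}

binaryErode <- function(mask, r) {
  if (r <= 0) return(mask)
  !binaryDilate(!mask, r)
}

binaryClose <- function(mask, r) {
  if (r <= 0) return(mask)
  binaryErode(binaryDilate(mask, r), r)
}

# Fill interior holes: background voxels not face-connected to the array
# border become foreground.
fillHoles <- function(mask) {
  dm <- dim(mask)
  d <- length(dm)
  bg <- !mask
  # seed: background voxels on the border
  outside <- array(FALSE, dm)
  for (k in seq_len(d)) {
    for (side in c(1L, dm[k])) {
      if (d == 2L) {
        if (k == 1L) outside[side, ] <- bg[side, ] else outside[, side] <- bg[, side]
      } else {
        if (k == 1L) outside[side, , ] <- bg[side, , ]
        else if (k == 2L) outside[, side, ] <- bg[, side, ]
        else outside[, , side] <- bg[, , side]
      }
    }
  }
  offs <- faceOffsets(d)
  repeat {
    grown <- outside
    for (o in offs) grown <- grown | (arrayShift(outside * 1L, o) > 0)
    grown <- grown & bg
    if (identical(grown, outside)) break
    outside <- grown
  }
  mask | (bg & !outside)
}

# Face-connected component labelling by iterative label propagation.
# Returns an integer array: 0 background, components numbered 1..k in
# decreasing size order.
labelComponents <- function(mask) {
  dm <- dim(mask)
  d <- length(dm)
  lab <- array(0, dm)
  lab[mask] <- which(mask)   # seed with linear index
  offs <- faceOffsets(d)
  repeat {
    new <- lab
    for (o in offs) new <- pmax(new, arrayShift(lab, o))
    new[!mask] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0]))
  sizes <- tabulate(match(lab[lab > 0], ids))
  ord <- order(sizes, decreasing = TRUE)
  relab <- integer(max(ids))
  relab[ids[ord]] <- seq_along(ids)
  out <- array(0L, dm)
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}
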