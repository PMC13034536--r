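# Shared fixture builders. Heavier objects are memoised so the suite builds
# them once.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

# 2D disc mask of given radius (voxels) centred in a square grid.
discMask <- function(radius, pad = 4) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  xs <- seq_len(n) - ctr
  array(outer(xs, xs, function(i, j) i^2 + j^2) <= radius^2, c(n, n))
}

# 3D ball mask.
ballMask <- function(radius, pad = 4) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  xs <- seq_len(n) - ctr
  r2 <- outer(outer(xs^2, xs^2, `+`), xs^2, `+`)
  array(r2 <= radius^2, c(n, n, n))
}

# A hand-built vector field with explicit base points/directions (2D or 3D),
# for slab-geometry profile tests where full control is needed.
manualField <- function(base, dirs, gridDim, spacing) {
  d <- ncol(base)
  vdf <- data.frame(id = seq_len(nrow(base)),
                    component_id = rep(1L, nrow(base)))
  vdf$x <- base[, 1]; vdf$y <- base[, 2]
  vdf$nx <- dirs[, 1]; vdf$ny <- dirs[, 2]
  if (d == 3L) { vdf$z <- base[, 3]; vdf$nz <- dirs[, 3] }
  new("SurfaceVectorField", vectors = vdf, gridDim = as.integer(gridDim),
      spacing = as.numeric(spacing),
      affine = diag(c(spacing, 1)), nSkipped = 0L)
}

# Slab world: 1D geometry embedded in 2D. Enhancing tumour occupies
# x <= 20 mm, a FLAIR shell extends `flair_extent_mm` beyond it, and one
# profile vector points along +x from the boundary at x = 20. Used for
# validity-rule cases with exact control of the contiguous run.
slabCase <- function(flair_extent_mm, ny = 9, nx = round(40 / spacing),
                     spacing = 1) {
  sc <- defaultLabelScheme()
  labels <- array(sc[["background"]], c(nx, ny))
  xs <- (seq_len(nx) - 1) * spacing
  labels[xs <= 20, ] <- sc[["enhancing"]]
  labels[xs > 20 & xs <= 20 + flair_extent_mm, ] <- sc[["flair_abnormality"]]
  seg <- SegmentationVolume(labels, spacing = c(spacing, spacing))
  vals <- array(rep(1e-3 + 5e-5 * xs, ny), c(nx, ny))
  vol <- ScalarVolume(vals, spacing = c(spacing, spacing),
                      units = "mm2_per_s")
  fld <- manualField(base = matrix(c(20, 4), 1), dirs = matrix(c(1, 0), 1),
                     gridDim = c(nx, ny), spacing = c(spacing, spacing))
  list(seg = seg, vol = vol, field = fld)
}

spherePhantom40 <- function() memo("phantom40", function() {
  makeSpherePhantom(grid_shape = c(40, 40, 40), radius_mm = 10,
                    gradient_per_mm = 1, v_at_centre = 100)
})

patientNoiseless <- function() memo("patient0", function() {
  makeSyntheticPatient(noise_sd = 0)
})
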