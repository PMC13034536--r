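# Brute-force boundary oracle: direct per-voxel neighbour scan, independent
# of the array-shift implementation.
bruteBoundary <- function(mask) {
  dm <- dim(mask)
  d <- length(dm)
  idx <- which(mask)
  coords <- arrayInd(idx, dm)
  isb <- vapply(seq_len(nrow(coords)), function(i) {
    for (k in seq_len(d)) for (s in c(-1L, 1L)) {
      nb <- coords[i, ]; nb[k] <- nb[k] + s
      if (any(nb < 1) || any(nb > dm)) return(TRUE)
      if (!mask[matrix(nb, 1)]) return(TRUE)
    }
    FALSE
  }, logical(1))
  coords[isb, , drop = FALSE]
}

test_that("boundary extraction matches brute-force enumeration", {
  sq <- array(FALSE, c(9, 9)); sq[3:7, 3:7] <- TRUE   # filled 5x5 square
  bnd <- extractBoundary(sq)
  expect_equal(nrow(bnd), 16)
  oracle <- bruteBoundary(sq)
  got <- as.matrix(bnd[, c("i1", "i2")])
  expect_setequal(paste(got[, 1], got[, 2]),
                  paste(oracle[, 1], oracle[, 2]))
  # single voxel is its own boundary
  one <- array(FALSE, c(5, 5)); one[3, 3] <- TRUE
  b1 <- extractBoundary(one)
  expect_equal(unname(as.matrix(b1[, c("i1", "i2")])), matrix(c(3, 3), 1))
  # a 1-voxel-thick shell is returned whole
  shell <- ballMask(6) & !ballMask(5, pad = 5)   # same 21^3 grid
  bs <- extractBoundary(shell)
  expect_equal(nrow(bs), sum(shell))
  expect_error(extractBoundary(array(FALSE, c(4, 4))), "empty")
})

test_that("ROI refinement fills holes and applies the component policy", {
  ball <- ballMask(10)
  holed <- ball
  ctr <- (dim(ball) + 1) / 2
  holed[ctr[1], ctr[2], ctr[3]] <- FALSE
  refined <- refineROI(holed, closing_radius_vox = 0)
  expect_equal(sum(refined), sum(holed) + 1)
  # two disjoint blobs both retained with distinct component ids
  two <- array(FALSE, c(30, 14)); two[3:8, 3:8] <- TRUE; two[20:26, 3:9] <- TRUE
  ref2 <- refineROI(two, closing_radius_vox = 0)
  comp <- extractBoundary(ref2)
  expect_setequal(unique(comp$component_id), c(1L, 2L))
  # isolated voxel removed by the min-size policy -> empty -> error
  iso <- array(FALSE, c(9, 9)); iso[5, 5] <- TRUE
  expect_error(refineROI(iso, closing_radius_vox = 0), "empty ROI")
  expect_error(refineROI(array(FALSE, c(5, 5))), "empty ROI")
})

test_that("disc and sphere normals are radial and outward", {
  disc <- discMask(20)
  bnd <- extractBoundary(disc)
  fld <- estimateNormals(bnd, disc)
  ctr <- (dim(disc)[1] - 1) / 2   # world mm of centre (spacing 1, 0-based)
  v <- fld@vectors
  radial <- cbind(v$x - ctr, v$y - ctr)
  radial <- radial / sqrt(rowSums(radial^2))
  dots <- radial[, 1] * v$nx + radial[, 2] * v$ny
  expect_gt(mean(dots), 0.98)
  expect_true(all(dots > 0.9))
  expect_gt(mean(dots >= 0.98), 0.9)  # digitization leaves a small tail
  # 3D sphere: mean angular error under 5 degrees, no inward vectors
  ball <- ballMask(10)
  fld3 <- estimateNormals(extractBoundary(ball), ball)
  ctr3 <- (dim(ball)[1] - 1) / 2
  v3 <- fld3@vectors
  rad3 <- cbind(v3$x - ctr3, v3$y - ctr3, v3$z - ctr3)
  rad3 <- rad3 / sqrt(rowSums(rad3^2))
  d3 <- rad3[, 1] * v3$nx + rad3[, 2] * v3$ny + rad3[, 3] * v3$nz
  expect_lt(mean(acos(pmin(d3, 1))) * 180 / pi, 5)
  expect_gt(mean(d3), 0.98)
  expect_true(all(d3 > 0.9))
  # skipped fraction below 1% on a convex ROI of radius >= 10
  expect_lt(fld3@nSkipped / (nrow(v3) + fld3@nSkipped), 0.01)
})

test_that("flat slab faces give axis-aligned normals", {
  slab <- array(FALSE, c(20, 20, 9)); slab[4:17, 4:17, 4:6] <- TRUE
  fld <- estimateNormals(extractBoundary(slab), slab)
  v <- fld@vectors
  top <- v[abs(v$z - 5) < 1e-9 & v$x > 7 & v$x < 13 & v$y > 7 & v$y < 13, ]
  expect_gt(nrow(top), 0)
  expect_equal(abs(top$nz), rep(1, nrow(top)), tolerance = 1e-6)
  expect_true(all(top$nz > 0))  # outward = +z on the top face
})

test_that("normals are equivariant under 90-degree axis rotations", {
  mask <- array(FALSE, c(24, 24, 24))
  mask[6:18, 8:16, 9:15] <- TRUE   # anisotropic box
  fld <- estimateNormals(extractBoundary(mask), mask)
  rot <- aperm(mask[, , rev(seq_len(24))], c(1, 3, 2))  # 90 deg about x
  fldR <- estimateNormals(extractBoundary(rot), rot)
  # rotation maps direction (nx,ny,nz) -> (nx, -nz, ny); compare multisets
  a <- fld@vectors; b <- fldR@vectors
  key <- function(m) sort(apply(round(m, 6), 1, paste, collapse = ","))
  expect_equal(key(cbind(a$nx, -a$nz, a$ny)), key(cbind(b$nx, b$ny, b$nz)))
})

test_that("overlap maps count sample points per voxel", {
  fld <- manualField(base = matrix(c(4, 10), 1), dirs = matrix(c(1, 0), 1),
                     gridDim = c(40, 40), spacing = c(0.5, 0.5))
  om <- overlapMap(fld, window_mm = c(-2, 6), rate_per_mm = 2)
  cnt <- volData(om)
  expect_equal(sum(cnt), 17)
  expect_true(all(cnt[cnt > 0] == 1))   # 0.5 mm samples on a 0.5 mm grid
  # two nearly-coincident parallel vectors exactly double the counts
  fld1 <- manualField(base = matrix(c(4, 10), 1), dirs = matrix(c(1, 0), 1),
                      gridDim = c(40, 40), spacing = c(2, 2))
  fld2 <- manualField(base = rbind(c(4, 10), c(4, 10.05)),
                      dirs = rbind(c(1, 0), c(1, 0)),
                      gridDim = c(40, 40), spacing = c(2, 2))
  expect_equal(volData(overlapMap(fld2)), 2 * volData(overlapMap(fld1)))
  # empty field -> all-zero counts
  empty <- manualField(base = matrix(numeric(), 0, 2),
                       dirs = matrix(numeric(), 0, 2),
                       gridDim = c(10, 10), spacing = c(1, 1))
  expect_true(all(volData(overlapMap(empty)) == 0))
})
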