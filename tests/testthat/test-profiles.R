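test_that("profile sampling hits the window layout and is exact on affine fields", {
  sc <- slabCase(20)
  prof <- sampleProfiles(sc$vol, sc$field)
  s <- prof@samples
  expect_equal(nrow(s), 17)                       # 8 mm * 2/mm + 1
  expect_equal(s$arc_mm, seq(-2, 6, 0.5))
  # the slab field is 1e-3 + 5e-5 * x, vector along +x from x = 20:
  # linear interpolation reproduces an affine field exactly
  expect_equal(s$value, 1e-3 + 5e-5 * (20 + s$arc_mm), tolerance = 1e-12)
  # constant volume -> constant values
  cvol <- ScalarVolume(array(7e-4, c(40, 9)), spacing = c(1, 1))
  expect_equal(unique(sampleProfiles(cvol, sc$field)@samples$value), 7e-4)
  # samples leaving the volume are missing, never zero-filled
  edge <- manualField(base = matrix(c(37, 4), 1), dirs = matrix(c(1, 0), 1),
                      gridDim = c(40, 9), spacing = c(1, 1))
  vals <- sampleProfiles(cvol, edge)@samples$value
  expect_true(anyNA(vals))
  expect_false(any(vals == 0, na.rm = TRUE))
})

test_that("validity filter applies the contiguous-span rule anchored at the boundary", {
  # fully inside abnormality: 8 mm span, valid
  full <- slabCase(20)
  p <- applyValidityFilter(sampleProfiles(full$vol, full$field), full$seg,
                           full$field)
  expect_true(p@profiles$valid)
  expect_equal(p@profiles$n_contiguous_mm, 8)
  # exits abnormality 3 mm beyond the boundary: 2 + 3 = 5 mm span, valid
  mid <- slabCase(3)
  p2 <- applyValidityFilter(sampleProfiles(mid$vol, mid$field), mid$seg,
                            mid$field)
  expect_true(p2@profiles$valid)
  expect_equal(p2@profiles$n_contiguous_mm, 5, tolerance = 0.51)
  # exits 1.5 mm beyond: 3.5 mm span, invalid under strict > 4 mm
  short <- slabCase(1.5)
  p3 <- applyValidityFilter(sampleProfiles(short$vol, short$field),
                            short$seg, short$field)
  expect_false(p3@profiles$valid)
  expect_lte(p3@profiles$n_contiguous_mm, 4)
})

test_that("slope fitting is exact on lines and converts per-index to per-mm", {
  expect_equal(fitSlope(rep(5, 9))$slope, 0)
  arc <- seq(-2, 6, 0.5)
  f <- fitSlope(1e-3 + 5e-5 * arc, rate_per_mm = 2)
  expect_equal(f$slope, 5e-5, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # per-index slope 0.05 at 2 points/mm is 0.1 per mm
  y <- 0.05 * (1:11)
  expect_equal(fitSlope(y, rate_per_mm = 2)$slope, 0.1, tolerance = 1e-12)
  expect_error(fitSlope(c(1, 2)), "3 samples")
  # regressing on index then rescaling equals regressing on arc directly
  set.seed(9)
  for (i in 1:25) {
    n <- sample(5:17, 1)
    y <- rnorm(n)
    a <- seq(-2, by = 0.5, length.out = n)
    direct <- unname(coef(lm(y ~ a))[2])
    viaIndex <- fitSlope(y, rate_per_mm = 2)$slope
    expect_equal(viaIndex, direct, tolerance = 1e-12)
  }
})

test_that("computeMDS responds linearly to affine ADC rescaling", {
  fx <- patientNoiseless()
  res <- computeMDS(fx$adc, fx$seg)
  scaled <- ScalarVolume(2 * volData(fx$adc), volSpacing(fx$adc),
                         volAffine(fx$adc), units = "mm2_per_s")
  res2 <- computeMDS(scaled, fx$seg)
  expect_equal(meanMDS(res2), 2 * meanMDS(res), tolerance = 1e-12)
  # adding a constant shifts intercepts, not slopes
  shifted <- ScalarVolume(volData(fx$adc) + 3e-4, volSpacing(fx$adc),
                          volAffine(fx$adc), units = "mm2_per_s")
  res3 <- computeMDS(shifted, fx$seg)
  expect_equal(meanMDS(res3), meanMDS(res), tolerance = 1e-12)
})

test_that("a focus with no surrounding abnormality yields the undefined sentinel", {
  sc <- defaultLabelScheme()
  labels <- array(sc[["background"]], c(24, 24, 24))
  r <- mdslope:::radialDistance(c(24, 24, 24), c(1, 1, 1), c(11.5, 11.5, 11.5))
  labels[r <= 6] <- sc[["enhancing"]]
  seg <- SegmentationVolume(labels, spacing = c(1, 1, 1))
  adc <- ScalarVolume(array(7e-4, c(24, 24, 24)), spacing = c(1, 1, 1))
  res <- computeMDS(adc, seg)
  expect_equal(nValidProfiles(res), 0L)
  expect_true(is.na(meanMDS(res)))   # explicit sentinel, never 0
})

test_that("ground-truth recovery: ramp covering the valid run is recovered to 5%", {
  fx <- makeSyntheticPatient(transition_width_mm = 9, flair_margin_mm = 4.5,
                             noise_sd = 0)
  res <- computeMDS(fx$adc, fx$seg)
  expect_lt(abs(meanMDS(res) - fx$true_slope) / fx$true_slope, 0.05)
  expect_gt(nValidProfiles(res), 500)
})

test_that("per-vector correlation maps detect imposed monotone relations", {
  # parallel axis-aligned vectors on a 0.5 mm grid: every sample lands on a
  # voxel centre, so profile values are exact voxel values (no interpolation
  # smoothing, which would correlate neighbouring samples)
  ny <- 60
  base <- cbind(rep(2, ny), 0.5 * (seq_len(ny) - 1))
  dirs <- cbind(rep(1, ny), rep(0, ny))
  fld <- manualField(base, dirs, gridDim = c(24, ny), spacing = c(0.5, 0.5))
  set.seed(4)
  a <- array(runif(24 * ny), c(24, ny))
  va <- ScalarVolume(a, spacing = c(0.5, 0.5))
  vb <- ScalarVolume(1 - a, spacing = c(0.5, 0.5))
  pc <- profileCorrelationMap(va, vb, fld)
  expect_equal(pc$rho, rep(-1, ny))
  expect_equal(pc$one_minus_p, 1 - pc$p)
  # independent volumes: weak correlations, ~5% nominal false positives
  reps <- lapply(1:10, function(i) {
    set.seed(100 + i)
    x <- ScalarVolume(array(rnorm(24 * ny), c(24, ny)), c(0.5, 0.5))
    y <- ScalarVolume(array(rnorm(24 * ny), c(24, ny)), c(0.5, 0.5))
    profileCorrelationMap(x, y, fld)
  })
  allp <- unlist(lapply(reps, `[[`, "p"))
  allrho <- unlist(lapply(reps, `[[`, "rho"))
  expect_lt(abs(mean(allp < 0.05, na.rm = TRUE) - 0.05), 0.03)
  expect_lt(mean(abs(allrho), na.rm = TRUE), 0.3)
  # runs shorter than 4 samples are flagged with NA rather than fitted
  strip <- manualField(base = matrix(c(0.5, 5), 1),
                       dirs = matrix(c(-1, 0), 1),
                       gridDim = c(2, 21), spacing = c(1, 1))
  sa <- ScalarVolume(array(runif(42), c(2, 21)), c(1, 1))
  sb <- ScalarVolume(1 - volData(sa), c(1, 1))
  expect_true(is.na(profileCorrelationMap(sa, sb, strip)$rho))
})
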