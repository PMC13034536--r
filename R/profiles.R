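#' @include surface-vectors.R
NULL

#' Sample centrifugal profiles along a vector field
#'
#' Samples a scalar volume along each outward normal over a fixed window
#' relative to the boundary (negative positions inside the ROI), at a fixed
#' rate, by bilinear (2D) or trilinear (3D) interpolation in world space.
#' Positions falling outside the volume are recorded as missing, never
#' zero-filled.
#'
#' @param volume a [ScalarVolume-class].
#' @param field a [SurfaceVectorField-class] on the same grid.
#' @param window_mm length-2 numeric, window start/end in mm (default
#'   `c(-2, 6)`).
#' @param rate_per_mm samples per mm (default 2, i.e. a 0.5 mm interval).
#' @return A [ProfileSet-class]; validity fields are unset until
#'   [applyValidityFilter()] is applied.
#' @export
sampleProfiles <- function(volume, field, window_mm = c(-2, 6),
                           rate_per_mm = 2) {
  v <- field@vectors
  if (nrow(v) == 0L) stop("empty vector field")
  d <- length(dim(volData(volume)))
  sp <- samplePoints(v, window_mm, rate_per_mm, d)
  vox <- worldToVoxel(sp$world, volAffine(volume))
  vals <- interpolateVoxel(volData(volume), vox)
  samples <- data.frame(vector_id = sp$vector_id, k = sp$k,
                        arc_mm = rep(sp$arcs, nrow(v)), value = vals,
                        in_flair = NA)
  profiles <- data.frame(vector_id = v$id, valid = NA,
                         run_start = NA_integer_, run_end = NA_integer_,
                         n_contiguous_mm = NA_real_)
  new("ProfileSet", samples = samples, profiles = profiles,
      params = list(window_mm = window_mm, rate_per_mm = rate_per_mm,
                    min_contiguous_mm = NA_real_))
}

#' Apply the abnormality/contiguity validity filter
#'
#' Marks each sample as inside the combined tumour-abnormality region
#' (enhancing tumour, non-enhancing core, or FLAIR abnormality: the inner
#' part of the window lies in enhancing tumour, which the FLAIR class alone
#' would exclude) and finds, per profile, the longest consecutive run of
#' in-abnormality, non-missing samples that contains the boundary crossing
#' (arc = 0). A profile is valid iff that run spans strictly more than
#' `min_contiguous_mm` millimetres. Missing (out-of-volume) samples break
#' contiguity and are never imputed. Slope fitting later uses only the
#' samples of this run.
#'
#' @param profiles a [ProfileSet-class].
#' @param seg a [SegmentationVolume-class] on the sampled grid.
#' @param field the [SurfaceVectorField-class] the profiles came from.
#' @param min_contiguous_mm contiguity threshold in mm (strict `>`;
#'   default 4).
#' @param roles roles whose union defines the measurable abnormality.
#' @return The [ProfileSet-class] with `in_flair`, run bounds and `valid`
#'   filled in.
#' @export
applyValidityFilter <- function(profiles, seg, field,
                                min_contiguous_mm = 4,
                                roles = c("enhancing", "nonenhancing_core",
                                          "flair_abnormality")) {
  s <- profiles@samples
  dm <- dim(volData(seg))
  d <- length(dm)
  v <- field@vectors
  sp <- samplePoints(v, profiles@params$window_mm,
                     profiles@params$rate_per_mm, d)
  vox <- worldToVoxel(sp$world, volAffine(seg))
  idx <- containingVoxel(vox, dm)
  ok <- stats::complete.cases(idx)
  ab <- roleMask(seg, roles)
  inAb <- rep(FALSE, nrow(idx))
  inAb[ok] <- ab[linearIndex(idx[ok, , drop = FALSE], dm)]
  s$in_flair <- inAb
  rate <- profiles@params$rate_per_mm
  arcs <- sort(unique(s$arc_mm))
  k0 <- which.min(abs(arcs))             # boundary-crossing sample
  p <- profiles@profiles
  m <- length(arcs)
  usable <- matrix(s$in_flair & !is.na(s$value), nrow = m)  # samples x vectors
  for (j in seq_len(nrow(p))) {
    u <- usable[, j]
    if (!u[k0]) {
      p$run_start[j] <- NA_integer_; p$run_end[j] <- NA_integer_
      p$n_contiguous_mm[j] <- 0; p$valid[j] <- FALSE
      next
    }
    lo <- k0; while (lo > 1L && u[lo - 1L]) lo <- lo - 1L
    hi <- k0; while (hi < m && u[hi + 1L]) hi <- hi + 1L
    span <- (hi - lo) / rate
    p$run_start[j] <- lo; p$run_end[j] <- hi
    p$n_contiguous_mm[j] <- span
    p$valid[j] <- span > min_contiguous_mm
  }
  new("ProfileSet", samples = s, profiles = p,
      params = utils::modifyList(profiles@params,
                                 list(min_contiguous_mm = min_contiguous_mm)))
}

#' Ordinary least-squares slope of one profile
#'
#' Regresses sampled values against the sample index and converts the
#' per-index slope to a per-mm slope by multiplying by the sampling rate
#' (points per mm); this is numerically identical to regressing directly on
#' the arc position in mm. Units are (mm\eqn{^2}/s)/mm when the input is an
#' ADC map.
#'
#' @param values numeric vector of consecutive profile samples (no NA).
#' @param rate_per_mm sampling rate (points per mm).
#' @return list with `slope` (per mm), `intercept` (value at the first
#'   sample), `r_squared` and `n`.
#' @export
fitSlope <- function(values, rate_per_mm = 2) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 samples to fit a slope")
  k <- seq_len(n)
  kc <- k - mean(k)
  b_index <- sum(kc * values) / sum(kc^2)
  slope <- b_index * rate_per_mm
  intercept <- mean(values) - b_index * mean(k) + b_index
  ssTot <- sum((values - mean(values))^2)
  ssRes <- sum((values - (intercept + b_index * (k - 1)))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
  list(slope = slope, intercept = intercept, r_squared = r2, n = n)
}

# Fit slopes for all valid profiles of a filtered ProfileSet.
fitProfileSlopes <- function(profiles) {
  p <- profiles@profiles
  s <- profiles@samples
  rate <- profiles@params$rate_per_mm
  m <- length(unique(s$k))
  valmat <- matrix(s$value, nrow = m)
  rows <- list()
  for (j in which(p$valid %in% TRUE)) {
    run <- p$run_start[j]:p$run_end[j]
    y <- valmat[run, j]
    if (length(y) < 3L) next   # dropped with diagnostic count downstream
    f <- fitSlope(y, rate)
    rows[[length(rows) + 1L]] <-
      data.frame(vector_id = p$vector_id[j], slope = f$slope,
                 intercept = f$intercept, r_squared = f$r_squared,
                 n_samples_used = f$n)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(vector_id = integer(), slope = numeric(),
                  intercept = numeric(), r_squared = numeric(),
                  n_samples_used = integer())
}

#' Compute the patient-level marginal diffusion slope
#'
#' Full pipeline: refine the enhancing-tumour ROI, extract its boundary,
#' estimate unit outward normals, sample the ADC map centrifugally along
#' each normal, apply the abnormality/contiguity validity filter, fit
#' per-profile OLS slopes over each contiguous run, and average the valid
#' slopes to the patient-level MDS. Deterministic for fixed inputs and
#' parameters.
#'
#' @param adc a [ScalarVolume-class] (ADC in mm\eqn{^2}/s).
#' @param seg a [SegmentationVolume-class] on the same grid, containing the
#'   enhancing role.
#' @param window_mm,rate_per_mm,min_contiguous_mm sampling/validity
#'   parameters (defaults: \eqn{-2} to \eqn{+6} mm window, 2 samples/mm,
#'   strict 4 mm contiguity).
#' @param closing_radius_vox,min_component_voxels,kernel_vox ROI-refinement
#'   and normal-estimation parameters (see [refineROI()],
#'   [estimateNormals()]).
#' @param keep_profiles logical; attach the filtered [ProfileSet-class] as
#'   attribute `"profiles"` of the result.
#' @return An [MDSResult-class]. When no profile is valid, `meanMDS` is the
#'   explicit `NA_real_` sentinel (never 0).
#' @examples
#' fx <- makeSyntheticPatient(grid_shape = c(40, 40, 40),
#'   core_semiaxes_mm = c(6, 6, 6), transition_width_mm = 4, noise_sd = 0)
#' res <- computeMDS(fx$adc, fx$seg)
#' meanMDS(res) / fx$true_slope
#' @export
computeMDS <- function(adc, seg, window_mm = c(-2, 6), rate_per_mm = 2,
                       min_contiguous_mm = 4, closing_radius_vox = 1,
                       min_component_voxels = 5, kernel_vox = 5,
                       keep_profiles = FALSE) {
  assertSameGrid(adc, seg)
  mask <- roleMask(seg, "enhancing")
  if (!any(mask)) stop("empty ROI: no enhancing voxels in segmentation")
  roi <- refineROI(mask, closing_radius_vox, min_component_voxels)
  bnd <- extractBoundary(roi)
  field <- estimateNormals(bnd, roi, kernel_vox, volSpacing(adc),
                           volAffine(adc))
  prof <- sampleProfiles(adc, field, window_mm, rate_per_mm)
  prof <- applyValidityFilter(prof, seg, field, min_contiguous_mm)
  fits <- fitProfileSlopes(prof)
  nTotal <- nrow(field@vectors)
  nValid <- nrow(fits)
  res <- new("MDSResult", perProfile = fits,
             meanMDS = if (nValid > 0) mean(fits$slope) else NA_real_,
             nValid = as.integer(nValid), nTotal = as.integer(nTotal),
             params = list(window_mm = window_mm, rate_per_mm = rate_per_mm,
                           min_contiguous_mm = min_contiguous_mm,
                           closing_radius_vox = closing_radius_vox,
                           min_component_voxels = min_component_voxels,
                           kernel_vox = kernel_vox))
  if (keep_profiles) {
    attr(res, "profiles") <- prof
    attr(res, "field") <- field
  }
  res
}

#' Per-vector rank correlation between two volumes along profiles
#'
#' Samples two co-registered volumes along the same vector field and
#' computes, per vector, Spearman's rho with a two-sided p-value between
#' the paired profile values over the usable (both non-missing) samples.
#' Used to probe the spatial diffusion-cellularity relation along
#' centrifugal profiles.
#'
#' @param vol_a,vol_b [ScalarVolume-class] objects on one grid.
#' @param field a [SurfaceVectorField-class].
#' @param window_mm,rate_per_mm sampling parameters (shared by both
#'   volumes).
#' @param min_samples minimum paired samples for a defined rho (default 4;
#'   shorter runs are flagged with NA).
#' @return data.frame with `vector_id`, `rho`, `p`, `one_minus_p`,
#'   `n_used`.
#' @export
profileCorrelationMap <- function(vol_a, vol_b, field, window_mm = c(-2, 6),
                                  rate_per_mm = 2, min_samples = 4) {
  assertSameGrid(vol_a, vol_b)
  pa <- sampleProfiles(vol_a, field, window_mm, rate_per_mm)
  pb <- sampleProfiles(vol_b, field, window_mm, rate_per_mm)
  m <- length(unique(pa@samples$k))
  va <- matrix(pa@samples$value, nrow = m)
  vb <- matrix(pb@samples$value, nrow = m)
  ids <- field@vectors$id
  out <- data.frame(vector_id = ids, rho = NA_real_, p = NA_real_,
                    one_minus_p = NA_real_, n_used = 0L)
  for (j in seq_along(ids)) {
    use <- !is.na(va[, j]) & !is.na(vb[, j])
    out$n_used[j] <- sum(use)
    if (sum(use) < min_samples) next
    ct <- suppressWarnings(stats::cor.test(va[use, j], vb[use, j],
                                           method = "spearman",
                                           exact = FALSE))
    out$rho[j] <- unname(ct$estimate)
    out$p[j] <- ct$p.value
    out$one_minus_p[j] <- 1 - ct$p.value
  }
  out
}
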