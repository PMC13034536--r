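#' @include profiles.R
NULL

#' Radial-gradient sphere phantom
#'
#' Builds the analytic validation phantom: a scalar volume whose value at
#' each voxel is `v_at_centre + gradient_per_mm * r`, with `r` the world-mm
#' distance from the phantom centre, plus a co-centred ball ROI whose
#' surface seeds the vector field. Because the field is exactly radial, the
#' pipeline's recovered mean slope can be compared against the imposed
#' gradient.
#'
#' @param grid_shape integer vector (length 3, or 2 for a disc phantom).
#' @param spacing voxel spacing in mm.
#' @param radius_mm ball ROI radius; must fit in the grid with >= 3 voxels
#'   margin.
#' @param gradient_per_mm imposed radial gradient (value units per mm).
#' @param v_at_centre value at the centre.
#' @param centre_mm phantom centre in world mm (default: grid centre).
#' @return list with `volume` ([ScalarVolume-class]), `mask` (logical ball)
#'   and `seg` (a [SegmentationVolume-class] with the ball as enhancing
#'   tumour and everything else as measurable abnormality, ready for
#'   [computeMDS()]).
#' @export
makeSpherePhantom <- function(grid_shape = c(48, 48, 48), spacing = 1,
                              radius_mm = 10, gradient_per_mm = 1,
                              v_at_centre = 100, centre_mm = NULL) {
  d <- length(grid_shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, d)
  affine <- spacingAffine(spacing)
  if (is.null(centre_mm)) centre_mm <- (grid_shape - 1) / 2 * spacing
  r <- radialDistance(grid_shape, spacing, centre_mm)
  margin <- centre_mm - radius_mm
  margin2 <- (grid_shape - 1) * spacing - centre_mm - radius_mm
  if (any(margin < 3 * spacing) || any(margin2 < 3 * spacing))
    stop("ball exceeds grid: need >= 3 voxels margin on every side")
  vol <- ScalarVolume(v_at_centre + gradient_per_mm * r, spacing = spacing,
                      affine = affine, units = "arbitrary")
  mask <- array(r <= radius_mm, grid_shape)
  sc <- defaultLabelScheme()
  labels <- array(sc[["flair_abnormality"]], grid_shape)
  labels[mask] <- sc[["enhancing"]]
  seg <- SegmentationVolume(labels, spacing = spacing, affine = affine)
  list(volume = vol, mask = mask, seg = seg)
}

# World-mm distance of every voxel centre from a point.
radialDistance <- function(grid_shape, spacing, centre_mm) {
  d <- length(grid_shape)
  ax <- lapply(seq_len(d), function(k) ((seq_len(grid_shape[k]) - 1) *
                                          spacing[k] - centre_mm[k])^2)
  r2 <- Reduce(function(acc, k) {
    acc + array(ax[[k]][slice.index(array(0, grid_shape), k)], grid_shape)
  }, seq_len(d), init = array(0, grid_shape))
  sqrt(r2)
}

#' Gaussian-cellularity diffusion model
#'
#' The in-silico apparatus probing MDS sensitivity: tumour cell density is
#' an isotropic Gaussian \eqn{\rho(x) = \rho_{peak} e^{-r^2/2\sigma^2}};
#' diffusivity follows Graham's relation \eqn{D \propto 1/\sqrt{\rho}}
#' (with a small background-cellularity floor so the far field is finite),
#' rescaled affinely so that D plateaus at common brain-parenchyma rates
#' far from the tumour and is minimal (`d_core`) at peak cellularity. The
#' simulated tumour core is the set of voxels with cellularity at or above
#' `core_threshold` of the peak.
#'
#' @param sigma_mm Gaussian SD of the cellularity front (mm); the knob that
#'   controls how infiltrative the margin is.
#' @param rho_peak peak cellularity (arbitrary units).
#' @param core_threshold cellularity fraction defining the core (in (0,1)).
#' @param d_plateau far-field diffusivity, mm\eqn{^2}/s (default 8e-4).
#' @param d_core diffusivity at peak cellularity, mm\eqn{^2}/s.
#' @param rho_floor background cellularity floor (default 1e-5 of peak).
#' @param grid_shape,spacing grid (default 2D, 256 x 256 at 0.5 mm).
#' @param centre_mm tumour centre (default grid centre).
#' @return list with `cellularity`, `diffusion`, `raw_diffusion`
#'   ([ScalarVolume-class] each; raw is the unscaled Graham value
#'   \eqn{1/\sqrt{\rho + floor}}), `core_mask`, and the model parameters.
#' @export
makeGaussianTumour <- function(sigma_mm, rho_peak = 1, core_threshold = 0.5,
                               d_plateau = 8e-4, d_core = 3e-4,
                               rho_floor = 1e-5 * rho_peak,
                               grid_shape = c(256, 256), spacing = 0.5,
                               centre_mm = NULL) {
  stopifnot(sigma_mm > 0, core_threshold > 0, core_threshold < 1,
            d_plateau > 0, d_core < d_plateau)
  d <- length(grid_shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, d)
  if (is.null(centre_mm)) centre_mm <- (grid_shape - 1) / 2 * spacing
  if (sigma_mm < min(spacing))
    warning("sigma smaller than one voxel: diffusion front under-resolved")
  affine <- spacingAffine(spacing)
  r <- radialDistance(grid_shape, spacing, centre_mm)
  rho <- rho_peak * exp(-r^2 / (2 * sigma_mm^2))
  raw <- 1 / sqrt(rho + rho_floor)
  raw_min <- 1 / sqrt(rho_peak + rho_floor)   # at peak cellularity
  raw_max <- 1 / sqrt(rho_floor)              # far field
  D <- d_core + (raw - raw_min) / (raw_max - raw_min) * (d_plateau - d_core)
  core_mask <- array(rho >= core_threshold * rho_peak, grid_shape)
  list(cellularity = ScalarVolume(rho, spacing, affine,
                                  units = "normalized_density"),
       diffusion = ScalarVolume(D, spacing, affine, units = "mm2_per_s"),
       raw_diffusion = ScalarVolume(raw, spacing, affine,
                                    units = "arbitrary"),
       core_mask = core_mask,
       params = list(sigma_mm = sigma_mm, rho_peak = rho_peak,
                     core_threshold = core_threshold, d_plateau = d_plateau,
                     d_core = d_core, rho_floor = rho_floor,
                     centre_mm = centre_mm))
}

#' Nested band ROIs across the diffusion decay region
#'
#' Thresholds the simulated diffusion map at linearly spaced levels between
#' the core-edge diffusivity and the plateau (endpoints excluded: the
#' plateau level set is the whole grid) and returns the nested level-set
#' ROIs `{D <= t_k}`, smallest first.
#'
#' @param diffusion diffusion [ScalarVolume-class] from
#'   [makeGaussianTumour()].
#' @param n_steps number of bands (>= 2).
#' @param core_mask the simulated core.
#' @return list of logical masks, strictly nested
#'   `ROI_1 < ROI_2 < ... < ROI_n`, each containing the core.
#' @export
bandROIs <- function(diffusion, n_steps, core_mask) {
  if (n_steps < 2) stop("n_steps must be >= 2")
  D <- volData(diffusion)
  d_edge <- max(D[core_mask])
  d_far <- max(D)
  th <- d_edge + seq_len(n_steps) / (n_steps + 1) * (d_far - d_edge)
  lapply(th, function(t) array(D <= t, dim(D)))
}

#' Infiltration sweep: mean MDS versus Gaussian front width
#'
#' For each front SD, builds the Gaussian-cellularity model, takes the
#' simulated core as the tumour ROI, and runs the full MDS pipeline on the
#' diffusion map. More infiltrative margins (larger sigma) yield a
#' shallower marginal slope, so `mean_mds` decreases with sigma.
#'
#' @param sigmas_mm numeric vector of front SDs (>= 2 values).
#' @param ... model parameters forwarded to [makeGaussianTumour()].
#' @param window_mm,rate_per_mm,min_contiguous_mm MDS sampling parameters.
#' @return data.frame with `sigma_mm`, `mean_mds`, `n_valid`, `n_total`.
#' @export
runInfiltrationSweep <- function(sigmas_mm, ..., window_mm = c(-2, 6),
                                 rate_per_mm = 2, min_contiguous_mm = 4) {
  if (length(sigmas_mm) < 2) stop("need at least 2 sigmas")
  rows <- lapply(sigmas_mm, function(sg) {
    mod <- tryCatch(makeGaussianTumour(sigma_mm = sg, ...),
                    error = function(e) stop("sigma ", sg, " mm: ",
                                             conditionMessage(e)))
    seg <- segFromCore(mod$core_mask, volSpacing(mod$diffusion),
                       volAffine(mod$diffusion))
    res <- tryCatch(
      computeMDS(mod$diffusion, seg, window_mm = window_mm,
                 rate_per_mm = rate_per_mm,
                 min_contiguous_mm = min_contiguous_mm),
      error = function(e) stop("sigma ", sg, " mm: ", conditionMessage(e)))
    data.frame(sigma_mm = sg, mean_mds = meanMDS(res),
               n_valid = nValidProfiles(res), n_total = nTotalProfiles(res))
  })
  do.call(rbind, rows)
}

# Segmentation wrapper for simulated ROIs: core is enhancing tumour, all
# remaining voxels are measurable abnormality (the simulator has no
# anatomical boundaries to exclude).
segFromCore <- function(core_mask, spacing, affine) {
  sc <- defaultLabelScheme()
  labels <- array(sc[["flair_abnormality"]], dim(core_mask))
  labels[core_mask] <- sc[["enhancing"]]
  SegmentationVolume(labels, spacing = spacing, affine = affine)
}
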