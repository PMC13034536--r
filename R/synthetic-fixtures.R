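#' @include simulation.R
NULL

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All fixture randomness flows through this.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# First-order signed distance (mm) to an ellipsoid surface: negative inside.
# Exact for spheres; near-surface accurate otherwise, which is where the
# transition ramp lives.
ellipsoidSignedDistance <- function(grid_shape, spacing, centre_mm,
                                    semiaxes_mm, orientation = NULL) {
  d <- length(grid_shape)
  ax <- lapply(seq_len(d), function(k) (seq_len(grid_shape[k]) - 1) *
                 spacing[k] - centre_mm[k])
  X <- lapply(seq_len(d), function(k) {
    array(ax[[k]][slice.index(array(0L, grid_shape), k)], grid_shape)
  })
  if (!is.null(orientation)) {  # body-frame coordinates: R^T (x - c)
    X <- lapply(seq_len(d), function(i) {
      Reduce(`+`, lapply(seq_len(d), function(j) orientation[j, i] * X[[j]]))
    })
  }
  l2 <- Reduce(`+`, lapply(seq_len(d), function(k) (X[[k]] / semiaxes_mm[k])^2))
  l <- sqrt(l2)
  g <- sqrt(Reduce(`+`, lapply(seq_len(d), function(k)
    (X[[k]] / semiaxes_mm[k]^2)^2)))
  ds <- (l - 1) * l / pmax(g, 1e-12)
  ds[l2 == 0] <- -min(semiaxes_mm)
  ds
}

#' Synthetic patient with a known marginal ADC slope
#'
#' Builds a co-registered ADC map and segmentation with controllable ground
#' truth: an ellipsoidal enhancing core at `adc_core`, a linear ADC ramp of
#' width `transition_width_mm` centred across the core boundary (slope
#' `(adc_plateau - adc_core)/transition_width_mm` along the boundary
#' normal), a plateau at `adc_plateau` outside, optional additive Gaussian
#' noise, and a surrounding FLAIR-abnormality shell of thickness
#' `flair_margin_mm`. The true slope is returned with the data so recovery
#' can be scored without external references.
#'
#' @param grid_shape,spacing_mm grid (default 48^3 at 1 mm isotropic).
#' @param core_semiaxes_mm ellipsoid semi-axes of the enhancing core (mm).
#' @param centre_mm core centre (default grid centre).
#' @param flair_margin_mm thickness of the abnormality shell beyond the
#'   core surface; must reach at least the outer half of the ramp, else the
#'   imposed truth would be truncated and the spec is refused.
#' @param adc_core,adc_plateau core and far-field ADC (mm\eqn{^2}/s);
#'   plateau must exceed core.
#' @param transition_width_mm full width of the linear ramp (centred on the
#'   boundary).
#' @param noise_sd additive Gaussian noise SD (mm\eqn{^2}/s).
#' @param seed RNG seed for the noise.
#' @param orientation optional rotation matrix giving the ellipsoid's body
#'   frame (for rigid-rotation invariance studies).
#' @return list with `adc` ([ScalarVolume-class]), `seg`
#'   ([SegmentationVolume-class]: enhancing core + FLAIR shell),
#'   `true_slope` ((mm\eqn{^2}/s)/mm), `core_mask`, and `spec` (the
#'   parameters).
#' @export
makeSyntheticPatient <- function(grid_shape = c(48, 48, 48), spacing_mm = 1,
                                 core_semiaxes_mm = c(8, 8, 8),
                                 centre_mm = NULL, flair_margin_mm = 8,
                                 adc_core = 6e-4, adc_plateau = 8e-4,
                                 transition_width_mm = 4, noise_sd = 0,
                                 seed = 1, orientation = NULL) {
  d <- length(grid_shape)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, d)
  if (is.null(centre_mm)) centre_mm <- (grid_shape - 1) / 2 * spacing_mm
  stopifnot(adc_plateau > adc_core, transition_width_mm > 0)
  if (transition_width_mm / 2 > flair_margin_mm)
    stop("transition ramp (", transition_width_mm / 2,
         " mm beyond the boundary) extends past the FLAIR margin (",
         flair_margin_mm, " mm): imposed truth would be truncated")
  ds <- ellipsoidSignedDistance(grid_shape, spacing_mm, centre_mm,
                                core_semiaxes_mm, orientation)
  core_mask <- array(ds <= 0, grid_shape)
  w <- transition_width_mm
  s <- (adc_plateau - adc_core) / w
  adc <- adc_core + s * pmin(pmax(ds + w / 2, 0), w)
  if (noise_sd > 0)
    adc <- adc + withSeed(seed, stats::rnorm(length(adc), 0, noise_sd))
  adc <- array(adc, grid_shape)
  sc <- defaultLabelScheme()
  labels <- array(sc[["background"]], grid_shape)
  labels[ds > 0 & ds <= flair_margin_mm] <- sc[["flair_abnormality"]]
  labels[core_mask] <- sc[["enhancing"]]
  affine <- spacingAffine(spacing_mm)
  list(adc = ScalarVolume(adc, spacing_mm, affine, units = "mm2_per_s"),
       seg = SegmentationVolume(labels, spacing_mm, affine),
       true_slope = s, core_mask = core_mask,
       spec = list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                   core_semiaxes_mm = core_semiaxes_mm,
                   centre_mm = centre_mm, flair_margin_mm = flair_margin_mm,
                   adc_core = adc_core, adc_plateau = adc_plateau,
                   transition_width_mm = transition_width_mm,
                   noise_sd = noise_sd, seed = seed))
}

#' Synthetic rodent: paired ADC and tumour-cell-density maps
#'
#' Emulates a co-registered MRI-histology pair: tumour cell density is an
#' isotropic 2D Gaussian (normalized to peak 1) of SD `sigma_mm`; the
#' noiseless ADC is a monotone decreasing function of the cell density seen
#' at imaging resolution (the density is blurred by a fixed point-spread
#' width `psf_mm` before the relation is applied, reflecting that MRI
#' resolves far coarser structure than histology). The TCD footprint mask
#' thresholds the raw density; the ADC ROI thresholds the noiseless ADC at
#' the level corresponding to half-peak blurred density. Because the
#' imaging blur is fixed in mm while the lesion scales with `sigma_mm`, the
#' TCD/ADC footprint ratio increases with sigma, giving the infiltration
#' index a known ordering.
#'
#' @param grid_shape,spacing_mm grid (default 160 x 160 at 0.2 mm).
#' @param sigma_mm SD of the cellularity Gaussian (mm).
#' @param relation monotone decreasing function mapping density in `[0,1]`
#'   to ADC (mm\eqn{^2}/s); default affine from 8e-4 down to 3e-4.
#' @param noise_sd additive Gaussian noise SD on ADC.
#' @param seed RNG seed.
#' @param psf_mm imaging point-spread SD (mm; default 0.4, typical of preclinical DWI in-plane resolution).
#' @param tcd_threshold density fraction defining the histology footprint
#'   (default 0.1 of peak).
#' @param centre_mm lesion centre (default grid centre).
#' @return list with `adc`, `tcd`, `adc_noiseless` ([ScalarVolume-class]),
#'   `adc_roi_mask`, `tcd_mask`, and `params`.
#' @export
makeSyntheticRodent <- function(grid_shape = c(160, 160), spacing_mm = 0.2,
                                sigma_mm = 1.5,
                                relation = function(t) 8e-4 - 5e-4 * t,
                                noise_sd = 0, seed = 1, psf_mm = 0.4,
                                tcd_threshold = 0.1, centre_mm = NULL) {
  d <- length(grid_shape)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, d)
  if (is.null(centre_mm)) centre_mm <- (grid_shape - 1) / 2 * spacing_mm
  tt <- seq(0, 1, length.out = 101)
  if (any(diff(relation(tt)) >= 0))
    stop("relation must be strictly monotone decreasing on [0, 1]")
  r <- radialDistance(grid_shape, spacing_mm, centre_mm)
  tcd <- exp(-r^2 / (2 * sigma_mm^2))
  sig_img <- sqrt(sigma_mm^2 + psf_mm^2)
  tcd_img <- (sigma_mm^2 / sig_img^2)^(d / 2) * exp(-r^2 / (2 * sig_img^2))
  adc0 <- relation(tcd_img)
  adc <- adc0
  if (noise_sd > 0)
    adc <- adc + withSeed(seed, stats::rnorm(length(adc), 0, noise_sd))
  adc <- array(adc, grid_shape)
  half_peak <- relation(max(tcd_img) / 2)
  adc_roi_mask <- array(adc0 <= half_peak, grid_shape)
  tcd_mask <- array(tcd >= tcd_threshold, grid_shape)
  affine <- spacingAffine(spacing_mm)
  list(adc = ScalarVolume(adc, spacing_mm, affine, units = "mm2_per_s"),
       adc_noiseless = ScalarVolume(array(adc0, grid_shape), spacing_mm,
                                    affine, units = "mm2_per_s"),
       tcd = ScalarVolume(array(tcd, grid_shape), spacing_mm, affine,
                          units = "normalized_density"),
       adc_roi_mask = adc_roi_mask, tcd_mask = tcd_mask,
       params = list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                     sigma_mm = sigma_mm, noise_sd = noise_sd, seed = seed,
                     psf_mm = psf_mm, tcd_threshold = tcd_threshold,
                     centre_mm = centre_mm))
}

#' Synthetic survival cohort with a known hazard model
#'
#' Draws per-patient MDS from a normal distribution, standardizes it, and
#' draws overall survival from an exponential with rate
#' `baseline_rate * exp(beta_log_hr_per_sd * z)`; age is independent. All
#' events are observed, matching a fully followed-up cohort. Fully
#' reproducible from the seed.
#'
#' @param n cohort size (>= 2).
#' @param beta_log_hr_per_sd true log hazard ratio per 1 SD of MDS
#'   (default `log(0.5)`: higher MDS halves the hazard per SD).
#' @param baseline_rate exponential baseline hazard per day.
#' @param seed RNG seed.
#' @param mds_mean,mds_sd distribution of raw MDS ((mm\eqn{^2}/s)/mm).
#' @return data.frame (`CohortTable`) with `patient_id`, `mds`, `os_days`
#'   (integer > 0), `age_years`, `event` (all 1).
#' @export
makeSyntheticCohort <- function(n, beta_log_hr_per_sd = log(0.5),
                                baseline_rate = 1 / 500, seed = 1,
                                mds_mean = 5e-5, mds_sd = 2e-5) {
  stopifnot(n >= 2)
  withSeed(seed, {
    mds <- stats::rnorm(n, mds_mean, mds_sd)
    z <- as.vector(scale(mds))
    os <- stats::rexp(n, rate = baseline_rate * exp(beta_log_hr_per_sd * z))
    age <- stats::rnorm(n, 62, 10)
    data.frame(patient_id = sprintf("P%04d", seq_len(n)), mds = mds,
               os_days = pmax(1L, as.integer(ceiling(os))),
               age_years = round(age, 1), event = 1L)
  })
}
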