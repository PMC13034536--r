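#' @include profiles.R
NULL

#' Perifocal bands of increasing thickness around an ROI
#'
#' `band_k = dilate(roi, k) \ roi` for k = 1..`max_thickness_vox`, with
#' Euclidean-ball dilation in voxel units, so the bands are nested by
#' construction. Bands reaching the grid edge are clipped with a warning.
#'
#' @param roi_mask logical array (refined ROI).
#' @param max_thickness_vox largest band thickness in voxels.
#' @return list of logical band masks, `band_1 < band_2 < ...`, each
#'   disjoint from the ROI.
#' @export
perifocalBands <- function(roi_mask, max_thickness_vox) {
  stopifnot(max_thickness_vox >= 1)
  d <- length(dim(roi_mask))
  bands <- vector("list", max_thickness_vox)
  for (k in seq_len(max_thickness_vox)) {
    dil <- binaryDilate(roi_mask, k)
    if (edgeTouches(dil)) warning("band ", k, " reaches the grid edge; clipped")
    bands[[k]] <- dil & !roi_mask
  }
  bands
}

edgeTouches <- function(mask) {
  dm <- dim(mask)
  if (length(dm) == 2L)
    any(mask[1, ], mask[dm[1], ], mask[, 1], mask[, dm[2]])
  else
    any(mask[1, , ], mask[dm[1], , ], mask[, 1, ], mask[, dm[2], ],
        mask[, , 1], mask[, , dm[3]])
}

#' Voxelwise ADC-versus-cellularity fit over a band
#'
#' Pairs ADC with normalized tumour cell density over the voxels of a
#' perifocal band and reports the OLS slope of ADC on TCD together with
#' Pearson and Spearman coefficients (two-sided p).
#'
#' @param adc,tcd [ScalarVolume-class] objects on one grid.
#' @param band_mask logical array selecting the band voxels.
#' @param min_voxels fits over fewer voxels are refused (default 10).
#' @return list (`BandFitResult`): `thickness_vox` (NA here; filled by
#'   callers that know it), `n_voxels`, `slope`, `intercept`, `pearson_r`,
#'   `spearman_rho`, `p` (Pearson two-sided).
#' @export
voxelwiseFit <- function(adc, tcd, band_mask, min_voxels = 10) {
  assertSameGrid(adc, tcd)
  x <- volData(tcd)[band_mask]
  y <- volData(adc)[band_mask]
  use <- !is.na(x) & !is.na(y)
  x <- x[use]; y <- y[use]
  if (length(x) < min_voxels)
    stop("band has ", length(x), " voxels; need >= ", min_voxels)
  fit <- stats::lm.fit(cbind(1, x), y)
  ct <- stats::cor.test(x, y, method = "pearson")
  rho <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  list(thickness_vox = NA_integer_, n_voxels = length(x),
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       pearson_r = unname(ct$estimate), spearman_rho = unname(rho$estimate),
       p = ct$p.value)
}

#' Slope-versus-thickness curve over perifocal bands
#'
#' Convenience wrapper running [voxelwiseFit()] for every band thickness.
#'
#' @param adc,tcd [ScalarVolume-class] objects on one grid.
#' @param roi_mask ADC-derived ROI mask.
#' @param max_thickness_vox largest thickness.
#' @param min_voxels forwarded to [voxelwiseFit()].
#' @return data.frame with one row per thickness.
#' @export
bandFitCurve <- function(adc, tcd, roi_mask, max_thickness_vox = 8,
                         min_voxels = 10) {
  bands <- perifocalBands(roi_mask, max_thickness_vox)
  rows <- lapply(seq_along(bands), function(k) {
    f <- voxelwiseFit(adc, tcd, bands[[k]], min_voxels)
    f$thickness_vox <- k
    as.data.frame(f)
  })
  do.call(rbind, rows)
}

#' Infiltration index: histology-to-imaging footprint ratio
#'
#' The ratio of the tumour-cell-density ROI volume to the ADC-abnormality
#' ROI volume; values above 1 indicate tumour infiltration extending beyond
#' what imaging probes.
#'
#' @param tcd_mask,adc_mask logical arrays on one grid; `adc_mask` must be
#'   nonempty.
#' @param spacing optional voxel spacing (mm) to also report mm^2/mm^3
#'   volumes.
#' @return list with `roi_tcd_volume`, `roi_adc_volume` (voxel counts),
#'   `ratio`, and when spacing is given `roi_tcd_mm`, `roi_adc_mm`.
#' @export
infiltrationIndex <- function(tcd_mask, adc_mask, spacing = NULL) {
  if (!any(adc_mask)) stop("empty adc_mask")
  nt <- sum(tcd_mask); na <- sum(adc_mask)
  out <- list(roi_tcd_volume = nt, roi_adc_volume = na, ratio = nt / na)
  if (!is.null(spacing)) {
    vv <- prod(spacing)
    out$roi_tcd_mm <- nt * vv
    out$roi_adc_mm <- na * vv
  }
  out
}

#' Relate mean MDS to the infiltration index across animals
#'
#' Pearson correlation and OLS line of the TCD/ADC volume ratio against
#' mean MDS across animals, with optional exclusion of flagged outliers
#' (e.g. animals whose vectors exceed the brain).
#'
#' @param per_animal data.frame with columns `mean_mds` and `ratio`, and
#'   optionally a logical `exclude` column.
#' @return list with `pearson_r`, `p`, `slope`, `intercept`, `n_used`.
#' @export
mdsVsInfiltration <- function(per_animal) {
  df <- per_animal
  if (!is.null(df$exclude)) df <- df[!df$exclude, , drop = FALSE]
  if (nrow(df) < 3) stop("need >= 3 animals")
  if (stats::sd(df$ratio) == 0 || stats::sd(df$mean_mds) == 0)
    stop("zero variance")
  ct <- stats::cor.test(df$mean_mds, df$ratio)
  fit <- stats::lm.fit(cbind(1, df$mean_mds), df$ratio)
  list(pearson_r = unname(ct$estimate), p = ct$p.value,
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n_used = nrow(df))
}
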