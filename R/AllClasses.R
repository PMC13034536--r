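#' @include AllGenerics.R
NULL

#' Scalar image volume in world millimetres
#'
#' A 2D or 3D scalar field (typically an apparent diffusion coefficient map
#' in mm\eqn{^2}/s, or a normalized tumour-cell-density map) together with
#' its grid geometry. All downstream geometry (profile windows, kernel
#' neighbourhoods, slopes per mm) is computed in world millimetres through
#' the affine, so anisotropic grids are handled correctly.
#'
#' @slot data numeric array of rank 2 or 3; no infinities allowed.
#' @slot spacing mm per voxel along each axis; all components positive.
#' @slot affine homogeneous (d+1)x(d+1) matrix mapping 0-based voxel indices
#'   to world mm.
#' @slot units one of `"mm2_per_s"`, `"normalized_density"`, `"arbitrary"`.
#'
#' @seealso [ScalarVolume()], [readScalarVolume()]
#' @export
setClass("ScalarVolume",
  representation(data = "array", spacing = "numeric", affine = "matrix",
                 units = "character"))

validScalarVolume <- function(object) {
  msg <- character()
  d <- length(dim(object@data))
  if (!d %in% c(2L, 3L)) msg <- c(msg, "data must have rank 2 or 3")
  if (any(!is.finite(object@data) & !is.na(object@data)))
    msg <- c(msg, "data contains infinities")
  if (length(object@spacing) != d) msg <- c(msg, "spacing length must match rank")
  if (any(object@spacing <= 0)) msg <- c(msg, "all spacing components must be > 0")
  if (!identical(dim(object@affine), c(d + 1L, d + 1L)))
    msg <- c(msg, "affine must be (rank+1) x (rank+1)")
  if (!object@units %in% c("mm2_per_s", "normalized_density", "arbitrary"))
    msg <- c(msg, "unknown units tag")
  if (length(msg)) msg else TRUE
}
setValidity("ScalarVolume", validScalarVolume)

#' Construct a ScalarVolume
#'
#' @param data numeric array (2D or 3D).
#' @param spacing voxel spacing in mm per axis; defaults to 1 mm isotropic.
#' @param affine voxel-to-world affine; defaults to a diagonal scaling by
#'   `spacing` with the origin at voxel 0.
#' @param units unit tag, one of `"mm2_per_s"`, `"normalized_density"`,
#'   `"arbitrary"`.
#' @return A [ScalarVolume-class] object.
#' @examples
#' v <- ScalarVolume(array(8e-4, c(4, 4, 4)), spacing = c(1, 1, 2))
#' volSpacing(v)
#' @export
ScalarVolume <- function(data, spacing = rep(1, length(dim(data))),
                         affine = spacingAffine(spacing),
                         units = "arbitrary") {
  new("ScalarVolume", data = data, spacing = as.numeric(spacing),
      affine = affine, units = units)
}

#' Integer label volume bound to a reference grid
#'
#' Segmentation labels on the same grid as a reference [ScalarVolume-class].
#' The scheme maps anatomical roles to integer codes; the default follows
#' the six-class brain-tumour convention (enhancing tumour, non-enhancing
#' core, FLAIR abnormality, GM, WM, CSF over a zero background).
#'
#' @slot labels integer array, same shape as the reference volume.
#' @slot spacing,affine grid geometry (see [ScalarVolume-class]).
#' @slot scheme named integer vector mapping role names to label codes.
#'
#' @seealso [SegmentationVolume()], [readSegmentation()], [defaultLabelScheme()]
#' @export
setClass("SegmentationVolume",
  representation(labels = "array", spacing = "numeric", affine = "matrix",
                 scheme = "integer"))

setValidity("SegmentationVolume", function(object) {
  msg <- character()
  d <- length(dim(object@labels))
  if (!d %in% c(2L, 3L)) msg <- c(msg, "labels must have rank 2 or 3")
  present <- unique(as.vector(object@labels))
  present <- present[present != 0]
  unknown <- setdiff(present, object@scheme)
  if (length(unknown))
    msg <- c(msg, paste0("labels not in scheme: ",
                         paste(sort(unknown), collapse = ", ")))
  if (is.null(names(object@scheme)) || anyDuplicated(object@scheme))
    msg <- c(msg, "scheme must be a named integer vector with unique codes")
  if (length(msg)) msg else TRUE
})

#' Default six-class label scheme
#'
#' @return Named integer vector mapping roles `background`, `enhancing`,
#'   `nonenhancing_core`, `flair_abnormality`, `gm`, `wm`, `csf` to codes
#'   0 through 6.
#' @export
defaultLabelScheme <- function() {
  c(background = 0L, enhancing = 1L, nonenhancing_core = 2L,
    flair_abnormality = 3L, gm = 4L, wm = 5L, csf = 6L)
}

#' Construct a SegmentationVolume
#'
#' @param labels integer array of label codes.
#' @param spacing,affine grid geometry (defaults as in [ScalarVolume()]).
#' @param scheme named integer vector mapping roles to codes.
#' @return A [SegmentationVolume-class] object.
#' @export
SegmentationVolume <- function(labels,
                               spacing = rep(1, length(dim(labels))),
                               affine = spacingAffine(spacing),
                               scheme = defaultLabelScheme()) {
  storage.mode(labels) <- "integer"
  new("SegmentationVolume", labels = labels, spacing = as.numeric(spacing),
      affine = affine, scheme = scheme)
}

#' Surface-normal vector field on a refined ROI boundary
#'
#' Unit outward normals anchored at boundary voxels of a refined tumour
#' mask, estimated by local eigen-decomposition of the boundary-point
#' scatter within a fixed kernel (see [estimateNormals()]).
#'
#' @slot vectors data.frame with one row per vector: `id`, `component_id`,
#'   base-point world coordinates (`x`, `y`, optionally `z`, in mm) and unit
#'   direction components (`nx`, `ny`, optionally `nz`).
#' @slot gridDim integer grid dimensions of the source mask.
#' @slot spacing,affine grid geometry of the source mask.
#' @slot nSkipped number of boundary voxels skipped as degenerate
#'   (fewer than 3 boundary points inside the kernel).
#' @export
setClass("SurfaceVectorField",
  representation(vectors = "data.frame", gridDim = "integer",
                 spacing = "numeric", affine = "matrix",
                 nSkipped = "integer"))

setValidity("SurfaceVectorField", function(object) {
  v <- object@vectors
  need <- c("id", "component_id", "x", "y", "nx", "ny")
  if (!all(need %in% names(v))) return("vectors is missing required columns")
  dcols <- intersect(c("nx", "ny", "nz"), names(v))
  if (nrow(v)) {
    nrm <- sqrt(rowSums(as.matrix(v[dcols])^2))
    if (any(abs(nrm - 1) > 1e-9)) return("directions must be unit length")
  }
  TRUE
})

#' Sampled centrifugal profiles across a boundary
#'
#' Per-vector scalar samples along each outward normal over a fixed window
#' (default \eqn{-2} to \eqn{+6} mm around the boundary at 2 samples/mm),
#' with per-sample abnormality membership and the profile-level validity
#' state set by [applyValidityFilter()].
#'
#' @slot samples data.frame with columns `vector_id`, `k` (sample index,
#'   1-based), `arc_mm` (signed position, negative inside), `value`
#'   (interpolated scalar, NA when out of volume), `in_flair` (logical,
#'   NA before filtering).
#' @slot profiles data.frame with per-vector columns `vector_id`, `valid`,
#'   `run_start`, `run_end` (sample indices of the contiguous usable run)
#'   and `n_contiguous_mm` (its span in mm).
#' @slot params list: `window_mm`, `rate_per_mm`, `min_contiguous_mm`
#'   (NA until filtering).
#' @export
setClass("ProfileSet",
  representation(samples = "data.frame", profiles = "data.frame",
                 params = "list"))

#' Patient-level marginal diffusion slope result
#'
#' @slot perProfile data.frame with per-valid-profile fit results:
#'   `vector_id`, `slope` ((mm\eqn{^2}/s)/mm for ADC input), `intercept`,
#'   `r_squared`, `n_samples_used`.
#' @slot meanMDS arithmetic mean of valid per-profile slopes; `NA_real_`
#'   sentinel when no profile is valid (never 0, which is a meaningful
#'   slope).
#' @slot nValid,nTotal counts of valid and of all seeded profiles.
#' @slot params list of the sampling/validity parameters used.
#' @export
setClass("MDSResult",
  representation(perProfile = "data.frame", meanMDS = "numeric",
                 nValid = "integer", nTotal = "integer", params = "list"))

setValidity("MDSResult", function(object) {
  if (object@nValid > object@nTotal) return("nValid exceeds nTotal")
  TRUE
})

## Accessors ----------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("volData", "ScalarVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("volData", "SegmentationVolume", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("volSpacing", "ScalarVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("volSpacing", "SegmentationVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("volAffine", "ScalarVolume", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("volAffine", "SegmentationVolume", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("volUnits", "ScalarVolume", function(x) x@units)
#' @rdname accessors
#' @export
setMethod("labelScheme", "SegmentationVolume", function(x) x@scheme)
#' @rdname accessors
#' @export
setMethod("meanMDS", "MDSResult", function(x) x@meanMDS)
#' @rdname accessors
#' @export
setMethod("perProfile", "MDSResult", function(x) x@perProfile)
#' @rdname accessors
#' @export
setMethod("nValidProfiles", "MDSResult", function(x) x@nValid)
#' @rdname accessors
#' @export
setMethod("nTotalProfiles", "MDSResult", function(x) x@nTotal)

## show methods --------------------------------------------------------------

setMethod("show", "ScalarVolume", function(object) {
  cat("ScalarVolume [", paste(dim(object@data), collapse = " x "), "] units:",
      object@units, "\n  spacing (mm):", paste(signif(object@spacing, 4),
      collapse = " x "), "\n  range:",
      paste(signif(range(object@data, na.rm = TRUE), 4), collapse = " .. "),
      "\n")
})

setMethod("show", "SegmentationVolume", function(object) {
  present <- sort(unique(as.vector(object@labels)))
  roles <- names(object@scheme)[match(present, object@scheme)]
  cat("SegmentationVolume [", paste(dim(object@labels), collapse = " x "),
      "]\n  labels present:",
      paste(sprintf("%d (%s)", present, roles), collapse = ", "), "\n")
})

setMethod("show", "SurfaceVectorField", function(object) {
  cat("SurfaceVectorField with", nrow(object@vectors), "unit normals over",
      length(unique(object@vectors$component_id)), "component(s);",
      object@nSkipped, "degenerate boundary voxel(s) skipped\n")
})

setMethod("show", "ProfileSet", function(object) {
  nv <- nrow(object@profiles)
  cat("ProfileSet:", nv, "profiles x",
      sum(object@samples$vector_id == object@profiles$vector_id[1]),
      "samples; window",
      paste(object@params$window_mm, collapse = " to "), "mm at",
      object@params$rate_per_mm, "samples/mm\n")
  if (!is.na(object@params$min_contiguous_mm %||% NA))
    cat("  valid:", sum(object@profiles$valid), "/", nv, "\n")
})

setMethod("show", "MDSResult", function(object) {
  cat("MDSResult: mean MDS =",
      if (is.na(object@meanMDS)) "undefined (no valid profiles)"
      else format(signif(object@meanMDS, 6)),
      sprintf("(%d/%d profiles valid)\n", object@nValid, object@nTotal))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
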