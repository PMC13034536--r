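#' @include AllClasses.R
NULL

#' Read a scalar NIfTI volume
#'
#' Reads a single 2D or 3D NIfTI volume into a [ScalarVolume-class], taking
#' spacing and the voxel-to-world affine from the header. 4D inputs are
#' rejected rather than silently squeezed: ADC maps are single-volume by
#' definition.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param units unit tag for the values (`"mm2_per_s"` for ADC maps,
#'   `"normalized_density"` for cellularity maps, `"arbitrary"` otherwise).
#' @return A [ScalarVolume-class].
#' @export
readScalarVolume <- function(path, units = "mm2_per_s") {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("not a NIfTI volume: ", path,
                                           " (", conditionMessage(e), ")"))
  nd <- RNifti::ndim(img)
  if (nd > 3L)
    stop("expected a single 2D/3D volume but '", path, "' has ", nd,
         " dimensions (extra axis ", nd, " of length ", dim(img)[nd], ")")
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  sp <- RNifti::pixdim(img)[seq_len(nd)]
  if (nd == 2L) {
    aff <- aff[c(1, 2, 4), c(1, 2, 4)]
  }
  ScalarVolume(dat, spacing = sp, affine = aff, units = units)
}

#' Write a ScalarVolume to NIfTI
#'
#' @param vol a [ScalarVolume-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeScalarVolume <- function(vol, path) {
  dat <- volData(vol)
  d <- length(dim(dat))
  aff <- volAffine(vol)
  if (d == 2L) {  # embed in a 3D header with a unit third axis
    dat <- array(dat, c(dim(dat), 1L))
    a4 <- diag(4)
    a4[c(1, 2, 4), c(1, 2, 4)] <- aff
    aff <- a4
    sp <- c(volSpacing(vol), 1)
  } else sp <- volSpacing(vol)
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- sp
  RNifti::`sform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a segmentation NIfTI volume
#'
#' Reads an integer label volume and validates every nonzero label against
#' the scheme.
#'
#' @param path path to a NIfTI label volume.
#' @param scheme named integer vector mapping roles to codes
#'   (default [defaultLabelScheme()]).
#' @return A [SegmentationVolume-class].
#' @export
readSegmentation <- function(path, scheme = defaultLabelScheme()) {
  vol <- readScalarVolume(path, units = "arbitrary")
  dat <- volData(vol)
  if (max(abs(dat - round(dat)), na.rm = TRUE) > 1e-6)
    stop("segmentation volume is not integer-valued: ", path)
  SegmentationVolume(round(dat), spacing = volSpacing(vol),
                     affine = volAffine(vol), scheme = scheme)
}

#' Assert two volumes share a grid
#'
#' Passes iff the shapes are equal and the affines agree within an absolute
#' tolerance of 1e-4 mm; otherwise stops naming the first differing
#' property. Symmetric in its arguments.
#'
#' @param a,b [ScalarVolume-class] or [SegmentationVolume-class] objects.
#' @param tol absolute affine tolerance in mm.
#' @return `TRUE`, invisibly.
#' @export
assertSameGrid <- function(a, b, tol = 1e-4) {
  da <- dim(volData(a)); db <- dim(volData(b))
  if (length(da) != length(db))
    stop("rank mismatch: ", length(da), " vs ", length(db))
  for (k in seq_along(da)) if (da[k] != db[k])
    stop("shape mismatch axis ", k - 1L, ": ", da[k], " vs ", db[k])
  if (max(abs(volAffine(a) - volAffine(b))) > tol)
    stop("affine mismatch (max abs difference ",
         signif(max(abs(volAffine(a) - volAffine(b))), 3), " mm)")
  invisible(TRUE)
}

#' Extract the binary mask of one or more roles from a segmentation
#'
#' @param seg a [SegmentationVolume-class].
#' @param roles character vector of role names in the scheme.
#' @return Logical array.
#' @export
roleMask <- function(seg, roles) {
  sc <- labelScheme(seg)
  bad <- setdiff(roles, names(sc))
  if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
  array(volData(seg) %in% sc[roles], dim(volData(seg)))
}

#' Write per-sample profile and per-vector summary tables
#'
#' Writes one CSV row per sample point (vector id, sample index, arc
#' position in mm, interpolated value, validity flag) plus a per-vector
#' summary CSV with the fitted slope and the number of samples used.
#'
#' @param profiles a [ProfileSet-class].
#' @param path output CSV path for the per-sample table.
#' @param mds optional [MDSResult-class]; when given, the per-vector
#'   summary is written next to `path` (suffix `_summary.csv`).
#' @return `path`, invisibly.
#' @export
writeProfilesTable <- function(profiles, path, mds = NULL) {
  s <- profiles@samples
  p <- profiles@profiles
  out <- data.frame(vector_id = s$vector_id, sample_index = s$k,
                    arc_mm = s$arc_mm, value = s$value,
                    valid = p$valid[match(s$vector_id, p$vector_id)])
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(mds)) {
    spath <- sub("\\.csv$", "_summary.csv", path)
    if (identical(spath, path)) spath <- paste0(path, "_summary.csv")
    utils::write.csv(perProfile(mds), spath, row.names = FALSE)
  }
  invisible(path)
}
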