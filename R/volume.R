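#' Construct an MRI volume
#'
#' A volume is a 3D array of finite scalar intensities with voxel spacing in
#' millimetres and free-form provenance metadata. The in-memory axis order is
#' canonical (sagittal, coronal, transverse): axis 1 runs left-right, axis 2
#' posterior-anterior, axis 3 inferior-superior.
#'
#' @param data 3D numeric array of finite values.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm.
#' @param meta named list of provenance fields (source path, normalization
#'   applied, original on-disk orientation, ...).
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(data, spacing = c(1, 1, 1), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data) %||% 1), " dimensions")
  if (!all(is.finite(data)))
    stop("volume contains non-finite voxels")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  structure(list(data = data, spacing = spacing, meta = meta),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mri_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mri_volume <- function(x) dim(x$data)

#' Load a NIfTI volume
#'
#' Reads a NIfTI-1 file (`.nii` or `.nii.gz`) and returns it in the canonical
#' (sagittal, coronal, transverse) axis order. Files whose stored orientation
#' differs from RAS are reoriented at load; the original orientation string is
#' recorded in `meta$orientation_on_disk`. Intensities are returned untouched.
#'
#' @param path path to an existing 3D NIfTI file.
#' @return An [mri_volume].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  ori <- RNifti::orientation(img)
  if (!is.na(ori) && nzchar(ori) && ori != "RAS")
    RNifti::orientation(img) <- "RAS"
  a <- as.array(img)
  a <- array(as.double(a), dim = dim(a))  # drop niftiImage attributes
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) {
    a <- array(a, dim = dim(a)[1:3])
  } else if (length(dim(a)) != 3L) {
    stop("expected 3D volume, got ", length(dim(a)), "D image: ", path)
  }
  if (!all(is.finite(a))) stop("volume contains non-finite voxels: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  mri_volume(a, sp, meta = list(source = path, orientation_on_disk = ori))
}

#' Write a volume as NIfTI
#'
#' @param v an [mri_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "mri_volume"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Min-max intensity normalization
#'
#' Rescales a volume to the unit interval by `(x - min) / (max - min)`, the
#' per-volume normalization applied before patch extraction; patches inherit
#' the volume's scale. The map is monotone and idempotent.
#'
#' @param v an [mri_volume] with at least two distinct intensities.
#' @return The normalized [mri_volume]; `meta$normalized` records the original
#'   range.
#' @export
normalize_minmax <- function(v) {
  stopifnot(inherits(v, "mri_volume"))
  lo <- min(v$data); hi <- max(v$data)
  if (hi <= lo) stop("constant volume: min-max normalization undefined")
  out <- v
  out$data <- (v$data - lo) / (hi - lo)
  out$meta$normalized <- c(min = lo, max = hi)
  out
}
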