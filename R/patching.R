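#' Patch geometry
#'
#' Overlapping cubic patch extraction is defined by a patch edge length and a
#' stride, both in voxels. The defaults (64, 32) halve the patch per step, so
#' interior voxels are covered by up to 8 patches.
#'
#' @param patch_size voxels per axis of the cubic patch.
#' @param stride step between consecutive patch starts, `0 < stride <= patch_size`.
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(patch_size = 64L, stride = 32L) {
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (stride <= 0L || stride > patch_size)
    stop("need 0 < stride <= patch_size")
  structure(list(patch_size = patch_size, stride = stride), class = "patch_spec")
}

#' Patch start coordinates along one axis
#'
#' Starts are `0, stride, 2*stride, ...` while `start + patch <= dim`; when the
#' last such patch does not reach the end of the axis, one final end-aligned
#' start `dim - patch` is appended. This is the unique simple policy whose
#' per-axis counts multiply to the patch totals of typical whole-head volumes
#' (7 x 9 x 9 = 567 for a 256 x 304 x 308 volume at 64/32).
#'
#' @param dim axis length in voxels.
#' @param patch patch edge length.
#' @param stride step between starts.
#' @return Strictly increasing integer vector of 0-based starts.
#' @export
axis_starts <- function(dim, patch, stride) {
  dim <- as.integer(dim); patch <- as.integer(patch); stride <- as.integer(stride)
  if (patch > dim) stop("patch size ", patch, " exceeds axis length ", dim)
  s <- seq.int(0L, dim - patch, by = stride)
  if (s[length(s)] + patch < dim) s <- c(s, dim - patch)
  unique(s)
}

#' Extract overlapping 3D patches
#'
#' Patch starts are the Cartesian product of [axis_starts()] over the three
#' axes, ordered lexicographically in (axis1, axis2, axis3) so patch lists are
#' reproducible. Every voxel is covered by at least one patch.
#'
#' @param v an [mri_volume] or 3D array.
#' @param spec a [patch_spec].
#' @return A list with `starts` (matrix n x 3 of 0-based starts) and `patches`
#'   (list of `patch_size^3` arrays).
#' @export
extract_patches <- function(v, spec) {
  a <- if (inherits(v, "mri_volume")) v$data else v
  d <- dim(a)
  st <- lapply(d, axis_starts, patch = spec$patch_size, stride = spec$stride)
  grid <- expand.grid(s1 = st[[1]], s2 = st[[2]], s3 = st[[3]],
                      KEEP.OUT.ATTRS = FALSE)
  # lexicographic in (axis1, axis2, axis3): axis3 slowest
  grid <- grid[order(grid$s1, grid$s2, grid$s3), , drop = FALSE]
  p <- spec$patch_size
  patches <- lapply(seq_len(nrow(grid)), function(i) {
    s <- as.integer(grid[i, ])
    a[s[1] + seq_len(p), s[2] + seq_len(p), s[3] + seq_len(p), drop = FALSE]
  })
  list(starts = unname(as.matrix(grid)), patches = patches)
}

#' Number of patches for a volume shape
#'
#' @param dims integer length-3 volume shape.
#' @param spec a [patch_spec].
#' @return Total patch count (product of per-axis start counts).
#' @export
count_patches <- function(dims, spec) {
  prod(vapply(dims, function(d)
    length(axis_starts(d, spec$patch_size, spec$stride)), integer(1)))
}

#' Reassemble patches into a volume
#'
#' Each output voxel is the arithmetic mean of all patch values covering it
#' (uniform-average blending), so reassembly inverts extraction exactly and is
#' independent of patch order.
#'
#' @param starts matrix n x 3 of 0-based patch start coordinates.
#' @param patches list of cubic arrays, one per row of `starts`.
#' @param dims integer length-3 output shape.
#' @param blend blending rule; only `"mean"` is currently implemented.
#' @return 3D array of blended values.
#' @export
reassemble <- function(starts, patches, dims, blend = c("mean")) {
  blend <- match.arg(blend)
  acc <- array(0, dim = dims)
  cnt <- array(0L, dim = dims)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    dp <- dim(p)
    s <- starts[i, ]
    i1 <- s[1] + seq_len(dp[1]); i2 <- s[2] + seq_len(dp[2]); i3 <- s[3] + seq_len(dp[3])
    acc[i1, i2, i3] <- acc[i1, i2, i3] + p
    cnt[i1, i2, i3] <- cnt[i1, i2, i3] + 1L
  }
  if (any(cnt == 0L)) {
    w <- which(cnt == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("voxel (%d,%d,%d) not covered by any patch", w[1], w[2], w[3]))
  }
  acc / cnt
}
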