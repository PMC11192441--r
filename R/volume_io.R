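#' Construct a statistic volume
#'
#' A `stat_volume` couples a 3-D array of voxelwise statistic values (typically
#' t statistics from a task-vs-baseline contrast) with a 4x4 voxel-to-world
#' affine in millimetres. All left/right logic in this package is defined in
#' world space: anatomical left is world x < 0 (the RAS+ convention of NIfTI),
#' never storage order.
#'
#' The affine must map exactly one storage axis onto the world x (left-right)
#' axis, and that axis must not be oblique; this is checked at construction.
#'
#' @param data numeric 3-D array of statistic values.
#' @param transform 4x4 numeric matrix mapping 0-based voxel indices to world
#'   coordinates in mm.
#' @return An object of class `stat_volume` with elements `data`, `transform`
#'   and `shape`.
#' @export
stat_volume <- function(data, transform = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("not a 3-D volume: data must be a 3-D array", call. = FALSE)
  transform <- as.matrix(transform)
  if (!identical(dim(transform), c(4L, 4L)))
    stop("transform must be a 4x4 matrix", call. = FALSE)
  if (abs(det(transform)) < 1e-12)
    stop("singular transform: voxel-to-world affine is not invertible",
         call. = FALSE)
  vol <- structure(
    list(data = data, transform = transform, shape = dim(data)),
    class = "stat_volume")
  lr_axis(vol)  # errors if no unique, non-oblique left-right storage axis
  vol
}

#' Read a 3-D statistic volume from a NIfTI file
#'
#' Reads a NIfTI-1 volume and resolves its voxel-to-world affine from the
#' header (sform/qform), so world coordinates are independent of on-disk
#' storage order.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3-D volume.
#' @return A [stat_volume()].
#' @export
read_stat_volume <- function(path) {
  if (!file.exists(path))
    stop("missing file: '", path, "'", call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("not a 3-D volume: '", path, "' has ", length(d), " dimensions",
         call. = FALSE)
  stat_volume(array(as.numeric(img), dim = d),
              unclass(RNifti::xform(img)))
}

#' Write a statistic volume to a NIfTI file
#'
#' @param vol a [stat_volume()] or [roi_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_stat_volume <- function(vol, path) {
  data <- if (inherits(vol, "roi_mask")) vol$data * 1 else vol$data
  img <- RNifti::asNifti(data)
  # voxel sizes must be on the header before the affine is attached,
  # or negative-determinant (flipped-storage) affines lose their scale
  RNifti::pixdim(img) <- sqrt(colSums(vol$transform[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(vol$transform, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a region-of-interest mask
#'
#' A binary mask on the same grid (shape and affine) as an associated
#' statistic volume. Masks read from file treat any nonzero voxel as included.
#'
#' @param data logical (or numeric, coerced by `!= 0`) 3-D array.
#' @param transform 4x4 voxel-to-world affine; typically taken from the
#'   companion `stat_volume`.
#' @param name region label, e.g. "frontal", "temporal", "parietal",
#'   "cerebellar", "mca" or "custom".
#' @param midline_excluded has [exclude_midline()] already been applied?
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, transform = diag(4), name = "custom",
                     midline_excluded = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("not a 3-D volume: mask data must be a 3-D array", call. = FALSE)
  mode_ok <- is.logical(data)
  mask <- structure(
    list(data = if (mode_ok) data else array(data != 0, dim = dim(data)),
         transform = as.matrix(transform), shape = dim(data),
         name = name, midline_excluded = isTRUE(midline_excluded)),
    class = "roi_mask")
  mask
}

#' Read a region-of-interest mask from a NIfTI file
#'
#' @inheritParams read_stat_volume
#' @param name region label.
#' @return A [roi_mask()].
#' @export
read_roi_mask <- function(path, name = "custom") {
  vol <- read_stat_volume(path)
  roi_mask(vol$data != 0, vol$transform, name = name)
}

# --- world-coordinate helpers -----------------------------------------------

# Identify the storage dimension that carries the world left-right (x) axis.
# Requires exactly one nonzero entry in row 1 of the 3x3 part, and that the
# corresponding column is not oblique (zero world-y/z contribution).
lr_axis <- function(vol, tol = 1e-6) {
  A <- vol$transform
  nz <- which(abs(A[1, 1:3]) > tol)
  if (length(nz) != 1L)
    stop("no unique left-right axis: world x must map from exactly one ",
         "storage axis", call. = FALSE)
  if (any(abs(A[2:3, nz]) > tol))
    stop("oblique left-right axis: the left-right storage axis must be ",
         "axis-aligned", call. = FALSE)
  list(dim = nz, step = A[1, nz], origin = A[1, 4])
}

# World x coordinate of every voxel centre along the left-right storage axis
# (one value per index along that dimension; 0-based voxel convention).
lr_centres <- function(vol) {
  ax <- lr_axis(vol)
  n <- vol$shape[ax$dim]
  list(x = ax$origin + ax$step * (seq_len(n) - 1), dim = ax$dim,
       width = abs(ax$step))
}

#' World coordinates of voxel centres
#'
#' @param vol a [stat_volume()] or [roi_mask()].
#' @param ijk integer matrix (n x 3) of 1-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
world_coords <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk - 1, 1) %*% t(vol$transform)
  h[, 1:3, drop = FALSE]
}

# 3-D array of world x per voxel (broadcast along the left-right dimension).
worldx_array <- function(vol) {
  cen <- lr_centres(vol)
  idx <- slice.index(array(0L, dim = vol$shape), cen$dim)
  array(cen$x[idx], dim = vol$shape)
}

#' Check grid symmetry about the midsagittal plane
#'
#' Mirror operations require a grid symmetric about world x = 0: for every
#' voxel centre at world x there must be a centre at -x, within `tol` times
#' the voxel width. Asymmetric grids make hemisphere flipping silently pair
#' non-homologous voxels, so such grids are refused.
#'
#' @param vol a [stat_volume()] or [roi_mask()].
#' @param tol pairing tolerance as a fraction of the voxel width.
#' @return `TRUE` invisibly, or an error.
#' @export
check_symmetric_grid <- function(vol, tol = 0.1) {
  cen <- lr_centres(vol)
  xs <- sort(cen$x)
  if (max(abs(xs + rev(xs))) > tol * cen$width)
    stop("asymmetric grid: voxel centres do not pair across world x = 0",
         call. = FALSE)
  invisible(TRUE)
}

# Permutation p along the left-right dimension such that index i pairs with
# p[i] at world x -> -x. For a symmetric grid this is the reversal.
lr_partner <- function(vol) {
  check_symmetric_grid(vol)
  rev(seq_len(vol$shape[lr_centres(vol)$dim]))
}

#' Exclude a band around the midline from a mask
#'
#' Removes every voxel whose centre lies within `half_width_mm` of the
#' midsagittal plane (closed interval: centres at exactly |x| = half width are
#' excluded). Mirrors the convention of masking out midline structures where
#' left and right signals mix; applying it twice is a no-op.
#'
#' @param mask a [roi_mask()].
#' @param half_width_mm exclusion half-width in mm (default 5).
#' @return The midline-excluded [roi_mask()].
#' @export
exclude_midline <- function(mask, half_width_mm = 5) {
  if (half_width_mm < 0)
    stop("half_width_mm must be non-negative", call. = FALSE)
  wx <- worldx_array(mask)
  mask$data <- mask$data & (abs(wx) > half_width_mm)
  mask$midline_excluded <- TRUE
  mask
}

#' Split mask voxel values by hemisphere
#'
#' Returns the statistic values at mask voxels on the anatomical left
#' (world x < 0) and right; together the two vectors exactly partition the
#' mask.
#'
#' @param volume a [stat_volume()].
#' @param mask a midline-excluded [roi_mask()] on the same grid.
#' @return list with numeric vectors `left` and `right`.
#' @export
hemisphere_values <- function(volume, mask) {
  check_same_grid(volume, mask)
  wx <- worldx_array(volume)
  inc <- mask$data
  list(left = volume$data[inc & wx < 0],
       right = volume$data[inc & wx >= 0])
}

check_same_grid <- function(volume, mask, tol = 1e-6) {
  if (!identical(volume$shape, mask$shape) ||
      max(abs(volume$transform - mask$transform)) > tol)
    stop("mask/volume grid mismatch: shapes or affines differ", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.stat_volume <- function(x, ...) {
  cat("<stat_volume> ", paste(x$shape, collapse = " x "),
      " voxels, values in [", sprintf("%.3g", min(x$data)), ", ",
      sprintf("%.3g", max(x$data)), "]\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> '", x$name, "', ", sum(x$data), " of ",
      prod(x$shape), " voxels included",
      if (x$midline_excluded) ", midline excluded" else "", "\n", sep = "")
  invisible(x)
}
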