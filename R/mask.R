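#' Construct a binary mask volume
#'
#' A `mask_volume` is a 3D binary voxel array plus an invertible 4x4 affine
#' mapping 0-based voxel indices (i, j, k) to world millimetre coordinates
#' via `affine %*% c(i, j, k, 1)`. This is the container for stimulation
#' volumes (VTAs) and for sphere proxies of stereotactic targets.
#'
#' @param data 3D numeric/logical array; values are binarized strictly at
#'   `> 0` (upstream pipelines store VTAs as 0/1 or probabilities; any
#'   E-field thresholding happens upstream).
#' @param affine 4x4 voxel-to-world transform, invertible.
#' @return an object of class `mask_volume` with integer 0/1 `data` and the
#'   `affine`.
#' @export
mask_volume <- function(data, affine) {
  if (!is.array(data) || length(dim(data)) != 3) stopf("data must be a 3D array")
  assert_affine(affine)
  bin <- array(0L, dim = dim(data))
  bin[which(data > 0)] <- 1L
  structure(list(data = bin, affine = affine), class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("mask_volume: %s voxels, %d in support, voxel edges %s mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(signif(voxel_edges(x), 4), collapse = "/")))
  invisible(x)
}

# physical edge lengths of a voxel along the three index axes
voxel_edges <- function(mask) {
  sqrt(colSums(mask$affine[1:3, 1:3, drop = FALSE]^2))
}

#' Read a binary mask from NIfTI
#'
#' @param path a 3D NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return a [mask_volume()]; data binarized at `> 0`, affine taken from the
#'   file's xform (sform preferred by RNifti's rules).
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stopf("mask file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) >= 4) {
    stopf("mask %s is %dD; select a single 3D volume before loading", path, length(d))
  }
  if (length(d) != 3) {
    stopf("mask %s has %d dimensions; a 3D volume is required", path, length(d))
  }
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  mask_volume(array(as.numeric(img), dim = d), aff)
}

#' Write a mask to NIfTI
#' @param mask a [mask_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)))
  RNifti::sform(img) <- structure(mask$affine, code = 2L)
  RNifti::qform(img) <- structure(mask$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Create an empty voxel grid
#'
#' Axis-aligned template grid used by the synthetic generator and the
#' literature-target sphere builder.
#'
#' @param dim 3 positive integers.
#' @param voxel_size voxel edge lengths in mm (scalar or length 3).
#' @param origin world coordinate of the center of voxel (0, 0, 0).
#' @return an all-zero [mask_volume()].
#' @export
mask_grid <- function(dim, voxel_size = 1, origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1))
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(all(voxel_size > 0))
  aff <- diag(c(voxel_size, 1))
  aff[1:3, 4] <- origin
  mask_volume(array(0L, dim = dim), aff)
}

# Map world-mm points (N x 3) to continuous 0-based voxel coordinates.
world_to_voxel <- function(mask, points) {
  apply_affine(solve(mask$affine), points)
}

# Nearest-voxel membership: TRUE where the point's nearest voxel (0-based
# rounding of the inverse-affine image) is inside the grid and in the mask
# support. This is the declared connectivity semantics.
mask_contains <- function(mask, points) {
  if (nrow(points) == 0) return(logical(0))
  v <- round(world_to_voxel(mask, points))
  d <- dim(mask$data)
  inside <- v[, 1] >= 0 & v[, 1] < d[1] &
    v[, 2] >= 0 & v[, 2] < d[2] &
    v[, 3] >= 0 & v[, 3] < d[3]
  out <- logical(nrow(points))
  if (any(inside)) {
    lin <- 1 + v[inside, 1] + d[1] * (v[inside, 2] + d[2] * v[inside, 3])
    out[inside] <- mask$data[lin] == 1L
  }
  out
}

#' Voxelized sphere on a template grid
#'
#' Marks every voxel whose center lies within `radius` mm of `center`.
#' Evaluation is restricted to the sphere's bounding sub-box, so large grids
#' are cheap.
#'
#' @param center world mm coordinate (length 3).
#' @param radius sphere radius in mm, > 0.
#' @param template a [mask_volume()] providing grid shape and affine.
#' @return a [mask_volume()] on the template grid.
#' @export
sphere_mask <- function(center, radius, template) {
  stopifnot(inherits(template, "mask_volume"), radius > 0, length(center) == 3)
  d <- dim(template$data)
  cv <- drop(world_to_voxel(template, matrix(center, 1, 3)))
  if (any(cv < -0.5) || any(cv > d - 0.5)) {
    stopf("sphere center (%s) lies outside the template grid", paste(signif(center, 4), collapse = ", "))
  }
  edges <- voxel_edges(template)
  lo <- pmax(0, floor(cv - radius / edges - 1))
  hi <- pmin(d - 1, ceiling(cv + radius / edges + 1))
  ii <- seq(lo[1], hi[1]); jj <- seq(lo[2], hi[2]); kk <- seq(lo[3], hi[3])
  grid <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  centers <- apply_affine(template$affine, grid)
  hit <- rowSums(sweep(centers, 2, center)^2) <= radius^2
  data <- array(0L, dim = d)
  if (any(hit)) {
    g <- grid[hit, , drop = FALSE]
    data[1 + g[, 1] + d[1] * (g[, 2] + d[2] * g[, 3])] <- 1L
  }
  mask_volume(data, template$affine)
}

#' Number of support voxels
#' @param mask a [mask_volume()].
#' @return integer count of voxels equal to 1.
#' @export
mask_support_size <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  sum(mask$data)
}
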