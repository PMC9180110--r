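#' Regular isotropic voxel grid
#'
#' Defines the sampling lattice shared by all volumetric objects in the
#' package. World coordinates are in millimetres; voxel indices are 0-based
#' (as in NIfTI) and a voxel cell is half-open, so a point lying exactly on
#' the boundary between two voxels belongs to the voxel with the larger
#' index. The anterior-posterior (AP) axis, along which slices, segments and
#' landmarks are defined, is a property of the grid rather than a global
#' convention.
#'
#' @param dims integer vector of length 3, voxel counts per axis.
#' @param voxel_size isotropic voxel edge length in mm (default 2).
#' @param origin world coordinate (mm) of the centre of voxel (0, 0, 0).
#' @param ap_axis which axis (1, 2 or 3) is anterior-posterior; default 2,
#'   so planes of constant second index are coronal slices.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, voxel_size = 2, origin = c(0, 0, 0), ap_axis = 2) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("`dims` must be three positive integers")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a positive scalar (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite length-3 vector (mm)")
  if (!ap_axis %in% 1:3)
    stop("`ap_axis` must be 1, 2 or 3")
  structure(
    list(dims = dims, voxel_size = voxel_size,
         origin = as.numeric(origin), ap_axis = as.integer(ap_axis)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, %.3g mm isotropic, AP axis %d\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size, x$ap_axis))
  invisible(x)
}

#' Spatial extent of a grid along one axis, in mm
#'
#' Distance from the first to the last face of the voxel lattice
#' (`dims * voxel_size`).
#'
#' @param grid a [voxel_grid].
#' @param axis axis index (defaults to the grid's AP axis).
#' @return extent in mm.
#' @export
grid_extent <- function(grid, axis = grid$ap_axis) {
  grid$dims[axis] * grid$voxel_size
}

#' Map world coordinates (mm) to 0-based voxel indices
#'
#' Half-open voxel cells: a point on a shared face maps to the voxel with
#' the larger index.
#'
#' @param grid a [voxel_grid].
#' @param points numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @return integer matrix (n x 3) of 0-based indices (not clipped to the
#'   grid; see [in_grid]).
#' @export
world_to_voxel <- function(grid, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  idx <- sweep(points, 2, grid$origin, "-") / grid$voxel_size
  storage.mode(idx) <- "double"
  matrix(as.integer(floor(idx + 0.5)), ncol = 3,
         dimnames = NULL)
}

#' Map 0-based voxel indices to world coordinates of voxel centres (mm)
#' @param grid a [voxel_grid].
#' @param idx integer matrix (n x 3) or length-3 vector of 0-based indices.
#' @return numeric matrix (n x 3) of mm coordinates.
#' @export
voxel_to_world <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  sweep(idx * grid$voxel_size, 2, grid$origin, "+")
}

#' Which index rows fall inside the grid
#' @param grid a [voxel_grid].
#' @param idx integer matrix (n x 3) of 0-based indices.
#' @return logical vector of length n.
#' @export
in_grid <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  idx[, 1] >= 0 & idx[, 1] < grid$dims[1] &
    idx[, 2] >= 0 & idx[, 2] < grid$dims[2] &
    idx[, 3] >= 0 & idx[, 3] < grid$dims[3]
}

#' World coordinates (mm) of slice centres along the AP axis
#' @param grid a [voxel_grid].
#' @return numeric vector of length `dims[ap_axis]`, indexed by 0-based
#'   slice number + 1.
#' @export
ap_slice_centers <- function(grid) {
  grid$origin[grid$ap_axis] + (seq_len(grid$dims[grid$ap_axis]) - 1L) * grid$voxel_size
}

#' 4x4 voxel-to-world affine of a grid (NIfTI convention)
#' @param grid a [voxel_grid].
#' @return a 4x4 numeric matrix.
#' @export
grid_affine <- function(grid) {
  aff <- diag(c(rep(grid$voxel_size, 3), 1))
  aff[1:3, 4] <- grid$origin
  aff
}

# Encode 0-based (i,j,k) into a single integer key (internal).
encode_voxels <- function(grid, idx) {
  idx[, 1] + grid$dims[1] * (idx[, 2] + grid$dims[2] * idx[, 3])
}

# Inverse of encode_voxels (internal).
decode_voxels <- function(grid, key) {
  i <- key %% grid$dims[1]
  rest <- key %/% grid$dims[1]
  j <- rest %% grid$dims[2]
  k <- rest %/% grid$dims[2]
  cbind(i, j, k, deparse.level = 0)
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(a$dims, b$dims) &&
    abs(a$voxel_size - b$voxel_size) < tol &&
    all(abs(a$origin - b$origin) < tol) &&
    a$ap_axis == b$ap_axis
}

grid_of <- function(x) {
  g <- attr(x, "grid", exact = TRUE)
  if (is.null(g)) g <- x$grid
  if (is.null(g)) stop("object carries no voxel_grid")
  g
}
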