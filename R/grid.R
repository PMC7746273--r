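#' Regular voxel sampling grid
#'
#' A grid of isotropic voxels in world (scanner) millimetre coordinates.
#' Voxel `(1,1,1)` has its centre at `origin_mm`; the voxel index axes are
#' aligned with the world axes (the affine is a scaled translation).
#'
#' @param dim integer vector of length 3, voxels per axis.
#' @param voxel_mm isotropic voxel size in mm (default 0.8).
#' @param origin_mm world coordinate of the first voxel centre; defaults to
#'   `voxel_mm / 2` on each axis so the grid starts at the world origin.
#' @return an object of class `sampling_grid`.
#' @export
sampling_grid <- function(dim, voxel_mm = 0.8, origin_mm = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim > 0L), is.numeric(voxel_mm), voxel_mm > 0)
  if (is.null(origin_mm)) origin_mm <- rep(voxel_mm / 2, 3)
  stopifnot(length(origin_mm) == 3L)
  structure(list(dim = dim, voxel_mm = voxel_mm, origin_mm = as.numeric(origin_mm)),
            class = "sampling_grid")
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat(sprintf("sampling_grid: %d x %d x %d voxels, %.3g mm isotropic\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_mm))
  invisible(x)
}

#' Voxel-to-world affine of a sampling grid
#' @param grid a `sampling_grid`.
#' @return 4x4 affine mapping 1-based voxel indices to world mm.
#' @export
grid_affine <- function(grid) {
  A <- diag(4)
  diag(A)[1:3] <- grid$voxel_mm
  A[1:3, 4] <- grid$origin_mm - grid$voxel_mm
  A
}

#' World coordinates of all voxel centres
#'
#' Ordering matches R array linearisation (first index fastest).
#' @param grid a `sampling_grid`.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_centres <- function(grid) {
  d <- grid$dim
  i <- seq_len(d[1]); j <- seq_len(d[2]); k <- seq_len(d[3])
  cbind(
    x = grid$origin_mm[1] + (rep(i, times = d[2] * d[3]) - 1) * grid$voxel_mm,
    y = grid$origin_mm[2] + (rep(rep(j, each = d[1]), times = d[3]) - 1) * grid$voxel_mm,
    z = grid$origin_mm[3] + (rep(k, each = d[1] * d[2]) - 1) * grid$voxel_mm
  )
}

# Continuous (0-based) voxel coordinates of world points.
world_to_voxel <- function(grid, pts) {
  sweep(sweep(pts, 2, grid$origin_mm, "-"), 2, rep(grid$voxel_mm, 3), "/")
}

#' Trilinear interpolation of a 3D array at world points
#'
#' Points outside the grid are clamped to the boundary (nearest-edge
#' extrapolation).
#'
#' @param arr 3D numeric array laid out on `grid`.
#' @param grid a `sampling_grid`.
#' @param pts n x 3 matrix of world mm coordinates.
#' @return numeric vector of interpolated values.
#' @export
interp3 <- function(arr, grid, pts) {
  d <- grid$dim
  stopifnot(all(dim(arr) == d))
  u <- world_to_voxel(grid, pts)
  # clamp into [0, d-1]
  for (a in 1:3) u[, a] <- pmin(pmax(u[, a], 0), d[a] - 1)
  i0 <- pmin(floor(u[, 1]), d[1] - 2); f1 <- u[, 1] - i0
  j0 <- pmin(floor(u[, 2]), d[2] - 2); f2 <- u[, 2] - j0
  k0 <- pmin(floor(u[, 3]), d[3] - 2); f3 <- u[, 3] - k0
  if (d[1] < 2 || d[2] < 2 || d[3] < 2) stop("grid too small for interpolation")
  base <- 1 + i0 + d[1] * (j0 + d[2] * k0)
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  v000 <- arr[base];            v100 <- arr[base + sx]
  v010 <- arr[base + sy];       v110 <- arr[base + sx + sy]
  v001 <- arr[base + sz];       v101 <- arr[base + sx + sz]
  v011 <- arr[base + sy + sz];  v111 <- arr[base + sx + sy + sz]
  w00 <- v000 * (1 - f1) + v100 * f1
  w10 <- v010 * (1 - f1) + v110 * f1
  w01 <- v001 * (1 - f1) + v101 * f1
  w11 <- v011 * (1 - f1) + v111 * f1
  (w00 * (1 - f2) + w10 * f2) * (1 - f3) + (w01 * (1 - f2) + w11 * f2) * f3
}

# TRUE for world points strictly inside the grid bounding box.
points_in_grid <- function(grid, pts) {
  u <- world_to_voxel(grid, pts)
  ok <- rep(TRUE, nrow(pts))
  for (a in 1:3) ok <- ok & u[, a] >= 0 & u[, a] <= grid$dim[a] - 1
  ok
}
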