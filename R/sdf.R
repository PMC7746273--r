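#' Signed distance from voxel centres to a boundary mesh
#'
#' Computes, for every voxel centre of `grid`, the Euclidean distance to the
#' nearest point of the mesh, signed by which side of the surface the point
#' lies on: negative on the white-matter side, positive towards CSF (the
#' mesh's face normals define the positive side). The surface itself is the
#' zero level set.
#'
#' @param mesh a [surface_mesh()]; must be closed, or the grid restricted to
#'   the band in which the nearest-face normal disambiguates sides (true for
#'   the phantom geometries).
#' @param grid a [sampling_grid()].
#' @return 3D array of signed distances (mm) with `dim(grid$dim)`.
#' @export
compute_sdf <- function(mesh, grid) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(grid, "sampling_grid"))
  face_normals(mesh)   # validates against degenerate triangles
  d <- cpp_mesh_sdf(voxel_centres(grid), mesh$vertices, mesh$faces)
  array(d, grid$dim)
}

#' Signed distance at arbitrary world points
#'
#' Same as [compute_sdf()] but evaluated at caller-supplied points rather
#' than a grid.
#' @param mesh a [surface_mesh()].
#' @param pts n x 3 matrix of world mm coordinates.
#' @return numeric vector of signed distances.
#' @export
mesh_sdf_at <- function(mesh, pts) {
  face_normals(mesh)
  cpp_mesh_sdf(as.matrix(pts), mesh$vertices, mesh$faces)
}
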