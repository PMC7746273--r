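#' Triangle surface mesh
#'
#' Minimal triangle-mesh container used for the white-matter and pial
#' boundaries: vertices in world mm, 1-based triangular faces, with faces
#' oriented so that the right-hand normal points from the white-matter side
#' towards CSF.
#'
#' @param vertices n x 3 numeric matrix of world mm coordinates.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            min(faces) >= 1L, max(faces) <= nrow(vertices),
            all(is.finite(vertices)))
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Per-face unit normals (right-hand rule); errors on degenerate faces.
face_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  if (any(len < 1e-12)) stop("mesh contains degenerate triangles")
  n / len
}

# Area-weighted per-vertex unit normals.
vertex_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])   # area-weighted
  vn <- matrix(0, nrow(V), 3)
  for (c in 1:3) {
    for (a in 1:3) {
      acc <- rowsum(n[, a], F[, c])
      vn[as.integer(rownames(acc)), a] <- vn[as.integer(rownames(acc)), a] + acc
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len < 1e-12] <- 1
  vn / len
}

#' Crop a mesh to the interior of a sampling grid
#'
#' Keeps the faces whose vertices all lie inside the grid bounding box
#' shrunk by `margin_mm`, dropping unreferenced vertices. Useful before
#' boundary-based registration, whose samples must fall inside the volume.
#'
#' @param mesh a [surface_mesh()].
#' @param grid a [sampling_grid()].
#' @param margin_mm extra inward margin (default 1 mm, the registration
#'   sampling distance).
#' @return a cropped [surface_mesh()].
#' @export
crop_mesh <- function(mesh, grid, margin_mm = 1) {
  lo <- grid$origin_mm + margin_mm
  hi <- grid$origin_mm + (grid$dim - 1) * grid$voxel_mm - margin_mm
  V <- mesh$vertices
  ok_v <- V[, 1] >= lo[1] & V[, 1] <= hi[1] &
          V[, 2] >= lo[2] & V[, 2] <= hi[2] &
          V[, 3] >= lo[3] & V[, 3] <= hi[3]
  ok_f <- ok_v[mesh$faces[, 1]] & ok_v[mesh$faces[, 2]] & ok_v[mesh$faces[, 3]]
  used <- sort(unique(as.vector(mesh$faces[ok_f, ])))
  remap <- integer(nrow(V)); remap[used] <- seq_along(used)
  surface_mesh(V[used, , drop = FALSE],
               matrix(remap[mesh$faces[ok_f, ]], ncol = 3))
}

# Rectangular height-field mesh z = z_fun(x, y) over [xr] x [yr] with n
# segments per axis.  Faces are oriented with normals towards +z.
mesh_heightfield <- function(xr, yr, n = 24, z_fun = function(x, y) 0 * x) {
  xs <- seq(xr[1], xr[2], length.out = n + 1)
  ys <- seq(yr[1], yr[2], length.out = n + 1)
  g <- expand.grid(x = xs, y = ys)
  V <- cbind(g$x, g$y, z_fun(g$x, g$y))
  idx <- function(i, j) i + (j - 1) * (n + 1)
  i <- rep(seq_len(n), times = n); j <- rep(seq_len(n), each = n)
  a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i + 1, j + 1); d <- idx(i, j + 1)
  F <- rbind(cbind(a, b, c), cbind(a, c, d))
  surface_mesh(V, F)
}

# Open cylinder of given radius about the z axis spanning zlim; outward
# normals (+r).
mesh_cylinder <- function(radius, zlim, centre_xy = c(0, 0),
                          n_theta = 64, n_z = 12) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(zlim[1], zlim[2], length.out = n_z + 1)
  V <- cbind(centre_xy[1] + radius * rep(cos(th), times = n_z + 1),
             centre_xy[2] + radius * rep(sin(th), times = n_z + 1),
             rep(zs, each = n_theta))
  idx <- function(i, k) ((i - 1) %% n_theta) + 1 + (k - 1) * n_theta
  i <- rep(seq_len(n_theta), times = n_z); k <- rep(seq_len(n_z), each = n_theta)
  a <- idx(i, k); b <- idx(i + 1, k); c <- idx(i + 1, k + 1); d <- idx(i, k + 1)
  F <- rbind(cbind(a, b, c), cbind(a, c, d))
  surface_mesh(V, F)
}

# UV sphere with triangle fans at the poles; outward normals.
mesh_sphere <- function(radius, centre = c(0, 0, 0), n_theta = 48, n_phi = 24) {
  ph <- seq(0, pi, length.out = n_phi + 1)[-c(1, n_phi + 1)]  # exclude poles
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  V <- cbind(radius * rep(sin(ph), each = n_theta) * cos(rep(th, times = length(ph))),
             radius * rep(sin(ph), each = n_theta) * sin(rep(th, times = length(ph))),
             radius * rep(cos(ph), each = n_theta))
  north <- nrow(V) + 1L; south <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, radius), c(0, 0, -radius))
  V <- sweep(V, 2, centre, "+")
  idx <- function(i, r) ((i - 1) %% n_theta) + 1 + (r - 1) * n_theta
  F <- NULL
  nr <- length(ph)
  if (nr > 1) {
    i <- rep(seq_len(n_theta), times = nr - 1)
    r <- rep(seq_len(nr - 1), each = n_theta)
    a <- idx(i, r); b <- idx(i + 1, r); c <- idx(i + 1, r + 1); d <- idx(i, r + 1)
    # rings go from north (small phi) downwards; keep outward orientation
    F <- rbind(cbind(a, c, b), cbind(a, d, c))
  }
  i <- seq_len(n_theta)
  F <- rbind(F,
             cbind(rep(north, n_theta), idx(i, 1), idx(i + 1, 1)),
             cbind(rep(south, n_theta), idx(i + 1, nr), idx(i, nr)))
  surface_mesh(V, F)
}
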