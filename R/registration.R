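# Boundary-based registration (BBR) of the cortical surface pair to a
# functional volume: a 7-degree-of-freedom affine (rigid body plus scaling
# along the phase-encoding axis), and the recursive variant (RBR) that
# re-registers successively bisected mesh partitions and takes the
# per-vertex median displacement over axis-order permutations.

# Mean-EPI-like intensity volume from boundary signed distances: WM below
# the WM boundary, brighter GM inside the ribbon, dimmer CSF above, with a
# one-voxel linear partial-volume ramp at each boundary.  Used to exercise
# boundary-based registration on phantoms.
ramp_intensity_volume <- function(wm_sdf, pial_sdf, voxel_mm,
                                  I_wm = 427, I_gm = 460, I_csf = 430,
                                  psf_sigma = NULL) {
  # smooth (erf) partial-volume profile, emulating the acquisition PSF: the
  # boundary contrast then peaks exactly at alignment, in every direction
  if (is.null(psf_sigma)) psf_sigma <- voxel_mm
  ramp <- function(d) pnorm(d / psf_sigma)
  I_wm + (I_gm - I_wm) * ramp(wm_sdf) + (I_csf - I_gm) * ramp(pial_sdf)
}

#' 7-DOF affine transform (rotation, translation, phase-axis scale)
#'
#' @param rot_deg length-3 rotation angles (degrees, about x, y, z; applied
#'   z * y * x).
#' @param trans_mm length-3 translation (mm).
#' @param scale scale factor along the phase-encoding axis (> 0).
#' @param phase_axis axis index (1-3) the scale applies to (default 2, the
#'   usual anterior-posterior phase encoding).
#' @param centre rotation/scaling centre (world mm); defaults to the origin.
#' @return object of class `affine7`.
#' @export
affine7 <- function(rot_deg = c(0, 0, 0), trans_mm = c(0, 0, 0), scale = 1,
                    phase_axis = 2, centre = c(0, 0, 0)) {
  stopifnot(length(rot_deg) == 3, length(trans_mm) == 3, scale > 0,
            phase_axis %in% 1:3)
  structure(list(rot_deg = as.numeric(rot_deg), trans_mm = as.numeric(trans_mm),
                 scale = scale, phase_axis = as.integer(phase_axis),
                 centre = as.numeric(centre)),
            class = "affine7")
}

rotmat3 <- function(rot_deg) {
  r <- rot_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# 4x4 homogeneous matrix of an affine7
#' @export
as.matrix.affine7 <- function(x, ...) {
  S <- diag(3); S[x$phase_axis, x$phase_axis] <- x$scale
  R <- rotmat3(x$rot_deg) %*% S
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- x$centre - R %*% x$centre + x$trans_mm
  A
}

#' Apply a 7-DOF transform to points
#' @param tf an [affine7()].
#' @param pts n x 3 matrix (world mm).
#' @return transformed n x 3 matrix.
#' @export
apply_affine7 <- function(tf, pts) {
  A <- as.matrix(tf)
  t(A[1:3, 1:3] %*% t(pts) + A[1:3, 4])
}

# transform unit direction vectors (rotation only; the small phase-axis
# scale is ignored for normals, then renormalised)
transform_normals <- function(tf, n) {
  out <- t(rotmat3(tf$rot_deg) %*% t(n))
  out / sqrt(rowSums(out^2))
}

param_to_affine7 <- function(p, phase_axis, centre) {
  affine7(rot_deg = p[1:3], trans_mm = p[4:6], scale = exp(p[7]),
          phase_axis = phase_axis, centre = centre)
}

#' Boundary-based registration cost
#'
#' Samples the volume at `sample_dist_mm` inside and outside the transformed
#' white-matter boundary along the vertex normals and returns
#' `1 - mean(tanh(slope * Q))`, where `Q` is the percent intensity contrast
#' `100 * 2 (outside - inside) / (|outside| + |inside|)`. The cost decreases
#' as the grey/white contrast across the boundary increases and is invariant
#' to global intensity scaling of the volume.
#'
#' @param volume 3D array (e.g. a mean EPI).
#' @param grid its [sampling_grid()].
#' @param wm_mesh white-matter [surface_mesh()] (normals towards grey
#'   matter/CSF).
#' @param transform an [affine7()] applied to the mesh.
#' @param sample_dist_mm sampling offset along the normal (default 1 mm).
#' @param slope tanh slope per percent contrast (default 0.5).
#' @param vertices optional vertex index subset.
#' @param normals optional precomputed per-vertex normals of the full mesh
#'   (cached by [fit_bbr()] across cost evaluations).
#' @return scalar cost; attribute `"mean_contrast"` carries the mean signed
#'   percent contrast.
#' @export
bbr_cost <- function(volume, grid, wm_mesh, transform = affine7(),
                     sample_dist_mm = 1, slope = 0.5, vertices = NULL,
                     normals = NULL) {
  stopifnot(sample_dist_mm > 0)
  V <- wm_mesh$vertices
  N <- if (is.null(normals)) vertex_normals(wm_mesh) else normals
  if (!is.null(vertices)) {
    V <- V[vertices, , drop = FALSE]
    N <- N[vertices, , drop = FALSE]
  }
  v <- apply_affine7(transform, V)
  n <- transform_normals(transform, N)
  p_out <- v + sample_dist_mm * n
  p_in <- v - sample_dist_mm * n
  inside_ok <- points_in_grid(grid, p_out) & points_in_grid(grid, p_in)
  if (mean(inside_ok) < 0.5)
    stop("more than 50% of boundary samples fall outside the volume")
  O <- interp3(volume, grid, p_out[inside_ok, , drop = FALSE])
  I <- interp3(volume, grid, p_in[inside_ok, , drop = FALSE])
  Q <- 100 * 2 * (O - I) / (abs(O) + abs(I) + .Machine$double.eps)
  cost <- 1 - mean(tanh(slope * Q))
  attr(cost, "mean_contrast") <- mean(Q)
  cost
}

# Coordinate-wise pattern search polish: evaluates cost differences at
# shrinking absolute steps, robust on the flat-ish tanh cost surface.
pattern_polish <- function(f, p, steps, min_step = 1e-4, max_iter = 200) {
  fp <- f(p)
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (j in seq_along(p)) {
      for (s in c(steps[j], -steps[j])) {
        q <- p; q[j] <- q[j] + s
        fq <- f(q)
        if (fq < fp - 1e-15) {
          p <- q; fp <- fq; improved <- TRUE
        }
      }
    }
    if (!improved) {
      steps <- steps / 2
      if (all(steps < min_step)) break
    }
  }
  list(par = p, value = fp)
}

#' Fit a 7-DOF boundary-based registration
#'
#' Minimises [bbr_cost()] over rotation, translation and phase-axis scale
#' with a derivative-free search: an optional coarse translation grid, a
#' Nelder-Mead stage, and a pattern-search polish (absolute step tolerance
#' 1e-3 mm or better).
#'
#' @inheritParams bbr_cost
#' @param surfaces list with element `wm` (and optionally `pial`), or a
#'   [surface_mesh()].
#' @param init an [affine7()] starting point (must be within the capture
#'   range; about 5 voxels of misalignment on phantoms).
#' @param phase_axis scaled axis (1-3).
#' @param coarse_search logical; scan integer-voxel translations first.
#' @param estimate_scale logical; if `FALSE` the 7th DOF is frozen at the
#'   initial value.
#' @param vertices optional vertex subset to register (used by RBR).
#' @param centre rotation centre; default mesh (subset) centroid.
#' @return an [affine7()] with attributes `cost`, `mean_contrast`,
#'   `converged`.
#' @export
fit_bbr <- function(volume, grid, surfaces, init = NULL, phase_axis = 2,
                    sample_dist_mm = 1, slope = 0.5, coarse_search = TRUE,
                    estimate_scale = TRUE, vertices = NULL, centre = NULL,
                    rot_limit_deg = 20, trans_limit_mm = 5 * grid$voxel_mm) {
  wm_mesh <- if (inherits(surfaces, "surface_mesh")) surfaces else surfaces$wm
  Vsub <- if (is.null(vertices)) wm_mesh$vertices else
    wm_mesh$vertices[vertices, , drop = FALSE]
  if (is.null(centre)) centre <- colMeans(Vsub)
  if (is.null(init)) init <- affine7(phase_axis = phase_axis, centre = centre)

  normals <- vertex_normals(wm_mesh)
  p0 <- c(init$rot_deg, init$trans_mm, log(init$scale))
  active <- if (estimate_scale) 1:7 else 1:6
  # capture-range box around the start point; keeps the search from drifting
  # along cost-flat null spaces (e.g. in-plane translation of a flat
  # boundary).  Recursive registration narrows it for partition fits.
  box_lo <- c(rep(-rot_limit_deg, 3), rep(-trans_limit_mm, 3), -0.1)
  box_hi <- -box_lo
  f <- function(p_act) {
    p <- p0; p[active] <- p_act
    if (any(p - p_ref < box_lo) || any(p - p_ref > box_hi)) return(10)
    tf <- param_to_affine7(p, phase_axis, centre)
    tryCatch(as.numeric(bbr_cost(volume, grid, wm_mesh, tf, sample_dist_mm,
                                 slope, vertices, normals = normals)),
             error = function(e) 10)
  }
  p_ref <- p0

  if (coarse_search) {
    v <- grid$voxel_mm
    best <- f(p0[active]); bestp <- p0
    for (dx in seq(-4, 4)) for (dy in seq(-4, 4)) for (dz in seq(-4, 4)) {
      p <- p0; p[4:6] <- p0[4:6] + c(dx, dy, dz) * v
      val <- f(p[active])
      if (val < best) { best <- val; bestp <- p }
    }
    p0 <- bestp
    p_ref <- p0
  }

  scale_par <- c(2, 2, 2, 1, 1, 1, 0.02)[active]   # deg / mm / log-scale
  opt <- optim(p0[active], f, method = "Nelder-Mead",
               control = list(maxit = 800, reltol = 1e-12,
                              parscale = scale_par))
  opt <- optim(opt$par, f, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12,
                              parscale = scale_par / 10))
  pol <- pattern_polish(f, opt$par,
                        steps = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.002)[active],
                        min_step = 2e-4)
  p <- p0; p[active] <- pol$par
  tf <- param_to_affine7(p, phase_axis, centre)
  final <- tryCatch(
    bbr_cost(volume, grid, wm_mesh, tf, sample_dist_mm, slope, vertices),
    error = function(e) structure(10, mean_contrast = NA_real_))
  attr(tf, "cost") <- as.numeric(final)
  attr(tf, "mean_contrast") <- attr(final, "mean_contrast")
  attr(tf, "converged") <- is.finite(final) && final < 10
  if (!attr(tf, "converged")) warning("BBR optimisation did not converge")
  tf
}

# Split vertex indices into two equal halves by the plane normal to `axis`
# through the median coordinate of the current positions (ties by index).
split_partition <- function(idx, positions, axis) {
  ord <- idx[order(positions[idx, axis], idx)]
  n <- length(ord)
  list(lower = sort(ord[seq_len(ceiling(n / 2))]),
       upper = sort(ord[(ceiling(n / 2) + 1):n]))
}

#' Recursive boundary registration
#'
#' After a global [fit_bbr()], the mesh is recursively bisected along the
#' cardinal axes (the cut axis cycling through a permutation of x, y, z:
#' each cut orthogonal to the previous ones) and each partition re-registered
#' with its own 7-DOF BBR. The procedure runs once per axis-order
#' permutation and the final per-vertex displacement is the component-wise
#' median over the permutation runs, correcting local distortions that a
#' single global transform cannot.
#'
#' @inheritParams fit_bbr
#' @param n_iterations recursion depth (default 6).
#' @param orderings matrix of axis orders (one row per run); defaults to all
#'   6 permutations of (1, 2, 3), cycled to `n_iterations` cuts.
#' @param min_vertices partitions whose halves would fall below this size
#'   are not split further (default 50).
#' @param global_fit optionally, a precomputed global [affine7()].
#' @param estimate_scale re-estimate the phase-axis scale per partition
#'   (default) or keep the global value.
#' @return object of class `displacement_field`: list `displacement`
#'   (n_vertices x 3, mm; RBR correction relative to the globally registered
#'   mesh), `total_displacement` (including the global transform),
#'   `positions` (final vertex positions), `global` (the global transform),
#'   `contrast_global`, `contrast_rbr` (mean absolute percent GM-WM
#'   contrast), `orderings`.
#' @export
recursive_bbr <- function(volume, grid, surfaces, n_iterations = 6,
                          orderings = NULL, phase_axis = 2,
                          sample_dist_mm = 1, slope = 0.5, min_vertices = 50,
                          global_fit = NULL, estimate_scale = TRUE,
                          partition_rot_limit_deg = 5,
                          partition_trans_limit_mm = 2.5 * grid$voxel_mm) {
  wm_mesh <- if (inherits(surfaces, "surface_mesh")) surfaces else surfaces$wm
  if (is.null(orderings)) {
    perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                   c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    orderings <- perms
  }
  if (is.null(global_fit))
    global_fit <- fit_bbr(volume, grid, wm_mesh, phase_axis = phase_axis,
                          sample_dist_mm = sample_dist_mm, slope = slope,
                          estimate_scale = estimate_scale)
  V0 <- wm_mesh$vertices
  Vg <- apply_affine7(global_fit, V0)
  nv <- nrow(V0)

  run_ordering <- function(axes) {
    axes <- rep_len(axes, n_iterations)
    pos <- Vg
    partitions <- list(seq_len(nv))
    for (it in seq_len(n_iterations)) {
      nxt <- list()
      for (part in partitions) {
        if (length(part) < 2 * min_vertices) {   # halves would be too small
          nxt[[length(nxt) + 1]] <- part
          next
        }
        halves <- split_partition(part, pos, axes[it])
        for (half in halves) {
          mesh_cur <- surface_mesh(pos, wm_mesh$faces)
          tf <- fit_bbr(volume, grid, mesh_cur, phase_axis = phase_axis,
                        sample_dist_mm = sample_dist_mm, slope = slope,
                        coarse_search = FALSE, estimate_scale = estimate_scale,
                        vertices = half,
                        rot_limit_deg = partition_rot_limit_deg,
                        trans_limit_mm = partition_trans_limit_mm)
          pos[half, ] <- apply_affine7(tf, pos[half, , drop = FALSE])
          nxt[[length(nxt) + 1]] <- half
        }
      }
      partitions <- nxt
    }
    pos - Vg
  }

  disp_runs <- lapply(seq_len(nrow(orderings)),
                      function(i) run_ordering(orderings[i, ]))
  med <- combine_displacements(disp_runs)

  pos_final <- Vg + med
  contrast <- function(pos) {
    m <- surface_mesh(pos, wm_mesh$faces)
    q <- bbr_cost(volume, grid, m, affine7(), sample_dist_mm, slope)
    # mean absolute percent contrast at these positions
    V <- m$vertices; N <- vertex_normals(m)
    O <- interp3(volume, grid, V + sample_dist_mm * N)
    I <- interp3(volume, grid, V - sample_dist_mm * N)
    mean(abs(100 * 2 * (O - I) / (abs(O) + abs(I) + .Machine$double.eps)))
  }
  structure(list(displacement = med, total_displacement = pos_final - V0,
                 positions = pos_final, global = global_fit,
                 contrast_global = contrast(Vg),
                 contrast_rbr = contrast(pos_final),
                 orderings = orderings),
            class = "displacement_field")
}

# Component-wise per-vertex median over the axis-ordering runs; the median
# makes the final field robust to a single aberrant ordering.
combine_displacements <- function(disp_list) {
  a <- array(unlist(disp_list), c(dim(disp_list[[1]]), length(disp_list)))
  apply(a, c(1, 2), median)
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(paste0("displacement_field: %d vertices, median |d| = %.3f mm, ",
                     "contrast %.2f%% -> %.2f%%\n"),
              nrow(x$displacement),
              median(sqrt(rowSums(x$displacement^2))),
              x$contrast_global, x$contrast_rbr))
  invisible(x)
}
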