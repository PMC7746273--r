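#' Specification of a synthetic cortical phantom
#'
#' Describes the geometry of a two-surface (white matter / pial) cortical
#' ribbon embedded in a voxel grid, used to generate ground-truth data for
#' every downstream stage.
#'
#' @param shape one of `"flat-slab"`, `"folded-sheet"`, `"cylinder-annulus"`,
#'   `"sphere-shell"`.
#' @param grid_shape integer vector of 3, voxels per axis.
#' @param voxel_size_mm isotropic voxel size (default 0.8 mm, the acquisition
#'   resolution the pipeline is designed for).
#' @param wm_radius_mm,pial_radius_mm radii for the annulus/shell shapes.
#' @param wm_z_mm,thickness_mm white-matter plane position and ribbon
#'   thickness for the slab/sheet shapes.
#' @param tilt_deg slab tilt about the y axis, in degrees. A slab exactly
#'   aligned with the voxel grid yields only a handful of distinct voxel
#'   layer-fraction patterns, which makes the laminar design matrix rank
#'   deficient; a modest tilt restores identifiability and is the more
#'   realistic geometry.
#' @param fold_amp_mm,fold_wavelength_mm sinusoidal fold parameters for the
#'   folded sheet.
#' @param mesh_segments mesh resolution (segments per axis / around the
#'   circumference).
#' @param seed integer seed stored with the geometry description.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("flat-slab", "folded-sheet",
                                   "cylinder-annulus", "sphere-shell"),
                         grid_shape = NULL, voxel_size_mm = 0.8,
                         wm_radius_mm = 2, pial_radius_mm = 4,
                         wm_z_mm = 5.0, thickness_mm = 2.4, tilt_deg = 0,
                         fold_amp_mm = 1.2, fold_wavelength_mm = 12,
                         mesh_segments = NULL, seed = 1L) {
  shape <- match.arg(shape)
  if (is.null(grid_shape)) {
    grid_shape <- switch(shape,
      "flat-slab"        = c(22L, 22L, 16L),
      "folded-sheet"     = c(26L, 20L, 18L),
      "cylinder-annulus" = c(18L, 18L, 8L),
      "sphere-shell"     = c(18L, 18L, 18L))
  }
  spec <- structure(list(shape = shape, grid_shape = as.integer(grid_shape),
                         voxel_size_mm = voxel_size_mm,
                         wm_radius_mm = wm_radius_mm,
                         pial_radius_mm = pial_radius_mm,
                         wm_z_mm = wm_z_mm, thickness_mm = thickness_mm,
                         tilt_deg = tilt_deg, fold_amp_mm = fold_amp_mm,
                         fold_wavelength_mm = fold_wavelength_mm,
                         mesh_segments = mesh_segments, seed = as.integer(seed)),
                    class = "phantom_spec")
  thick <- switch(shape,
    "flat-slab"        = thickness_mm,
    "folded-sheet"     = thickness_mm,
    "cylinder-annulus" = pial_radius_mm - wm_radius_mm,
    "sphere-shell"     = pial_radius_mm - wm_radius_mm)
  if (!is.finite(thick) || thick <= voxel_size_mm)
    stop("cortical ribbon thickness must exceed one voxel (",
         signif(thick, 3), " mm <= ", voxel_size_mm, " mm)")
  if (shape %in% c("cylinder-annulus", "sphere-shell") &&
      pial_radius_mm <= wm_radius_mm)
    stop("pial surface must lie strictly outside the white-matter surface")
  spec
}

#' Build a synthetic cortical phantom
#'
#' Constructs the white-matter and pial boundary meshes, a voxel grid, a
#' spatially interleaved orientation-preference map (alternating 2-voxel
#' columns of 45 and 135 degrees, so that both orientation ROIs sample all
#' layers), and analytic ground-truth geometry: signed distances to both
#' boundaries (negative towards white matter, positive towards CSF) and each
#' voxel centre's cumulative volume fraction from the white-matter boundary.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `cortical_phantom` with elements `surfaces`
#'   (list `wm`, `pial` of [surface_mesh()]), `grid`, `preference` (3D array,
#'   45/135), and `truth_geometry` (list `wm_sdf`, `pial_sdf`, `vol_frac`
#'   arrays; `vol_frac` is NA outside grey matter and, for the folded sheet,
#'   everywhere, as no closed form exists there).
#' @export
make_cortical_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- sampling_grid(spec$grid_shape, spec$voxel_size_mm)
  ext <- grid$dim * grid$voxel_mm            # world extent per axis
  ctr <- ext / 2
  cc <- voxel_centres(grid)
  nseg <- spec$mesh_segments
  # meshes extend past the grid so in-grid voxels see the idealised geometry
  margin <- max(4 * grid$voxel_mm, 4)

  if (spec$shape == "flat-slab") {
    if (is.null(nseg)) nseg <- 24
    tau <- spec$tilt_deg * pi / 180
    nrm <- c(sin(tau), 0, cos(tau))          # plane normal, towards CSF
    z_fun <- function(z0) function(x, y) z0 - tan(tau) * (x - ctr[1])
    wm <- mesh_heightfield(c(-margin, ext[1] + margin), c(-margin, ext[2] + margin),
                           nseg, z_fun(spec$wm_z_mm))
    pial_z0 <- spec$wm_z_mm + spec$thickness_mm / cos(tau)
    pial <- mesh_heightfield(c(-margin, ext[1] + margin), c(-margin, ext[2] + margin),
                             nseg, z_fun(pial_z0))
    dwm <- (cc[, 1] - ctr[1]) * nrm[1] + (cc[, 3] - spec$wm_z_mm) * nrm[3]
    wm_sdf <- array(dwm, grid$dim)
    pial_sdf <- wm_sdf - spec$thickness_mm
    vf <- wm_sdf / spec$thickness_mm         # planar: volume frac = depth frac
  } else if (spec$shape == "folded-sheet") {
    if (is.null(nseg)) nseg <- 32
    zf <- function(z0) function(x, y)
      z0 + spec$fold_amp_mm * sin(2 * pi * x / spec$fold_wavelength_mm)
    wm <- mesh_heightfield(c(-margin, ext[1] + margin), c(-margin, ext[2] + margin),
                           nseg, zf(spec$wm_z_mm))
    pial <- mesh_heightfield(c(-margin, ext[1] + margin), c(-margin, ext[2] + margin),
                             nseg, zf(spec$wm_z_mm + spec$thickness_mm))
    wm_sdf <- pial_sdf <- array(NA_real_, grid$dim)   # no closed form; use meshes
    vf <- array(NA_real_, grid$dim)
  } else if (spec$shape == "cylinder-annulus") {
    if (is.null(nseg)) nseg <- 64
    wm <- mesh_cylinder(spec$wm_radius_mm, c(-margin, ext[3] + margin),
                        centre_xy = ctr[1:2], n_theta = nseg)
    pial <- mesh_cylinder(spec$pial_radius_mm, c(-margin, ext[3] + margin),
                          centre_xy = ctr[1:2], n_theta = nseg)
    r <- sqrt((cc[, 1] - ctr[1])^2 + (cc[, 2] - ctr[2])^2)
    wm_sdf <- array(r - spec$wm_radius_mm, grid$dim)
    pial_sdf <- array(r - spec$pial_radius_mm, grid$dim)
    vf <- (r^2 - spec$wm_radius_mm^2) /
          (spec$pial_radius_mm^2 - spec$wm_radius_mm^2)
    vf <- array(vf, grid$dim)
  } else {                                    # sphere-shell
    if (is.null(nseg)) nseg <- 48
    wm <- mesh_sphere(spec$wm_radius_mm, centre = ctr, n_theta = nseg,
                      n_phi = max(12, nseg %/% 2))
    pial <- mesh_sphere(spec$pial_radius_mm, centre = ctr, n_theta = nseg,
                        n_phi = max(12, nseg %/% 2))
    r <- sqrt((cc[, 1] - ctr[1])^2 + (cc[, 2] - ctr[2])^2 + (cc[, 3] - ctr[3])^2)
    wm_sdf <- array(r - spec$wm_radius_mm, grid$dim)
    pial_sdf <- array(r - spec$pial_radius_mm, grid$dim)
    vf <- (r^3 - spec$wm_radius_mm^3) /
          (spec$pial_radius_mm^3 - spec$wm_radius_mm^3)
    vf <- array(vf, grid$dim)
  }
  if (!all(is.na(vf))) vf[!(vf >= 0 & vf <= 1) | is.na(vf)] <- NA_real_

  # alternating 2-voxel columns of orientation preference along x
  ix <- slice.index(array(0, grid$dim), 1)
  preference <- array(ifelse(((ix - 1) %/% 2) %% 2 == 0, 45, 135), grid$dim)

  structure(list(spec = spec, grid = grid,
                 surfaces = list(wm = wm, pial = pial),
                 preference = preference,
                 truth_geometry = list(wm_sdf = wm_sdf, pial_sdf = pial_sdf,
                                       vol_frac = vf)),
            class = "cortical_phantom")
}

#' @export
print.cortical_phantom <- function(x, ...) {
  cat(sprintf("cortical_phantom (%s): grid %s, voxel %.2f mm\n", x$spec$shape,
              paste(x$grid$dim, collapse = "x"), x$grid$voxel_mm))
  invisible(x)
}
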