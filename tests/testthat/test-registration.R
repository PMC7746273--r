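# Boundary-based registration: cost properties, 7-DOF recovery, and the
# recursive variant. The full-size recursive recovery runs in the acceptance
# suite; here a reduced configuration exercises the mechanics.

# shared thick-shell phantom with an erf intensity profile
shell_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- phantom_spec("sphere-shell", wm_radius_mm = 2.8, pial_radius_mm = 6,
                         grid_shape = c(22, 22, 22))
      ph <- make_cortical_phantom(sp)
      cc <- voxel_centres(ph$grid)
      ctr <- ph$grid$dim * ph$grid$voxel_mm / 2
      mkimg <- function(shift = c(0, 0, 0)) {
        r <- sqrt(rowSums(sweep(cc, 2, ctr + shift)^2))
        array(layerglm:::ramp_intensity_volume(r - 2.8, r - 6, 0.8,
                                               psf_sigma = 0.5), ph$grid$dim)
      }
      cache <<- list(phantom = ph, ctr = ctr, mkimg = mkimg)
    }
    cache
  }
})

test_that("BBR cost is minimal at alignment and scale-invariant", {
  fx <- shell_fixture()
  img <- fx$mkimg()
  mesh <- fx$phantom$surfaces$wm
  c0 <- bbr_cost(img, fx$phantom$grid, mesh, affine7())
  # cost on a grid of z-shifts: minimum at the identity
  shifts <- seq(-1.6, 1.6, by = 0.4)
  costs <- vapply(shifts, function(dz)
    as.numeric(bbr_cost(img, fx$phantom$grid, mesh,
                        affine7(trans_mm = c(0, 0, dz)))), numeric(1))
  expect_equal(shifts[which.min(costs)], 0)
  expect_gt(attr(c0, "mean_contrast"), 0)           # GM brighter outside WM
  # invariant to global intensity scaling
  c10 <- bbr_cost(10 * img, fx$phantom$grid, mesh, affine7())
  expect_equal(as.numeric(c0), as.numeric(c10), tolerance = 1e-12)
  # shifted volume: identity costs more than the shift-correcting transform
  img_sh <- fx$mkimg(c(0, 0, 1.6))
  c_id <- bbr_cost(img_sh, fx$phantom$grid, mesh, affine7())
  c_fix <- bbr_cost(img_sh, fx$phantom$grid, mesh,
                    affine7(trans_mm = c(0, 0, 1.6)))
  expect_gt(as.numeric(c_id), as.numeric(c_fix))
})

test_that("out-of-volume sampling is an error", {
  fx <- shell_fixture()
  expect_error(bbr_cost(fx$mkimg(), fx$phantom$grid, fx$phantom$surfaces$wm,
                        affine7(trans_mm = c(40, 0, 0))),
               "outside the volume")
})

test_that("7-DOF fit recovers a known translation to a tenth of a voxel", {
  fx <- shell_fixture()
  shift <- c(1.6, 0, 0.8)
  tf <- fit_bbr(fx$mkimg(shift), fx$phantom$grid, fx$phantom$surfaces$wm)
  expect_lt(max(abs(tf$trans_mm - shift)), 0.08)
  expect_true(attr(tf, "converged"))
})

test_that("aligned phantom fit stays at the identity (boundary-normal metric)", {
  fx <- shell_fixture()
  tf <- fit_bbr(fx$mkimg(), fx$phantom$grid, fx$phantom$surfaces$wm,
                coarse_search = FALSE, estimate_scale = FALSE)
  V <- fx$phantom$surfaces$wm$vertices
  N <- layerglm:::vertex_normals(fx$phantom$surfaces$wm)
  dn <- rowSums((apply_affine7(tf, V) - V) * N)
  expect_lt(max(abs(dn)), 0.02)
})

test_that("phase-axis scale is recovered on a high-resolution shell", {
  sp <- phantom_spec("sphere-shell", wm_radius_mm = 8, pial_radius_mm = 12,
                     grid_shape = c(70, 70, 70), voxel_size_mm = 0.4,
                     mesh_segments = 72)
  ph <- make_cortical_phantom(sp)
  cc <- voxel_centres(ph$grid); ctr <- ph$grid$dim * 0.4 / 2
  r_sc <- sqrt((cc[, 1] - ctr[1])^2 + ((cc[, 2] - ctr[2]) / 1.03)^2 +
                 (cc[, 3] - ctr[3])^2)
  img <- array(layerglm:::ramp_intensity_volume(r_sc - 8, r_sc - 12, 0.4,
                                                psf_sigma = 0.5), ph$grid$dim)
  tf <- fit_bbr(img, ph$grid, ph$surfaces$wm, coarse_search = FALSE)
  expect_lt(abs(tf$scale - 1.03), 0.005)
})

test_that("affine7 transforms compose sensibly and are invertible", {
  tf <- affine7(rot_deg = c(3, -2, 5), trans_mm = c(1, -0.5, 2), scale = 1.02,
                centre = c(5, 5, 5))
  A <- as.matrix(tf)
  expect_equal(det(A[1:3, 1:3]), 1.02, tolerance = 1e-10)
  p <- matrix(rnorm(30, 5), 10, 3)
  q <- apply_affine7(tf, p)
  back <- t(solve(A) %*% rbind(t(q), 1))[, 1:3]
  expect_equal(back, p, tolerance = 1e-10)
})

test_that("partition splits are equal to within one vertex", {
  set.seed(8)
  pos <- matrix(runif(303 * 3, 0, 10), 303, 3)
  sp <- layerglm:::split_partition(seq_len(303), pos, 2)
  expect_lte(abs(length(sp$lower) - length(sp$upper)), 1)
  expect_setequal(c(sp$lower, sp$upper), seq_len(303))
  expect_lte(max(pos[sp$lower, 2]), min(pos[sp$upper, 2]) + 1e-12)
})

test_that("the median over orderings rejects a single aberrant run", {
  set.seed(5)
  consistent <- matrix(rnorm(60 * 3, sd = 0.01), 60, 3)
  runs <- list(consistent, consistent + rnorm(180, sd = 0.005),
               consistent + rnorm(180, sd = 0.005),
               consistent + 5)                      # one outlier ordering
  med <- layerglm:::combine_displacements(runs)
  expect_lt(max(abs(med - consistent)), 0.05)
})

test_that("recursive registration recovers opposite half-shifts (reduced size)", {
  tau <- 6 * pi / 180
  sp <- phantom_spec("flat-slab", grid_shape = c(24, 24, 18), wm_z_mm = 6.0,
                     thickness_mm = 3.2, tilt_deg = 6, mesh_segments = 40)
  ph <- make_cortical_phantom(sp)
  wm_mesh <- crop_mesh(ph$surfaces$wm, ph$grid, margin_mm = 1.5)
  cc <- voxel_centres(ph$grid); ctr <- ph$grid$dim * 0.8 / 2
  zb <- 6.0 - tan(tau) * (cc[, 1] - ctr[1]) + 0.8 * sign(cc[, 1] - ctr[1])
  wm_d <- (cc[, 3] - zb) * cos(tau)
  img <- array(layerglm:::ramp_intensity_volume(wm_d, wm_d - 3.2, 0.8,
                                                psf_sigma = 0.6), ph$grid$dim)
  rbr <- suppressWarnings(
    recursive_bbr(img, ph$grid, wm_mesh, n_iterations = 4,
                  orderings = rbind(c(1, 2, 3), c(2, 1, 3)),
                  global_fit = affine7(), estimate_scale = FALSE))
  V <- wm_mesh$vertices
  n <- c(sin(tau), 0, cos(tau))
  dn <- rbr$total_displacement %*% n
  target <- 0.8 * cos(tau)
  left <- V[, 1] < ctr[1] - 5; right <- V[, 1] > ctr[1] + 5
  expect_lt(abs(median(dn[left]) + target), 0.1)
  expect_lt(abs(median(dn[right]) - target), 0.1)
  # contrast never decreases relative to the starting registration
  expect_gte(rbr$contrast_rbr, rbr$contrast_global - 1e-9)
})
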