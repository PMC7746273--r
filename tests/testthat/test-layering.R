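# Equivolume surface placement and per-voxel volume distribution against
# closed-form and Monte-Carlo oracles.

test_that("flat slab equivolume boundaries are the equidistant thirds", {
  sp <- phantom_spec("flat-slab", wm_z_mm = 5.0, thickness_mm = 2.4,
                     tilt_deg = 0, grid_shape = c(12, 12, 14))
  ph <- make_cortical_phantom(sp)
  tg <- ph$truth_geometry
  ls <- equivolume_surfaces(tg$wm_sdf, tg$pial_sdf, ph$grid)
  expect_equal(as.vector(tg$wm_sdf - ls$sdf$deep_middle),
               rep(0.8, length(tg$wm_sdf)), tolerance = 1e-6)
  expect_equal(as.vector(tg$wm_sdf - ls$sdf$middle_superficial),
               rep(1.6, length(tg$wm_sdf)), tolerance = 1e-6)
})

test_that("annulus equivolume boundaries match the equal-area closed form", {
  an <- small_annulus()
  ph <- an$phantom; ls <- an$level_set
  cc <- voxel_centres(ph$grid); ctr <- ph$grid$dim * ph$grid$voxel_mm / 2
  r <- sqrt((cc[, 1] - ctr[1])^2 + (cc[, 2] - ctr[2])^2)
  gm <- which(r > 2 & r < 4)
  # implied boundary radius at each GM voxel: r - psi (|grad psi| = 1 radially)
  rb2 <- r[gm] - as.vector(ls$sdf$deep_middle)[gm]
  rb3 <- r[gm] - as.vector(ls$sdf$middle_superficial)[gm]
  e2 <- annulus_radius(1 / 3, 2, 4)   # sqrt(12) measured as 1/3 from WM = 2/3 below pia
  e3 <- annulus_radius(2 / 3, 2, 4)
  expect_equal(e3, sqrt(12), tolerance = 1e-12)
  expect_lt(max(abs(rb2 - e2)) / e2, 0.01)
  expect_lt(max(abs(rb3 - e3)) / e3, 0.01)
})

test_that("sphere-shell equivolume boundaries match the equal-volume closed form", {
  sp <- phantom_spec("sphere-shell", wm_radius_mm = 2, pial_radius_mm = 3.2)
  ph <- make_cortical_phantom(sp)
  wm <- compute_sdf(ph$surfaces$wm, ph$grid)
  pl <- compute_sdf(ph$surfaces$pial, ph$grid)
  ls <- equivolume_surfaces(wm, pl, ph$grid)
  cc <- voxel_centres(ph$grid); ctr <- ph$grid$dim * ph$grid$voxel_mm / 2
  r <- sqrt(rowSums(sweep(cc, 2, ctr)^2))
  gm <- which(r > 2 & r < 3.2)
  rb2 <- r[gm] - as.vector(ls$sdf$deep_middle)[gm]
  rb3 <- r[gm] - as.vector(ls$sdf$middle_superficial)[gm]
  expect_lt(max(abs(rb2 - shell_radius(1 / 3, 2, 3.2))) / shell_radius(1 / 3, 2, 3.2), 0.01)
  expect_lt(max(abs(rb3 - shell_radius(2 / 3, 2, 3.2))) / shell_radius(2 / 3, 2, 3.2), 0.01)
})

test_that("level set boundaries are ordered and thin ribbons are rejected", {
  ls <- small_annulus()$level_set
  expect_true(all(ls$sdf$wm_deep >= ls$sdf$deep_middle))
  expect_true(all(ls$sdf$deep_middle >= ls$sdf$middle_superficial))
  expect_true(all(ls$sdf$middle_superficial >= ls$sdf$superficial_csf))
  g <- sampling_grid(c(8, 8, 8), 0.8)
  cc <- voxel_centres(g)
  wm <- array(cc[, 3] - 2.8, g$dim)
  expect_error(equivolume_surfaces(wm, wm - 0.4, g), "thinner|resolution")
})

test_that("voxel volume distributions: pure compartments, half splits, row sums", {
  sp <- phantom_spec("flat-slab", wm_z_mm = 4.8, thickness_mm = 2.4,
                     tilt_deg = 0, grid_shape = c(8, 8, 14))
  ph <- make_cortical_phantom(sp)
  tg <- ph$truth_geometry
  ls <- equivolume_surfaces(tg$wm_sdf, tg$pial_sdf, ph$grid)
  lv <- layer_volume_distribution(ls, subdivision = 4)
  expect_true(all(abs(rowSums(lv$fractions) - 1) < 1e-12))
  cc <- voxel_centres(ph$grid)
  deep_wm <- which(cc[, 3] < 4.0)          # entirely below the WM boundary
  expect_true(all(lv$fractions[deep_wm, "wm"] == 1))
  # boundaries at 4.8, 5.6, 6.4, 7.2 coincide with voxel faces: GM voxels pure
  pure_deep <- which(abs(cc[, 3] - 5.2) < 1e-9)
  expect_equal(unname(lv$fractions[pure_deep, "deep"]),
               rep(1, length(pure_deep)), tolerance = 1e-12)
  expect_error(layer_volume_distribution(ls, subdivision = 1), "subdivision")
})

test_that("a face-bisected voxel splits one half each", {
  # shift the slab by half a voxel so the WM boundary bisects a voxel row
  sp <- phantom_spec("flat-slab", wm_z_mm = 5.2, thickness_mm = 2.4,
                     tilt_deg = 0, grid_shape = c(8, 8, 14))
  ph <- make_cortical_phantom(sp)
  tg <- ph$truth_geometry
  ls <- equivolume_surfaces(tg$wm_sdf, tg$pial_sdf, ph$grid)
  lv <- layer_volume_distribution(ls, subdivision = 8)
  cc <- voxel_centres(ph$grid)
  split_vox <- which(abs(cc[, 3] - 5.2) < 1e-9)
  expect_equal(unname(lv$fractions[split_vox, "wm"]),
               rep(0.5, length(split_vox)), tolerance = 1e-12)
  expect_equal(unname(lv$fractions[split_vox, "deep"]),
               rep(0.5, length(split_vox)), tolerance = 1e-12)
})

test_that("curved-phantom fractions agree with a Monte-Carlo volume oracle", {
  # 0.5-mm grid so trilinear interpolation resolves the curvature (the
  # classification bias scales with voxel^2 x curvature)
  sp <- phantom_spec("cylinder-annulus", grid_shape = c(29, 29, 9),
                     voxel_size_mm = 0.5)
  ph <- make_cortical_phantom(sp)
  tg <- ph$truth_geometry
  ls <- equivolume_surfaces(tg$wm_sdf, tg$pial_sdf, ph$grid)
  lv <- layer_volume_distribution(ls, subdivision = 4)
  cc <- voxel_centres(ph$grid); ctr <- ph$grid$dim * ph$grid$voxel_mm / 2
  r <- sqrt((cc[, 1] - ctr[1])^2 + (cc[, 2] - ctr[2])^2)
  vox <- which(r > 2.1 & r < 3.9)[c(3, 20, 57, 101)]
  set.seed(99)
  h <- ph$grid$voxel_mm / 2
  for (v in vox) {
    p <- matrix(runif(3e5, -h, h), ncol = 3)
    p <- sweep(p, 2, cc[v, ], "+")
    rr <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
    # classify by the closed-form equal-area radii
    br <- c(2, annulus_radius(1 / 3, 2, 4), annulus_radius(2 / 3, 2, 4), 4)
    mc <- c(mean(rr < br[1]),
            mean(rr >= br[1] & rr < br[2]),
            mean(rr >= br[2] & rr < br[3]),
            mean(rr >= br[3] & rr < br[4]),
            mean(rr >= br[4]))
    expect_lt(max(abs(lv$fractions[v, ] - mc)), 0.02)
  }
})

test_that("deep fraction decreases towards the pial surface on a slab", {
  sp <- phantom_spec("flat-slab", wm_z_mm = 5.0, thickness_mm = 2.4,
                     tilt_deg = 0, grid_shape = c(6, 6, 14))
  ph <- make_cortical_phantom(sp)
  tg <- ph$truth_geometry
  ls <- equivolume_surfaces(tg$wm_sdf, tg$pial_sdf, ph$grid)
  lv <- layer_volume_distribution(ls, subdivision = 4)
  col <- which(lv$ijk[, "i"] == 3 & lv$ijk[, "j"] == 3)
  ord <- col[order(lv$ijk[col, "k"])]
  f <- lv$fractions[ord, "deep"]
  # non-increasing from the deep layer towards the pial surface
  peak <- which.max(f)
  expect_true(all(diff(f[peak:length(f)]) <= 1e-9))
})

test_that("GM volume is conserved and the three layers have equal volume", {
  # finer grid so the curvature of the annulus is resolved by interpolation
  sp <- phantom_spec("cylinder-annulus", grid_shape = c(29, 29, 13),
                     voxel_size_mm = 0.5)
  ph <- make_cortical_phantom(sp)
  wm <- compute_sdf(ph$surfaces$wm, ph$grid)
  pl <- compute_sdf(ph$surfaces$pial, ph$grid)
  ls <- equivolume_surfaces(wm, pl, ph$grid)
  lv <- layer_volume_distribution(ls, subdivision = 6)
  vols <- colSums(lv$fractions)[c("deep", "middle", "superficial")] *
    lv$voxel_volume_mm3
  zlen <- ph$grid$dim[3] * ph$grid$voxel_mm
  analytic <- pi * (4^2 - 2^2) * zlen
  expect_lt(abs(sum(vols) - analytic) / analytic, 0.02)       # conservation
  expect_lt((max(vols) - min(vols)) / mean(vols), 0.01)       # equivolume
})
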