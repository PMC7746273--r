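# Localizer GLM, ROI selection, time-course weighting, and the
# layer-balancing control.

loc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- small_slab()
      loc <- simulate_localizer(fx$phantom, fx$layers, noise_sd = 1, seed = 21)
      stats <- localizer_glm(loc$run, loc$blocks)
      gm <- fx$layers$voxel_index[rowSums(fx$layers$fractions[, 2:4]) > 0]
      cache <<- list(fx = fx, loc = loc, stats = stats, gm = gm)
    }
    cache
  }
})

test_that("noiseless preference phantom: T sign equals the generating label", {
  fx <- small_slab()
  loc <- simulate_localizer(fx$phantom, fx$layers, noise_sd = 0.01, seed = 3)
  stats <- localizer_glm(loc$run, loc$blocks)
  gm <- fx$layers$voxel_index[rowSums(fx$layers$fractions[, 2:4]) > 0.2]
  sgn <- sign(stats$t_preference[gm])
  lab <- fx$phantom$preference[gm]
  expect_true(all(sgn == ifelse(lab == 45, 1, -1)))
})

test_that("null localizer holds the nominal type-I rate", {
  fx <- small_slab()
  truth0 <- ground_truth_amplitudes()
  loc <- simulate_localizer(fx$phantom, fx$layers, amp_preferred = 0,
                            amp_nonpreferred = 0, noise_sd = 5, seed = 10)
  stats <- localizer_glm(loc$run, loc$blocks)
  tp <- stats$t_preference[fx$layers$voxel_index]
  tp <- tp[is.finite(tp)]
  crit <- qt(0.975, stats$df)
  expect_equal(mean(abs(tp) > crit), 0.05, tolerance = 0.012)
  # and the preference map is centred on zero
  expect_equal(mean(tp), 0, tolerance = 0.05)
})

test_that("constant voxels are excluded with a log message", {
  fx <- small_slab()
  # noiseless run: pure-WM voxels carry a constant baseline
  loc <- simulate_localizer(fx$phantom, fx$layers, noise_sd = 0, seed = 4)
  wm_pure <- fx$layers$voxel_index[fx$layers$fractions[, "wm"] == 1][1:30]
  expect_message(stats <- localizer_glm(loc$run, loc$blocks, voxels = wm_pure),
                 "constant voxel")
  expect_true(all(is.na(stats$t_activation[wm_pure])))
})

test_that("ROI selection is deterministic, bounded, and correctly labelled", {
  z <- loc_fixture()
  rois <- select_rois(z$stats, z$gm, activation_t = 2.3,
                      n_per_orientation = 100)
  expect_equal(length(rois$roi45$voxels), 100)
  expect_equal(length(rois$roi135$voxels), 100)
  expect_length(intersect(rois$roi45$voxels, rois$roi135$voxels), 0)
  expect_true(all(z$fx$phantom$preference[rois$roi45$voxels] == 45))
  expect_true(all(z$fx$phantom$preference[rois$roi135$voxels] == 135))
  rois2 <- select_rois(z$stats, z$gm, activation_t = 2.3,
                       n_per_orientation = 100)
  expect_identical(rois, rois2)
  # infinite threshold: empty set with a warning
  expect_warning(empty <- select_rois(z$stats, z$gm, activation_t = Inf),
                 "no voxels")
  expect_length(empty$roi45$voxels, 0)
  # more voxels than eligible: capped with a warning
  expect_warning(all_of_them <- select_rois(z$stats, z$gm,
                                            n_per_orientation = 10000),
                 "eligible")
  expect_lte(length(all_of_them$roi45$voxels), length(z$gm))
})

test_that("ROI mean |T| is non-increasing as the ROI grows", {
  z <- loc_fixture()
  sizes <- c(50, 100, 200, 300)
  meanT <- vapply(sizes, function(n) {
    r <- select_rois(z$stats, z$gm, n_per_orientation = n)
    mean(c(r$roi45$weights, r$roi135$weights))
  }, numeric(1))
  expect_true(all(diff(meanT) <= 1e-12))
})

test_that("weighting scales variance by T^2 and raw mode is the identity", {
  z <- loc_fixture()
  rois <- select_rois(z$stats, z$gm, n_per_orientation = 50)
  runs <- list(simulate_bold(z$fx$phantom, z$fx$layers, short_design_run(),
                             ground_truth_amplitudes(), noise_sd = 2, seed = 6))
  pw <- weight_timecourses(runs, rois, z$stats, mode = "weighted")
  v <- apply(pw$panels$roi45[[1]], 1, var)
  w <- abs(z$stats$t_preference[pw$voxels$roi45])
  expect_equal(v, w^2 * 1, tolerance = 1e-8, ignore_attr = TRUE)
  praw <- weight_timecourses(runs, rois, z$stats, mode = "raw")
  flat <- matrix(runs[[1]]$data, prod(z$fx$phantom$grid$dim),
                 dim(runs[[1]]$data)[4])
  expect_equal(praw$panels$roi45[[1]], flat[rois$roi45$voxels, ],
               tolerance = 1e-12)
})

test_that("per-run z-scoring is unaffected by run order", {
  z <- loc_fixture()
  rois <- select_rois(z$stats, z$gm, n_per_orientation = 40)
  r1 <- simulate_bold(z$fx$phantom, z$fx$layers, short_design_run(seed = 1),
                      ground_truth_amplitudes(), noise_sd = 2, seed = 6)
  r2 <- simulate_bold(z$fx$phantom, z$fx$layers, short_design_run(seed = 2),
                      ground_truth_amplitudes(), noise_sd = 2, seed = 7)
  a <- weight_timecourses(list(r1, r2), rois, z$stats)
  b <- weight_timecourses(list(r2, r1), rois, z$stats)
  expect_equal(a$panels$roi45[[1]], b$panels$roi45[[2]], tolerance = 1e-12)
  expect_equal(a$panels$roi45[[2]], b$panels$roi45[[1]], tolerance = 1e-12)
})

test_that("layer balancing removes superficial-heavy voxels until p > alpha", {
  z <- loc_fixture()
  lv <- z$fx$layers
  gmfrac <- lv$fractions[, 2:4]
  # balanced partial-volume core plus a superficial-dominant surplus
  spread <- apply(gmfrac, 1, max) < 0.6 & rowSums(gmfrac) > 0.5
  core <- lv$voxel_index[spread][1:60]
  sup_heavy <- lv$voxel_index[gmfrac[, "superficial"] > 0.9][1:25]
  roi <- unique(c(core, sup_heavy))
  out <- balance_layers(roi, lv, alpha = 0.1)
  expect_lt(length(out), length(roi))
  expect_gt(attr(out, "p_final"), 0.1)
  removed <- attr(out, "removed")
  pos <- match(removed, lv$voxel_index)
  # removals come from the overrepresented (superficial) layer
  expect_true(all(apply(gmfrac[pos, , drop = FALSE], 1, which.max) == 3))
})

test_that("balancing stops immediately for balanced input and alpha = 1 semantics", {
  z <- loc_fixture()
  lv <- z$fx$layers
  gm <- lv$fractions[, 2:4]
  # symmetric construction: equal numbers of deep/middle/superficial-dominant
  picks <- lapply(1:3, function(l) lv$voxel_index[order(-gm[, l])][1:20])
  roi <- unique(unlist(picks))
  out <- balance_layers(roi, lv, alpha = 1e-12)   # nothing is 'significant'
  expect_equal(length(out), length(roi))
  expect_length(attr(out, "removed"), 0)
})

test_that("balancing iterations never increase the imbalance F statistic", {
  z <- loc_fixture()
  lv <- z$fx$layers
  gm <- lv$fractions[, 2:4]
  roi <- lv$voxel_index[order(-gm[, "superficial"])][1:50]
  roi <- c(roi, lv$voxel_index[gm[, "deep"] > 0.5][1:25])
  Fstat <- function(vox) {
    g <- gm[match(vox, lv$voxel_index), ]
    df <- data.frame(frac = as.vector(g),
                     layer = rep(colnames(g), each = nrow(g)))
    anova(lm(frac ~ layer, df))[1, "F value"]
  }
  out <- suppressWarnings(balance_layers(roi, lv, alpha = 0.1))
  removed <- attr(out, "removed")
  vox <- roi
  fs <- Fstat(vox)
  for (r in removed) {
    vox <- setdiff(vox, r)
    fs <- c(fs, Fstat(vox))
  }
  expect_true(all(diff(fs) <= 1e-8))
})
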