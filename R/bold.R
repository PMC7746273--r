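# Forward BOLD model: layer-resolved condition amplitudes mixed into voxels
# through the layer volume distribution, convolved with the canonical HRF,
# on top of a compartment intensity profile, with drift, thermal noise, and
# optionally recorded/applied rigid head motion.

#' Ground-truth laminar condition amplitudes
#'
#' Encodes the simulation truth as percent-signal-change amplitudes per
#' grey-matter layer for every condition cell: stimulus present vs omitted,
#' voxel preferred vs non-preferred orientation, orientation vs contrast
#' task. The defaults carry an orientation-specific (preferred minus
#' non-preferred) response of 0.14% in all layers for presented gratings, and
#' an omission response confined to the deep layer (0.15% in the orientation
#' task, 0.05% in the contrast task) - the effect structure under study.
#'
#' @param present_preferred,present_nonpreferred length-3 vectors
#'   (deep, middle, superficial), percent signal change, shared by tasks.
#' @param omitted_preferred_orientation_task,omitted_preferred_contrast_task
#'   length-3 vectors for omission trials in each task.
#' @param omitted_nonpreferred length-3 vector (both tasks).
#' @param superficial_bias_gain multiplicative per-layer gain (deep, middle,
#'   superficial) emulating the draining-vein amplitude bias; must be > 0.
#' @param noise_sd thermal noise SD in raw signal units, or `NULL` to derive
#'   it from `tsnr_target` at simulation time.
#' @param tsnr_target temporal SNR (mean/SD) the default noise level
#'   reproduces (12.5, the post-realignment in-brain value of the target
#'   acquisition).
#' @return object of class `ground_truth_amplitudes`: list with `amplitude`
#'   (3 x 2 x 2 x 2 array: layer, stimulus, preference, task),
#'   `superficial_bias_gain`, `noise_sd`, `tsnr_target`.
#' @export
ground_truth_amplitudes <- function(present_preferred = c(0.30, 0.30, 0.30),
                                    present_nonpreferred = c(0.16, 0.16, 0.16),
                                    omitted_preferred_orientation_task = c(0.15, 0, 0),
                                    omitted_preferred_contrast_task = c(0.05, 0, 0),
                                    omitted_nonpreferred = c(0, 0, 0),
                                    superficial_bias_gain = c(1, 1, 1),
                                    noise_sd = NULL, tsnr_target = 12.5) {
  amp <- array(0, dim = c(3, 2, 2, 2),
               dimnames = list(layer = c("deep", "middle", "superficial"),
                               stimulus = c("present", "omitted"),
                               preference = c("preferred", "nonpreferred"),
                               task = c("orientation", "contrast")))
  amp[, "present", "preferred", ] <- present_preferred
  amp[, "present", "nonpreferred", ] <- present_nonpreferred
  amp[, "omitted", "preferred", "orientation"] <- omitted_preferred_orientation_task
  amp[, "omitted", "preferred", "contrast"] <- omitted_preferred_contrast_task
  amp[, "omitted", "nonpreferred", ] <- omitted_nonpreferred
  if (!all(is.finite(amp))) stop("amplitudes must be finite")
  if (!all(superficial_bias_gain > 0)) stop("bias gains must be > 0")
  structure(list(amplitude = amp,
                 superficial_bias_gain = superficial_bias_gain,
                 noise_sd = noise_sd, tsnr_target = tsnr_target),
            class = "ground_truth_amplitudes")
}

#' Orientation-specific (preferred minus non-preferred) truth amplitudes
#'
#' The quantity the pipeline estimates: per layer, stimulus and task, the
#' preferred-minus-non-preferred amplitude including the per-layer gain.
#' @param truth a [ground_truth_amplitudes()].
#' @return 3 x 2 x 2 array (layer, stimulus, task), percent signal change.
#' @export
specific_amplitudes <- function(truth) {
  a <- truth$amplitude
  s <- a[, , "preferred", ] - a[, , "nonpreferred", ]
  sweep(s, 1, truth$superficial_bias_gain, "*")
}

# Compartment baseline intensities (raw EPI units): grey matter brighter
# than white matter and out-of-brain signal.
default_compartment_intensity <- c(wm = 427, deep = 455, middle = 456,
                                   superficial = 461, csf = 430)

# volumes needed to cover the design plus washout
run_volumes <- function(design_run, TR_s, trial_dur_s = 2.5, lead_out_s = 20) {
  ceiling((max(design_run$onset_s) + trial_dur_s + lead_out_s) / TR_s)
}

# random-walk motion parameters (T x 6: tx ty tz rx ry rz), mm / deg
simulate_motion <- function(n_vol, step_sd_mm = 0.02) {
  m <- apply(matrix(rnorm(n_vol * 6, sd = step_sd_mm), n_vol, 6), 2, cumsum)
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Simulate one BOLD run on a cortical phantom
#'
#' The voxel signal is `sum_c X[v,c] * I_c * (1 + g_c * a_c(t) / 100)`: each
#' compartment contributes its volume fraction times its baseline intensity,
#' and the grey-matter layers additionally carry the HRF-convolved condition
#' responses for the voxel's preferred/non-preferred orientation (in percent
#' signal change of the layer baseline, times the per-layer bias gain).
#' Event onsets are the expected first-grating onsets (cue onset + SOA), for
#' omission trials too - the expectation pertains to the grating time.
#' Optional linear drift, Gaussian thermal noise, and rigid head motion
#' (recorded in the motion table; applied to the volumes only when
#' `apply_motion = TRUE`, translations only).
#'
#' @param phantom a [make_cortical_phantom()] result.
#' @param layers a [layer_volume_distribution()] over the phantom grid (the
#'   same matrix the analysis will use, making the forward model exactly
#'   invertible in the noiseless case).
#' @param design_run rows of a [simulate_design()] table for a single run.
#' @param truth a [ground_truth_amplitudes()].
#' @param TR_s volume acquisition time (default 3.583 s).
#' @param noise_sd Gaussian noise SD in raw units; `NULL` derives it from
#'   `truth$tsnr_target`; 0 disables noise.
#' @param drift_pct_per_min linear drift amplitude (percent of baseline per
#'   minute; default 0).
#' @param motion_step_sd_mm random-walk step SD of the recorded motion
#'   parameters (0 disables); motion is applied to the data only when
#'   `apply_motion = TRUE`.
#' @param apply_motion logical.
#' @param seed integer seed.
#' @return object of class `bold_run`: list `data` (4D array x,y,z,t),
#'   `TR_s`, `grid`, `affine`, `motion` (T x 6), `design`, `n_baseline_vols`
#'   (volumes before the first possible response, usable as a baseline
#'   image).
#' @export
simulate_bold <- function(phantom, layers, design_run, truth,
                          TR_s = 3.583, noise_sd = NULL,
                          drift_pct_per_min = 0, motion_step_sd_mm = 0,
                          apply_motion = FALSE, seed = 1L) {
  stopifnot(inherits(phantom, "cortical_phantom"),
            inherits(layers, "layer_volume_matrix"),
            inherits(truth, "ground_truth_amplitudes"), TR_s > 0)
  if (!all(dim(phantom$preference) == phantom$grid$dim))
    stop("preference map shape does not match the phantom grid")
  if (length(unique(design_run$run)) != 1)
    stop("design_run must contain exactly one run")
  set.seed(as.integer(seed))
  grid <- phantom$grid
  task <- design_run$task[1]
  n_vol <- run_volumes(design_run, TR_s,
                       attr(design_run, "trial_dur_s") %||% 2.5)

  # condition regressors at expected grating onsets
  reg <- list()
  for (stim in c("present", "omitted")) for (ori in c(45, 135)) {
    sel <- design_run$trial_type == ifelse(stim == "present", "present", "omission") &
      design_run$cued_orientation_deg == ori
    reg[[paste(stim, ori, sep = "_")]] <-
      hrf_regressor(design_run$grating_onset_s[sel], n_vol, TR_s)
  }

  I <- default_compartment_intensity
  gain <- c(1, truth$superficial_bias_gain, 1)    # wm, 3 GM layers, csf
  amp <- truth$amplitude

  # layer time courses per preference group: 5 x T
  layer_course <- function(pref) {
    C <- matrix(rep(I, n_vol), nrow = 5)
    for (l in 1:3) {
      a <- numeric(n_vol)
      for (stim in c("present", "omitted")) for (ori in c(45, 135)) {
        match_pref <- if (ori == pref) "preferred" else "nonpreferred"
        a <- a + reg[[paste(stim, ori, sep = "_")]] *
          amp[l, stim, match_pref, task]
      }
      C[l + 1, ] <- I[l + 1] * (1 + gain[l + 1] * a / 100)
    }
    C
  }

  X <- layers$fractions
  pref_vox <- phantom$preference[layers$voxel_index]
  Y <- matrix(0, length(layers$voxel_index), n_vol)
  for (pref in c(45, 135)) {
    sel <- pref_vox == pref
    if (any(sel)) Y[sel, ] <- X[sel, , drop = FALSE] %*% layer_course(pref)
  }

  if (drift_pct_per_min != 0) {
    tmin <- (seq_len(n_vol) - 1) * TR_s / 60
    Y <- Y + outer(rowMeans(Y[, 1:2, drop = FALSE]) * drift_pct_per_min / 100,
                   tmin - mean(tmin))
  }
  if (is.null(noise_sd))
    noise_sd <- mean(default_compartment_intensity) / truth$tsnr_target
  if (noise_sd > 0)
    Y <- Y + matrix(rnorm(length(Y), sd = noise_sd), nrow(Y))

  vol <- array(0, c(grid$dim, n_vol))
  flat <- matrix(vol, prod(grid$dim), n_vol)
  flat[layers$voxel_index, ] <- Y
  vol <- array(flat, c(grid$dim, n_vol))

  motion <- matrix(0, n_vol, 6,
                   dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
  if (motion_step_sd_mm > 0) {
    motion <- simulate_motion(n_vol, motion_step_sd_mm)
    if (apply_motion) {
      cc <- voxel_centres(grid)
      for (tt in seq_len(n_vol)) {
        shift <- pmin(pmax(motion[tt, 1:3], -grid$voxel_mm), grid$voxel_mm)
        vol[, , , tt] <- array(interp3(vol[, , , tt], grid,
                                       sweep(cc, 2, shift, "-")), grid$dim)
      }
    }
  }

  structure(list(data = vol, TR_s = TR_s, grid = grid,
                 affine = grid_affine(grid), motion = motion,
                 design = design_run,
                 n_baseline_vols = max(1L, floor(min(design_run$grating_onset_s) / TR_s)),
                 noise_sd = noise_sd),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("bold_run: %s voxels x %d volumes, TR %.3f s\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4], x$TR_s))
  invisible(x)
}

#' Simulate the orientation localizer run
#'
#' Flickering-grating blocks of a fixed orientation (~14.3 s, 4 volumes at
#' the default TR), each followed by an equally long rest, orientations
#' pseudorandomised with equal counts. Voxels respond more strongly to their
#' preferred orientation.
#'
#' @param phantom,layers,truth as in [simulate_bold()].
#' @param n_blocks number of blocks (must be even so both orientations are
#'   shown equally; default 16).
#' @param block_dur_s block duration (default 4 volumes).
#' @param amp_preferred,amp_nonpreferred percent-signal-change response of a
#'   voxel to its preferred / non-preferred orientation.
#' @param TR_s,noise_sd,seed as in [simulate_bold()].
#' @return list `run` (a `bold_run`), `blocks` (data.frame `onset_s`,
#'   `duration_s`, `orientation_deg`).
#' @export
simulate_localizer <- function(phantom, layers, truth = ground_truth_amplitudes(),
                               n_blocks = 16, block_dur_s = 4 * 3.583,
                               amp_preferred = 2, amp_nonpreferred = 1,
                               TR_s = 3.583, noise_sd = NULL, seed = 1L) {
  stopifnot(inherits(phantom, "cortical_phantom"),
            inherits(layers, "layer_volume_matrix"))
  if (n_blocks %% 2 != 0)
    stop("n_blocks must be even so both orientations appear equally often")
  set.seed(as.integer(seed))
  grid <- phantom$grid
  lead_in <- 2 * TR_s
  ori <- sample(rep(c(45, 135), n_blocks / 2))
  onset <- lead_in + (seq_len(n_blocks) - 1) * 2 * block_dur_s
  blocks <- data.frame(onset_s = onset, duration_s = block_dur_s,
                       orientation_deg = ori)
  n_vol <- ceiling((max(onset) + 2 * block_dur_s) / TR_s)

  r45 <- hrf_regressor(blocks$onset_s[ori == 45], n_vol, TR_s, block_dur_s)
  r135 <- hrf_regressor(blocks$onset_s[ori == 135], n_vol, TR_s, block_dur_s)

  I <- default_compartment_intensity
  gain <- c(1, truth$superficial_bias_gain, 1)
  course <- function(pref) {
    C <- matrix(rep(I, n_vol), nrow = 5)
    a45 <- if (pref == 45) amp_preferred else amp_nonpreferred
    a135 <- if (pref == 135) amp_preferred else amp_nonpreferred
    for (l in 2:4)
      C[l, ] <- I[l] * (1 + gain[l] * (a45 * r45 + a135 * r135) / 100)
    C
  }
  X <- layers$fractions
  pref_vox <- phantom$preference[layers$voxel_index]
  Y <- matrix(0, length(layers$voxel_index), n_vol)
  for (pref in c(45, 135)) {
    sel <- pref_vox == pref
    if (any(sel)) Y[sel, ] <- X[sel, , drop = FALSE] %*% course(pref)
  }
  if (is.null(noise_sd))
    noise_sd <- mean(default_compartment_intensity) / truth$tsnr_target
  if (noise_sd > 0)
    Y <- Y + matrix(rnorm(length(Y), sd = noise_sd), nrow(Y))

  flat <- matrix(0, prod(grid$dim), n_vol)
  flat[layers$voxel_index, ] <- Y
  run <- structure(list(data = array(flat, c(grid$dim, n_vol)), TR_s = TR_s,
                        grid = grid, affine = grid_affine(grid),
                        motion = matrix(0, n_vol, 6), design = blocks,
                        n_baseline_vols = max(1L, floor(lead_in / TR_s)),
                        noise_sd = noise_sd),
                   class = "bold_run")
  list(run = run, blocks = blocks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
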