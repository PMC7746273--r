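# Trial-level experimental design generator: cued-orientation trials with
# omissions, two interleaved tasks, counterbalanced cue-orientation
# contingency with a mid-experiment flip, and jittered inter-trial intervals.

# Rate of a truncated exponential on [0, range] whose mean is range/3
# (solved once, numerically; the jitter bounds are the only stated
# constraint, the mean placement is a design choice).
trunc_exp_rate <- function(range_s) {
  f <- function(l) 1 / l - range_s / (exp(range_s * l) - 1) - range_s / 3
  stats::uniroot(f, c(1e-4, 50))$root
}

# Draw truncated exponential jitters on [lo, hi] via inverse CDF.
draw_iti <- function(n, lo, hi) {
  r <- hi - lo
  lam <- trunc_exp_rate(r)
  u <- runif(n)
  lo + (-log(1 - u * (1 - exp(-lam * r))) / lam)
}

#' Simulate the trial table of the cued-orientation experiment
#'
#' Generates the full session: `n_runs` runs of `blocks_per_run` blocks of
#' `trials_per_block` trials, tasks alternating between runs (orientation,
#' contrast, ...), a colour cue predicting the grating orientation with the
#' stated validity, the remaining trials being omissions (cue but no
#' gratings), and the cue-colour/orientation contingency flipped halfway
#' through the session. Omission and orientation counts are balanced exactly
#' within each block and their positions randomised. Onsets are cue onsets,
#' in seconds from the start of each run; `grating_onset_s = onset_s + soa_s`
#' is the (expected) onset of the first grating.
#'
#' @param n_runs,blocks_per_run,trials_per_block session structure
#'   (defaults 4, 2, 64 - i.e. 512 trials, 256 per task).
#' @param validity probability that the cue is followed by gratings (0.75).
#' @param omission_rate probability of an omission trial (0.25); must equal
#'   `1 - validity`.
#' @param soa_s cue-to-grating stimulus onset asynchrony (0.75 s).
#' @param iti_range_s inter-trial interval jitter bounds (2.15-5.15 s).
#' @param trial_dur_s duration from cue onset to the end of the response
#'   window (2.5 s).
#' @param lead_in_s rest before the first trial of each run (10 s).
#' @param delta_orientation_deg,delta_contrast mean second-grating
#'   orientation/contrast differences; used when no staircase traces are
#'   supplied.
#' @param staircase optional list with elements `orientation` and `contrast`,
#'   each a [simulate_staircase_observer()] trace whose per-trial deltas set
#'   the second-grating differences.
#' @param seed integer seed; identical seeds give identical tables.
#' @return a `data.frame` (class `design_table`) with one row per trial.
#' @export
simulate_design <- function(n_runs = 4, blocks_per_run = 2, trials_per_block = 64,
                            validity = 0.75, omission_rate = 0.25,
                            soa_s = 0.75, iti_range_s = c(2.15, 5.15),
                            trial_dur_s = 2.5, lead_in_s = 10,
                            delta_orientation_deg = 3.3, delta_contrast = 6.9,
                            staircase = NULL, seed = 1L) {
  stopifnot(n_runs >= 1, blocks_per_run >= 1, trials_per_block >= 1,
            validity >= 0, validity <= 1, omission_rate >= 0, omission_rate <= 1)
  if (abs(validity + omission_rate - 1) > 1e-9)
    stop("cue validity and omission rate must sum to 1")
  set.seed(as.integer(seed))

  tasks <- rep(c("orientation", "contrast"), length.out = n_runs)
  flip_after <- ceiling(n_runs / 2)
  n_omit <- round(trials_per_block * omission_rate)

  rows <- vector("list", n_runs * blocks_per_run)
  trial_counter <- 0L
  for (run in seq_len(n_runs)) {
    # contingency A: orange -> 45, cyan -> 135; flipped halfway
    flipped <- run > flip_after
    for (block in seq_len(blocks_per_run)) {
      nt <- trials_per_block
      type <- rep("present", nt)
      if (n_omit > 0) type[sample.int(nt, n_omit)] <- "omission"
      ori <- sample(rep(c(45, 135), length.out = nt))
      cue <- ifelse(ori == 45, "orange", "cyan")
      if (flipped) cue <- ifelse(ori == 45, "cyan", "orange")
      iti <- draw_iti(nt, iti_range_s[1], iti_range_s[2])
      rows[[(run - 1) * blocks_per_run + block]] <- data.frame(
        trial_index = trial_counter + seq_len(nt),
        run = run, block = block, task = tasks[run],
        cue_colour = cue, cued_orientation_deg = ori,
        trial_type = type, iti_s = iti, stringsAsFactors = FALSE)
      trial_counter <- trial_counter + nt
    }
  }
  d <- do.call(rbind, rows)

  # onsets per run: cue onsets, strictly increasing
  d$onset_s <- NA_real_
  for (run in seq_len(n_runs)) {
    sel <- d$run == run
    gaps <- trial_dur_s + d$iti_s[sel]
    d$onset_s[sel] <- lead_in_s + c(0, cumsum(gaps[-sum(sel)]))
  }
  d$grating_onset_s <- d$onset_s + soa_s

  # second-grating differences on present trials (staircase-driven if given)
  d$grating1_orientation_deg <- ifelse(d$trial_type == "present",
                                       d$cued_orientation_deg, NA_real_)
  n_present <- sum(d$trial_type == "present")
  sgn <- sample(c(-1, 1), n_present, replace = TRUE)
  get_deltas <- function(trace, fallback) {
    if (is.null(trace)) return(rep(fallback, n_present))
    rep_len(trace$delta, n_present)
  }
  d$grating2_delta_orientation_deg <- NA_real_
  d$grating2_delta_contrast <- NA_real_
  pres <- d$trial_type == "present"
  d$grating2_delta_orientation_deg[pres] <-
    sgn * get_deltas(staircase$orientation, delta_orientation_deg)
  d$grating2_delta_contrast[pres] <-
    sample(c(-1, 1), n_present, replace = TRUE) *
    get_deltas(staircase$contrast, delta_contrast)

  attr(d, "soa_s") <- soa_s
  attr(d, "trial_dur_s") <- trial_dur_s
  attr(d, "validity") <- validity
  attr(d, "omission_rate") <- omission_rate
  class(d) <- c("design_table", "data.frame")
  d
}

#' Simulate an observer driven by an adaptive staircase
#'
#' A weighted up-down staircase (step-size ratio 3:1, one step down after a
#' correct response, one step up after an error) whose equilibrium is the
#' 75%-correct point of the observer's psychometric function. The observer
#' performs a two-interval discrimination with internal Gaussian noise:
#' `P(correct | delta) = Phi(delta / (sqrt(2) * psychometric_sd))`. Setting
#' `psychometric_sd = 0` gives a step (always-correct for any positive
#' delta) observer.
#'
#' @param psychometric_sd internal noise SD of the observer, in stimulus
#'   units (> 0, or exactly 0 for the deterministic step observer).
#' @param n_trials number of trials (>= 20, otherwise convergence cannot be
#'   assessed).
#' @param seed integer seed.
#' @param start_delta initial stimulus difference.
#' @param step_down decrement after a correct response; the increment after
#'   an error is `3 * step_down`, targeting 75% correct.
#' @param floor_delta smallest allowed difference.
#' @param target target proportion correct (default 0.75).
#' @return object of class `staircase_trace`: data.frame columns `trial`,
#'   `delta`, `correct`, `reversal`, `threshold` (running mean of reversal
#'   deltas), plus attributes `target` and `pct_correct_last_half`.
#' @export
simulate_staircase_observer <- function(psychometric_sd, n_trials = 512,
                                        seed = 1L, start_delta = 2,
                                        step_down = 0.1,
                                        floor_delta = 0.02, target = 0.75) {
  if (!is.numeric(psychometric_sd) || psychometric_sd < 0)
    stop("psychometric_sd must be >= 0")
  if (n_trials < 20) stop("need at least 20 trials to assess convergence")
  set.seed(as.integer(seed))
  step_up <- step_down * target / (1 - target)

  delta <- numeric(n_trials); correct <- logical(n_trials)
  cur <- start_delta
  last_dir <- 0L
  reversal <- logical(n_trials)
  rev_deltas <- numeric(0)
  threshold <- rep(NA_real_, n_trials)
  for (i in seq_len(n_trials)) {
    delta[i] <- cur
    p <- if (psychometric_sd == 0) as.numeric(cur > 0)
         else pnorm(cur / (sqrt(2) * psychometric_sd))
    correct[i] <- runif(1) < p
    dir <- if (correct[i]) -1L else 1L
    if (last_dir != 0L && dir != last_dir) {
      reversal[i] <- TRUE
      rev_deltas <- c(rev_deltas, cur)
    }
    last_dir <- dir
    cur <- max(floor_delta, cur + if (correct[i]) -step_down else step_up)
    if (length(rev_deltas)) threshold[i] <- mean(rev_deltas)
  }
  out <- data.frame(trial = seq_len(n_trials), delta = delta,
                    correct = correct, reversal = reversal,
                    threshold = threshold)
  attr(out, "target") <- target
  half <- (n_trials %/% 2 + 1):n_trials
  attr(out, "pct_correct_last_half") <- 100 * mean(correct[half])
  class(out) <- c("staircase_trace", "data.frame")
  out
}
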