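# Temporal GLM: condition regressors (canonical HRF at the expected grating
# onsets), motion nuisance set, run-wise cosine high-pass filtering, OLS
# fitting of laminar time courses, and the reduction to orientation-specific
# layer amplitudes.

interest_conditions <- c("present_45", "present_135", "omitted_45", "omitted_135")

#' Build the temporal design for one task
#'
#' Constructs, over that task's (possibly several) runs: four regressors of
#' interest - presentation/omission of 45/135-degree gratings, stick
#' functions at the expected first-grating onsets convolved with the
#' canonical HRF -, the motion nuisance set (6 parameters, their backward
#' differences, and the squared differences; all-zero columns dropped with a
#' message), and a run-wise discrete-cosine high-pass basis (cutoff 128 s by
#' default) applied to the design here and to the data at fit time. Run
#' means are removed by the filter, so no intercepts remain in the model.
#'
#' @param design_runs list of per-run [simulate_design()] subsets (all the
#'   same task).
#' @param motion list of per-run T x 6 motion parameter matrices (or NULL
#'   for none).
#' @param TR_s repetition time.
#' @param n_vols integer vector, volumes per run.
#' @param hp_cutoff_s high-pass cutoff in seconds (default 128; `Inf`
#'   disables filtering apart from mean removal).
#' @return object of class `temporal_design`: list `X` (filtered, stacked),
#'   `interest` (column names of the 4 interest regressors), `n_vols`,
#'   `bases` (per-run cosine bases), `TR_s`, `task`.
#' @export
build_design <- function(design_runs, motion = NULL, TR_s = 3.583,
                         n_vols, hp_cutoff_s = 128) {
  stopifnot(is.list(design_runs), length(n_vols) == length(design_runs))
  task <- unique(vapply(design_runs, function(d) d$task[1], character(1)))
  if (length(task) != 1) stop("all runs in one design must share the task")

  Xint <- NULL
  for (i in seq_along(design_runs)) {
    d <- design_runs[[i]]
    cols <- sapply(c("present", "omission"), function(tt)
      sapply(c(45, 135), function(ori) {
        sel <- d$trial_type == tt & d$cued_orientation_deg == ori
        hrf_regressor(d$grating_onset_s[sel], n_vols[i], TR_s)
      }))
    dim(cols) <- c(n_vols[i], 4)
    colnames(cols) <- c("present_45", "present_135", "omitted_45", "omitted_135")
    Xint <- rbind(Xint, cols)
  }

  Xnuis <- NULL
  if (!is.null(motion)) {
    blocks <- lapply(seq_along(motion), function(i) {
      m <- as.matrix(motion[[i]])
      stopifnot(nrow(m) == n_vols[i], ncol(m) == 6)
      dm <- rbind(0, diff(m))            # backward differences, first volume 0
      cbind(m, dm, dm^2)
    })
    Xnuis <- do.call(rbind, blocks)
    colnames(Xnuis) <- c(paste0("mo", 1:6), paste0("dmo", 1:6), paste0("dmo2_", 1:6))
    zero <- colSums(abs(Xnuis)) <= 1e-12
    if (any(zero)) {
      message("dropping all-zero nuisance column(s): ",
              paste(colnames(Xnuis)[zero], collapse = ", "))
      Xnuis <- Xnuis[, !zero, drop = FALSE]
    }
    if (!ncol(Xnuis)) Xnuis <- NULL
  }

  bases <- lapply(n_vols, dct_basis, TR = TR_s, cutoff_s = hp_cutoff_s)
  X <- cbind(Xint, Xnuis)
  X <- filter_by_run(X, n_vols, bases)
  structure(list(X = X, interest = colnames(Xint), n_vols = n_vols,
                 bases = bases, TR_s = TR_s, task = task,
                 hp_cutoff_s = hp_cutoff_s),
            class = "temporal_design")
}

# Apply the run-wise high-pass projection (removing run means and cosine
# drift terms) to stacked data or design columns.
filter_by_run <- function(M, n_vols, bases) {
  v <- is.null(dim(M)); M <- as.matrix(M)
  off <- 0L
  for (i in seq_along(n_vols)) {
    rows <- off + seq_len(n_vols[i])
    M[rows, ] <- highpass_filter(M[rows, , drop = FALSE], bases[[i]])
    off <- off + n_vols[i]
  }
  if (v) drop(M) else M
}

#' Fit the temporal GLM to a laminar time course
#'
#' High-pass filters the course per run with the design's cosine bases, then
#' fits OLS. `R2 = 1 - SS_res / SS_tot` is computed on the filtered data.
#'
#' @param course numeric vector, the concatenated layer time course
#'   (`sum(n_vols)` volumes).
#' @param design a [build_design()] result.
#' @return list `betas` (named; interest conditions first), `R2`, `df`,
#'   `fitted`, `residuals`.
#' @export
fit_temporal_glm <- function(course, design) {
  stopifnot(inherits(design, "temporal_design"),
            length(course) == sum(design$n_vols))
  y <- filter_by_run(course, design$n_vols, design$bases)
  X <- design$X
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("temporal design rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  b <- qr.coef(qx, y)
  fit <- drop(X %*% b)
  res <- y - fit
  ss_tot <- sum(y^2)      # filtered data are mean-free per run
  R2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  list(betas = b, R2 = R2, df = length(y) - qx$rank, fitted = fit,
       residuals = res)
}

#' Orientation-specific laminar responses
#'
#' For each ROI the response to its non-preferred orientation is subtracted
#' from the response to its preferred orientation (per layer, stimulus type
#' and task), and the two ROIs are then averaged, yielding the
#' orientation-specific, layer-specific amplitudes. Swapping the 45/135
#' labels everywhere negates the output exactly.
#'
#' @param betas_by_roi nested list `roi45`/`roi135` -> task
#'   (`orientation`/`contrast`) -> 3 x 4 matrix of layer x interest-condition
#'   betas (columns named as in [build_design()]).
#' @return object of class `laminar_effects`: 3 x 2 x 2 array (layer:
#'   deep/middle/superficial; stimulus: present/omitted; task:
#'   orientation/contrast).
#' @export
orientation_specific_response <- function(betas_by_roi) {
  tasks <- c("orientation", "contrast")
  out <- array(NA_real_, c(3, 2, 2),
               dimnames = list(layer = c("deep", "middle", "superficial"),
                               stimulus = c("present", "omitted"),
                               task = tasks))
  for (task in tasks) {
    per_roi <- lapply(c(roi45 = "roi45", roi135 = "roi135"), function(nm) {
      b <- betas_by_roi[[nm]][[task]]
      if (is.null(b) || !all(interest_conditions %in% colnames(b)))
        stop("missing condition betas for ", nm, " / ", task)
      pref <- if (nm == "roi45") "45" else "135"
      nonpref <- if (nm == "roi45") "135" else "45"
      cbind(present = b[, paste0("present_", pref)] - b[, paste0("present_", nonpref)],
            omitted = b[, paste0("omitted_", pref)] - b[, paste0("omitted_", nonpref)])
    })
    out[, , task] <- (per_roi$roi45 + per_roi$roi135) / 2
  }
  class(out) <- c("laminar_effects", class(out))
  out
}
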