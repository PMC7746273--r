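# Localizer temporal GLM, orientation-preference contrasts, top-N voxel
# selection, time-course normalisation/weighting, and the layer-balancing
# control.

#' Localizer temporal GLM and orientation contrasts
#'
#' Fits, per voxel, an OLS model with HRF-convolved boxcars for the 45- and
#' 135-degree blocks (plus intercept), and returns T statistics for the
#' stimulus-vs-baseline contrast (mean of the two block regressors against
#' zero) and the 45-vs-135 preference contrast. Voxels with (numerically)
#' zero residual variance but a nonzero contrast get a signed infinite T;
#' constant voxels are excluded and logged.
#'
#' @param localizer_run a `bold_run` (from [simulate_localizer()] or real
#'   data).
#' @param blocks block design table (`onset_s`, `duration_s`,
#'   `orientation_deg`).
#' @param voxels linear voxel indices to fit (default: all voxels).
#' @return object of class `voxel_stat_map`: list `t_activation`,
#'   `t_preference` (3D arrays, NA where not fitted/excluded), `df`,
#'   `excluded` (linear indices of zero-variance voxels), `grid`.
#' @export
localizer_glm <- function(localizer_run, blocks, voxels = NULL) {
  stopifnot(inherits(localizer_run, "bold_run"))
  grid <- localizer_run$grid
  n_vol <- dim(localizer_run$data)[4]
  if (max(blocks$onset_s + blocks$duration_s) > n_vol * localizer_run$TR_s)
    stop("block design extends past the end of the run")
  r45 <- hrf_regressor(blocks$onset_s[blocks$orientation_deg == 45], n_vol,
                       localizer_run$TR_s, blocks$duration_s[blocks$orientation_deg == 45])
  r135 <- hrf_regressor(blocks$onset_s[blocks$orientation_deg == 135], n_vol,
                        localizer_run$TR_s, blocks$duration_s[blocks$orientation_deg == 135])
  X <- cbind(1, r45, r135)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient localizer design")

  if (is.null(voxels)) voxels <- seq_len(prod(grid$dim))
  Y <- t(matrix(localizer_run$data, prod(grid$dim), n_vol)[voxels, , drop = FALSE])

  qx <- qr(X)
  B <- qr.coef(qx, Y)                       # 3 x n_vox
  res <- Y - X %*% B
  df <- n_vol - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  tstat <- function(cvec) {
    est <- drop(crossprod(cvec, B))
    se2 <- drop(crossprod(cvec, XtXinv %*% cvec)) * sigma2
    tt <- est / sqrt(se2)
    zero_var <- sigma2 <= .Machine$double.eps * mean(Y^2)
    tt[zero_var] <- sign(est[zero_var]) * Inf
    tt
  }
  t_act <- tstat(c(0, 0.5, 0.5))
  t_pref <- tstat(c(0, 1, -1))
  # constant voxels (no signal at all): excluded
  const_vox <- apply(Y, 2, function(y) var(y) == 0)
  t_act[const_vox] <- NA; t_pref[const_vox] <- NA

  a_act <- array(NA_real_, grid$dim); a_act[voxels] <- t_act
  a_pref <- array(NA_real_, grid$dim); a_pref[voxels] <- t_pref
  excluded <- voxels[const_vox]
  if (length(excluded))
    message(length(excluded), " constant voxel(s) excluded from the localizer GLM")
  structure(list(t_activation = a_act, t_preference = a_pref, df = df,
                 excluded = excluded, grid = grid),
            class = "voxel_stat_map")
}

#' Select orientation-preference ROIs
#'
#' Restricts to the mask and to voxels whose stimulus-vs-baseline T exceeds
#' the activation threshold, then takes the `n` most positive and `n` most
#' negative 45-vs-135 preference T values (45- and 135-preferring ROIs).
#' Ties are broken by voxel index, making selection deterministic.
#'
#' @param stats a [localizer_glm()] result.
#' @param mask logical 3D array or vector of linear voxel indices defining
#'   eligibility (e.g. the V1 label, or the phantom grey-matter ribbon).
#' @param activation_t activation threshold (default 2.3).
#' @param n_per_orientation voxels per ROI (default 500).
#' @return object of class `roi_set`: lists `roi45`, `roi135` each with
#'   `voxels` (linear indices) and `weights` (|T| of the preference
#'   contrast).
#' @export
select_rois <- function(stats, mask, activation_t = 2.3,
                        n_per_orientation = 500) {
  stopifnot(inherits(stats, "voxel_stat_map"))
  mask_idx <- if (is.logical(mask) || is.array(mask)) which(mask) else as.integer(mask)
  if (!length(mask_idx)) stop("mask is empty")
  t_act <- stats$t_activation[mask_idx]
  t_pref <- stats$t_preference[mask_idx]
  elig <- which(!is.na(t_act) & !is.na(t_pref) & t_act > activation_t)
  if (!length(elig)) {
    warning("no voxels exceed the activation threshold; empty ROI set")
    empty <- list(voxels = integer(0), weights = numeric(0))
    return(structure(list(roi45 = empty, roi135 = empty,
                          activation_t = activation_t, df = stats$df),
                     class = "roi_set"))
  }
  idx <- mask_idx[elig]
  tp <- t_pref[elig]
  if (length(idx) < 2 * n_per_orientation)
    warning("only ", length(idx), " eligible voxels for 2 x ",
            n_per_orientation, " requested; returning all")
  # each ROI draws only from voxels actually tuned towards its orientation
  pos <- which(tp > 0); neg <- which(tp < 0)
  take45 <- head(pos[order(-tp[pos], idx[pos])], n_per_orientation)
  take135 <- head(neg[order(tp[neg], idx[neg])], n_per_orientation)
  structure(list(
    roi45 = list(voxels = idx[take45], weights = abs(tp[take45])),
    roi135 = list(voxels = idx[take135], weights = abs(tp[take135])),
    activation_t = activation_t, df = stats$df),
    class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set: %d voxels (45 deg), %d voxels (135 deg)\n",
              length(x$roi45$voxels), length(x$roi135$voxels)))
  invisible(x)
}

#' Extract and weight ROI voxel time courses
#'
#' For each ROI and run, extracts the voxel x time panel and (in the default
#' weighted mode) z-scores each voxel's time course within the run and
#' multiplies it by the absolute preference T value, weighting towards the
#' most orientation-selective voxels. `mode = "raw"` bypasses both steps
#' (the raw-time-course control). Zero-variance voxels are excluded from the
#' weighted panels and logged.
#'
#' @param runs list of `bold_run` objects (the main experiment runs).
#' @param rois a [select_rois()] result.
#' @param stats the [localizer_glm()] map supplying |T| weights (required
#'   for weighted mode).
#' @param mode `"weighted"` (default) or `"raw"`.
#' @return object of class `voxel_timecourse_panel`: list `panels` - per ROI
#'   (`roi45`, `roi135`) a list of n_voxel x T matrices, one per run -,
#'   `voxels` (kept voxel indices per ROI), `mode`, `excluded`.
#' @export
weight_timecourses <- function(runs, rois, stats = NULL,
                               mode = c("weighted", "raw")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rois, "roi_set"))
  if (mode == "weighted" && is.null(stats))
    stop("weighted mode needs the localizer stat map")
  out <- list(); kept <- list(); excluded <- integer(0)
  for (nm in c("roi45", "roi135")) {
    vox <- rois[[nm]]$voxels
    mats <- lapply(runs, function(r) {
      n_vol <- dim(r$data)[4]
      matrix(r$data, prod(r$grid$dim), n_vol)[vox, , drop = FALSE]
    })
    if (mode == "weighted") {
      w <- abs(stats$t_preference[vox])
      sds <- lapply(mats, function(m) apply(m, 1, sd))
      ok <- Reduce(`&`, lapply(sds, function(s) s > 0)) & is.finite(w)
      excluded <- c(excluded, vox[!ok])
      mats <- lapply(seq_along(mats), function(i) {
        m <- mats[[i]][ok, , drop = FALSE]
        m <- (m - rowMeans(m)) / sds[[i]][ok]
        m * w[ok]
      })
      vox <- vox[ok]
    }
    out[[nm]] <- mats
    kept[[nm]] <- vox
  }
  if (length(excluded))
    message(length(excluded), " zero-variance voxel(s) excluded from weighting")
  structure(list(panels = out, voxels = kept, mode = mode,
                 excluded = excluded),
            class = "voxel_timecourse_panel")
}

#' Balance the laminar composition of an ROI
#'
#' Iteratively removes voxels from the most over-represented grey-matter
#' layer - the member voxel with the largest fraction in that layer goes
#' first - until a one-way ANOVA on the per-voxel GM layer fractions (factor:
#' layer) no longer shows a significant imbalance (`p > alpha`), or fewer
#' than `3 * n_layers` voxels remain.
#'
#' @param roi vector of linear voxel indices (or a `roi_set` element).
#' @param layer_matrix a [layer_volume_distribution()] covering the ROI.
#' @param alpha imbalance significance threshold (default 0.1).
#' @return the reduced voxel index vector, with attributes `removed`,
#'   `p_final`, `balanced`.
#' @export
balance_layers <- function(roi, layer_matrix, alpha = 0.1) {
  vox <- if (is.list(roi)) roi$voxels else as.integer(roi)
  if (!length(vox)) stop("ROI is empty")
  pos <- match(vox, layer_matrix$voxel_index)
  if (anyNA(pos)) stop("ROI voxels missing from the layer volume matrix")
  gm <- layer_matrix$fractions[pos, c("deep", "middle", "superficial"), drop = FALSE]
  floor_n <- 3 * 3
  removed <- integer(0)

  imbalance_p <- function(g) {
    df <- data.frame(frac = as.vector(g),
                     layer = factor(rep(colnames(g), each = nrow(g))))
    a <- anova(lm(frac ~ layer, data = df))
    p <- a[["Pr(>F)"]][1]
    if (is.na(p)) 1 else p
  }
  p <- imbalance_p(gm)
  while (p <= alpha && nrow(gm) > floor_n) {
    over <- which.max(colSums(gm))
    drop_i <- which.max(gm[, over])     # ties: which.max takes the first
    removed <- c(removed, vox[drop_i])
    vox <- vox[-drop_i]
    gm <- gm[-drop_i, , drop = FALSE]
    p <- imbalance_p(gm)
  }
  balanced <- p > alpha
  if (!balanced)
    warning("layer balance not reached before the voxel floor; ",
            "returning best achieved (p = ", signif(p, 3), ")")
  structure(vox, removed = removed, p_final = p, balanced = balanced)
}
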