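# Spatial GLM: unmix layer-specific time courses from an ROI's voxel panel
# using the per-voxel layer volume distribution as the design matrix, with
# the depth-interpolation estimator as a control.

# Align a layer_volume_matrix (or plain matrix) to a set of voxel indices.
spatial_design <- function(X, voxels = NULL) {
  if (inherits(X, "layer_volume_matrix")) {
    if (is.null(voxels)) return(X$fractions)
    pos <- match(voxels, X$voxel_index)
    if (anyNA(pos)) stop("panel voxels missing from the layer volume matrix")
    return(X$fractions[pos, , drop = FALSE])
  }
  as.matrix(X)
}

#' Spatial GLM extraction of layer time courses
#'
#' Solves `Y = X B + e` by ordinary least squares for every functional
#' volume: `Y` is the ROI's voxel x time panel, `X` the voxel x compartment
#' layer volume distribution, and `B` the 5 x time matrix of compartment
#' (WM, deep, middle, superficial, CSF) time courses. Solved via QR (the
#' adjacent-layer columns of `X` are correlated; QR is numerically safer
#' than the normal equations, to which it is algebraically identical).
#' Compartments absent from every voxel are dropped from the fit and their
#' course returned as zero with an `absent` flag; a warning is emitted when
#' `cond(X) > 1e3`.
#'
#' @param Y n_voxel x T matrix (one ROI's time courses, weighted or raw).
#' @param X a [layer_volume_distribution()] or an n_voxel x 5 matrix aligned
#'   with the rows of `Y`.
#' @param voxels voxel indices of the rows of `Y` (needed when `X` is a
#'   `layer_volume_matrix`).
#' @return object of class `layer_timecourses`: list `courses` (5 x T,
#'   rownames the compartments), `estimator = "glm"`, `absent` (character
#'   vector of dropped compartments), `condition_number`.
#' @export
spatial_glm <- function(Y, X, voxels = NULL) {
  Y <- as.matrix(Y)
  Xm <- spatial_design(X, voxels)
  stopifnot(nrow(Xm) == nrow(Y), ncol(Xm) == 5)
  if (is.null(colnames(Xm))) colnames(Xm) <- compartment_names
  present <- colSums(abs(Xm)) > 1e-12
  Xf <- Xm[, present, drop = FALSE]
  qx <- qr(Xf)
  if (qx$rank < ncol(Xf))
    stop("laminar design matrix is rank deficient over this ROI (columns: ",
         paste(colnames(Xf), collapse = ", "), ")")
  kappa_x <- kappa(Xf, exact = TRUE)
  if (kappa_x > 1e3)
    warning("laminar design matrix poorly conditioned (cond = ",
            signif(kappa_x, 3), ")")
  B <- matrix(0, 5, ncol(Y), dimnames = list(compartment_names, NULL))
  B[present, ] <- qr.coef(qx, Y)
  structure(list(courses = B, estimator = "glm",
                 absent = compartment_names[!present],
                 condition_number = kappa_x),
            class = "layer_timecourses")
}

#' Interpolation (weighted-average) extraction of layer time courses
#'
#' The control estimator `B = X' Y / N` with `N` the number of voxels:
#' effectively interpolating the panel at each depth with the layer volumes
#' as weights. Unlike the spatial GLM it does not unmix partial-volume
#' contributions, so signal confined to one layer leaks into neighbouring
#' layer estimates.
#'
#' @inheritParams spatial_glm
#' @return a `layer_timecourses` with `estimator = "interpolation"`.
#' @export
interpolation_extract <- function(Y, X, voxels = NULL) {
  Y <- as.matrix(Y)
  Xm <- spatial_design(X, voxels)
  stopifnot(nrow(Xm) == nrow(Y), ncol(Xm) == 5)
  B <- crossprod(Xm, Y) / nrow(Y)
  rownames(B) <- compartment_names
  structure(list(courses = B, estimator = "interpolation",
                 absent = compartment_names[colSums(abs(Xm)) <= 1e-12],
                 condition_number = NA_real_),
            class = "layer_timecourses")
}

#' @export
print.layer_timecourses <- function(x, ...) {
  cat(sprintf("layer_timecourses (%s): 5 x %d\n", x$estimator,
              ncol(x$courses)))
  invisible(x)
}

#' Volume-weighted mean intensity per compartment
#'
#' `X`-weighted mean of a (mean EPI) image over each compartment:
#' `(X' m) / colSums(X)`. Confirms the layering identified grey matter
#' (grey-matter compartments should be brighter than WM and out-of-brain
#' signal in a gradient-echo EPI).
#'
#' @param mean_epi numeric vector over the panel's voxels, or a 3D array
#'   (then `voxels` indexes into it).
#' @param X as in [spatial_glm()].
#' @param voxels voxel indices (required when `mean_epi` is an array or `X`
#'   is a `layer_volume_matrix`).
#' @return named length-5 vector; compartments absent from `X` are NA (with
#'   a warning).
#' @export
compartment_intensity <- function(mean_epi, X, voxels = NULL) {
  Xm <- spatial_design(X, voxels)
  m <- if (is.array(mean_epi) && length(dim(mean_epi)) == 3) {
    if (is.null(voxels)) stop("voxels required with an image input")
    mean_epi[voxels]
  } else as.numeric(mean_epi)
  stopifnot(length(m) == nrow(Xm), all(is.finite(m)))
  w <- colSums(Xm)
  out <- drop(crossprod(Xm, m)) / w
  out[w <= 1e-12] <- NA_real_
  names(out) <- compartment_names
  if (anyNA(out))
    warning("compartment(s) with no volume in this ROI: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}
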