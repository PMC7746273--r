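# Canonical haemodynamic response function, event regressor construction,
# and discrete-cosine high-pass filtering shared by the simulator and the
# temporal GLM.

#' Canonical double-gamma haemodynamic response function
#'
#' The conventional parameterisation: response gamma with shape 6, undershoot
#' gamma with shape 16 (both rate 1/s), undershoot ratio 1/6, 32-s support.
#' Scaled to unit peak so that temporal-GLM betas are in the units of the
#' data at the response peak.
#'
#' @param t time in seconds (vector).
#' @param peak_shape,under_shape,rate,under_ratio gamma parameters.
#' @param normalize logical; scale to unit maximum.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak_shape = 6, under_shape = 16, rate = 1,
                          under_ratio = 1 / 6, normalize = TRUE) {
  h <- dgamma(t, shape = peak_shape, rate = rate) -
    under_ratio * dgamma(t, shape = under_shape, rate = rate)
  h[t < 0] <- 0
  if (normalize) {
    tt <- seq(0, 32, by = 0.01)
    pk <- max(dgamma(tt, shape = peak_shape, rate = rate) -
                under_ratio * dgamma(tt, shape = under_shape, rate = rate))
    h <- h / pk
  }
  h
}

# Convolve unit sticks (or boxcars of the given durations) at `onsets`
# seconds with the canonical HRF, sampled at volume times (0, TR, 2TR, ...).
hrf_regressor <- function(onsets, n_vol, TR, durations = 0, dt = 0.1,
                          kernel_s = 32) {
  if (!length(onsets)) return(numeric(n_vol))
  total_s <- n_vol * TR
  if (any(onsets < 0 | onsets >= total_s))
    stop("events outside the run: onsets at ",
         paste(signif(onsets[onsets < 0 | onsets >= total_s], 5), collapse = ", "),
         " s (run length ", signif(total_s, 5), " s)")
  L <- ceiling(total_s / dt) + 1L
  x <- numeric(L)
  durations <- rep_len(durations, length(onsets))
  for (e in seq_along(onsets)) {
    i0 <- floor(onsets[e] / dt) + 1L
    i1 <- floor((onsets[e] + max(durations[e], 0)) / dt) + 1L
    x[i0:min(i1, L)] <- x[i0:min(i1, L)] + 1
  }
  k <- canonical_hrf(seq(0, kernel_s, by = dt))
  y <- convolve(x, rev(k), type = "open")[seq_len(L)]
  y[pmin(floor((seq_len(n_vol) - 1) * TR / dt) + 1L, L)]
}

# Discrete cosine high-pass basis (cutoff in seconds); K columns with
# periods longer than the cutoff.  Infinite cutoff gives zero columns.
dct_basis <- function(n_vol, TR, cutoff_s = 128) {
  if (!is.finite(cutoff_s)) return(matrix(0, n_vol, 0))
  K <- floor(2 * n_vol * TR / cutoff_s)
  if (K < 1) return(matrix(0, n_vol, 0))
  t <- seq_len(n_vol) - 0.5
  sapply(seq_len(K), function(k) cos(pi * k * t / n_vol))
}

# Residualise the columns of M against [1, basis] (an orthogonal projection,
# hence idempotent).  M may be a vector.
highpass_filter <- function(M, basis) {
  v <- is.null(dim(M))
  M <- as.matrix(M)
  X <- cbind(1, basis)
  R <- M - X %*% qr.coef(qr(X), M)
  if (v) drop(R) else R
}
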