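# Group-level repeated-measures statistics: within-subject ANOVA (via aov
# error strata), paired t tests, within-subject SEM error bars, temporal SNR,
# and a generator of per-subject laminar-effect tables with known truth.

#' Repeated-measures ANOVA (fully within-subject)
#'
#' Univariate within-subject ANOVA for a balanced complete design with up to
#' three within factors: each effect is tested against its own
#' effect-by-subject interaction stratum (e.g. for 18 subjects and a
#' 2-level x 3-level interaction, df = 2 and 34). No sphericity correction
#' is applied by default; Greenhouse-Geisser is available for the reported
#' p-values of multi-df effects.
#'
#' @param data data.frame in long format.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor columns (1-3).
#' @param subject name of the subject identifier column.
#' @param gg logical; apply the Greenhouse-Geisser correction.
#' @return data.frame with one row per effect: `effect`, `F`, `df_num`,
#'   `df_den`, `p`, `ss`, `ss_error` (plus `ggeps`, `p_gg` when `gg`).
#' @export
rm_anova <- function(data, dv, within, subject = "subject", gg = FALSE) {
  stopifnot(is.data.frame(data), all(c(dv, within, subject) %in% names(data)),
            length(within) >= 1, length(within) <= 3)
  d <- data
  d[[subject]] <- factor(d[[subject]])
  for (w in within) d[[w]] <- factor(d[[w]])
  counts <- table(d[, c(subject, within)])
  if (any(counts != 1))
    stop("design must be complete and balanced with one observation per cell")

  rhs <- paste(within, collapse = " * ")
  fml <- stats::as.formula(paste0("`", dv, "` ~ ", rhs, " + Error(`", subject,
                                  "`/(", rhs, "))"))
  fit <- aov(fml, data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] %in% c("Residuals")) next
      err <- which(trimws(rownames(tab)) == "Residuals")
      rows[[length(rows) + 1]] <- data.frame(
        effect = terms[i],
        F = tab[i, "F value"], df_num = tab[i, "Df"],
        df_den = tab[err, "Df"], p = tab[i, "Pr(>F)"],
        ss = tab[i, "Sum Sq"], ss_error = tab[err, "Sum Sq"],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # degenerate data: an effect SS at floating-point noise level (relative to
  # the data scale) is zero -> F = 0, p = 1 with the usual df
  tot <- sum((d[[dv]] - mean(d[[dv]]))^2)
  degen <- !is.finite(out$F) |
    out$ss <= 1e-12 * max(tot, .Machine$double.eps)
  out$F[degen] <- 0
  out$p[degen] <- 1
  if (gg) {
    out$ggeps <- NA_real_; out$p_gg <- out$p
    wide_err <- function(effect) {
      # Greenhouse-Geisser epsilon from the subject x effect-cell matrix
      cols <- strsplit(effect, ":")[[1]]
      cell <- interaction(d[cols], drop = TRUE)
      M <- tapply(d[[dv]], list(d[[subject]], cell), mean)
      S <- stats::cov(M)
      k <- ncol(S)
      eps <- (sum(diag(S)) - k * mean(S))^2 /
        ((k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mean(S)^2))
      max(min(eps, 1), 1 / (k - 1))
    }
    for (i in seq_len(nrow(out))) {
      if (out$df_num[i] > 1) {
        eps <- wide_err(out$effect[i])
        out$ggeps[i] <- eps
        out$p_gg[i] <- pf(out$F[i], eps * out$df_num[i], eps * out$df_den[i],
                          lower.tail = FALSE)
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Two-sided paired t test
#'
#' Thin wrapper around [stats::t.test()] with explicit handling of the
#' degenerate cases: identical pairs give `t = 0, p = 1`; constant nonzero
#' differences give a signed infinite `t` with `p = 0` and a flag.
#'
#' @param x,y paired numeric vectors (equal length >= 2).
#' @return list `t`, `df`, `p`, `mean_diff`, `flag` (`"ok"` or
#'   `"zero-variance"`).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, flag = "zero-variance"))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d), flag = "zero-variance"))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), flag = "ok")
}

#' Within-subject standard error of the mean
#'
#' Removes between-subject offsets (subtract each subject's mean, add back
#' the grand mean) and returns the per-condition SD of the corrected values
#' over sqrt(n), multiplied by the small-sample bias factor
#' `sqrt(C / (C - 1))` for `C` conditions - the error bars appropriate for
#' repeated-measures comparisons.
#'
#' @param table subjects x conditions numeric matrix (or data.frame).
#' @param correct logical; apply the `sqrt(C/(C-1))` bias factor (default
#'   TRUE).
#' @return named numeric vector of per-condition SEMs.
#' @export
within_subject_sem <- function(table, correct = TRUE) {
  M <- as.matrix(table)
  if (nrow(M) < 2) stop("within-subject SEM undefined for a single subject")
  C <- ncol(M)
  corr <- M - rowMeans(M) + mean(M)
  sem <- apply(corr, 2, sd) / sqrt(nrow(M))
  if (correct && C > 1) sem <- sem * sqrt(C / (C - 1))
  sem
}

#' Temporal signal-to-noise ratio
#'
#' `mean / SD` over time, per voxel time course. Zero-SD series give
#' (signed) infinity.
#'
#' @param series numeric vector, or a matrix with time in columns (one row
#'   per voxel/course).
#' @return scalar or per-row vector.
#' @export
tsnr <- function(series) {
  one <- function(x) {
    if (length(x) < 2) stop("need at least 2 time points")
    s <- sd(x)
    if (s == 0) return(sign(mean(x)) * Inf)
    mean(x) / s
  }
  if (is.matrix(series)) apply(series, 1, one) else one(series)
}

#' Simulate per-subject laminar effect tables with known truth
#'
#' Draws per-subject orientation-specific amplitude estimates around the
#' ground-truth profile: each subject's cell estimate is the truth plus a
#' subject offset (between-subject variability, removed by within-subject
#' statistics) plus independent per-cell estimation noise. The default
#' `within_sd` makes each subject's task-averaged deep-layer omission
#' estimate a t ~ 3 measurement (SE = amplitude / 3), the single-subject
#' reliability regime the pipeline targets.
#'
#' @param n_subjects number of subjects (default 18).
#' @param truth 3 x 2 x 2 array of specific amplitudes (layer, stimulus,
#'   task); default [specific_amplitudes()] of [ground_truth_amplitudes()].
#' @param within_sd per-cell estimation noise SD (default `amp_deep_omit *
#'   sqrt(2) / 3` with `amp_deep_omit` the task-averaged deep omission
#'   amplitude).
#' @param between_sd SD of the per-subject offset (default 0.05).
#' @param seed integer seed.
#' @return long data.frame: `subject`, `layer`, `stimulus`, `task`,
#'   `amplitude`; attribute `truth`.
#' @export
simulate_effects_table <- function(n_subjects = 18,
                                   truth = specific_amplitudes(ground_truth_amplitudes()),
                                   within_sd = NULL, between_sd = 0.05,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(within_sd)) {
    amp_deep_omit <- mean(truth["deep", "omitted", ])
    within_sd <- abs(amp_deep_omit) * sqrt(2) / 3
    if (within_sd == 0) within_sd <- 0.05
  }
  cells <- expand.grid(layer = dimnames(truth)[[1]],
                       stimulus = dimnames(truth)[[2]],
                       task = dimnames(truth)[[3]],
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    offset <- rnorm(1, 0, between_sd)
    amp <- truth[cbind(cells$layer, cells$stimulus, cells$task)] + offset +
      rnorm(nrow(cells), 0, within_sd)
    cbind(data.frame(subject = s), cells, amplitude = amp)
  }))
  attr(out, "truth") <- truth
  out
}
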