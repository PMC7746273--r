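# Temporal design construction, GLM fitting, and the orientation-specific
# reduction.

test_that("an isolated stick regressor peaks near 5 s and decays by 25 s", {
  h <- canonical_hrf(seq(0, 32, by = 0.1))
  t_peak <- seq(0, 32, by = 0.1)[which.max(h)]
  expect_equal(t_peak, 5, tolerance = 0.2)
  expect_lt(abs(h[251] / max(h)), 0.10)      # value at 25 s below 10% of peak
  r <- layerglm:::hrf_regressor(0, n_vol = 40, TR = 1)
  expect_equal(which.max(r), 6, tolerance = 1)       # volumes at 0,1,...: peak ~5 s
  expect_lt(r[26] / max(r), 0.10)
})

test_that("design matrix has the four interest regressors and filtered motion", {
  d <- short_design_run()
  n_vol <- layerglm:::run_volumes(d, 3.583)
  motion <- matrix(rnorm(n_vol * 6, sd = 0.05), n_vol, 6)
  dsn <- build_design(list(d), list(motion), TR_s = 3.583, n_vols = n_vol)
  expect_equal(dsn$interest,
               c("present_45", "present_135", "omitted_45", "omitted_135"))
  expect_equal(ncol(dsn$X), 4 + 18)
  # filtering is idempotent
  again <- layerglm:::filter_by_run(dsn$X, dsn$n_vols, dsn$bases)
  expect_lt(max(abs(again - dsn$X)), 1e-10)
})

test_that("zero motion columns are dropped with a message; hp = Inf disables cosines", {
  d <- short_design_run()
  n_vol <- layerglm:::run_volumes(d, 3.583)
  expect_message(dsn <- build_design(list(d), list(matrix(0, n_vol, 6)),
                                     TR_s = 3.583, n_vols = n_vol),
                 "all-zero nuisance")
  expect_equal(ncol(dsn$X), 4)
  dsn_inf <- build_design(list(d), NULL, TR_s = 3.583, n_vols = n_vol,
                          hp_cutoff_s = Inf)
  expect_equal(ncol(dsn_inf$bases[[1]]), 0)
})

test_that("events beyond the run end are an error", {
  d <- short_design_run()
  expect_error(build_design(list(d), NULL, TR_s = 3.583, n_vols = 10),
               "outside the run")
})

test_that("noiseless self-consistent fits give R2 = 1 and exact betas", {
  d <- short_design_run()
  n_vol <- layerglm:::run_volumes(d, 3.583)
  dsn <- build_design(list(d), NULL, TR_s = 3.583, n_vols = n_vol)
  b_true <- c(2, -1, 0.5, 0.25)
  y <- drop(dsn$X %*% b_true) + 100     # constant removed by the filter
  fit <- fit_temporal_glm(y, dsn)
  expect_equal(unname(fit$betas), b_true, tolerance = 1e-9)
  expect_equal(fit$R2, 1, tolerance = 1e-9)
})

test_that("betas match the normal-equations oracle and scale linearly", {
  set.seed(12)
  d <- short_design_run()
  n_vol <- layerglm:::run_volumes(d, 3.583)
  motion <- matrix(rnorm(n_vol * 6, sd = 0.1), n_vol, 6)
  dsn <- build_design(list(d), list(motion), TR_s = 3.583, n_vols = n_vol)
  y <- rnorm(n_vol, 400, 3)
  fit <- fit_temporal_glm(y, dsn)
  yf <- layerglm:::filter_by_run(y, dsn$n_vols, dsn$bases)
  oracle <- solve(crossprod(dsn$X), crossprod(dsn$X, yf))
  expect_lt(max(abs(fit$betas - drop(oracle))), 1e-8)
  fit3 <- fit_temporal_glm(3 * y, dsn)
  expect_equal(unname(fit3$betas), unname(3 * fit$betas), tolerance = 1e-9)
})

test_that("pure-noise courses give calibrated interest-beta t statistics", {
  set.seed(77)
  d <- simulate_design(n_runs = 2, blocks_per_run = 1, trials_per_block = 24,
                       seed = 13)
  d1 <- d[d$run == 1, ]
  n_vol <- layerglm:::run_volumes(d1, 3.583)
  dsn <- build_design(list(d1), NULL, TR_s = 3.583, n_vols = n_vol)
  X <- dsn$X
  XtXinv <- solve(crossprod(X))
  hits <- 0; total <- 0
  for (i in 1:400) {
    y <- layerglm:::filter_by_run(rnorm(n_vol), dsn$n_vols, dsn$bases)
    b <- XtXinv %*% crossprod(X, y)
    res <- y - X %*% b
    df <- n_vol - ncol(X) - ncol(dsn$bases[[1]]) - 1
    s2 <- sum(res^2) / df
    tt <- b / sqrt(s2 * diag(XtXinv))
    hits <- hits + sum(abs(tt) > qt(0.975, df)); total <- total + length(tt)
  }
  expect_lt(abs(hits / total - 0.05), 0.015)
})

test_that("rank-deficient temporal designs raise an error naming the columns", {
  d <- short_design_run()
  n_vol <- layerglm:::run_volumes(d, 3.583)
  dsn <- build_design(list(d), NULL, TR_s = 3.583, n_vols = n_vol)
  dsn$X <- cbind(dsn$X, dup = dsn$X[, 1])
  expect_error(fit_temporal_glm(rnorm(n_vol), dsn), "collinear")
})

test_that("orientation-specific reduction: antisymmetry and null contrast", {
  set.seed(3)
  mk <- function() {
    m <- matrix(rnorm(12), 3, 4,
                dimnames = list(c("deep", "middle", "superficial"),
                                c("present_45", "present_135",
                                  "omitted_45", "omitted_135")))
    m
  }
  betas <- list(roi45 = list(orientation = mk(), contrast = mk()),
                roi135 = list(orientation = mk(), contrast = mk()))
  eff <- orientation_specific_response(betas)
  swap <- function(m) m[, c("present_135", "present_45",
                            "omitted_135", "omitted_45")] |>
    (\(x) {colnames(x) <- c("present_45", "present_135",
                            "omitted_45", "omitted_135"); x})()
  # swapping which orientation counts as preferred negates the output
  betas_neg <- list(roi45 = lapply(betas$roi45, swap),
                    roi135 = lapply(betas$roi135, swap))
  expect_equal(unclass(orientation_specific_response(betas_neg)),
               unclass(-eff), tolerance = 1e-12)
  # relabelling conditions and ROI identities together is a symmetry
  betas_sw <- list(roi45 = lapply(betas$roi135, swap),
                   roi135 = lapply(betas$roi45, swap))
  expect_equal(unclass(orientation_specific_response(betas_sw)),
               unclass(eff), tolerance = 1e-12)
  # identical preferred and non-preferred betas give zero
  same <- mk(); same[, c(2, 4)] <- same[, c(1, 3)]
  betas0 <- list(roi45 = list(orientation = same, contrast = same),
                 roi135 = list(orientation = same, contrast = same))
  expect_true(all(orientation_specific_response(betas0) == 0))
  # missing condition
  broken <- betas; broken$roi45$orientation <- broken$roi45$orientation[, 1:3]
  expect_error(orientation_specific_response(broken), "missing condition")
})
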