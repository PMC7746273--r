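# Repeated-measures ANOVA, paired t, within-subject SEM, tSNR.

test_that("rm-ANOVA matches the brute-force sums-of-squares oracle", {
  set.seed(101)
  for (rep in 1:3) {
    d <- expand.grid(subject = 1:6, A = c("a1", "a2"), B = c("b1", "b2", "b3"))
    d$y <- rnorm(nrow(d)) + 0.4 * as.numeric(d$A) + 0.2 * as.numeric(d$B)
    r <- rm_anova(d, "y", c("A", "B"))
    o <- rm_anova_oracle(d, "y", c("A", "B"))
    m <- match(o$effect, r$effect)
    expect_false(anyNA(m))
    expect_equal(r$F[m], o$F, tolerance = 1e-8)
    expect_equal(r$df_num[m], o$df_num)
    expect_equal(r$df_den[m], o$df_den)
    expect_equal(r$p[m], o$p, tolerance = 1e-8)
  }
})

test_that("three-way rm-ANOVA reproduces the oracle and the published df layout", {
  set.seed(5)
  d <- expand.grid(subject = 1:18, stimulus = c("present", "omitted"),
                   layer = c("deep", "middle", "superficial"),
                   task = c("orientation", "contrast"))
  d$amplitude <- rnorm(nrow(d), 0, 0.1)
  r <- rm_anova(d, "amplitude", c("stimulus", "layer", "task"))
  o <- rm_anova_oracle(d, "amplitude", c("stimulus", "layer", "task"))
  m <- match(o$effect, r$effect)
  expect_equal(r$F[m], o$F, tolerance = 1e-8)
  sl <- r[r$effect == "stimulus:layer", ]
  expect_equal(sl$df_num, 2)              # 18 subjects, 2 x 3 interaction
  expect_equal(sl$df_den, 34)
})

test_that("constant tables give F = 0 with defined df; missing cells error", {
  d <- expand.grid(subject = 1:5, A = c("a1", "a2"), B = c("b1", "b2"))
  d$y <- 3
  r <- rm_anova(d, "y", c("A", "B"))
  expect_true(all(r$F == 0))
  expect_true(all(r$p == 1))
  expect_true(all(is.finite(r$df_den)))
  expect_error(rm_anova(d[-1, ], "y", c("A", "B")), "complete")
})

test_that("for a 2-level factor F equals the paired t squared", {
  set.seed(9)
  d <- expand.grid(subject = 1:12, A = c("a1", "a2"))
  d$y <- rnorm(24)
  r <- rm_anova(d, "y", "A")
  x <- d$y[d$A == "a1"]; y <- d$y[d$A == "a2"]
  tt <- paired_t(x, y)
  expect_equal(r$F[1], tt$t^2, tolerance = 1e-8)
  expect_equal(r$p[1], tt$p, tolerance = 1e-10)
})

test_that("paired t handles the printed toy pairs and degenerate inputs", {
  # pairs (1,0), (2,1), (3,1): differences 1, 1, 2
  x <- c(1, 2, 3); y <- c(0, 1, 1)
  expect_equal(mean(x - y), 4 / 3, tolerance = 1e-12)
  expect_equal(sd(x - y), 0.5773503, tolerance = 1e-6)
  tt <- paired_t(x, y)
  expect_equal(tt$t, 4.0, tolerance = 1e-8)
  expect_equal(tt$df, 2)
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  const <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(is.infinite(const$t) && const$t > 0)
  expect_equal(const$flag, "zero-variance")
})

test_that("paired t power matches the closed-form noncentral-t prediction", {
  set.seed(2024)
  n <- 18; dd <- 0.8; reps <- 1500
  hits <- vapply(seq_len(reps), function(i) {
    diff <- rnorm(n, dd, 1)
    tt <- paired_t(diff, rep(0, n))
    tt$p < 0.05
  }, logical(1))
  power_analytic <- 1 - pt(qt(0.975, n - 1), n - 1, ncp = dd * sqrt(n)) +
    pt(-qt(0.975, n - 1), n - 1, ncp = dd * sqrt(n))
  se <- sqrt(power_analytic * (1 - power_analytic) / reps)
  expect_lt(abs(mean(hits) - power_analytic), 4 * se)
})

test_that("within-subject SEM removes subject offsets and matches the identity", {
  profile <- c(0.1, 0.4, 0.2, 0.6)
  M <- outer(rnorm(10, 0, 5), rep(1, 4)) + rep(profile, each = 10)
  expect_equal(unname(within_subject_sem(M)), rep(0, 4), tolerance = 1e-12)
  # without offsets: within-subject SEM = ordinary SEM * sqrt(C/(C-1))
  set.seed(1)
  M2 <- matrix(rnorm(40), 10, 4)
  M2 <- M2 - rowMeans(M2)      # no subject offsets by construction
  sem_w <- within_subject_sem(M2)
  sem_o <- apply(M2, 2, sd) / sqrt(10)
  expect_equal(unname(sem_w), unname(sem_o * sqrt(4 / 3)), tolerance = 1e-12)
  # permutation invariance over subjects
  expect_equal(within_subject_sem(M2[sample(10), ]), sem_w, tolerance = 1e-12)
  expect_error(within_subject_sem(M2[1, , drop = FALSE]), "single subject")
})

test_that("tSNR definition and invariances", {
  set.seed(6)
  x <- rnorm(20000, 100, 1)
  expect_equal(tsnr(x), 100, tolerance = 2)
  expect_equal(tsnr(5 * x), tsnr(x), tolerance = 1e-12)
  expect_equal(tsnr(rep(c(-1, 1), 50)), 0, tolerance = 1e-12)
  expect_true(is.infinite(tsnr(rep(2, 10))))
  M <- matrix(rnorm(200, 50, 2), 10, 20)
  expect_length(tsnr(M), 10)
})

test_that("simulated effects tables carry the generating truth", {
  tab <- simulate_effects_table(n_subjects = 18, seed = 3)
  expect_equal(nrow(tab), 18 * 12)
  truth <- attr(tab, "truth")
  cellmeans <- tapply(tab$amplitude,
                      tab[, c("layer", "stimulus", "task")], mean)
  dn <- dimnames(truth)
  expect_lt(max(abs(cellmeans[dn[[1]], dn[[2]], dn[[3]]] - truth)), 0.1)
  expect_identical(simulate_effects_table(seed = 3), tab)
})
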