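# Shared fixtures and independent oracles for the test suite.

# Exact point-to-triangle distance by candidate enumeration: the
# unconstrained quadratic minimiser (if inside the simplex), the three
# clamped edge minimisers, and the three vertices.  Independent of the
# implementation's region-classification algorithm.
point_tri_dist_oracle <- function(p, a, b, c) {
  e1 <- b - a; e2 <- c - a
  cand <- list(a, b, c)
  G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  if (abs(det(G)) > 1e-14) {
    uv <- solve(G, c(sum(e1 * (p - a)), sum(e2 * (p - a))))
    if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1)
      cand <- c(cand, list(a + uv[1] * e1 + uv[2] * e2))
  }
  for (edge in list(list(a, b), list(a, c), list(b, c))) {
    q <- edge[[1]]; r <- edge[[2]]
    t <- sum((p - q) * (r - q)) / sum((r - q)^2)
    t <- min(max(t, 0), 1)
    cand <- c(cand, list(q + t * (r - q)))
  }
  sqrt(min(vapply(cand, function(x) sum((p - x)^2), numeric(1))))
}

mesh_dist_oracle <- function(p, mesh) {
  min(vapply(seq_len(nrow(mesh$faces)), function(f) {
    v <- mesh$faces[f, ]
    point_tri_dist_oracle(p, mesh$vertices[v[1], ], mesh$vertices[v[2], ],
                          mesh$vertices[v[3], ])
  }, numeric(1)))
}

# Closed-form equal-volume boundary radii for annulus / shell geometry,
# g = cumulative volume fraction measured from the WM surface.
annulus_radius <- function(g, r_wm, r_pial) sqrt(g * r_pial^2 + (1 - g) * r_wm^2)
shell_radius <- function(g, r_wm, r_pial) (g * r_pial^3 + (1 - g) * r_wm^3)^(1 / 3)

# Brute-force fully-within-subject ANOVA from marginal means: the estimate
# of any (interaction) effect is built by inclusion-exclusion over marginal
# means, SS = replicates * sum(estimate^2), and each effect is tested
# against its own interaction with subject.  Independent of aov().
rm_anova_oracle <- function(data, dv, within, subject = "subject") {
  d <- data
  d[[subject]] <- factor(d[[subject]])
  for (w in within) d[[w]] <- factor(d[[w]])
  n_sub <- nlevels(d[[subject]])
  grand <- mean(d[[dv]])

  # inclusion-exclusion effect estimates over the margins of `cols`
  est <- local({
    memo <- list()
    function(cols) {
      key <- paste(sort(cols), collapse = "|")
      if (!is.null(memo[[key]])) return(memo[[key]])
      cm <- tapply(d[[dv]], d[sort(cols)], mean)
      out <- cm - grand
      if (length(cols) > 1) {
        scols <- sort(cols)
        subsets <- unlist(lapply(seq_len(length(scols) - 1), function(m)
          utils::combn(scols, m, simplify = FALSE)), recursive = FALSE)
        for (s in subsets) {
          dims <- match(s, scols)
          out <- sweep(out, dims, est(s), "-")
        }
      }
      memo[[key]] <<- out
      out
    }
  })
  ss <- function(cols) {
    e <- est(cols)
    sum(e^2) * nrow(d) / length(e)
  }
  effects <- unlist(lapply(seq_along(within), function(m)
    utils::combn(within, m, simplify = FALSE)), recursive = FALSE)
  do.call(rbind, lapply(effects, function(cols) {
    df1 <- prod(vapply(cols, function(cc) nlevels(d[[cc]]) - 1L, 1L))
    df2 <- (n_sub - 1) * df1
    ss1 <- ss(cols)
    ss2 <- ss(c(subject, cols))
    F <- (ss1 / df1) / (ss2 / df2)
    data.frame(effect = paste(cols, collapse = ":"), F = F, df_num = df1,
               df_den = df2, p = pf(F, df1, df2, lower.tail = FALSE),
               ss = ss1, ss_error = ss2, stringsAsFactors = FALSE)
  }))
}

# small annulus phantom reused across layering tests
small_annulus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- phantom_spec("cylinder-annulus", wm_radius_mm = 2, pial_radius_mm = 4)
      ph <- make_cortical_phantom(sp)
      wm <- compute_sdf(ph$surfaces$wm, ph$grid)
      pl <- compute_sdf(ph$surfaces$pial, ph$grid)
      ls <- equivolume_surfaces(wm, pl, ph$grid)
      cache <<- list(phantom = ph, wm_sdf = wm, pial_sdf = pl, level_set = ls)
    }
    cache
  }
})

# small, fast pipeline configuration (short runs, small ROIs)
quick_config <- function(...) {
  pipeline_config(trials_per_block = 8, n_per_orientation = 150,
                  grid_shape = c(16L, 16L, 14L), subdivision = 3L,
                  localizer_noise_sd = 0.5, run_noise_sd = 1,
                  motion_step_sd_mm = 0, ...)
}
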