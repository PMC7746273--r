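# Small tilted-slab phantom with layer volumes, shared by simulator and
# pipeline tests.
small_slab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- phantom_spec("flat-slab", grid_shape = c(16, 16, 14),
                         tilt_deg = 10)
      ph <- make_cortical_phantom(sp)
      tg <- ph$truth_geometry
      ls <- equivolume_surfaces(tg$wm_sdf, tg$pial_sdf, ph$grid)
      cache <<- list(phantom = ph,
                     layers = layer_volume_distribution(ls, subdivision = 3))
    }
    cache
  }
})

# one short run's design rows
short_design_run <- function(seed = 1, task_run = 1) {
  d <- simulate_design(n_runs = 2, blocks_per_run = 1, trials_per_block = 16,
                       seed = seed)
  d[d$run == task_run, ]
}
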