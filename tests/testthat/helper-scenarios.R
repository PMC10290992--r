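# One shared runner for the phantom-scale scenario reproductions. N = 32,
# T = 20 with 5 heartbeats mirrors the study layout at desk scale.

scenario_phantoms <- function(N = 32, T = 20) {
  list(train = make_phantom_cycle(N, T, seed = 1),
       test = make_phantom_cycle(N, T, seed = 2))
}

run_phantom_scenario <- function(kind, sampling = "radial",
                                 variant = "two_stage", noise_seed = 7,
                                 n_cycles = 5, N = 32, T = 20,
                                 noise_sigma = 0.02, ...) {
  ph <- scenario_phantoms(N, T)
  sc <- build_scenario(ph$train, ph$test, scenario_spec(kind, n_cycles = n_cycles, ...))
  truth <- rescale_means(sc$test, sc$train)
  M <- dim(truth$frames)[3]
  pats <- switch(sampling,
    radial = radial_patterns(N, 5, M),
    cartesian = cartesian_mask(N, 5, seed = 0))
  ks <- measure_series(truth, pats, noise_sigma = noise_sigma,
                       seed = noise_seed)
  V <- if (kind == "temporal_upsample") attr(sc$train, "temporal_factor") else 1L
  cfg <- filter_config(variant,
                       temporal_factor = if (variant == "two_stage") V else 1L)
  res <- run_reconstruction(sc$train, ks, truth$phase_labels, cfg,
                            truth = truth)
  list(mse = res$mse_trace, truth = truth, train = sc$train, result = res)
}
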