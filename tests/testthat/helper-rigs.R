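# Small rigs and shared fixtures for the test suite. Heavy scenario runs are
# computed once per session and memoised here.

test_morse <- function() {
  # generic Morse pair with its equilibrium inside the cutoff
  morse_params(U0 = 5, xi0 = 0.1, W0 = 1.2, ga0 = 0.3, cutoff = 1.2)
}

test_spring <- function(k = 9, r0 = 0.5) spring_params(k = k, r0 = r0)

# deterministic small tissue used by force/engine tests
mini_tissue <- local({
  cache <- NULL
  function(ep = energy_params()) {
    if (is.null(cache))
      cache <<- build_tissue(tissue_config(preset = "mini"), ep)
    cache
  }
})

# a tiny 3-cell rig built directly through the tissue builder; unrelaxed by
# default so spring rests and target areas coincide exactly with the
# constructed geometry (analytic reference configurations for force tests)
three_cell_rig <- function(ep = energy_params(), relax = FALSE) {
  cfg <- tissue_config(n_columnar = 3, n_squamous = 1,
                       n_boundary_per_side = 1,
                       membrane_node_spacing = 1.25, ecm_node_spacing = 1.25)
  build_tissue(cfg, ep, relax = relax)
}

# central finite-difference gradient of the total energy
fd_forces <- function(state, ep, h = 1e-6, nodes = seq_len(nrow(state$pos))) {
  out <- matrix(NA_real_, length(nodes), 2)
  for (k in seq_along(nodes)) {
    i <- nodes[k]
    for (d in 1:2) {
      sp <- state; sp$pos[i, d] <- sp$pos[i, d] + h
      sm <- state; sm$pos[i, d] <- sm$pos[i, d] - h
      out[k, d] <- -(total_energy(sp, ep) - total_energy(sm, ep)) / (2 * h)
    }
  }
  out
}

# memoised scenario results shared across acceptance blocks (one reduced-
# resolution run each; recomputing them per block would dominate the suite)
scenario_cache <- new.env(parent = emptyenv())

cached_scenario <- function(name, spec,
                            cfg = tissue_config(preset = "reduced"),
                            sim = sim_config()) {
  if (is.null(scenario_cache[[name]]))
    scenario_cache[[name]] <- run_scenario(spec, cfg, sim = sim)
  scenario_cache[[name]]
}
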