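# Shared fixtures built in code.

water_material <- function(mass_density = 1, atomic_density = 10.02) {
  material("water", c("H", "O"), c(2, 1),
           atomic_density = atomic_density, mass_density = mass_density)
}

water_phantom <- function(depth_mm = 90, ...) {
  phantom("water-slab", list(phantom_layer(water_material(...), depth_mm)))
}

# Small, fast transport settings for unit tests.
fast_config <- function(n_depth_bins = 200, ...) {
  transport_config(n_depth_bins = n_depth_bins, ...)
}

# Lazily computed, shared small water simulation (2000 ions, 354 MeV).
.sim_cache <- new.env(parent = emptyenv())

reference_water_sim <- function() {
  if (is.null(.sim_cache$water)) {
    .sim_cache$water <- run_simulation(
      beam_spec(354, n_ions = 2000, seed = 42), water_phantom(90),
      fast_config())
  }
  .sim_cache$water
}

# Lazily computed full two-phantom study at the study scale (1e4 ions,
# 12 energies); shared across the acceptance checks.
reference_study <- function() {
  if (is.null(.sim_cache$study)) {
    .sim_cache$study <- reproduce_study(n_ions = 1e4, seed = 20260927,
                                        n_boot = 50)
  }
  .sim_cache$study
}
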