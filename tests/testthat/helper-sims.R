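# Shared simulation fixtures, built once per test run.
.sim_cache <- new.env(parent = emptyenv())

# A small nutrient-coupled colony: cheap enough for repeated assertions.
small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    p <- colony_params(domain_width = 320, agar_depth = 160, air_height = 36,
                       grid_h = 8, dt_macro = 0.1, t_end = 7,
                       snapshot_every = 3.5, seed = 42)
    .sim_cache$small <- run_simulation(p)
    .sim_cache$small_params <- p
  }
  .sim_cache$small
}
small_sim_params <- function() {
  small_sim()
  .sim_cache$small_params
}

# Scaled colony-development run: 0.8 mm lateral window over a deep agar
# column (the reservoir is scaled so that radial expansion is monolayer-driven
# and replete through most of the run). Cached per initial glucose
# concentration.
scaled_params <- function(C_g_init) {
  colony_params(C_g_init = C_g_init, domain_width = 800, agar_depth = 1200,
                air_height = 80, grid_h = 10, dt_macro = 0.1, t_end = 15,
                snapshot_every = 1, n_subcycle = 2, seed = 101)
}

# First time at which colony-wide growth has arrested (growing fraction below
# 5%), or t_end; the radial-expansion phase of a scaled run ends here.
growth_arrest_time <- function(sim) {
  k <- kinetics(sim)
  t <- k$time[which(k$growing_fraction < 0.05)[1]]
  if (is.na(t)) max(k$time) else t
}
scaled_sim <- function(C_g_init = 20) {
  key <- paste0("scaled_", C_g_init)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- run_simulation(scaled_params(C_g_init))
  .sim_cache[[key]]
}
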