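# Shared construction helpers for the test suite.  Everything is generated
# in code; no stored fixtures.

# A hand-constructible simulation result (for fitness-module unit tests that
# need exact trajectories without running the simulator).
fake_result <- function(times_hours, totals, outcome = "censored",
                        death_time_hours = NA_real_, seed = 0L) {
  structure(
    list(times_hours = times_hours,
         totals = totals,
         damage_fraction = rep(0, length(times_hours)),
         infection_total = rep(0, length(times_hours)),
         outcome = outcome, death_time_hours = death_time_hours,
         seed = seed),
    class = "simulation_result")
}

# Minimal targets: one or more cytokines over an explicit grid.
simple_targets <- function(cytokines = "TNFa",
                           time_points_hours = c(3, 48, 72),
                           mins, maxs, mortality_rate = 0.5,
                           weights = NULL, k = 10,
                           held_out_hours = intersect(48, time_points_hours)) {
  nc <- length(cytokines); nt <- length(time_points_hours)
  arr <- array(NA_real_, dim = c(nc, nt, 2),
               dimnames = list(cytokines, NULL, c("min", "max")))
  arr[, , 1] <- matrix(mins, nc, nt, byrow = TRUE)
  arr[, , 2] <- matrix(maxs, nc, nt, byrow = TRUE)
  clinical_targets(cytokines, time_points_hours, arr,
                   mortality_rate = mortality_rate, weights = weights,
                   mortality_coefficient = k,
                   held_out_hours = held_out_hours)
}

# The worked two-rule, three-mediator system encoded as triples.
worked_example_matrix <- function() {
  build_matrix(
    data.frame(rule = c("r1", "r1", "r2", "r2"),
               entity = c("M1", "M2", "M1", "M3"),
               value = c(1, 1, -1, 1)),
    rule_labels = c("r1", "r2"),
    entity_labels = c("M1", "M2", "M3"))
}

# A tiny simulator configuration for deterministic dynamics checks:
# no diffusion/decay/toxicity unless overridden, no agents, sterile scenario.
bare_config <- function(...) {
  sim_config(grid_width = 5L, grid_height = 5L, step_minutes = 60,
             mediators = c("TNFa", "IL10"),
             diffusion = 0, decay = 0, toxicity = 0, phagocytosis = 0,
             agent_counts = c(macrophage = 0, neutrophil = 0, th0 = 0,
                              th1 = 0, th2 = 0),
             rules = data.frame(cell_type = "endothelial", output = "TNFa"),
             ...)
}

zero_genome <- function(config) rep(0, genome_length(config))
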