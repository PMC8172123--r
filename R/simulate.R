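#' Running the immune agent-based simulation
#'
#' The simulator advances in fixed-order substeps: (1) mediator diffusion and
#' decay, (2) agent movement (chemotaxis up the attractant gradient where a
#' gradient exists, otherwise a seeded random step), (3) rule firing -- each
#' agent fires the rules its cell type owns, adding
#' `max(0, sum_j M[r, j] * input_j) * production_scale` of the rule's output
#' mediator at its site, with inputs read from the start-of-step snapshot of
#' mediator fields and the damage/infection lattice signals; endothelial rules
#' fire at every damaged site, (4) infection spread/toxigenesis, phagocytosis
#' and cytokine toxicity, (5) tissue repair, (6) environmental re-exposure.
#' The in-silico patient dies when the total damage fraction exceeds 0.80,
#' heals when damage and infection both reach zero, and is censored at the
#' horizon otherwise.
#'
#' @name simulate
NULL

AGENT_TYPES <- c("macrophage", "neutrophil", "th0", "th1", "th2")
OUTCOME_LABELS <- c("running", "died", "healed", "censored")

cpp_cfg <- function(config) {
  list(grid_width = as.integer(config$grid_width),
       grid_height = as.integer(config$grid_height),
       step_minutes = config$step_minutes,
       n_mediators = length(config$mediators),
       diffusion = unname(config$diffusion),
       decay = unname(config$decay),
       toxicity = unname(config$toxicity),
       init_fields = unname(config$init_fields),
       production_scale = config$production_scale,
       phagocytosis = config$phagocytosis,
       infection_cap = config$infection_cap,
       field_cap = config$field_cap,
       agent_counts = as.integer(config$agent_counts[AGENT_TYPES]),
       attractant_index = as.integer(
         ifelse(is.na(config$attractant[AGENT_TYPES]), -1L,
                match(config$attractant[AGENT_TYPES], config$mediators) - 1L)))
}

#' Initialize a simulation
#'
#' Builds the lattice with a contiguous injured patch of
#' `ceiling(injury_size * n_sites)` fully damaged sites (infected as well for
#' microbial injuries), places agents uniformly at random from the seeded
#' stream, and zeroes all mediator fields (unless the configuration sets
#' baselines).
#'
#' @param params an [injury_params()]
#' @param genome numeric genome of length [genome_length()]`(config)`
#' @param config a [sim_config()]
#' @param seed integer seed for the simulation's private RNG
#' @return an `immune_sim` handle
#' @export
init_simulation <- function(params, genome, config = sim_config(),
                            seed = 1L) {
  stopifnot(inherits(params, "injury_params"))
  genome <- as.numeric(genome)
  if (length(genome) != genome_length(config))
    stop(sprintf("genome length %d, config requires %d",
                 length(genome), genome_length(config)))
  if (any(genome < GENE_MIN | genome > GENE_MAX))
    stop("genome gene outside [-2, 2]")
  nent <- length(entity_columns(config))
  rule_matrix <- matrix(genome, nrow = nrow(config$rules), ncol = nent,
                        byrow = TRUE)
  owner <- match(config$rules$cell_type, c(AGENT_TYPES, "endothelial")) - 1L
  outp <- match(config$rules$output, config$mediators) - 1L
  ptr <- sim_create(cpp_cfg(config), rule_matrix, owner, outp,
                    unclass(params), as.integer(seed))
  structure(list(ptr = ptr, config = config, params = params,
                 seed = as.integer(seed)),
            class = "immune_sim")
}

#' Advance a simulation by one or more steps
#'
#' Applies the fixed-order substep update `n` times.  Pure state advance:
#' the died/healed/censored termination rules are applied by
#' [run_simulation()], not here, so mediator dynamics can be examined on any
#' lattice.
#'
#' @param sim an `immune_sim`
#' @param n number of steps
#' @return `sim`, invisibly
#' @export
step_simulation <- function(sim, n = 1) {
  stopifnot(inherits(sim, "immune_sim"))
  sim_step_n(sim$ptr, as.integer(n))
  invisible(sim)
}

#' Inspect the current state of a simulation
#'
#' @param sim an `immune_sim`
#' @return list with `damage` and `infection` lattices, per-mediator `fields`,
#'   an `agents` data frame, `clock_hours`, `damage_fraction`,
#'   `infection_total`, `outcome` and `death_time_hours`
#' @export
sim_state <- function(sim) {
  stopifnot(inherits(sim, "immune_sim"))
  s <- sim_snapshot(sim$ptr)
  names(s$fields) <- sim$config$mediators
  list(damage = s$damage, infection = s$infection, fields = s$fields,
       agents = data.frame(type = AGENT_TYPES[s$agent_type + 1L],
                           x = s$agent_x, y = s$agent_y),
       clock_hours = s$clock_hours,
       damage_fraction = s$damage_fraction,
       infection_total = s$infection_total,
       outcome = OUTCOME_LABELS[s$outcome + 1L],
       death_time_hours = s$death_hours)
}

result_from_sim <- function(sim) {
  tr <- sim_trajectory(sim$ptr)
  med <- sim$config$mediators
  colnames(tr) <- c("time_hours", med, "damage_fraction", "infection_total")
  s <- sim_snapshot(sim$ptr)
  structure(
    list(times_hours = tr[, "time_hours"],
         totals = tr[, med, drop = FALSE],
         damage_fraction = tr[, "damage_fraction"],
         infection_total = tr[, "infection_total"],
         outcome = OUTCOME_LABELS[s$outcome + 1L],
         death_time_hours = s$death_hours,
         seed = sim$seed),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %s at %.1f h (%d recorded steps, %d mediators)\n",
              x$outcome, max(x$times_hours), length(x$times_hours),
              ncol(x$totals)))
  invisible(x)
}

#' Run one stochastic simulation to its outcome
#'
#' Steps until the patient dies (total damage fraction > 0.80), heals (zero
#' damage and infection) or reaches the horizon.  The per-step trajectory of
#' lattice-total mediator amounts is recorded throughout.
#'
#' @inheritParams init_simulation
#' @param horizon_hours censoring horizon; defaults to the configuration's
#'   `horizon_days * 24`
#' @return a `simulation_result`: `times_hours`, `totals` (steps x mediators),
#'   `damage_fraction`, `infection_total`, `outcome`, `death_time_hours`,
#'   `seed`
#' @export
run_simulation <- function(params, genome, config = sim_config(), seed = 1L,
                           horizon_hours = NULL) {
  if (is.null(horizon_hours)) horizon_hours <- config$horizon_days * 24
  sim <- init_simulation(params, genome, config, seed)
  sim_run(sim$ptr, horizon_hours)
  result_from_sim(sim)
}

#' Run stochastic replicates of one parameterization
#'
#' Replicates are independent simulations of the same `(params, genome)` pair
#' under distinct seeds; the replicate mortality `R_m` is the fraction that
#' died.
#'
#' @inheritParams run_simulation
#' @param seeds integer vector of distinct replicate seeds (see
#'   [derive_seeds()])
#' @return list of `simulation_result`s with attribute `mortality`
#' @export
run_replicates <- function(params, genome, config = sim_config(),
                           seeds = derive_seeds(1L, 50L),
                           horizon_hours = NULL) {
  if (anyDuplicated(seeds)) stop("replicate seeds must be distinct")
  results <- lapply(seeds, function(s)
    run_simulation(params, genome, config, s, horizon_hours))
  attr(results, "mortality") <- replicate_mortality(results)
  results
}

#' Replicate mortality rate
#'
#' @param results list of `simulation_result`s
#' @return fraction of replicates that died
#' @export
replicate_mortality <- function(results) {
  mean(vapply(results, function(r) r$outcome == "died", logical(1)))
}

#' Derive independent child seeds from a root seed
#'
#' Stateless counter scheme: child `i` of stream `stream` is a 64-bit hash of
#' `(root, stream, i)` reduced to a positive 32-bit integer, so replicate and
#' candidate evaluations are reproducible regardless of scheduling order.
#'
#' @param root integer root seed
#' @param n number of seeds
#' @param stream integer stream index (e.g. a candidate index)
#' @return integer vector of `n` seeds
#' @export
derive_seeds <- function(root, n, stream = 0L) {
  vapply(seq_len(n), function(i)
    hash_seed(as.integer(root), as.integer(stream), as.integer(i)),
    integer(1))
}
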