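#' Genetic-algorithm calibration engine
#'
#' A real-valued generational GA over flattened Model Rule Matrices.
#' Candidates are scored by simulating stochastic replicates and computing the
#' range-envelope fitness ([compute_fitness()]); lower is better.  Selection
#' is by tournaments of size 2, elitism re-inserts the fittest fraction of the
#' previous generation, crossover is uniform-arithmetic with an independent
#' mixing weight per gene, and mutation replaces a single uniformly chosen
#' gene with a fresh U(-2, 2) draw with probability
#' `r_m = mutation_base + mutation_increment * g_n` (so diversity is
#' re-injected as the population converges).  Non-viable candidates are
#' replaced by viable ones of the same generation; every bioplausible
#' candidate encountered anywhere along the run is retained in an append-only
#' ensemble archive.
#'
#' @name ga_engine
NULL

#' GA hyperparameters
#'
#' Defaults are the full-scale settings (population 1024, 250 generations,
#' 50 replicates per candidate); `desk = TRUE` switches to the desk-scale
#' settings used by the packaged examples and tests (population 64,
#' 30 generations, 10 replicates).
#'
#' @param population_size even number of candidates per generation.
#' @param max_generations stopping bound on completed generations.
#' @param tournament_size fixed at 2.
#' @param elite_fraction fraction (0, 1) of the population treated as elites.
#' @param mutation_base,mutation_increment mutation schedule constants:
#'   `r_m = mutation_base + mutation_increment * g_n`, capped at 1.
#' @param replicates_per_candidate stochastic replicates per evaluation.
#' @param root_seed master seed; all candidate/replicate seeds derive from it.
#' @param mortality_coefficient optional override of the targets' `k`.
#' @param fitness_ceiling optional `F_c`: candidates with fitness above it are
#'   also treated as non-viable (disabled by default).
#' @param nonviable_mode `"any"` or `"all"` (see [is_nonviable()]).
#' @param range_mode `"max"` or `"minmax"` (see [compute_fitness()]).
#' @param crossover_mode `"per_gene"` (independent mixing weight per gene,
#'   default) or `"single_beta"` (one weight per mating).
#' @param pairing `"without_replacement"` (default) or `"with_replacement"`.
#' @param desk logical; use desk-scale defaults.
#' @return a `ga_config`
#' @export
ga_config <- function(population_size = if (desk) 64L else 1024L,
                      max_generations = if (desk) 30L else 250L,
                      tournament_size = 2L,
                      elite_fraction = 0.10,
                      mutation_base = 0.01,
                      mutation_increment = 0.002,
                      replicates_per_candidate = if (desk) 10L else 50L,
                      root_seed = 1L,
                      mortality_coefficient = NULL,
                      fitness_ceiling = Inf,
                      nonviable_mode = c("any", "all"),
                      range_mode = c("max", "minmax"),
                      crossover_mode = c("per_gene", "single_beta"),
                      pairing = c("without_replacement", "with_replacement"),
                      desk = FALSE) {
  cfg <- list(population_size = as.integer(population_size),
              max_generations = as.integer(max_generations),
              tournament_size = as.integer(tournament_size),
              elite_fraction = elite_fraction,
              mutation_base = mutation_base,
              mutation_increment = mutation_increment,
              replicates_per_candidate = as.integer(replicates_per_candidate),
              root_seed = as.integer(root_seed),
              mortality_coefficient = mortality_coefficient,
              fitness_ceiling = fitness_ceiling,
              nonviable_mode = match.arg(nonviable_mode),
              range_mode = match.arg(range_mode),
              crossover_mode = match.arg(crossover_mode),
              pairing = match.arg(pairing))
  stopifnot(cfg$population_size >= 2, cfg$population_size %% 2 == 0,
            cfg$max_generations >= 1, cfg$tournament_size >= 2,
            cfg$elite_fraction > 0, cfg$elite_fraction < 1,
            cfg$mutation_base >= 0, cfg$mutation_increment >= 0,
            cfg$replicates_per_candidate >= 1)
  structure(cfg, class = "ga_config")
}

#' Initialize a random population
#'
#' Every gene of every candidate is drawn i.i.d. uniform on \[-2, 2\] from the
#' seeded stream.
#'
#' @param n_genes genome length
#' @param config a `ga_config`
#' @return list of unevaluated candidates (`list(genome = ...)`)
#' @export
initialize_population <- function(n_genes, config) {
  lapply(seq_len(config$population_size), function(i)
    list(genome = stats::runif(n_genes, GENE_MIN, GENE_MAX)))
}

candidate_fitnesses <- function(population) {
  f <- vapply(population, function(c) {
    if (is.null(c$fitness)) NA_real_ else c$fitness
  }, numeric(1))
  if (anyNA(f)) stop("population contains unevaluated candidates")
  f
}

#' Tournament selection
#'
#' Repeatedly draws random pairs (without replacement within a pair, with
#' replacement across tournaments); the lower-fitness member joins the
#' breeding pool.  Ties are broken by a seeded coin flip.  The pool has the
#' same size as the population.
#'
#' @param population list of evaluated candidates
#' @param n_select pool size (default: population size)
#' @return list of selected candidates
#' @export
tournament_select <- function(population, n_select = length(population)) {
  fit <- candidate_fitnesses(population)
  n <- length(population)
  lapply(seq_len(n_select), function(i) {
    pair <- sample.int(n, 2, replace = FALSE)
    fa <- fit[pair[1]]; fb <- fit[pair[2]]
    win <- if (fa < fb) pair[1]
           else if (fb < fa) pair[2]
           else pair[1 + (stats::runif(1) < 0.5)]
    population[[win]]
  })
}

#' Elitism: re-insert the previous generation's fittest candidates
#'
#' The `floor(elite_fraction * size)` worst members of the breeding pool are
#' replaced by the same number of fittest candidates from the previous
#' generation (evaluations carried along unchanged).
#'
#' @param pool breeding pool (evaluated candidates)
#' @param previous_population previous generation (evaluated)
#' @param elite_fraction fraction in (0, 1)
#' @return pool of unchanged size
#' @export
apply_elitism <- function(pool, previous_population, elite_fraction = 0.10) {
  n_elite <- floor(elite_fraction * length(pool))
  if (n_elite == 0) return(pool)
  pool_fit <- candidate_fitnesses(pool)
  prev_fit <- candidate_fitnesses(previous_population)
  worst <- order(pool_fit, decreasing = TRUE)[seq_len(n_elite)]
  best <- order(prev_fit)[seq_len(n_elite)]
  pool[worst] <- previous_population[best]
  pool
}

#' Uniform arithmetic crossover
#'
#' Per gene `i`, with mixing weight `beta_i ~ U(0, 1)`:
#' `c1_i = beta_i * p1_i + (1 - beta_i) * p2_i` and
#' `c2_i = beta_i * p2_i + (1 - beta_i) * p1_i`, so `c1 + c2 = p1 + p2`
#' exactly.  `mode = "single_beta"` draws one weight per mating instead.
#'
#' @param p1,p2 equal-length parent genomes
#' @param mode `"per_gene"` (default) or `"single_beta"`
#' @param beta optional fixed mixing weight(s) (mainly for tests)
#' @return list of two child genomes `c1`, `c2`
#' @export
crossover <- function(p1, p2, mode = c("per_gene", "single_beta"),
                      beta = NULL) {
  mode <- match.arg(mode)
  if (length(p1) != length(p2)) stop("parent genomes differ in length")
  if (is.null(beta)) {
    beta <- if (mode == "per_gene") stats::runif(length(p1)) else
      rep(stats::runif(1), length(p1))
  }
  list(c1 = beta * p1 + (1 - beta) * p2,
       c2 = beta * p2 + (1 - beta) * p1)
}

#' Mutation schedule
#'
#' With probability `r_m(g_n) = mutation_base + mutation_increment * g_n`
#' (capped at 1), exactly one uniformly chosen gene is replaced by a fresh
#' U(-2, 2) draw; otherwise the genome is returned unchanged.
#'
#' @param genome numeric genome
#' @param g_n completed generations
#' @param mutation_base,mutation_increment schedule constants
#' @return possibly-mutated genome
#' @export
mutate <- function(genome, g_n, mutation_base = 0.01,
                   mutation_increment = 0.002) {
  r_m <- mutation_rate(g_n, mutation_base, mutation_increment)
  if (stats::runif(1) <= r_m) {
    i <- sample.int(length(genome), 1)
    genome[i] <- stats::runif(1, GENE_MIN, GENE_MAX)
  }
  genome
}

#' @rdname mutate
#' @export
mutation_rate <- function(g_n, mutation_base = 0.01,
                          mutation_increment = 0.002) {
  min(1, mutation_base + mutation_increment * g_n)
}

#' Total population diversity
#'
#' Per gene, the range (max - min) of that gene's value across the
#' population; the total diversity is the sum of those ranges (bounded above
#' by 4 per gene, the full width of the legal range).
#'
#' @param population list of candidates (or a list of genomes)
#' @return list with `per_gene` range vector and scalar `total`
#' @export
population_diversity <- function(population) {
  if (length(population) == 0) stop("empty population")
  genomes <- lapply(population, function(c)
    if (is.list(c)) c$genome else c)
  g <- do.call(rbind, genomes)
  rng <- apply(g, 2, max) - apply(g, 2, min)
  list(per_gene = rng, total = sum(rng))
}

#' Evaluate one candidate genome
#'
#' Runs the replicate simulations, builds the range envelope, and attaches
#' fitness, viability and bioplausibility flags.
#'
#' @param genome numeric genome
#' @param targets a `clinical_targets`
#' @param params an `injury_params`
#' @param sim_config a `sim_config`
#' @param ga a `ga_config`
#' @param seeds replicate seeds (default: derived from the GA root seed,
#'   stream 0)
#' @param simulator a function `(params, genome, config, seed) ->
#'   simulation_result`; the default runs [run_simulation()]
#' @return an evaluated candidate list
#' @export
evaluate_candidate <- function(genome, targets, params, sim_config, ga,
                               seeds = NULL, simulator = run_simulation) {
  if (is.null(seeds))
    seeds <- derive_seeds(ga$root_seed, ga$replicates_per_candidate, 0L)
  targets <- override_k(targets, ga)
  results <- lapply(seeds, function(s) simulator(params, genome, sim_config, s))
  env <- build_envelope(results, targets)
  ntg <- normalize_targets(targets)
  fit <- compute_fitness(env, ntg, range_mode = ga$range_mode)
  viable <- !is_nonviable(results, first_sample_hours =
                            min(targets$time_points_hours),
                          mode = ga$nonviable_mode) &&
    fit <= ga$fitness_ceiling
  list(genome = genome, fitness = fit, viable = viable,
       bioplausible = viable && is_bioplausible(env, ntg),
       envelope = env, seeds = seeds)
}

override_k <- function(targets, ga) {
  if (!is.null(ga$mortality_coefficient))
    targets$mortality_coefficient <- ga$mortality_coefficient
  targets
}

#' Run the full evolutionary loop
#'
#' Implements the generational procedure: evaluate every candidate
#' (replicates, envelope, fitness), replace non-viable candidates with
#' uniformly chosen viable candidates of the same generation, retain every
#' bioplausible candidate in the append-only ensemble archive, then build the
#' next generation by tournament selection, elitism, pairing, uniform
#' arithmetic crossover and single-gene mutation.  Elites are additionally
#' copied verbatim (with their cached evaluation) into the next generation,
#' which guarantees a monotone non-increasing best-fitness trace.  The loop
#' stops when a fitness of 0 is reached or `max_generations` generations are
#' complete.  The whole run is a deterministic function of
#' `ga$root_seed`.
#'
#' @param targets a `clinical_targets`
#' @param params an `injury_params` describing the injury scenario
#' @param sim_config a `sim_config`
#' @param ga a `ga_config`
#' @param simulator simulation callback, see [evaluate_candidate()]
#' @param initial_population optional list of starting candidates
#'   (`list(genome = ...)`); defaults to [initialize_population()]
#' @param verbose print a per-generation log line
#' @return a `ga_state`: final `population`, `archive` (ensemble), traces
#'   (`best_fitness_trace`, `mean_fitness_trace`, `diversity_trace`,
#'   `archive_size_trace`), `generations` completed and the configs used
#' @export
evolve <- function(targets, params, sim_config, ga, simulator = run_simulation,
                   initial_population = NULL, verbose = FALSE) {
  validate_targets(targets)
  set.seed(ga$root_seed)
  n_genes <- genome_length(sim_config)
  n <- ga$population_size
  n_elite <- floor(ga$elite_fraction * n)

  eval_pop <- function(pop, g_n) {
    lapply(seq_along(pop), function(i) {
      seeds <- derive_seeds(ga$root_seed,
                            ga$replicates_per_candidate,
                            stream = g_n * n + i)
      if (!is.null(pop[[i]]$fitness)) return(pop[[i]]) # cached elite
      evaluate_candidate(pop[[i]]$genome, targets, params, sim_config, ga,
                         seeds = seeds, simulator = simulator)
    })
  }

  replace_nonviable <- function(pop, g_n) {
    viable_idx <- which(vapply(pop, `[[`, logical(1), "viable"))
    nonviable_idx <- setdiff(seq_along(pop), viable_idx)
    if (length(nonviable_idx) == 0) return(pop)
    if (length(viable_idx) == 0) {
      if (g_n > 0) return(pop) # keep; selection pressure will handle it
      for (tries in 1:20) {
        pop <- eval_pop(initialize_population(n_genes, ga), g_n = -tries)
        viable_idx <- which(vapply(pop, `[[`, logical(1), "viable"))
        if (length(viable_idx) > 0) break
      }
      if (length(viable_idx) == 0)
        stop("no viable candidate found in generation 0 after 20 re-draws; ",
             "the injury scenario kills every random parameterization ",
             "before the first clinical time point")
      nonviable_idx <- setdiff(seq_along(pop), viable_idx)
      if (length(nonviable_idx) == 0) return(pop)
    }
    for (i in nonviable_idx) {
      pop[[i]] <- pop[[viable_idx[sample.int(length(viable_idx), 1)]]]
    }
    pop
  }

  archive <- list()
  archive_keys <- character(0)
  retain <- function(pop, g_n) {
    for (cand in pop) {
      if (isTRUE(cand$bioplausible)) {
        key <- paste(signif(cand$genome, 15), collapse = ",")
        if (!(key %in% archive_keys)) {
          cand$generation_retained <- g_n
          archive[[length(archive) + 1]] <<- cand
          archive_keys <<- c(archive_keys, key)
        }
      }
    }
  }

  best_trace <- numeric(0)
  mean_trace <- numeric(0)
  div_trace <- numeric(0)
  arch_trace <- integer(0)

  if (is.null(initial_population))
    initial_population <- initialize_population(n_genes, ga)
  stopifnot(length(initial_population) == n)
  pop <- eval_pop(initial_population, g_n = 0L)
  pop <- replace_nonviable(pop, 0L)

  g_n <- 0L
  repeat {
    fit <- candidate_fitnesses(pop)
    retain(pop, g_n)
    best_trace <- c(best_trace, min(fit))
    mean_trace <- c(mean_trace, mean(fit))
    div_trace <- c(div_trace, population_diversity(pop)$total)
    arch_trace <- c(arch_trace, length(archive))
    if (verbose)
      message(sprintf(
        "gen %3d  best F %.4f  mean F %.4f  diversity %.1f  archive %d",
        g_n, min(fit), mean(fit), div_trace[length(div_trace)],
        length(archive)))

    if (min(fit) == 0 || g_n >= ga$max_generations) break

    pool <- tournament_select(pop)
    pool <- apply_elitism(pool, pop, ga$elite_fraction)
    elites <- pop[order(fit)[seq_len(n_elite)]]

    n_children <- n - n_elite
    order_idx <- if (ga$pairing == "without_replacement") {
      sample.int(n, n)
    } else {
      sample.int(n, n, replace = TRUE)
    }
    children <- vector("list", n_children)
    ci <- 1L
    pi <- 1L
    while (ci <= n_children) {
      p1 <- pool[[order_idx[pi]]]$genome
      p2 <- pool[[order_idx[pi %% n + 1L]]]$genome
      pi <- (pi + 2L - 1L) %% n + 1L
      kids <- crossover(p1, p2, mode = ga$crossover_mode)
      for (k in kids) {
        if (ci > n_children) break
        children[[ci]] <- list(genome = clamp_genome(
          mutate(k, g_n, ga$mutation_base, ga$mutation_increment)))
        ci <- ci + 1L
      }
    }
    g_n <- g_n + 1L
    pop <- c(elites, eval_pop(children, g_n))
    pop <- replace_nonviable(pop, g_n)
  }

  structure(
    list(population = pop, archive = archive, generations = g_n,
         best_fitness_trace = best_trace, mean_fitness_trace = mean_trace,
         diversity_trace = div_trace, archive_size_trace = arch_trace,
         ga_config = ga, targets = targets, params = params,
         sim_config = sim_config),
    class = "ga_state")
}

#' @export
print.ga_state <- function(x, ...) {
  cat(sprintf(paste0("ga_state: %d generations, population %d, best F %.4f, ",
                     "ensemble archive %d\n"),
              x$generations, length(x$population),
              min(x$best_fitness_trace), length(x$archive)))
  invisible(x)
}
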