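#' Run outputs, the ensemble archive on disk, and the run manifest
#'
#' A completed calibration run is written as plain-text artifacts: the
#' ensemble as JSON Lines (one genome with metadata per line, matching the
#' archive's append-only contract), the fitness and diversity traces as CSV,
#' the best genome as JSON, and a manifest recording seeds, configuration
#' snapshots and per-file checksums.
#'
#' @name cli_io
NULL

#' Write the outputs of a calibration run
#'
#' @param state a `ga_state` from [evolve()]
#' @param dir output directory (created if needed)
#' @return the run manifest (also written as `manifest.json`), invisibly
#' @export
write_run_outputs <- function(state, dir) {
  stopifnot(inherits(state, "ga_state"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) stop("cannot write to ", dir)

  ens_path <- file.path(dir, "ensemble.jsonl")
  con <- file(ens_path, "w")
  for (cand in state$archive) {
    writeLines(jsonlite::toJSON(
      list(genome = cand$genome, fitness = cand$fitness,
           mortality = cand$envelope$mortality,
           generation_retained = cand$generation_retained,
           seeds = cand$seeds),
      auto_unbox = TRUE, digits = I(17)), con)
  }
  close(con)

  gens <- seq_along(state$best_fitness_trace) - 1L
  utils::write.csv(
    data.frame(generation = gens, best_fitness = state$best_fitness_trace,
               mean_fitness = state$mean_fitness_trace,
               archive_size = state$archive_size_trace),
    file.path(dir, "fitness_trace.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(generation = gens, total_diversity = state$diversity_trace),
    file.path(dir, "diversity.csv"), row.names = FALSE)

  fit <- candidate_fitnesses(state$population)
  write_genome_json(state$population[[which.min(fit)]]$genome,
                    file.path(dir, "best_genome.json"))

  targets_path <- file.path(dir, "targets.json")
  write_targets_json(state$targets, targets_path)
  save_sim_config(state$sim_config, file.path(dir, "sim_config.yaml"))

  files <- c("ensemble.jsonl", "fitness_trace.csv", "diversity.csv",
             "best_genome.json", "targets.json", "sim_config.yaml")
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("mrmcal")),
    root_seed = state$ga_config$root_seed,
    generations = state$generations,
    population_size = state$ga_config$population_size,
    replicates_per_candidate = state$ga_config$replicates_per_candidate,
    archive_size = length(state$archive),
    files = lapply(stats::setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(file.path(dir, f))))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read an ensemble archive back from disk
#'
#' @param path an `ensemble.jsonl` written by [write_run_outputs()]
#' @return list of archive members (genome, fitness, mortality,
#'   generation_retained, seeds), genomes at full floating precision
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    j <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    j$genome <- as.numeric(j$genome)
    j
  })
}

#' Per-gene range summary of an ensemble archive
#'
#' For each matrix element, the minimum, maximum and range of its value
#' across the archived genomes -- the ensemble's per-element diversity, in
#' the same spirit as the population diversity trace.
#'
#' @param archive a list of archive members (from a `ga_state` or
#'   [read_ensemble()])
#' @param config optional `sim_config` used to label rows with their
#'   rule/entity cell
#' @return data frame with columns `gene`, (optionally `rule`, `entity`,)
#'   `min`, `max`, `range`
#' @export
inspect_ensemble <- function(archive, config = NULL) {
  if (length(archive) == 0) stop("empty archive")
  g <- do.call(rbind, lapply(archive, function(a)
    if (is.list(a)) a$genome else a))
  out <- data.frame(gene = seq_len(ncol(g)),
                    min = apply(g, 2, min), max = apply(g, 2, max))
  out$range <- out$max - out$min
  if (!is.null(config)) {
    ent <- entity_columns(config)
    out$rule <- rep(rule_labels(config), each = length(ent))
    out$entity <- rep(ent, times = nrow(config$rules))
    out <- out[, c("gene", "rule", "entity", "min", "max", "range")]
  }
  out
}

#' Write a simulation trajectory as CSV
#'
#' Columns `time_hours`, one per mediator (lattice totals), then
#' `damage_fraction` and `infection_total`; outcome metadata goes to a JSON
#' sidecar `<path>.meta.json`.
#'
#' @param result a `simulation_result`
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_trajectory_csv <- function(result, path) {
  df <- data.frame(time_hours = result$times_hours, result$totals,
                   damage_fraction = result$damage_fraction,
                   infection_total = result$infection_total,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(outcome = result$outcome,
         death_time_hours = result$death_time_hours,
         seed = result$seed),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
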