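#' Simulator configuration
#'
#' All structural constants of the reduced endothelial-blood interface model
#' live in one configuration object: lattice size, time step, the mediator
#' list, diffusion/decay constants, the production scale, the cytokine
#' toxicity channel, agent counts and chemotaxis attractants, and the rule
#' table mapping each Model Rule Matrix row to the cell type that owns it and
#' the mediator it produces.  Entity columns of the matrix are the mediators
#' followed by the two lattice signals `damage` and `infection`.
#'
#' @param ... named overrides of the default fields (unknown names are an
#'   error).
#' @return a validated `sim_config` object
#' @details
#' Default mediators are the five cytokines scored against clinical data
#' (TNFa, IL10, IFNg, IL4, GCSF) plus three generic intermediates.  The
#' default rule table lets each of the six producing cell types (endothelial
#' plus five mobile immune cell types) produce each mediator, so the default
#' simulator genome has `48 * 10 = 480` genes.  Rates are per step; the step
#' length is `step_minutes` simulated minutes.
#' @export
sim_config <- function(...) {
  cell_types <- c("macrophage", "neutrophil", "th0", "th1", "th2")
  mediators <- c("TNFa", "IL10", "IFNg", "IL4", "GCSF", "GEN1", "GEN2", "GEN3")
  cfg <- list(
    grid_width = 40L,
    grid_height = 40L,
    step_minutes = 10,
    mediators = mediators,
    diffusion = 0.4,
    decay = 0.12,
    production_scale = 1,
    toxicity = c(TNFa = 0.0),
    phagocytosis = 0.5,
    infection_cap = 10,
    field_cap = 1e6,
    agent_counts = c(macrophage = 30, neutrophil = 30, th0 = 10,
                     th1 = 10, th2 = 10),
    attractant = c(macrophage = "TNFa", neutrophil = "TNFa", th0 = "TNFa",
                   th1 = "TNFa", th2 = "TNFa"),
    init_fields = 0,
    horizon_days = 22,
    rules = expand.grid(
      cell_type = c("endothelial", cell_types),
      output = mediators, stringsAsFactors = FALSE,
      KEEP.OUT.ATTRS = FALSE)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown sim_config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg <- normalize_sim_config(cfg)
  validate_sim_config(cfg)
  cfg
}

normalize_sim_config <- function(cfg) {
  agent_types <- c("macrophage", "neutrophil", "th0", "th1", "th2")
  expand_named <- function(x, full_names, default) {
    if (is.null(names(x))) {
      if (length(x) == 1) x <- rep(x, length(full_names))
      if (length(x) != length(full_names))
        stop("unnamed vector must have length 1 or ", length(full_names))
      names(x) <- full_names
      return(x)
    }
    full <- stats::setNames(rep(default, length(full_names)), full_names)
    keep <- intersect(names(x), full_names)
    full[keep] <- x[keep]
    full
  }
  cfg$diffusion <- expand_named(cfg$diffusion, cfg$mediators, 0)
  cfg$decay <- expand_named(cfg$decay, cfg$mediators, 0)
  cfg$toxicity <- expand_named(cfg$toxicity, cfg$mediators, 0)
  cfg$init_fields <- expand_named(cfg$init_fields, cfg$mediators, 0)
  cfg$agent_counts <- expand_named(cfg$agent_counts, agent_types, 0)
  cfg$attractant <- expand_named(cfg$attractant, agent_types, NA_character_)
  cfg$rules <- as.data.frame(cfg$rules, stringsAsFactors = FALSE)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$grid_width >= 1, cfg$grid_height >= 1, cfg$step_minutes > 0,
            length(cfg$mediators) >= 1, !anyDuplicated(cfg$mediators),
            cfg$production_scale >= 0, cfg$horizon_days > 0,
            all(cfg$diffusion >= 0), all(cfg$diffusion <= 1),
            all(cfg$decay >= 0), all(cfg$decay <= 1),
            all(cfg$toxicity >= 0), all(cfg$agent_counts >= 0),
            cfg$field_cap > 0, cfg$infection_cap > 0)
  if (!all(c("cell_type", "output") %in% names(cfg$rules)))
    stop("rules table needs cell_type and output columns")
  bad <- setdiff(cfg$rules$cell_type,
                 c("endothelial", names(cfg$agent_counts)))
  if (length(bad)) stop("unknown rule cell_type: ", bad[1])
  bad <- setdiff(cfg$rules$output, cfg$mediators)
  if (length(bad)) stop("rule output not a mediator: ", bad[1])
  att <- cfg$attractant
  bad <- setdiff(att[!is.na(att)], cfg$mediators)
  if (length(bad)) stop("attractant not a mediator: ", bad[1])
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %dx%d torus, %g-min steps, %d mediators, ",
                     "%d rules (genome length %d)\n"),
              x$grid_width, x$grid_height, x$step_minutes,
              length(x$mediators), nrow(x$rules), genome_length(x)))
  invisible(x)
}

#' Entity columns of a simulator configuration
#'
#' Mediators followed by the `damage` and `infection` lattice signals.
#' @param config a `sim_config`
#' @return character vector of entity labels
#' @export
entity_columns <- function(config) c(config$mediators, "damage", "infection")

#' Genome length implied by a simulator configuration
#' @param config a `sim_config`
#' @return integer: `n_rules * n_entities`
#' @export
genome_length <- function(config) {
  nrow(config$rules) * length(entity_columns(config))
}

#' Rule labels of a simulator configuration
#' @param config a `sim_config`
#' @return character vector, one label per rule row
#' @export
rule_labels <- function(config) {
  paste0(config$rules$cell_type, "->", config$rules$output)
}

#' Interpret a genome as this configuration's Model Rule Matrix
#' @param genome numeric genome vector of length [genome_length()]
#' @param config a `sim_config`
#' @return a `model_rule_matrix` with the configuration's labels
#' @export
genome_to_mrm <- function(genome, config) {
  unflatten(genome, nrow(config$rules), length(entity_columns(config)),
            rule_labels = rule_labels(config),
            entity_labels = entity_columns(config))
}

#' Injury/host parameters
#'
#' The five scalar parameters that position a simulation in injury space.
#'
#' @param injury_size fraction of the lattice initially damaged, in \[0, 1\].
#' @param microbial_invasiveness per-step infection spread rate, >= 0.
#' @param microbial_toxigenesis per-step damage rate per unit infection, >= 0.
#' @param environmental_toxicity per-step probability of spontaneous
#'   re-exposure, in \[0, 1\].
#' @param host_resilience per-step recovery rate of damaged tissue, in (0, 1\]
#'   (0 allowed to disable repair entirely, e.g. for harm-monotonicity checks).
#' @return an `injury_params` list
#' @export
injury_params <- function(injury_size = 0.25, microbial_invasiveness = 0,
                          microbial_toxigenesis = 0,
                          environmental_toxicity = 0,
                          host_resilience = 0.05) {
  p <- list(injury_size = injury_size,
            microbial_invasiveness = microbial_invasiveness,
            microbial_toxigenesis = microbial_toxigenesis,
            environmental_toxicity = environmental_toxicity,
            host_resilience = host_resilience)
  stopifnot(p$injury_size >= 0, p$injury_size <= 1,
            p$microbial_invasiveness >= 0, p$microbial_toxigenesis >= 0,
            p$environmental_toxicity >= 0, p$environmental_toxicity <= 1,
            p$host_resilience >= 0, p$host_resilience <= 1)
  structure(p, class = "injury_params")
}

#' Is an injury parameterization a sterile burn?
#'
#' A burn is a caustic, sterile injury: both microbial parameters are zero.
#' @param params an `injury_params`
#' @return logical
#' @export
is_sterile <- function(params) {
  params$microbial_invasiveness == 0 && params$microbial_toxigenesis == 0
}

#' Save / load simulator configurations
#'
#' YAML (or JSON, by extension) round-trip of a `sim_config`.  Unknown keys
#' are rejected on load.
#' @param config a `sim_config`
#' @param path file path ending in `.yaml`/`.yml` or `.json`
#' @name sim-config-io
NULL

#' @rdname sim-config-io
#' @export
save_sim_config <- function(config, path) {
  obj <- unclass(config)
  obj$diffusion <- as.list(obj$diffusion)
  obj$decay <- as.list(obj$decay)
  obj$toxicity <- as.list(obj$toxicity)
  obj$init_fields <- as.list(obj$init_fields)
  obj$agent_counts <- as.list(obj$agent_counts)
  obj$attractant <- as.list(obj$attractant)
  obj$rules <- list(cell_type = obj$rules$cell_type, output = obj$rules$output)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname sim-config-io
#' @export
load_sim_config <- function(path) {
  obj <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (k in c("diffusion", "decay", "toxicity", "init_fields",
              "agent_counts", "attractant")) {
    if (!is.null(obj[[k]])) obj[[k]] <- unlist(obj[[k]])
  }
  if (!is.null(obj$rules))
    obj$rules <- data.frame(cell_type = unlist(obj$rules$cell_type),
                            output = unlist(obj$rules$output),
                            stringsAsFactors = FALSE)
  do.call(sim_config, obj)
}
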