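#' Clinical target ranges and the range-envelope fitness
#'
#' Calibration targets are not single curves but *ranges*: for each cytokine
#' and each post-injury sampling time the clinical cohort contributes a
#' `[min, max]` interval, plus a cohort mortality rate.  A candidate
#' parameterization is scored by simulating stochastic replicates, building
#' the replicate min/max envelope at the clinical sampling times, and summing
#' the weighted absolute differences between the clinical and simulated range
#' maxima, plus a mortality mismatch term:
#' \deqn{F = \sum_{i,t} w_i \, | \max(C^e_{i,t}) - \max(C^m_{i,t}) | + k \, | R_e - R_m |}
#' Two sampling times (48 h and 8 d by default) are held out of the fitness
#' to guard against overfitting.  A candidate is *non-viable* if a replicate
#' dies before the first clinical sampling time (3 h); it is *bioplausible*
#' if its whole envelope lies inside the clinical ranges, in which case the
#' data cannot invalidate it and it is retained in the ensemble.
#'
#' @name fitness
NULL

#' Construct a clinical targets object
#'
#' @param cytokines ordered cytokine names.
#' @param time_points_hours post-injury sampling times in hours, strictly
#'   increasing.
#' @param ranges numeric array `c(n_cytokines, n_times, 2)` (min and max in
#'   the last dimension), with dimnames optional; or a data frame with
#'   columns `cytokine`, `time_hours`, `min`, `max`.
#' @param mortality_rate cohort mortality `R_e` in \[0, 1\].
#' @param weights per-cytokine fitness multipliers; defaults to 1 for every
#'   cytokine except IL10, which defaults to 2 (a doubled IL-10 contribution
#'   is sufficient to recover its late peak).
#' @param mortality_coefficient `k >= 0`, the weight of the mortality term
#'   (default 10).
#' @param held_out_hours sampling times excluded from the fitness (default
#'   48 h and 8 d = 192 h); must be a subset of `time_points_hours`.
#' @return a `clinical_targets` object
#' @export
clinical_targets <- function(cytokines, time_points_hours, ranges,
                             mortality_rate, weights = NULL,
                             mortality_coefficient = 10,
                             held_out_hours = c(48, 192)) {
  if (is.data.frame(ranges)) {
    arr <- array(NA_real_, dim = c(length(cytokines),
                                   length(time_points_hours), 2),
                 dimnames = list(cytokines, NULL, c("min", "max")))
    arr[cbind(match(ranges$cytokine, cytokines),
              match(ranges$time_hours, time_points_hours), 1L)] <- ranges$min
    arr[cbind(match(ranges$cytokine, cytokines),
              match(ranges$time_hours, time_points_hours), 2L)] <- ranges$max
    ranges <- arr
  }
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(cytokines)), cytokines)
    if ("IL10" %in% cytokines) weights[["IL10"]] <- 2
  }
  if (is.null(names(weights))) names(weights) <- cytokines
  obj <- structure(
    list(cytokines = cytokines,
         time_points_hours = as.numeric(time_points_hours),
         ranges = ranges,
         mortality_rate = mortality_rate,
         weights = weights[cytokines],
         mortality_coefficient = mortality_coefficient,
         held_out_hours = as.numeric(held_out_hours)),
    class = "clinical_targets")
  validate_targets(obj)
  obj
}

validate_targets <- function(targets) {
  stopifnot(inherits(targets, "clinical_targets"))
  with(targets, {
    stopifnot(length(cytokines) >= 1, !anyDuplicated(cytokines),
              all(diff(time_points_hours) > 0),
              identical(dim(ranges)[1:2],
                        c(length(cytokines), length(time_points_hours))),
              dim(ranges)[3] == 2,
              mortality_rate >= 0, mortality_rate <= 1,
              mortality_coefficient >= 0,
              all(held_out_hours %in% time_points_hours),
              !anyNA(ranges))
    if (any(ranges[, , 1] > ranges[, , 2]))
      stop("target range with min > max")
  })
  invisible(targets)
}

#' @export
print.clinical_targets <- function(x, ...) {
  cat(sprintf(paste0("clinical_targets: %d cytokines x %d time points ",
                     "(%.0f h to %.0f d), R_e = %.2f, k = %g, %d held out\n"),
              length(x$cytokines), length(x$time_points_hours),
              min(x$time_points_hours), max(x$time_points_hours) / 24,
              x$mortality_rate, x$mortality_coefficient,
              length(x$held_out_hours)))
  invisible(x)
}

#' Per-cytokine clinical normalization constants
#'
#' The clinical maximum of each cytokine over all sampling times; model and
#' clinical series are divided by it so that clinical ranges map into
#' \[0, ~1\] and the per-cytokine fitness weights are comparable.
#'
#' @param targets a `clinical_targets`
#' @return named numeric vector
#' @export
clinical_max <- function(targets) {
  stats::setNames(apply(targets$ranges[, , 2, drop = FALSE], 1, max),
                  targets$cytokines)
}

#' Express clinical targets on the normalized scale
#'
#' Divides every cytokine's range by that cytokine's clinical maximum, the
#' same denominator [normalize_trajectory()] applies to model output, so
#' normalized envelopes and normalized targets are directly comparable.
#'
#' @param targets a `clinical_targets`
#' @return a `clinical_targets` with ranges in \[0, ~1\]
#' @export
normalize_targets <- function(targets) {
  cmax <- clinical_max(targets)
  cmax[cmax == 0] <- 1
  targets$ranges <- sweep(targets$ranges, 1, cmax, "/")
  targets
}

#' Normalize a simulated trajectory against clinical targets
#'
#' Each target cytokine's model series is divided by that cytokine's clinical
#' maximum over all sampling times.  A zero clinical maximum leaves the series
#' unchanged, with a warning.
#'
#' @param result a `simulation_result`
#' @param targets a `clinical_targets`; every target cytokine must be a
#'   simulated mediator
#' @return matrix (recorded steps x target cytokines) of normalized totals
#' @export
normalize_trajectory <- function(result, targets) {
  missing <- setdiff(targets$cytokines, colnames(result$totals))
  if (length(missing))
    stop("cytokine not in trajectory: ", paste(missing, collapse = ", "))
  cmax <- clinical_max(targets)
  zero <- cmax == 0
  if (any(zero)) {
    warning("zero clinical maximum for ",
            paste(targets$cytokines[zero], collapse = ", "),
            "; series left unnormalized")
    cmax[zero] <- 1
  }
  sweep(result$totals[, targets$cytokines, drop = FALSE], 2, cmax, "/")
}

#' Sample a trajectory at the clinical time points
#'
#' Each sampling time maps to the nearest recorded step.  Replicates that end
#' (death or healing) before a sampling time contribute their last recorded
#' value, carried forward, so the envelope stays rectangular.
#'
#' @param result a `simulation_result`
#' @param targets a `clinical_targets`
#' @return matrix (target cytokines x time points) of normalized values
#' @export
sample_at_targets <- function(result, targets) {
  norm <- normalize_trajectory(result, targets)
  idx <- vapply(targets$time_points_hours, function(t) {
    which.min(abs(result$times_hours - t))
  }, integer(1))
  t(norm[idx, , drop = FALSE])
}

#' Build the replicate range envelope
#'
#' Per (cytokine, time point) minimum and maximum of the normalized totals
#' over stochastic replicates, plus the replicate mortality `R_m`.
#'
#' @param results non-empty list of `simulation_result`s
#' @param targets a `clinical_targets`
#' @return a `range_envelope`: array `env` of dim (cytokines, times, 2) and
#'   scalar `mortality`
#' @export
build_envelope <- function(results, targets) {
  if (length(results) == 0) stop("cannot build an envelope from no replicates")
  samples <- lapply(results, sample_at_targets, targets = targets)
  arr <- array(unlist(samples),
               dim = c(length(targets$cytokines),
                       length(targets$time_points_hours), length(results)))
  env <- array(NA_real_, dim = c(dim(arr)[1], dim(arr)[2], 2),
               dimnames = list(targets$cytokines, NULL, c("min", "max")))
  env[, , 1] <- apply(arr, c(1, 2), min)
  env[, , 2] <- apply(arr, c(1, 2), max)
  structure(list(env = env, mortality = replicate_mortality(results),
                 n_replicates = length(results)),
            class = "range_envelope")
}

evaluated_time_mask <- function(targets) {
  !(targets$time_points_hours %in% targets$held_out_hours)
}

#' Range-difference fitness of an envelope against clinical targets
#'
#' The printed range-maximum form: the weighted sum, over cytokines and
#' evaluated (non-held-out) time points, of the absolute difference between
#' the clinical and simulated range maxima, plus `k * |R_e - R_m|`.
#' `range_mode = "minmax"` adds the symmetric range-minimum terms as well.
#'
#' Envelope and targets must be on a common scale: envelopes built by
#' [build_envelope()] are normalized, so pass targets through
#' [normalize_targets()] first (as [evaluate_candidate()] does).
#'
#' @param envelope a `range_envelope`
#' @param targets a `clinical_targets`
#' @param range_mode `"max"` (default) or `"minmax"`
#' @return scalar fitness `F >= 0`; 0 means the envelope maxima (and minima,
#'   under `"minmax"`) match the clinical ranges perfectly and `R_m = R_e`
#' @export
compute_fitness <- function(envelope, targets, range_mode = c("max", "minmax")) {
  range_mode <- match.arg(range_mode)
  stopifnot(inherits(envelope, "range_envelope"))
  if (!identical(dim(envelope$env)[1:2], dim(targets$ranges)[1:2]))
    stop("envelope and targets have mismatched cytokine/time axes")
  keep <- evaluated_time_mask(targets)
  tr <- targets$ranges
  dmax <- abs(tr[, keep, 2, drop = FALSE] -
                envelope$env[, keep, 2, drop = FALSE])
  f <- sum(targets$weights * rowSums(dmax[, , 1, drop = FALSE]))
  if (range_mode == "minmax") {
    dmin <- abs(tr[, keep, 1, drop = FALSE] -
                  envelope$env[, keep, 1, drop = FALSE])
    f <- f + sum(targets$weights * rowSums(dmin[, , 1, drop = FALSE]))
  }
  f + targets$mortality_coefficient *
    abs(targets$mortality_rate - envelope$mortality)
}

#' Non-viability test
#'
#' A parameterization is rejected outright when a simulation dies before the
#' first clinical sampling time (3 h post-injury by default).  Under
#' `mode = "any"` (default, the strict reading) one early-dying replicate is
#' enough; `mode = "all"` requires every replicate to die early.
#'
#' @param results list of `simulation_result`s
#' @param first_sample_hours the first clinical sampling time (default 3)
#' @param mode `"any"` or `"all"`
#' @return logical: `TRUE` if the parameterization is non-viable
#' @export
is_nonviable <- function(results, first_sample_hours = 3,
                         mode = c("any", "all")) {
  mode <- match.arg(mode)
  early <- vapply(results, function(r) {
    r$outcome == "died" && r$death_time_hours < first_sample_hours
  }, logical(1))
  if (mode == "any") any(early) else all(early)
}

#' Bioplausibility test (ensemble retainment criterion)
#'
#' A parameterization whose replicate envelope always lies within the
#' clinically observed ranges cannot be invalidated by the data and is
#' therefore biologically plausible.  Boundaries are inclusive; held-out time
#' points are not examined.  Envelope and targets must be on a common scale
#' (see [compute_fitness()]).
#'
#' @param envelope a `range_envelope`
#' @param targets a `clinical_targets`
#' @return logical
#' @export
is_bioplausible <- function(envelope, targets) {
  stopifnot(inherits(envelope, "range_envelope"))
  if (!identical(dim(envelope$env)[1:2], dim(targets$ranges)[1:2]))
    stop("envelope and targets have mismatched cytokine/time axes")
  keep <- evaluated_time_mask(targets)
  tr <- targets$ranges
  all(envelope$env[, keep, 1] >= tr[, keep, 1] - 1e-12) &&
    all(envelope$env[, keep, 2] <= tr[, keep, 2] + 1e-12)
}

#' Widen clinical target ranges
#'
#' Over-encompasses the observed data: each `[min, max]` interval is widened
#' symmetrically by `(factor - 1)` times its own width, with the minimum
#' floored at 0 (cytokine levels cannot be negative).  A `factor` of 1 leaves
#' the targets unchanged.  Useful when the targets should generously cover
#' sampling variation, e.g. when testing envelope containment under fresh
#' replicate seeds.
#'
#' @param targets a `clinical_targets`
#' @param factor inflation factor >= 1
#' @return a widened `clinical_targets`
#' @export
inflate_targets <- function(targets, factor = 1.5) {
  stopifnot(factor >= 1)
  width <- targets$ranges[, , 2] - targets$ranges[, , 1]
  targets$ranges[, , 2] <- targets$ranges[, , 2] + (factor - 1) * width
  targets$ranges[, , 1] <- pmax(0, targets$ranges[, , 1] - (factor - 1) * width)
  validate_targets(targets)
  targets
}

#' Save / load clinical targets
#'
#' JSON form: `{cytokines, time_points_hours, ranges: {cytokine: [[min, max],
#' ...]}, mortality_rate, weights, mortality_coefficient, held_out_hours}`.
#' CSV form: long table `(cytokine, time_hours, min, max)` with the scalar
#' metadata in a JSON sidecar `<path>.meta.json`.
#'
#' @param targets a `clinical_targets`
#' @param path file path
#' @name targets-io
NULL

#' @rdname targets-io
#' @export
write_targets_json <- function(targets, path) {
  validate_targets(targets)
  rng <- lapply(stats::setNames(seq_along(targets$cytokines),
                                targets$cytokines),
                function(i) lapply(seq_along(targets$time_points_hours),
                                   function(t) unname(targets$ranges[i, t, ])))
  jsonlite::write_json(
    list(cytokines = targets$cytokines,
         time_points_hours = targets$time_points_hours,
         ranges = rng,
         mortality_rate = targets$mortality_rate,
         weights = as.list(targets$weights),
         mortality_coefficient = targets$mortality_coefficient,
         held_out_hours = targets$held_out_hours),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname targets-io
#' @export
read_targets_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  arr <- array(NA_real_, dim = c(length(j$cytokines),
                                 length(j$time_points_hours), 2),
               dimnames = list(j$cytokines, NULL, c("min", "max")))
  for (i in seq_along(j$cytokines)) {
    r <- j$ranges[[j$cytokines[i]]]
    if (is.list(r)) r <- do.call(rbind, lapply(r, as.numeric))
    arr[i, , ] <- as.matrix(r)
  }
  clinical_targets(j$cytokines, j$time_points_hours, arr,
                   mortality_rate = j$mortality_rate,
                   weights = unlist(j$weights),
                   mortality_coefficient = j$mortality_coefficient,
                   held_out_hours = j$held_out_hours)
}

#' @rdname targets-io
#' @export
write_targets_csv <- function(targets, path) {
  validate_targets(targets)
  df <- expand.grid(cytokine = targets$cytokines,
                    time_hours = targets$time_points_hours,
                    stringsAsFactors = FALSE)
  df$min <- targets$ranges[cbind(match(df$cytokine, targets$cytokines),
                                 match(df$time_hours,
                                       targets$time_points_hours), 1L)]
  df$max <- targets$ranges[cbind(match(df$cytokine, targets$cytokines),
                                 match(df$time_hours,
                                       targets$time_points_hours), 2L)]
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(mortality_rate = targets$mortality_rate,
         weights = as.list(targets$weights),
         mortality_coefficient = targets$mortality_coefficient,
         held_out_hours = targets$held_out_hours),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname targets-io
#' @export
read_targets_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  cytokines <- unique(df$cytokine)
  times <- sort(unique(df$time_hours))
  clinical_targets(cytokines, times, df,
                   mortality_rate = meta$mortality_rate,
                   weights = unlist(meta$weights),
                   mortality_coefficient = meta$mortality_coefficient,
                   held_out_hours = meta$held_out_hours)
}
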