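#' Model Rule Matrix construction and genome encoding
#'
#' The Model Rule Matrix (MRM) is the evolvable heart of the package: rows are
#' model rules, columns are the computationally relevant entities (mediators
#' and lattice signals) that can contribute to each rule, and every element is
#' a dimensionless coefficient in the closed interval \[-2, 2\].  A zero element
#' means "no connection": rule existence is encoded by nonzeroness, so the
#' genetic algorithm can both re-weight existing rules and discover new ones.
#' Flattened row-major, the matrix becomes the real-valued genome the genetic
#' algorithm operates on.
#'
#' @name mrm
NULL

GENE_MIN <- -2
GENE_MAX <- 2

#' Reference matrix shape
#'
#' The reference configuration uses 18 rules by 24 entities, i.e. a genome of
#' 432 free continuous parameters.  Both dimensions are configuration-driven;
#' the reduced simulator shipped with the package uses its own (smaller)
#' entity set.
#'
#' @return integer vector `c(n_rules, n_entities)`
#' @export
default_mrm_shape <- function() c(n_rules = 18L, n_entities = 24L)

new_mrm <- function(values, rule_labels, entity_labels) {
  structure(
    list(values = values, rule_labels = rule_labels,
         entity_labels = entity_labels),
    class = "model_rule_matrix")
}

#' Build a Model Rule Matrix from (rule, entity, value) triples
#'
#' Cells not named by any triple are 0 (no connection).
#'
#' @param coefficients data frame with columns `rule`, `entity`, `value`, or a
#'   list of length-3 lists/vectors `(rule, entity, value)`.
#' @param rule_labels,entity_labels ordered, duplicate-free label vectors
#'   defining the matrix axes.
#' @return a `model_rule_matrix`
#' @examples
#' # the two-rule system  M1' = M1 + M2 ;  M2' = -M1 + M3
#' m <- build_matrix(
#'   data.frame(rule = c("r1", "r1", "r2", "r2"),
#'              entity = c("M1", "M2", "M1", "M3"),
#'              value = c(1, 1, -1, 1)),
#'   rule_labels = c("r1", "r2"), entity_labels = c("M1", "M2", "M3"))
#' m$values
#' @export
build_matrix <- function(coefficients, rule_labels, entity_labels) {
  if (anyDuplicated(rule_labels)) stop("duplicate rule labels")
  if (anyDuplicated(entity_labels)) stop("duplicate entity labels")
  if (!is.data.frame(coefficients)) {
    coefficients <- do.call(rbind, lapply(coefficients, function(tr) {
      data.frame(rule = as.character(tr[[1]]), entity = as.character(tr[[2]]),
                 value = as.numeric(tr[[3]]))
    }))
  }
  vals <- matrix(0, nrow = length(rule_labels), ncol = length(entity_labels),
                 dimnames = list(rule_labels, entity_labels))
  if (!is.null(coefficients) && nrow(coefficients) > 0) {
    key <- paste(coefficients$rule, coefficients$entity, sep = "\r")
    if (anyDuplicated(key)) {
      d <- coefficients[duplicated(key), , drop = FALSE]
      stop(sprintf("duplicate coefficient triple for (%s, %s)",
                   d$rule[1], d$entity[1]))
    }
    bad_r <- setdiff(coefficients$rule, rule_labels)
    if (length(bad_r)) stop("unknown rule label: ", bad_r[1])
    bad_e <- setdiff(coefficients$entity, entity_labels)
    if (length(bad_e)) stop("unknown entity label: ", bad_e[1])
    oob <- coefficients$value < GENE_MIN | coefficients$value > GENE_MAX
    if (any(oob)) {
      b <- coefficients[which(oob)[1], ]
      stop(sprintf("coefficient out of [-2, 2] at cell (%s, %s): %g",
                   b$rule, b$entity, b$value))
    }
    vals[cbind(match(coefficients$rule, rule_labels),
               match(coefficients$entity, entity_labels))] <- coefficients$value
  }
  new_mrm(vals, rule_labels, entity_labels)
}

#' Validate a Model Rule Matrix
#'
#' Checks element bounds, label/dimension agreement and label uniqueness.
#'
#' @param m a `model_rule_matrix`
#' @return `m`, invisibly, or an error
#' @export
validate_mrm <- function(m) {
  stopifnot(inherits(m, "model_rule_matrix"))
  if (nrow(m$values) != length(m$rule_labels) ||
      ncol(m$values) != length(m$entity_labels))
    stop("label lists do not match matrix dimensions")
  if (anyDuplicated(m$rule_labels) || anyDuplicated(m$entity_labels))
    stop("duplicate labels")
  if (any(m$values < GENE_MIN | m$values > GENE_MAX))
    stop("matrix element outside [-2, 2]")
  invisible(m)
}

#' @export
print.model_rule_matrix <- function(x, ...) {
  cat(sprintf("Model Rule Matrix: %d rules x %d entities (%d nonzero)\n",
              nrow(x$values), ncol(x$values), sum(x$values != 0)))
  invisible(x)
}

#' Flatten a Model Rule Matrix into a genome
#'
#' Row-major order: all coefficients of rule 1, then rule 2, and so on.
#'
#' @param m a `model_rule_matrix`
#' @return numeric genome of length `n_rules * n_entities`
#' @export
flatten <- function(m) {
  validate_mrm(m)
  as.numeric(t(m$values))
}

#' Rebuild a Model Rule Matrix from a genome
#'
#' Exact inverse of [flatten()].
#'
#' @param genome numeric vector, length `n_rules * n_entities`
#' @param n_rules,n_entities target shape
#' @param rule_labels,entity_labels optional axis labels (defaults `r1..`, `e1..`)
#' @return a `model_rule_matrix`
#' @export
unflatten <- function(genome, n_rules, n_entities,
                      rule_labels = paste0("r", seq_len(n_rules)),
                      entity_labels = paste0("e", seq_len(n_entities))) {
  if (length(genome) != n_rules * n_entities)
    stop(sprintf("genome length %d does not match %d x %d",
                 length(genome), n_rules, n_entities))
  vals <- matrix(genome, nrow = n_rules, ncol = n_entities, byrow = TRUE,
                 dimnames = list(rule_labels, entity_labels))
  validate_mrm(new_mrm(vals, rule_labels, entity_labels))
  new_mrm(vals, rule_labels, entity_labels)
}

#' Clamp a genome to the legal gene range
#'
#' Every gene is forced into \[-2, 2\]; idempotent.
#'
#' @param genome numeric vector
#' @return clamped numeric vector
#' @export
clamp_genome <- function(genome) {
  pmin(GENE_MAX, pmax(GENE_MIN, genome))
}

#' Read/write Model Rule Matrix serializations
#'
#' CSV form: header row of entity labels, first column of rule labels, cells
#' holding the coefficients.  JSON form: `{rule_labels, entity_labels, values}`
#' with `values` row-major by rule.
#'
#' @param m a `model_rule_matrix`
#' @param path file path
#' @return `write_*` return `path` invisibly; `read_*` return the object.
#' @name mrm-io
NULL

#' @rdname mrm-io
#' @export
write_mrm_csv <- function(m, path) {
  validate_mrm(m)
  df <- data.frame(rule = m$rule_labels, m$values, check.names = FALSE)
  colnames(df) <- c("rule", m$entity_labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mrm-io
#' @export
read_mrm_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  m <- new_mrm(vals, df[[1]], colnames(df)[-1])
  validate_mrm(m)
  m
}

#' @rdname mrm-io
#' @export
write_mrm_json <- function(m, path) {
  validate_mrm(m)
  jsonlite::write_json(
    list(rule_labels = m$rule_labels, entity_labels = m$entity_labels,
         values = lapply(seq_along(m$rule_labels),
                         function(i) unname(m$values[i, ]))),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname mrm-io
#' @export
read_mrm_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- j$values
  if (is.list(vals)) vals <- do.call(rbind, lapply(vals, as.numeric))
  dimnames(vals) <- list(j$rule_labels, j$entity_labels)
  m <- new_mrm(vals, j$rule_labels, j$entity_labels)
  validate_mrm(m)
  m
}

#' @rdname mrm-io
#' @param genome numeric genome vector
#' @export
write_genome_json <- function(genome, path) {
  jsonlite::write_json(as.numeric(genome), path, digits = I(17))
  invisible(path)
}

#' @rdname mrm-io
#' @export
read_genome_json <- function(path) {
  as.numeric(jsonlite::read_json(path, simplifyVector = TRUE))
}
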