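# Discrete Bayesian networks: CPT containers, joint probability, forward
# sampling, random parameterization, and the discrete dataset container.

#' Create a discrete Bayesian network
#'
#' Couples a directed acyclic structure with one conditional probability
#' table (CPT) per node.  States of a node with arity r are coded
#' `0..r-1`.  The CPT of node `Xi` is a matrix with one row per parent
#' configuration and one column per state; rows are indexed by the
#' mixed-radix encoding of the parent states with the first-listed parent
#' (in node order) most significant.  A node with no parents has a
#' single-row CPT.
#'
#' @param structure a `bn_dag`.
#' @param arities named integer vector, one arity (>= 2) per node.
#' @param cpts named list of CPT matrices, one per node.
#' @return an object of class `discrete_bn`.
#' @seealso [random_cpts()] to parameterize a structure randomly,
#'   [forward_sample()] to draw data.
#' @export
discrete_bn <- function(structure, arities, cpts) {
  stopifnot(inherits(structure, "bn_dag"))
  nodes <- structure$nodes
  arities <- arities[nodes]
  if (any(is.na(arities))) stop("arities must be named for every node")
  if (any(arities < 2L)) stop("every arity must be >= 2")
  for (v in nodes) {
    cpt <- cpts[[v]]
    if (is.null(cpt)) stop("missing CPT for node ", v)
    cpt <- as.matrix(cpt)
    q <- prod(arities[parents(structure, v)])
    if (nrow(cpt) != q)
      stop("CPT for ", v, " must have ", q, " rows, has ", nrow(cpt))
    if (ncol(cpt) != arities[[v]])
      stop("CPT for ", v, " must have ", arities[[v]], " columns")
    if (any(cpt < 0)) stop("CPT for ", v, " has negative entries")
    if (any(abs(rowSums(cpt) - 1) > 1e-6))
      stop("CPT rows for ", v, " must sum to 1")
    cpts[[v]] <- cpt
  }
  structure(list(structure = structure, arities = arities,
                 cpts = cpts[nodes]),
            class = "discrete_bn")
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$structure$nodes), "nodes,",
      nrow(x$structure$arcs), "arcs, arities",
      paste(x$arities, collapse = "/"), "\n")
  invisible(x)
}

# Mixed-radix row index (1-based) of a parent configuration.
# `pstates` is a matrix of 0-based parent states, columns in parent order
# (first-listed parent most significant); `pars_arity` the parent arities.
config_index <- function(pstates, pars_arity) {
  if (length(pars_arity) == 0L) return(rep(1L, NROW(pstates)))
  pstates <- as.matrix(pstates)
  idx <- rep(0, nrow(pstates))
  for (k in seq_along(pars_arity))
    idx <- idx * pars_arity[k] + pstates[, k]
  as.integer(idx) + 1L
}

#' Joint probability of a full assignment
#'
#' Evaluates the factorization of the joint distribution of a Bayesian
#' network, the product over nodes of P(Xi | parents(Xi)).
#'
#' @param bn a `discrete_bn`.
#' @param assignment named integer vector covering every node, states coded
#'   from 0.
#' @return probability in `[0, 1]`.
#' @examples
#' g <- dag("X")
#' bn <- discrete_bn(g, c(X = 2L), list(X = matrix(c(0.3, 0.7), 1)))
#' joint_probability(bn, c(X = 1))  # 0.7
#' @export
joint_probability <- function(bn, assignment) {
  nodes <- bn$structure$nodes
  if (!all(nodes %in% names(assignment)))
    stop("assignment must cover every variable")
  a <- assignment[nodes]
  if (any(is.na(a)) || any(a < 0) || any(a >= bn$arities))
    stop("assignment state out of range")
  p <- 1
  for (v in nodes) {
    pars <- parents(bn$structure, v)
    row <- config_index(matrix(a[pars], nrow = 1L), bn$arities[pars])
    p <- p * bn$cpts[[v]][row, a[[v]] + 1L]
  }
  unname(p)
}

#' Create a discrete dataset
#'
#' @param records integer matrix or data frame, one row per sample, one
#'   column per variable, states coded from 0; column names are variable
#'   names.
#' @param arities named integer arities; defaults to `max(column) + 1`
#'   (at least 2).
#' @return object of class `discrete_dataset` with elements `records`
#'   (integer matrix), `nodes` and `arities`.
#' @export
discrete_dataset <- function(records, arities = NULL) {
  records <- as.matrix(records)
  storage.mode(records) <- "integer"
  if (is.null(colnames(records)))
    colnames(records) <- paste0("X", seq_len(ncol(records)))
  nodes <- colnames(records)
  if (is.null(arities)) {
    arities <- pmax(apply(records, 2L, max) + 1L, 2L)
    names(arities) <- nodes
  }
  arities <- as.integer(arities[nodes])
  names(arities) <- nodes
  if (nrow(records) < 1L) stop("dataset must contain at least one record")
  for (k in seq_along(nodes))
    if (any(records[, k] < 0L | records[, k] >= arities[k]))
      stop("value out of range for variable ", nodes[k])
  structure(list(records = records, nodes = nodes, arities = arities),
            class = "discrete_dataset")
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat("Discrete dataset:", nrow(x$records), "records x",
      length(x$nodes), "variables\n")
  invisible(x)
}

#' Forward-sample a dataset from a Bayesian network
#'
#' Draws each record by ancestral (topological-order) sampling: every node
#' is drawn from its CPT row selected by the already-sampled states of its
#' parents.  Deterministic for a fixed seed.
#'
#' @param bn a `discrete_bn`.
#' @param n_samples number of records (>= 1).
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @return a `discrete_dataset` with columns in the network's node order.
#' @export
forward_sample <- function(bn, n_samples, seed = NULL) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nodes <- bn$structure$nodes
  ord <- topological_order(bn$structure)
  rec <- matrix(0L, n_samples, length(nodes), dimnames = list(NULL, nodes))
  for (v in ord) {
    pars <- parents(bn$structure, v)
    cpt <- bn$cpts[[v]]
    rows <- config_index(rec[, pars, drop = FALSE], bn$arities[pars])
    u <- stats::runif(n_samples)
    # inverse-CDF draw against the cumulative rows
    cum <- t(apply(cpt, 1L, cumsum))
    rec[, v] <- rowSums(u > cum[rows, , drop = FALSE])
  }
  discrete_dataset(rec, bn$arities)
}

#' Random CPT parameterization of a structure
#'
#' Draws every CPT row independently from a symmetric Dirichlet
#' distribution.  Small concentration values give near-deterministic rows
#' (strong dependence), large values give near-uniform rows.
#'
#' @param g a `bn_dag`.
#' @param arities named integer arities (default: all binary).
#' @param concentration Dirichlet concentration parameter (> 0).  The
#'   default 0.3 yields strongly diagnostic rows, in the spirit of the
#'   near-deterministic tables of the clinical benchmark networks.
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @return a `discrete_bn`.
#' @export
random_cpts <- function(g, arities = NULL, concentration = 0.3, seed = NULL) {
  if (concentration <= 0) stop("concentration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(arities)) {
    arities <- rep(2L, length(g$nodes))
    names(arities) <- g$nodes
  }
  cpts <- lapply(g$nodes, function(v) {
    r <- arities[[v]]
    q <- prod(arities[parents(g, v)])
    gm <- matrix(stats::rgamma(q * r, shape = concentration), q, r)
    # guard against all-zero rows at tiny concentration
    gm[rowSums(gm) == 0, ] <- 1
    gm / rowSums(gm)
  })
  names(cpts) <- g$nodes
  discrete_bn(g, arities, cpts)
}
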