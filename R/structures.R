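# Core graph containers: directed acyclic structures, partially directed
# structures, and discrete Bayesian networks (structure + CPTs).

#' Create a directed acyclic structure
#'
#' A directed acyclic structure (DAG) is the graphical component of a
#' Bayesian network: an ordered set of node labels plus a set of directed
#' arcs.  Node order is significant: it fixes the enumeration order of node
#' pairs used throughout the package (see [enumerate_node_pairs()]).
#'
#' @param nodes character vector of unique node names.
#' @param arcs two-column character matrix (or data frame) of arcs,
#'   `from` and `to`.  May be `NULL` or zero-row for an empty graph.
#' @return an object of class `bn_dag` with elements `nodes` and `arcs`
#'   (two-column character matrix).
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' narcs(g)
#' @export
dag <- function(nodes, arcs = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node names must be unique")
  if (length(nodes) < 1L) stop("at least one node is required")
  arcs <- normalize_arcs(arcs, nodes)
  g <- structure(list(nodes = nodes, arcs = arcs), class = "bn_dag")
  if (!is_acyclic(amat(g))) stop("arc set contains a directed cycle")
  g
}

normalize_arcs <- function(arcs, nodes) {
  if (is.null(arcs) || NROW(arcs) == 0L) {
    arcs <- matrix(character(0), ncol = 2L)
  } else {
    arcs <- as.matrix(arcs)
    storage.mode(arcs) <- "character"
    if (ncol(arcs) != 2L) stop("arcs must have two columns (from, to)")
  }
  colnames(arcs) <- c("from", "to")
  rownames(arcs) <- NULL
  bad <- !(arcs %in% nodes)
  if (any(bad)) stop("unknown node in arcs: ", paste(unique(arcs[bad]), collapse = ", "))
  if (any(arcs[, 1L] == arcs[, 2L])) stop("self-arcs are not allowed")
  key <- paste(arcs[, 1L], arcs[, 2L])
  if (anyDuplicated(key)) stop("duplicate arcs are not allowed")
  rkey <- paste(arcs[, 2L], arcs[, 1L])
  if (any(rkey %in% key)) stop("both orientations of one pair are not allowed")
  arcs
}

#' Create a partially directed structure
#'
#' Intermediate output of constraint-based learning: a mixed graph holding
#' both directed arcs and undirected edges.  The directed and undirected
#' parts must be disjoint on unordered pairs.
#'
#' @param nodes character vector of unique node names.
#' @param arcs two-column character matrix of directed arcs (from, to).
#' @param edges two-column character matrix of undirected edges; row order
#'   and within-row order carry no meaning.
#' @return an object of class `bn_pdag`.
#' @export
pdag <- function(nodes, arcs = NULL, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node names must be unique")
  arcs <- normalize_arcs(arcs, nodes)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2L) stop("edges must have two columns")
    if (any(!(edges %in% nodes))) stop("unknown node in edges")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-edges are not allowed")
    # canonical order within each row, drop duplicates
    edges <- t(apply(edges, 1L, sort))
    edges <- edges[!duplicated(paste(edges[, 1L], edges[, 2L])), , drop = FALSE]
  }
  colnames(edges) <- c("x", "y")
  ukey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  if (NROW(arcs) > 0L && NROW(edges) > 0L &&
      any(ukey(arcs[, 1L], arcs[, 2L]) %in% ukey(edges[, 1L], edges[, 2L])))
    stop("a pair cannot carry both a directed arc and an undirected edge")
  structure(list(nodes = nodes, arcs = arcs, edges = edges), class = "bn_pdag")
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("Directed acyclic structure:", length(x$nodes), "nodes,",
      nrow(x$arcs), "arcs\n")
  if (nrow(x$arcs) > 0L)
    cat(paste0("  ", x$arcs[, 1L], " -> ", x$arcs[, 2L]), sep = "\n")
  invisible(x)
}

#' @export
print.bn_pdag <- function(x, ...) {
  cat("Partially directed structure:", length(x$nodes), "nodes,",
      nrow(x$arcs), "arcs,", nrow(x$edges), "undirected edges\n")
  invisible(x)
}

#' Number of arcs in a structure
#' @param g a `bn_dag` or `bn_pdag`.
#' @return integer arc count.
#' @export
narcs <- function(g) nrow(g$arcs)

#' Adjacency matrix of a directed structure
#'
#' @param g a `bn_dag`, or a `bn_pdag` (undirected edges appear in both
#'   orientations).
#' @return integer 0/1 matrix with node names on both dimensions;
#'   `amat[i, j] == 1` means an arc i -> j.
#' @export
amat <- function(g) {
  n <- length(g$nodes)
  a <- matrix(0L, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$arcs) > 0L)
    a[cbind(match(g$arcs[, 1L], g$nodes), match(g$arcs[, 2L], g$nodes))] <- 1L
  if (!is.null(g$edges) && NROW(g$edges) > 0L) {
    i <- match(g$edges[, 1L], g$nodes); j <- match(g$edges[, 2L], g$nodes)
    a[cbind(i, j)] <- 1L
    a[cbind(j, i)] <- 1L
  }
  a
}

#' Build a DAG from an adjacency matrix
#' @param a square 0/1 matrix; dimnames (if present) give node names.
#' @param nodes optional node names overriding dimnames.
#' @return a `bn_dag`.
#' @export
dag_from_amat <- function(a, nodes = NULL) {
  if (is.null(nodes)) nodes <- rownames(a)
  if (is.null(nodes)) nodes <- paste0("X", seq_len(nrow(a)))
  idx <- which(a != 0, arr.ind = TRUE)
  dag(nodes, cbind(nodes[idx[, 1L]], nodes[idx[, 2L]]))
}

# Kahn's algorithm on an adjacency matrix; used everywhere a cycle check is
# needed, including the BPSO inner loop, so kept allocation-light.
is_acyclic <- function(a) {
  n <- nrow(a)
  if (n == 0L) return(TRUE)
  indeg <- colSums(a)
  alive <- rep(TRUE, n)
  repeat {
    src <- which(alive & indeg == 0)
    if (length(src) == 0L) break
    alive[src] <- FALSE
    if (length(src) == 1L) indeg <- indeg - a[src, ]
    else indeg <- indeg - colSums(a[src, , drop = FALSE])
  }
  !any(alive)
}

#' Parents of a node
#' @param g a `bn_dag`.
#' @param node node name.
#' @return character vector of parents, in node order.
#' @export
parents <- function(g, node) {
  p <- g$arcs[g$arcs[, 2L] == node, 1L]
  g$nodes[sort(match(p, g$nodes))]
}

#' Topological order of a DAG
#' @param g a `bn_dag`.
#' @return character vector of node names in a topological order.
#' @export
topological_order <- function(g) {
  a <- amat(g)
  n <- nrow(a)
  indeg <- colSums(a)
  alive <- rep(TRUE, n)
  out <- character(0)
  while (any(alive)) {
    src <- which(alive & indeg == 0)
    if (length(src) == 0L) stop("graph contains a cycle")
    s <- src[1L]  # stable: lowest index first
    out <- c(out, g$nodes[s])
    alive[s] <- FALSE
    indeg <- indeg - a[s, ]
  }
  out
}

#' Enumerate unordered node pairs
#'
#' Returns the canonical ordering of the n(n-1)/2 unordered node pairs used
#' for pair indexing: row-major over the node ordering, i.e. for nodes
#' A, B, C, D the pairs are (A,B), (A,C), (A,D), (B,C), (B,D), (C,D).
#'
#' @param nodes character vector of node names, or a single integer n (pairs
#'   over `X1..Xn`... the names are then positional indices).
#' @return a two-column character (or integer, for numeric input) matrix
#'   with one row per pair.
#' @examples
#' enumerate_node_pairs(c("A", "B", "C", "D"))
#' @export
enumerate_node_pairs <- function(nodes) {
  if (is.numeric(nodes) && length(nodes) == 1L) {
    n <- as.integer(nodes)
    if (is.na(n) || n < 1L) stop("variable count must be >= 1")
    ids <- seq_len(n)
  } else {
    ids <- as.character(nodes)
    n <- length(ids)
    if (n < 1L) stop("variable count must be >= 1")
  }
  if (n == 1L) {
    m <- matrix(ids[0], ncol = 2L)
  } else {
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
    m <- cbind(ids[i], ids[j])
  }
  colnames(m) <- c("x", "y")
  m
}

#' Count directed acyclic graphs on n labelled nodes
#'
#' Evaluates the classical recurrence for the number of labelled DAGs:
#' f(1) = 1 and
#' f(n) = sum over i of (-1)^(i+1) choose(n, i) 2^(i (n-i)) f(n-i).
#' The count is super-exponential; values are exact for n up to about 15
#' within double precision.
#'
#' @param n number of nodes (>= 1).
#' @return the number of DAGs as a double.
#' @examples
#' count_dags(4)  # 543
#' @export
count_dags <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("variable count must be >= 1")
  f <- numeric(n)
  f[1L] <- 1
  if (n > 1L) for (m in 2:n) {
    i <- seq_len(m)
    prev <- c(f[(m - 1L):1L], 1)[seq_len(m)]  # f(m-i), with f(0) = 1
    f[m] <- sum((-1)^(i + 1) * choose(m, i) * 2^(i * (m - i)) * prev)
  }
  f[n]
}

#' Enumerate all DAGs over a node set
#'
#' Exhaustive enumeration used as a search/scoring oracle in tests and small
#' exact analyses; feasible up to 4-5 nodes (543 / 29281 structures).
#'
#' @param nodes character vector of node names.
#' @return list of `bn_dag` objects.
#' @export
all_dags <- function(nodes) {
  pairs <- enumerate_node_pairs(nodes)
  np <- nrow(pairs)
  # each unordered pair takes one of three states: ->, <-, absent
  states <- rep(list(0:2), np)
  grid <- as.matrix(expand.grid(states, KEEP.OUT.ATTRS = FALSE))
  out <- vector("list", nrow(grid))
  keep <- 0L
  for (r in seq_len(nrow(grid))) {
    st <- grid[r, ]
    from <- c(pairs[st == 0L, 1L], pairs[st == 1L, 2L])
    to   <- c(pairs[st == 0L, 2L], pairs[st == 1L, 1L])
    a <- matrix(0L, length(nodes), length(nodes))
    a[cbind(match(from, nodes), match(to, nodes))] <- 1L
    if (is_acyclic(a)) {
      keep <- keep + 1L
      out[[keep]] <- dag(nodes, if (length(from)) cbind(from, to) else NULL)
    }
  }
  out[seq_len(keep)]
}

#' Edge state of each node pair in a structure
#'
#' For the canonical pair ordering of [enumerate_node_pairs()], returns the
#' state of each pair in `g`: `1` for x -> y, `2` for y -> x (i.e. x <- y)
#' and `3` for no arc.
#'
#' @param g a `bn_dag`.
#' @return integer vector of length n(n-1)/2.
#' @export
pair_states <- function(g) {
  pairs <- enumerate_node_pairs(g$nodes)
  a <- amat(g)
  i <- match(pairs[, 1L], g$nodes); j <- match(pairs[, 2L], g$nodes)
  ifelse(a[cbind(i, j)] == 1L, 1L, ifelse(a[cbind(j, i)] == 1L, 2L, 3L))
}
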