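# Stage 1: constraint-based initial structure.
#
# Pipeline: pairwise MIC thresholding builds an undirected skeleton, which
# is pruned by G-squared conditional-independence tests; vague-adjacency
# and explicit-absence knowledge rules modify the undirected graph;
# v-structures are oriented; vague-exclusion and explicit-arc rules modify
# the partially directed graph.

#' Maximal information coefficient of two discrete vectors
#'
#' Normalized mutual information maximized over grid partitions of the two
#' axes, in the style of the maximal information coefficient: every pair
#' of contiguous groupings of the state codes with `nx * ny` cells not
#' exceeding `n^0.6` (and at least the native 2x2) is scored as
#' `I(binned x; binned y) / log(min(nx, ny))`, and the maximum is
#' returned.  For discrete inputs the native category grid is always
#' admissible.  The score is symmetric and lies in `[0, 1]`.
#'
#' @param x,y equal-length integer vectors of state codes.
#' @return score in `[0, 1]`; 0 if either vector is constant.
#' @export
mic_score <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least two observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(0)
  x <- match(x, sort(unique(x))) - 1L
  y <- match(y, sort(unique(y))) - 1L
  rx <- max(x) + 1L; ry <- max(y) + 1L
  bound <- max(n^0.6, 4)
  best <- 0
  for (cx in contiguous_binnings(rx)) {
    nx <- max(cx)
    for (cy in contiguous_binnings(ry)) {
      ny <- max(cy)
      native <- nx == rx && ny == ry
      if (nx * ny > bound && !native) next
      tab <- table(cx[x + 1L], cy[y + 1L])
      best <- max(best, mutual_information(tab) / log(min(nx, ny)))
    }
  }
  min(best, 1)
}

# all partitions of 0..(r-1) into >= 2 contiguous bins, returned as bin
# assignment vectors of length r (including the trivial one bin per level)
contiguous_binnings <- function(r) {
  if (r == 2L) return(list(c(1L, 2L)))
  out <- list()
  # each subset of the r-1 internal cut points with >= 1 cut
  for (mask in 1:(2^(r - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, 2^(0:(r - 2L))) > 0)
    out[[length(out) + 1L]] <- c(0L, cumsum(seq_len(r - 1L) %in% cuts)) + 1L
  }
  out
}

mutual_information <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

#' G-squared conditional independence test
#'
#' Likelihood-ratio test of X independent of Y given a (possibly empty)
#' conditioning set Z on the contingency tables of a discrete dataset.
#' Degrees of freedom are `(rx - 1) (ry - 1) * prod(arities of Z)`;
#' strata with no observations contribute 0 to the statistic.
#'
#' @param x,y variable names.
#' @param z character vector of conditioning variable names (may be empty).
#' @param data a `discrete_dataset`.
#' @param alpha significance level for the independence call.
#' @return list with `statistic`, `df`, `p_value`, `independent`.
#' @export
ci_test <- function(x, y, z = character(0), data, alpha = 0.05) {
  if (x %in% z || y %in% z) stop("conditioning set must exclude x and y")
  rec <- data$records
  rx <- data$arities[[x]]; ry <- data$arities[[y]]
  zi <- if (length(z)) config_index(rec[, z, drop = FALSE], data$arities[z])
        else rep(1L, nrow(rec))
  g2 <- 0
  for (s in unique(zi)) {
    sel <- zi == s
    tab <- table(factor(rec[sel, x], levels = 0:(rx - 1L)),
                 factor(rec[sel, y], levels = 0:(ry - 1L)))
    n <- sum(tab)
    if (n == 0L) next
    e <- outer(rowSums(tab), colSums(tab)) / n
    nz <- tab > 0
    g2 <- g2 + 2 * sum(tab[nz] * log(tab[nz] / e[nz]))
  }
  df <- (rx - 1L) * (ry - 1L) * prod(data$arities[z])
  p <- stats::pchisq(g2, df, lower.tail = FALSE)
  list(statistic = g2, df = df, p_value = p, independent = p > alpha)
}

#' Build the undirected skeleton
#'
#' Places an undirected edge on every node pair whose [mic_score()]
#' exceeds `tau`, then (optionally) prunes: an edge (X, Y) is removed if
#' some conditioning subset Z of the current neighbours of X or Y, with
#' `|Z| <= max_cond`, renders them conditionally independent by
#' [ci_test()].  The separating set found for each removed (or never
#' present) pair is recorded for v-structure orientation.
#'
#' @param data a `discrete_dataset`.
#' @param tau MIC threshold in `[0, 1]` (default 0.1).
#' @param alpha CI-test significance level (default 0.05).
#' @param max_cond maximum conditioning-set size (default 3).
#' @param prune run the CI pruning pass (default `TRUE`).
#' @return a `bn_pdag` with only undirected edges; attribute `"sepsets"`
#'   holds a named list of separating sets keyed by `"x|y"` (canonical
#'   pair order).
#' @export
build_skeleton <- function(data, tau = 0.1, alpha = 0.05, max_cond = 3L,
                           prune = TRUE) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  nodes <- data$nodes
  pairs <- enumerate_node_pairs(nodes)
  present <- vapply(seq_len(nrow(pairs)), function(j)
    mic_score(data$records[, pairs[j, 1L]],
              data$records[, pairs[j, 2L]]) > tau, logical(1))
  adj <- lapply(stats::setNames(nodes, nodes), function(v) character(0))
  for (j in which(present)) {
    adj[[pairs[j, 1L]]] <- c(adj[[pairs[j, 1L]]], pairs[j, 2L])
    adj[[pairs[j, 2L]]] <- c(adj[[pairs[j, 2L]]], pairs[j, 1L])
  }
  sepsets <- list()
  if (prune) {
    for (size in 0:max_cond) {
      for (j in which(present)) {
        x <- pairs[j, 1L]; y <- pairs[j, 2L]
        cand <- setdiff(union(adj[[x]], adj[[y]]), c(x, y))
        cand <- nodes[sort(match(cand, nodes))]
        if (length(cand) < size) next
        for (zc in combn_list(cand, size)) {
          if (ci_test(x, y, zc, data, alpha)$independent) {
            present[j] <- FALSE
            adj[[x]] <- setdiff(adj[[x]], y)
            adj[[y]] <- setdiff(adj[[y]], x)
            sepsets[[paste(x, y, sep = "|")]] <- zc
            break
          }
        }
      }
    }
  }
  sk <- pdag(nodes, edges = pairs[present, , drop = FALSE])
  attr(sk, "sepsets") <- sepsets
  sk
}

# deterministic list of size-k subsets (lexicographic over input order)
combn_list <- function(x, k) {
  if (k == 0L) return(list(character(0)))
  if (length(x) < k) return(list())
  apply(utils::combn(x, k), 2L, identity, simplify = FALSE)
}

#' Orient head-to-head (v-structure) patterns
#'
#' For every unshielded triple x - z - y (x, y non-adjacent), the triple
#' is oriented as the collider x -> z <- y when no separating set of
#' (x, y) contains z: the recorded separating set from skeleton pruning is
#' consulted first, otherwise a separating set is searched among
#' conditioning subsets of the neighbours of x and y (sizes ascending).
#' If (x, y) are dependent given every candidate set, the triple is left
#' unoriented.  An edge already oriented by an earlier triple is never
#' re-oriented; a conflicting later orientation is skipped.
#'
#' @param skeleton a `bn_pdag` with only undirected edges (as produced by
#'   [build_skeleton()]); its `"sepsets"` attribute is used when present.
#' @param data a `discrete_dataset`.
#' @param alpha CI-test significance level.
#' @param max_cond maximum conditioning-set size for the sepset search.
#' @return a `bn_pdag` with v-structures directed.
#' @export
orient_head_to_head <- function(skeleton, data, alpha = 0.05, max_cond = 3L) {
  if (nrow(skeleton$arcs) > 0L)
    stop("skeleton must contain only undirected edges")
  nodes <- skeleton$nodes
  edges <- skeleton$edges
  sepsets <- attr(skeleton, "sepsets")
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    c(edges[edges[, 1L] == v, 2L], edges[edges[, 2L] == v, 1L]))
  ukey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  ekeys <- ukey(edges[, 1L], edges[, 2L])
  # oriented_from[k] holds "from" when edge k has been oriented; a
  # direction that conflicts with an earlier triple, or would close a
  # directed cycle among the arcs oriented so far, is skipped
  oriented_from <- rep(NA_character_, nrow(edges))
  dmat <- matrix(0L, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  pairs <- enumerate_node_pairs(nodes)
  for (j in seq_len(nrow(pairs))) {
    x <- pairs[j, 1L]; y <- pairs[j, 2L]
    if (y %in% adj[[x]]) next  # shielded
    zs <- intersect(adj[[x]], adj[[y]])
    if (length(zs) == 0L) next
    sep <- find_sepset(x, y, adj, sepsets, data, alpha, max_cond)
    if (is.null(sep)) next  # dependent under every candidate set
    for (z in nodes[sort(match(zs, nodes))]) {
      if (z %in% sep) next
      for (end in c(x, y)) {
        k <- match(ukey(end, z), ekeys)
        if (!is.na(oriented_from[k])) next  # first orientation kept
        dmat[end, z] <- 1L
        if (is_acyclic(dmat)) oriented_from[k] <- end
        else dmat[end, z] <- 0L             # cycle-creating: skipped
      }
    }
  }
  dir <- !is.na(oriented_from)
  arcs <- NULL
  if (any(dir)) {
    from <- oriented_from[dir]
    other <- ifelse(edges[dir, 1L] == from, edges[dir, 2L], edges[dir, 1L])
    arcs <- cbind(from, other)
  }
  out <- pdag(nodes, arcs = arcs, edges = edges[!dir, , drop = FALSE])
  attr(out, "sepsets") <- sepsets
  out
}

find_sepset <- function(x, y, adj, sepsets, data, alpha, max_cond) {
  key <- paste(x, y, sep = "|")
  if (!is.null(sepsets[[key]])) return(sepsets[[key]])
  cand <- setdiff(union(adj[[x]], adj[[y]]), c(x, y))
  for (size in 0:min(max_cond, length(cand)))
    for (zc in combn_list(cand, size))
      if (ci_test(x, y, zc, data, alpha)$independent) return(zc)
  NULL
}

#' Apply knowledge rules to the undirected skeleton
#'
#' Vague adjacency statements add edges and explicit absence statements
#' delete edges, each firing with probability equal to its credibility:
#' for every fused vague-adjacency pair (X, Y), if a uniform draw falls in
#' the open interval (0, theta) the undirected edge is added; for every
#' fused explicit-absence pair, the edge is deleted under the same
#' mechanism.  Vague rules run before explicit rules; within each, pairs
#' are processed in [enumerate_node_pairs()] order.  Every statement
#' consumes exactly one random draw, fired or not.
#'
#' @param h a `bn_pdag` with only undirected edges.
#' @param fused a `fused_knowledge` object.
#' @param log logical: attach a diagnostics log (attribute `"rule_log"`)?
#' @return the modified `bn_pdag`.
#' @export
modify_undirected <- function(h, fused, log = FALSE) {
  if (nrow(h$arcs) > 0L) stop("h must contain only undirected edges")
  edges <- h$edges
  ukey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  logrows <- list()
  apply_set <- function(df, action) {
    if (NROW(df) == 0L) return()
    ord <- order(match(df[[1L]], h$nodes), match(df[[2L]], h$nodes))
    for (r in ord) {
      a <- df[[1L]][r]; b <- df[[2L]][r]; th <- df$theta[r]
      u <- stats::runif(1L)
      fired <- u > 0 && u < th
      if (fired) {
        k <- ukey(a, b)
        have <- ukey(edges[, 1L], edges[, 2L]) == k
        if (action == "add" && !any(have))
          edges <<- rbind(edges, cbind(a, b))
        if (action == "delete" && any(have))
          edges <<- edges[!have, , drop = FALSE]
      }
      logrows[[length(logrows) + 1L]] <<- data.frame(
        x = a, y = b, rule = if (action == "add") "vague-add" else
          "explicit-delete", theta = th, draw = u, fired = fired)
    }
  }
  apply_set(fused$ie, "add")      # Rule: vague adjacency adds
  apply_set(fused$ca, "delete")   # Rule: explicit absence deletes
  out <- pdag(h$nodes, edges = edges)
  attr(out, "sepsets") <- attr(h, "sepsets")
  if (log) attr(out, "rule_log") <- do.call(rbind, logrows)
  out
}

#' Apply knowledge rules to the partially directed structure
#'
#' Vague exclusion statements delete arcs and explicit arc statements add
#' arcs, each firing with probability equal to its credibility.  A fired
#' exclusion "X is not a parent of Y" removes the arc X -> Y when
#' present (undirected edges are left alone).  A fired explicit arc
#' statement inserts X -> Y, replacing an undirected (X, Y) edge or a
#' reversed arc; the insertion is skipped (and logged) when it would close
#' a directed cycle.  Vague rules run before explicit rules; pairs in
#' [enumerate_node_pairs()] order; one random draw per statement.
#'
#' @param h a `bn_pdag`.
#' @param fused a `fused_knowledge` object.
#' @param log logical: attach a diagnostics log (attribute `"rule_log"`)?
#' @return the modified `bn_pdag`.
#' @export
modify_partial <- function(h, fused, log = FALSE) {
  nodes <- h$nodes
  arcs <- h$arcs
  edges <- h$edges
  ukey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  logrows <- list()
  note <- function(a, b, rule, th, u, fired) {
    logrows[[length(logrows) + 1L]] <<- data.frame(
      x = a, y = b, rule = rule, theta = th, draw = u, fired = fired)
  }
  # vague exclusions: delete arc from -> to
  df <- fused$ia
  for (r in order(match(df$from, nodes), match(df$to, nodes))) {
    a <- df$from[r]; b <- df$to[r]; th <- df$theta[r]
    u <- stats::runif(1L)
    fired <- u > 0 && u < th
    if (fired) {
      hit <- arcs[, 1L] == a & arcs[, 2L] == b
      if (any(hit)) arcs <- arcs[!hit, , drop = FALSE]
    }
    note(a, b, "vague-delete", th, u, fired)
  }
  # explicit arcs: insert from -> to unless it closes a cycle
  df <- fused$ce
  for (r in order(match(df$from, nodes), match(df$to, nodes))) {
    a <- df$from[r]; b <- df$to[r]; th <- df$theta[r]
    u <- stats::runif(1L)
    fired <- u > 0 && u < th
    if (fired && !any(arcs[, 1L] == a & arcs[, 2L] == b)) {
      arcs2 <- arcs[!(arcs[, 1L] == b & arcs[, 2L] == a), , drop = FALSE]
      arcs2 <- rbind(arcs2, cbind(a, b))
      amat2 <- matrix(0L, length(nodes), length(nodes),
                      dimnames = list(nodes, nodes))
      amat2[cbind(match(arcs2[, 1L], nodes), match(arcs2[, 2L], nodes))] <- 1L
      if (is_acyclic(amat2)) {
        arcs <- arcs2
        edges <- edges[ukey(edges[, 1L], edges[, 2L]) != ukey(a, b), ,
                       drop = FALSE]
      } else {
        fired <- FALSE  # cycle-creating insertion skipped
      }
    }
    note(a, b, "explicit-add", th, u, fired)
  }
  out <- pdag(nodes, arcs = arcs, edges = edges)
  if (log) attr(out, "rule_log") <- do.call(rbind, logrows)
  out
}

#' Stage-1 pipeline: knowledge-modified initial structure
#'
#' Runs the full constraint-based first stage: MIC skeleton with CI
#' pruning, undirected-graph knowledge rules, v-structure orientation,
#' and partial-graph knowledge rules.
#'
#' @param data a `discrete_dataset`.
#' @param fused a `fused_knowledge` object, or `NULL` for the
#'   knowledge-free structure.
#' @param tau,alpha,max_cond,prune passed to [build_skeleton()] /
#'   [orient_head_to_head()].
#' @param seed integer seed for the rule draws; `NULL` uses the current
#'   RNG state.
#' @param log logical: attach the combined rule diagnostics (attribute
#'   `"rule_log"`: pair, rule, credibility, draw, action taken), writable
#'   with [write_rule_log()].
#' @return a `bn_pdag`, the initial structure for stage-2 search.
#' @export
initial_structure <- function(data, fused = NULL, tau = 0.1, alpha = 0.05,
                              max_cond = 3L, prune = TRUE, seed = NULL,
                              log = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  h <- build_skeleton(data, tau = tau, alpha = alpha, max_cond = max_cond,
                      prune = prune)
  logs <- list()
  if (!is.null(fused)) {
    h <- modify_undirected(h, fused, log = log)
    logs[[1L]] <- attr(h, "rule_log")
  }
  h <- orient_head_to_head(h, data, alpha = alpha, max_cond = max_cond)
  if (!is.null(fused)) {
    h <- modify_partial(h, fused, log = log)
    logs[[2L]] <- attr(h, "rule_log")
  }
  if (log) attr(h, "rule_log") <- do.call(rbind, logs)
  h
}

#' Write stage-1 rule diagnostics as TSV
#' @param h a `bn_pdag` carrying a `"rule_log"` attribute (see
#'   [initial_structure()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rule_log <- function(h, path) {
  lg <- attr(h, "rule_log")
  if (is.null(lg))
    lg <- data.frame(x = character(0), y = character(0),
                     rule = character(0), theta = numeric(0),
                     draw = numeric(0), fired = logical(0))
  utils::write.table(lg, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
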