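# Stage 2: binary particle swarm optimization over DAG space.
#
# A particle's position is an n x n binary adjacency matrix (diagonal
# fixed at 0); its velocity is a real matrix of the same shape.  Standard
# Kennedy-Eberhart binary PSO: velocities updated with inertia, cognitive
# and social terms, clamped to +/- v_max, passed through the sigmoid
# transfer function, and thresholded against uniform draws; positions are
# repaired to acyclicity after every update.

#' Swarm hyperparameters
#'
#' @param n_particles swarm size (default 30).
#' @param n_iterations iterations (default 200).
#' @param w inertia weight (default 0.8).
#' @param c1,c2 cognitive and social acceleration (default 2 each).
#' @param v_max velocity clamp (default 4).
#' @return list of class `swarm_params`.
#' @export
swarm_params <- function(n_particles = 30L, n_iterations = 200L, w = 0.8,
                         c1 = 2, c2 = 2, v_max = 4) {
  if (n_particles < 1L || n_iterations < 0L || w <= 0 || c1 <= 0 ||
      c2 <= 0 || v_max <= 0)
    stop("swarm parameters must be positive (n_iterations >= 0)")
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 w = w, c1 = c1, c2 = c2, v_max = v_max),
            class = "swarm_params")
}

#' Randomly complete a partially directed structure
#'
#' Keeps directed arcs and orients every undirected edge uniformly at
#' random; an orientation that would close a directed cycle is retried in
#' the opposite direction, and the edge is dropped if both directions
#' create cycles.  The output is always acyclic.
#'
#' @param h a `bn_pdag`.
#' @return a `bn_dag`.
#' @export
complete_orientation <- function(h) {
  nodes <- h$nodes
  a <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(h$arcs) > 0L)
    a[cbind(match(h$arcs[, 1L], nodes), match(h$arcs[, 2L], nodes))] <- 1L
  if (!is_acyclic(a)) stop("directed part of h is cyclic")
  edges <- h$edges
  if (nrow(edges) > 0L) for (r in sample.int(nrow(edges))) {
    i <- match(edges[r, 1L], nodes); j <- match(edges[r, 2L], nodes)
    if (stats::runif(1L) < 0.5) { t <- i; i <- j; j <- t }
    a[i, j] <- 1L
    if (!is_acyclic(a)) {
      a[i, j] <- 0L; a[j, i] <- 1L
      if (!is_acyclic(a)) a[j, i] <- 0L  # both directions cycle: drop
    }
  }
  dag_from_amat(a)
}

#' Repair an adjacency matrix to acyclicity
#'
#' While a directed cycle exists, one arc on a detected cycle is removed:
#' the arc with the largest ordered-pair index (row-major).  Idempotent on
#' acyclic input.
#'
#' @param position square 0/1 matrix.
#' @return acyclic 0/1 matrix.
#' @export
repair_acyclic <- function(position) {
  n <- nrow(position)
  while (!is_acyclic(position)) {
    cyc <- find_cycle(position)
    from <- cyc[-length(cyc)]; to <- cyc[-1L]
    idx <- (from - 1L) * n + to  # row-major ordered-pair index
    k <- which.max(idx)
    position[from[k], to[k]] <- 0L
  }
  position
}

# return one directed cycle as a vertex index sequence c(v1, ..., vk, v1)
find_cycle <- function(a) {
  n <- nrow(a)
  color <- integer(n)  # 0 white, 1 gray (on current path), 2 black
  result <- NULL
  dfs <- function(v, path) {
    color[v] <<- 1L
    for (w in which(a[v, ] == 1L)) {
      if (!is.null(result)) return()
      if (color[w] == 1L) {          # back edge closes a cycle
        i <- match(w, path)
        result <<- c(path[i:length(path)], w)
        return()
      }
      if (color[w] == 0L) dfs(w, c(path, w))
    }
    color[v] <<- 2L
  }
  for (s in seq_len(n)) {
    if (color[s] == 0L) dfs(s, s)
    if (!is.null(result)) return(result)
  }
  stop("no cycle found in a cyclic graph (internal error)")
}

#' Binary particle swarm search over DAGs
#'
#' Maximizes `score_fn` over directed acyclic structures on the nodes of
#' `seed_structure`.  Half the swarm is initialized from independent
#' random completions of the seed structure, half from random sparse
#' digraphs; all positions are repaired to acyclicity.  The global-best
#' score trace is monotone non-decreasing; ties keep the first-found
#' particle.
#'
#' @param score_fn function taking a `bn_dag` and returning a numeric
#'   score (higher is better).
#' @param seed_structure a `bn_pdag` (or `bn_dag`) used to seed the swarm.
#' @param params a [swarm_params()] list.
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return list with `best` (a `bn_dag`), `best_score`, and `trace`
#'   (best score per iteration, length `n_iterations + 1` including
#'   initialization).
#' @export
bpso_search <- function(score_fn, seed_structure, params = swarm_params(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- seed_structure$nodes
  n <- length(nodes)
  np <- params$n_particles
  offdiag <- diag(n) == 0
  if (inherits(seed_structure, "bn_dag"))
    seed_structure <- pdag(nodes, arcs = seed_structure$arcs)
  positions <- vector("list", np)
  for (p in seq_len(np)) {
    if (p <= ceiling(np / 2)) {
      positions[[p]] <- amat(complete_orientation(seed_structure))
    } else {
      a <- matrix(0L, n, n, dimnames = list(nodes, nodes))
      a[offdiag] <- as.integer(stats::runif(n * (n - 1L)) < 2 / n)
      positions[[p]] <- repair_acyclic(a)
    }
  }
  velocities <- lapply(seq_len(np), function(p)
    matrix(stats::runif(n * n, -params$v_max, params$v_max), n, n))
  scores <- vapply(positions, function(a) score_fn(dag_from_amat(a)),
                   numeric(1))
  pbest <- positions
  pbest_score <- scores
  gi <- which.max(scores)
  gbest <- positions[[gi]]
  gbest_score <- scores[gi]
  trace <- gbest_score
  if (params$n_iterations > 0L) for (it in seq_len(params$n_iterations)) {
    for (p in seq_len(np)) {
      r1 <- matrix(stats::runif(n * n), n, n)
      r2 <- matrix(stats::runif(n * n), n, n)
      v <- params$w * velocities[[p]] +
        params$c1 * r1 * (pbest[[p]] - positions[[p]]) +
        params$c2 * r2 * (gbest - positions[[p]])
      v <- pmin(pmax(v, -params$v_max), params$v_max)
      velocities[[p]] <- v
      s <- 1 / (1 + exp(-v))
      x <- matrix(0L, n, n, dimnames = list(nodes, nodes))
      x[offdiag] <- as.integer(stats::runif(sum(offdiag)) < s[offdiag])
      x <- repair_acyclic(x)
      positions[[p]] <- x
      sc <- score_fn(dag_from_amat(x))
      if (sc > pbest_score[p]) {
        pbest[[p]] <- x
        pbest_score[p] <- sc
      }
      if (sc > gbest_score) {
        gbest <- x
        gbest_score <- sc
      }
    }
    trace <- c(trace, gbest_score)
  }
  list(best = dag_from_amat(gbest), best_score = gbest_score, trace = trace)
}
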