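# Decomposable data scores (log-likelihood, BIC, BDeu marginal likelihood)
# and knowledge-penalized scores: the explicit-accuracy score (BDeu plus
# explicit-report log-likelihood) and EVBIC (BIC plus explicit and
# k-weighted vague report log-likelihoods).

# floor for log of a zero-probability knowledge term; keeps search scores
# finite when an accuracy parameter is exactly 0 or 1
LOG_FLOOR <- log(1e-12)

safe_log <- function(p) ifelse(p > 1e-12, log(pmax(p, 1e-300)), LOG_FLOOR)

# sufficient statistics m_ijk for one node: q x r count matrix, rows in
# mixed-radix parent-configuration order
local_counts <- function(data, v, pars) {
  r <- data$arities[[v]]
  q <- prod(data$arities[pars])
  cfg <- config_index(data$records[, pars, drop = FALSE], data$arities[pars])
  idx <- (cfg - 1L) * r + data$records[, v] + 1L
  matrix(tabulate(idx, nbins = q * r), nrow = q, ncol = r, byrow = TRUE)
}

local_ll <- function(counts) {
  m_ij <- rowSums(counts)
  nz <- counts > 0
  rs <- matrix(m_ij, nrow(counts), ncol(counts))
  sum(counts[nz] * log(counts[nz] / rs[nz]))
}

#' Log-likelihood of a structure given data
#'
#' The maximized multinomial log-likelihood,
#' sum over nodes, states and parent configurations of
#' `m_ijk * ln(m_ijk / m_ij)`; zero counts contribute 0.
#'
#' @param data a `discrete_dataset`.
#' @param g a `bn_dag` over the same variables.
#' @return log score (<= 0).
#' @export
log_likelihood <- function(data, g) {
  check_same_vars(data, g)
  sum(vapply(g$nodes, function(v)
    local_ll(local_counts(data, v, parents(g, v))), numeric(1)))
}

check_same_vars <- function(data, g) {
  if (!setequal(data$nodes, g$nodes))
    stop("dataset and structure must share the same variables")
}

#' BIC score of a structure
#'
#' [log_likelihood()] minus the complexity penalty
#' `0.5 * ln(N) * sum_i q_i (r_i - 1)`, where `q_i` is the number of
#' parent configurations of node i and `r_i` its arity.  Higher is better.
#'
#' @inheritParams log_likelihood
#' @return log score.
#' @export
bic_score <- function(data, g) {
  check_same_vars(data, g)
  n <- nrow(data$records)
  dims <- sum(vapply(g$nodes, function(v)
    prod(data$arities[parents(g, v)]) * (data$arities[[v]] - 1), numeric(1)))
  log_likelihood(data, g) - 0.5 * log(n) * dims
}

#' BDeu log marginal likelihood of a structure
#'
#' The Bayesian Dirichlet equivalent uniform score: the closed-form log
#' marginal likelihood under per-row Dirichlet priors with hyperparameters
#' `ess / (q_i r_i)`.
#'
#' @inheritParams log_likelihood
#' @param ess equivalent sample size (> 0, default 1).
#' @return log score.
#' @export
bdeu_score <- function(data, g, ess = 1) {
  if (ess <= 0) stop("ess must be > 0")
  check_same_vars(data, g)
  total <- 0
  for (v in g$nodes) {
    pars <- parents(g, v)
    counts <- local_counts(data, v, pars)
    q <- nrow(counts); r <- ncol(counts)
    a_ijk <- ess / (q * r)
    a_ij <- ess / q
    m_ij <- rowSums(counts)
    total <- total +
      sum(lgamma(a_ij) - lgamma(a_ij + m_ij)) +
      sum(lgamma(a_ijk + counts) - lgamma(a_ijk))
  }
  total
}

# edge state (1 ->, 2 <-, 3 none) of the ordered pair (x, y) in g
edge_state <- function(g, x, y) {
  a <- amat(g)
  ifelse(a[cbind(x, y)] == 1L, 1L, ifelse(a[cbind(y, x)] == 1L, 2L, 3L))
}

#' Explicit-knowledge penalty of a structure
#'
#' Sum over all explicit knowledge items of the log-likelihood of the
#' report given the edge state the structure assigns to the pair,
#' `sum ln P(V | e(g), gamma)`.  Zero-probability terms contribute a
#' finite floor of `ln(1e-12)`.
#'
#' @param g a `bn_dag`.
#' @param items a `knowledge_items` data frame (explicit kinds 1-3 only).
#' @param accuracies accuracy table keyed by `expert`.
#' @return log score (0 when `items` is empty).
#' @export
explicit_penalty <- function(g, items, accuracies) {
  if (NROW(items) == 0L) return(0)
  if (any(!is_explicit_kind(items$kind)))
    stop("explicit_penalty takes explicit kinds (1..3) only")
  knowledge_loglik(g, items, accuracies)
}

#' Vague-knowledge penalty of a structure
#'
#' Sum over all vague knowledge items of `ln P(V | e(g), beta)`; the
#' weight k is applied by [evbic_score()], not here.
#'
#' @param g a `bn_dag`.
#' @param items a `knowledge_items` data frame (vague kinds 4-6 only).
#' @param accuracies accuracy table keyed by `expert`.
#' @return log score (0 when `items` is empty).
#' @export
vague_penalty <- function(g, items, accuracies) {
  if (NROW(items) == 0L) return(0)
  if (any(is_explicit_kind(items$kind)))
    stop("vague_penalty takes vague kinds (4..6) only")
  knowledge_loglik(g, items, accuracies)
}

knowledge_loglik <- function(g, items, accuracies) {
  e <- edge_state(g, items$x, items$y)
  acc <- accuracies[match(items$expert, accuracies$expert), ]
  if (anyNA(acc$gamma1)) stop("missing accuracy row for some expert")
  p <- vapply(seq_len(nrow(items)), function(i) {
    if (is_explicit_kind(items$kind[i]))
      knowledge_likelihood_explicit(items$kind[i], e[i], acc[i, ])
    else
      knowledge_likelihood_vague(items$kind[i], e[i], acc[i, ])
  }, numeric(1))
  sum(safe_log(p))
}

#' EVBIC: knowledge-penalized BIC score
#'
#' `total = BIC + sum ln P(V_explicit | e, gamma)
#'        + k * sum ln P(V_vague | e, beta)`.
#' The data term measures fit to the data; the two penalty terms measure
#' the agreement of the structure with the experts' explicit and vague
#' reports; k in `[0, 1]` down-weights vague reports (default 0.5, as each
#' vague statement leaves two causal states possible).
#'
#' @param data a `discrete_dataset`.
#' @param g a `bn_dag`.
#' @param items a `knowledge_items` data frame with any mix of kinds.
#' @param accuracies accuracy table keyed by `expert`.
#' @param k vague-knowledge weight in `[0, 1]`.
#' @return object of class `score_breakdown`: list with `data_term`,
#'   `explicit_penalty`, `vague_penalty`, `k`, `total`.
#' @export
evbic_score <- function(data, g, items = NULL, accuracies = NULL, k = 0.5) {
  if (k < 0 || k > 1) stop("k must lie in [0, 1]")
  expl <- 0; vague <- 0
  if (NROW(items) > 0L) {
    is_e <- is_explicit_kind(items$kind)
    if (any(is_e))
      expl <- explicit_penalty(g, items[is_e, , drop = FALSE], accuracies)
    if (any(!is_e))
      vague <- vague_penalty(g, items[!is_e, , drop = FALSE], accuracies)
  }
  dt <- bic_score(data, g)
  structure(list(data_term = dt, explicit_penalty = expl,
                 vague_penalty = vague, k = k,
                 total = dt + expl + k * vague),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("EVBIC %.4f = data %.4f + explicit %.4f + %.2f * vague %.4f\n",
              x$total, x$data_term, x$explicit_penalty, x$k, x$vague_penalty))
  invisible(x)
}

#' Explicit-accuracy score (BDeu + explicit penalty)
#'
#' The baseline knowledge-aware score: BDeu log marginal likelihood plus
#' the explicit-report log-likelihood.  Vague knowledge is ignored.
#'
#' @inheritParams evbic_score
#' @param ess BDeu equivalent sample size.
#' @return log score.
#' @export
explicit_accuracy_score <- function(data, g, items = NULL, accuracies = NULL,
                                    ess = 1) {
  s <- bdeu_score(data, g, ess)
  if (NROW(items) > 0L) {
    is_e <- is_explicit_kind(items$kind)
    s <- s + explicit_penalty(g, items[is_e, , drop = FALSE], accuracies)
  }
  s
}

#' Build a fast score function for structure search
#'
#' Returns a closure `function(dag) -> numeric` evaluating BIC, EVBIC or
#' the explicit-accuracy score with per-node local-score memoization and
#' precomputed per-pair knowledge penalties, suitable as the objective of
#' [bpso_search()].
#'
#' @param data a `discrete_dataset`.
#' @param items optional `knowledge_items`.
#' @param accuracies accuracy table (required when `items` given).
#' @param k vague-knowledge weight.
#' @param type `"evbic"` (BIC data term) or `"explicit"` (BDeu data term,
#'   explicit penalty only).
#' @param ess BDeu equivalent sample size (type `"explicit"`).
#' @return scoring closure.
#' @export
make_score_fn <- function(data, items = NULL, accuracies = NULL, k = 0.5,
                          type = c("evbic", "explicit"), ess = 1) {
  type <- match.arg(type)
  nodes <- data$nodes
  n <- length(nodes)
  nlogn <- 0.5 * log(nrow(data$records))
  cache <- new.env(parent = emptyenv())
  local_score <- function(v, pars) {
    key <- paste(v, paste(pars, collapse = ","), sep = "|")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    counts <- local_counts(data, v, pars)
    val <- if (type == "evbic") {
      local_ll(counts) - nlogn * nrow(counts) * (ncol(counts) - 1)
    } else {
      q <- nrow(counts); r <- ncol(counts)
      a_ijk <- ess / (q * r); a_ij <- ess / q
      sum(lgamma(a_ij) - lgamma(a_ij + rowSums(counts))) +
        sum(lgamma(a_ijk + counts) - lgamma(a_ijk))
    }
    cache[[key]] <- val
    val
  }
  # per-pair penalty lookup: pen[j, e] for canonical pair j, edge state e
  pairs <- enumerate_node_pairs(nodes)
  pi_ <- match(pairs[, 1L], nodes); pj_ <- match(pairs[, 2L], nodes)
  pen <- matrix(0, nrow(pairs), 3L)
  if (NROW(items) > 0L) {
    acc <- accuracies[match(items$expert, accuracies$expert), ]
    pk <- function(a, b) ((match(a, nodes) - 1L) * (2L * n - match(a, nodes))) / 2L +
      match(b, nodes) - match(a, nodes)
    for (i in seq_len(nrow(items))) {
      if (type == "explicit" && !is_explicit_kind(items$kind[i])) next
      x <- items$x[i]; y <- items$y[i]
      canon <- match(x, nodes) < match(y, nodes)
      j <- if (canon) pk(x, y) else pk(y, x)
      for (e_canon in 1:3) {
        e_item <- if (canon) e_canon else c(2L, 1L, 3L)[e_canon]
        if (is_explicit_kind(items$kind[i]))
          pen[j, e_canon] <- pen[j, e_canon] +
            safe_log(knowledge_likelihood_explicit(items$kind[i], e_item, acc[i, ]))
        else
          pen[j, e_canon] <- pen[j, e_canon] +
            k * safe_log(knowledge_likelihood_vague(items$kind[i], e_item, acc[i, ]))
      }
    }
  }
  haspen <- NROW(items) > 0L
  function(g) {
    s <- 0
    for (v in g$nodes) s <- s + local_score(v, parents(g, v))
    if (haspen) {
      a <- amat(g)
      st <- ifelse(a[cbind(pi_, pj_)] == 1L, 1L,
                   ifelse(a[cbind(pj_, pi_)] == 1L, 2L, 3L))
      s <- s + sum(pen[cbind(seq_len(nrow(pairs)), st)])
    }
    s
  }
}
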