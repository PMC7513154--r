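# Expert knowledge: the six knowledge kinds, expert accuracy parameters,
# credibility, multi-expert fusion, knowledge likelihood trees, and the
# simulated-expert generator.
#
# Kind codes (an expert's statement about an ordered node pair (X, Y)):
#   1  ->   X is a parent of Y                      (explicit)
#   2  <-   Y is a parent of X                      (explicit)
#   3  none X and Y are not adjacent                (explicit)
#   4  --   X and Y are adjacent, direction unknown (vague)
#   5  n->  X is not a parent of Y (so <- or none)  (vague)
#   6  n<-  Y is not a parent of X (so -> or none)  (vague)
#
# Edge states of a pair (X, Y) in a structure: 1 = ->, 2 = <-, 3 = none.

#' Knowledge kind codes
#'
#' Named integer constants for the six kinds of expert knowledge.  Codes
#' 1-3 are explicit (they fix the causal state of the pair exactly), codes
#' 4-6 are vague (they leave two states possible).
#' @format named integer vector.
#' @export
KIND <- c(arc = 1L, rev = 2L, none = 3L, undirected = 4L,
          not_parent = 5L, not_child = 6L)

#' @rdname KIND
#' @param kind integer kind code(s) 1-6.
#' @return logical: is the kind explicit (1-3)?
#' @export
is_explicit_kind <- function(kind) kind %in% 1:3

#' Expert accuracy parameters
#'
#' Six probabilities describe one expert: `gamma1` correct orientation,
#' `gamma2` reversed orientation and `gamma3` correct detection of an
#' absent edge, all for explicit knowledge; `beta1`, `beta2`, `beta3` are
#' the analogous parameters for vague knowledge.
#'
#' @param gamma1,gamma2,gamma3,beta1,beta2,beta3 probabilities in `[0, 1]`,
#'   with `gamma1 + gamma2 <= 1` and `beta1 + beta2 <= 1`.
#' @return a one-row data frame of class `expert_accuracy`.
#' @export
expert_accuracy <- function(gamma1, gamma2, gamma3, beta1, beta2, beta3) {
  p <- c(gamma1, gamma2, gamma3, beta1, beta2, beta3)
  if (any(p < 0 | p > 1)) stop("accuracy parameters must lie in [0, 1]")
  if (gamma1 + gamma2 > 1 + 1e-12) stop("gamma1 + gamma2 must be <= 1")
  if (beta1 + beta2 > 1 + 1e-12) stop("beta1 + beta2 must be <= 1")
  structure(data.frame(gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
                       beta1 = beta1, beta2 = beta2, beta3 = beta3),
            class = c("expert_accuracy", "data.frame"))
}

#' Bundled panel of ten simulated-expert accuracies
#'
#' The package's default heterogeneous expert panel: ten experts whose
#' explicit and vague accuracy parameters coincide
#' (`gamma_i == beta_i` per expert), shipped as a plain CSV in
#' `inst/extdata/expert_accuracies.csv`.
#'
#' @return data frame with columns `expert`, `gamma1..3`, `beta1..3`.
#' @export
default_expert_accuracies <- function() {
  path <- system.file("extdata", "expert_accuracies.csv", package = "evbic")
  read_accuracies(path)
}

#' Read an expert accuracy table from CSV
#'
#' Columns: `expert`, `gamma1`, `gamma2`, `gamma3`, `beta1`, `beta2`,
#' `beta3`.
#' @param path CSV path.
#' @return data frame keyed by `expert`.
#' @export
read_accuracies <- function(path) {
  df <- utils::read.csv(path)
  need <- c("expert", "gamma1", "gamma2", "gamma3", "beta1", "beta2", "beta3")
  if (!all(need %in% names(df)))
    stop("accuracy file must have columns ", paste(need, collapse = ", "))
  for (r in seq_len(nrow(df)))
    expert_accuracy(df$gamma1[r], df$gamma2[r], df$gamma3[r],
                    df$beta1[r], df$beta2[r], df$beta3[r])  # validates
  df[, need]
}

#' Create a table of knowledge items
#'
#' One knowledge item is one expert's statement about one ordered node
#' pair.  For kinds 1, 2, 5 and 6 the pair order is semantically
#' significant.
#'
#' @param expert integer expert ids.
#' @param x,y variable names of the pair (X, Y).
#' @param kind integer kind codes 1-6 (see [KIND]).
#' @return data frame of class `knowledge_items`.
#' @export
knowledge_items <- function(expert, x, y, kind) {
  if (any(x == y)) stop("a knowledge item must involve two distinct nodes")
  if (any(!(kind %in% 1:6))) stop("kind codes must be 1..6")
  structure(data.frame(expert = as.integer(expert), x = as.character(x),
                       y = as.character(y), kind = as.integer(kind)),
            class = c("knowledge_items", "data.frame"))
}

#' Read knowledge items from CSV
#' @param path CSV with columns `expert_id`, `var_x`, `var_y`, `kind`.
#' @return a `knowledge_items` data frame.
#' @export
read_knowledge <- function(path) {
  df <- utils::read.csv(path)
  need <- c("expert_id", "var_x", "var_y", "kind")
  if (!all(need %in% names(df)))
    stop("knowledge file must have columns ", paste(need, collapse = ", "))
  knowledge_items(df$expert_id, df$var_x, df$var_y, df$kind)
}

#' Write knowledge items to CSV
#' @param items a `knowledge_items` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_knowledge <- function(items, path) {
  utils::write.csv(data.frame(expert_id = items$expert, var_x = items$x,
                              var_y = items$y, kind = items$kind),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Credibility of one piece of expert knowledge
#'
#' The credibility theta is the probability that the statement is true,
#' determined by the expert's accuracy parameters:
#' `theta1 = theta2 = gamma1`, `theta3 = gamma3`,
#' `theta4 = beta1 + beta2`, `theta5 = theta6 = 1 - beta2`.
#'
#' @param kind integer kind code(s) 1-6.
#' @param acc one row of an accuracy table (list or data frame row with
#'   `gamma1..3`, `beta1..3`).
#' @return credibility in `[0, 1]`, vectorized over `kind`.
#' @export
credibility <- function(kind, acc) {
  if (any(!(kind %in% 1:6))) stop("kind codes must be 1..6")
  th <- c(acc$gamma1, acc$gamma1, acc$gamma3,
          acc$beta1 + acc$beta2, 1 - acc$beta2, 1 - acc$beta2)
  th[kind]
}

#' Fuse the knowledge of several experts about one node pair
#'
#' Experts are partitioned by the kind they assert (groups G1..G6); the
#' credibilities are summed per kind and normalized into selection
#' probabilities P_l; one kind is selected by roulette over the six
#' subintervals of `[0, 1]`; its credibility is the arithmetic mean of the
#' credibilities of its supporters.
#'
#' @param items `knowledge_items` rows, all addressing the same unordered
#'   pair (kinds of reversed-pair rows are flipped internally).
#' @param accuracies accuracy table keyed by `expert`.
#' @return list with `kind` (selected code, relative to the pair as
#'   ordered in the first item), `theta`, and `probs` (the six selection
#'   probabilities).
#' @export
fuse_pair <- function(items, accuracies) {
  if (NROW(items) < 1L) stop("at least one knowledge item is required")
  x0 <- items$x[1L]; y0 <- items$y[1L]
  ok <- (items$x == x0 & items$y == y0) | (items$x == y0 & items$y == x0)
  if (!all(ok)) stop("all items must address the same node pair")
  kind <- items$kind
  flip <- items$x == y0
  kind[flip] <- flip_kind(kind[flip])
  acc <- accuracies[match(items$expert, accuracies$expert), ]
  if (anyNA(acc$gamma1)) stop("missing accuracy row for some expert")
  theta <- vapply(seq_along(kind),
                  function(i) credibility(kind[i], acc[i, ]), numeric(1))
  sums <- vapply(1:6, function(l) sum(theta[kind == l]), numeric(1))
  probs <- sums / sum(sums)
  u <- stats::runif(1L)
  sel <- findInterval(u, cumsum(probs), left.open = TRUE) + 1L
  sel <- min(sel, 6L)  # u == 1 lands in the last subinterval
  # roulette can only select a kind someone asserted (its interval has
  # positive length); guard against numeric fringe
  if (sums[sel] == 0) sel <- which.max(sums)
  list(kind = sel, theta = mean(theta[kind == sel]), probs = probs)
}

# express a statement about (X, Y) as the equivalent statement about (Y, X)
flip_kind <- function(kind) c(2L, 1L, 3L, 4L, 6L, 5L)[kind]

#' Fuse all expert knowledge, pair by pair
#'
#' Applies [fuse_pair()] to every node pair with at least one item and
#' routes the fused statements into four sets: `ce` (explicit arcs, kinds
#' 1-2, stored as ordered parent/child), `ca` (explicit absences, kind 3),
#' `ie` (vague adjacencies, kind 4) and `ia` (vague exclusions, kinds 5-6,
#' canonicalized to ordered "from is not a parent of to" assertions).  The
#' credibility of every fused statement is carried along (credibility set).
#'
#' @param items a `knowledge_items` data frame (may be empty).
#' @param accuracies accuracy table keyed by `expert`.
#' @param nodes optional node ordering; pairs are processed in
#'   [enumerate_node_pairs()] order over it (default: order of appearance).
#' @return object of class `fused_knowledge`: list of data frames `ce`
#'   (`from`, `to`, `theta`), `ca` (`x`, `y`, `theta`), `ie` (`x`, `y`,
#'   `theta`), `ia` (`from`, `to`, `theta`).
#' @export
fuse_all <- function(items, accuracies, nodes = NULL) {
  ce <- data.frame(from = character(0), to = character(0), theta = numeric(0))
  ca <- data.frame(x = character(0), y = character(0), theta = numeric(0))
  ie <- ca; ia <- ce
  if (NROW(items) > 0L) {
    if (is.null(nodes)) nodes <- unique(c(rbind(items$x, items$y)))
    ux <- pmin(match(items$x, nodes), match(items$y, nodes))
    uy <- pmax(match(items$x, nodes), match(items$y, nodes))
    key <- paste(nodes[ux], nodes[uy])
    for (k in unique(key[order(ux, uy)])) {
      sub <- items[key == k, , drop = FALSE]
      # canonical pair order (x before y in node order)
      px <- nodes[min(match(sub$x[1L], nodes), match(sub$y[1L], nodes))]
      py <- nodes[max(match(sub$x[1L], nodes), match(sub$y[1L], nodes))]
      if (sub$x[1L] != px) {  # reorder first item's frame to canonical
        sub <- rbind(knowledge_items(sub$expert[1L], px, py,
                                     flip_kind(sub$kind[1L])),
                     sub[-1L, , drop = FALSE])
      }
      fz <- fuse_pair(sub, accuracies)
      if (fz$kind == 1L)
        ce <- rbind(ce, data.frame(from = px, to = py, theta = fz$theta))
      else if (fz$kind == 2L)
        ce <- rbind(ce, data.frame(from = py, to = px, theta = fz$theta))
      else if (fz$kind == 3L)
        ca <- rbind(ca, data.frame(x = px, y = py, theta = fz$theta))
      else if (fz$kind == 4L)
        ie <- rbind(ie, data.frame(x = px, y = py, theta = fz$theta))
      else if (fz$kind == 5L)
        ia <- rbind(ia, data.frame(from = px, to = py, theta = fz$theta))
      else
        ia <- rbind(ia, data.frame(from = py, to = px, theta = fz$theta))
    }
  }
  structure(list(ce = ce, ca = ca, ie = ie, ia = ia),
            class = "fused_knowledge")
}

#' @export
print.fused_knowledge <- function(x, ...) {
  cat("Fused expert knowledge:", nrow(x$ce), "explicit arcs,",
      nrow(x$ca), "explicit absences,", nrow(x$ie), "vague adjacencies,",
      nrow(x$ia), "vague exclusions\n")
  invisible(x)
}

#' Likelihood of an explicit report given the true edge state
#'
#' The decision tree for explicit knowledge: under a true arc the expert
#' reports the correct orientation with probability `gamma1`, the reversed
#' orientation with `gamma2`, and a (false) absence with
#' `1 - gamma1 - gamma2`; under a truly absent edge the expert reports
#' absence with `gamma3` and each orientation with `(1 - gamma3) / 2`.
#'
#' @param v reported kind, one of 1 (`->`), 2 (`<-`), 3 (absent).
#' @param e true edge state, same coding.
#' @param acc accuracy row (`gamma1`, `gamma2`, `gamma3`).
#' @return probability P(v | e).
#' @export
knowledge_likelihood_explicit <- function(v, e, acc) {
  if (!(v %in% 1:3)) stop("explicit kinds are 1..3")
  if (!(e %in% 1:3)) stop("edge states are 1..3")
  g1 <- acc$gamma1; g2 <- acc$gamma2; g3 <- acc$gamma3
  if (e == 1L)      c(g1, g2, 1 - g1 - g2)[v]
  else if (e == 2L) c(g2, g1, 1 - g1 - g2)[v]
  else              c((1 - g3) / 2, (1 - g3) / 2, g3)[v]
}

#' Likelihood of a vague report given the true edge state
#'
#' The decision tree for vague knowledge mirrors the explicit one with the
#' beta parameters: under a true arc X -> Y the expert reports "adjacent"
#' (kind 4) with `beta1`, the exclusion that wrongly rules out the true
#' direction (kind 5, "X is not a parent of Y") with `beta2`, and the
#' compatible exclusion (kind 6) with `1 - beta1 - beta2`; under a truly
#' absent edge the expert reports "adjacent" with `1 - beta3` and each
#' exclusion with `beta3 / 2`.
#'
#' @param v reported kind, one of 4 (`--`), 5 (X not parent of Y),
#'   6 (Y not parent of X).
#' @param e true edge state 1-3.
#' @param acc accuracy row (`beta1`, `beta2`, `beta3`).
#' @return probability P(v | e).
#' @export
knowledge_likelihood_vague <- function(v, e, acc) {
  if (!(v %in% 4:6)) stop("vague kinds are 4..6")
  if (!(e %in% 1:3)) stop("edge states are 1..3")
  b1 <- acc$beta1; b2 <- acc$beta2; b3 <- acc$beta3
  i <- v - 3L
  if (e == 1L)      c(b1, b2, 1 - b1 - b2)[i]
  else if (e == 2L) c(b1, 1 - b1 - b2, b2)[i]
  else              c(1 - b3, b3 / 2, b3 / 2)[i]
}

#' Simulate expert reports about a true structure
#'
#' Selects `round(v * n_pairs)` node pairs uniformly without replacement
#' (ties rounded up); every expert in the panel reports on every selected
#' pair.  Each report is drawn from the explicit likelihood tree
#' (`case = "explicit"`) or the vague tree (`case = "vague"`),
#' conditioned on the true edge state of the pair.  In the mixed case
#' (`case = "ev"`) every expert contributes both an explicit and a vague
#' report on every selected pair, so mixed knowledge carries strictly
#' more information than either single-type case.
#'
#' @param truth a `bn_dag`, the true structure.
#' @param accuracies accuracy table, one row per expert.
#' @param v coverage fraction in `[0, 1]`.
#' @param case one of `"explicit"`, `"vague"`, `"ev"`.
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @return a `knowledge_items` data frame.
#' @export
simulate_experts <- function(truth, accuracies, v,
                             case = c("explicit", "vague", "ev"),
                             seed = NULL) {
  case <- match.arg(case)
  if (v < 0 || v > 1) stop("coverage v must lie in [0, 1]")
  if (NROW(accuracies) < 1L) stop("at least one expert is required")
  if (!is.null(seed)) set.seed(seed)
  pairs <- enumerate_node_pairs(truth$nodes)
  npair <- nrow(pairs)
  ntake <- floor(v * npair + 0.5)  # nearest integer, ties up
  if (ntake == 0L)
    return(knowledge_items(integer(0), character(0), character(0), integer(0)))
  take <- sort(sample.int(npair, ntake))
  states <- pair_states(truth)
  # one full pass per report type; under a common seed the explicit pass
  # of case "ev" reproduces case "explicit" exactly, so mixed knowledge is
  # a superset of explicit knowledge (common-random-numbers pairing)
  types <- switch(case, explicit = "explicit", vague = "vague",
                  ev = c("explicit", "vague"))
  out_e <- integer(0); out_x <- character(0); out_y <- character(0)
  out_k <- integer(0)
  for (ty in types) for (j in take) {
    e <- states[j]
    for (r in seq_len(nrow(accuracies))) {
      acc <- accuracies[r, ]
      if (ty == "explicit") {
        p <- vapply(1:3, knowledge_likelihood_explicit, numeric(1),
                    e = e, acc = acc)
        k <- sample.int(3L, 1L, prob = p)
      } else {
        p <- vapply(4:6, knowledge_likelihood_vague, numeric(1),
                    e = e, acc = acc)
        k <- sample.int(3L, 1L, prob = p) + 3L
      }
      out_e <- c(out_e, acc$expert)
      out_x <- c(out_x, pairs[j, 1L]); out_y <- c(out_y, pairs[j, 2L])
      out_k <- c(out_k, k)
    }
  }
  knowledge_items(out_e, out_x, out_y, out_k)
}
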