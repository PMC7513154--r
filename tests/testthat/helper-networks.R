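# Small networks used across the test files; all built in code.

# A -> B -> C chain with strong (0.9 / 0.1) transition rows.
chain3_bn <- function(p = 0.9) {
  g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  row2 <- matrix(c(p, 1 - p, 1 - p, p), 2, byrow = TRUE)
  discrete_bn(g, c(A = 2L, B = 2L, C = 2L),
              list(A = matrix(c(0.5, 0.5), 1), B = row2, C = row2))
}

# collider X -> W <- Y with independent uniform roots
collider_bn <- function() {
  g <- dag(c("X", "W", "Y"), rbind(c("X", "W"), c("Y", "W")))
  w <- matrix(c(0.95, 0.05,
                0.20, 0.80,
                0.20, 0.80,
                0.05, 0.95), 4, byrow = TRUE)
  discrete_bn(g, c(X = 2L, W = 2L, Y = 2L),
              list(X = matrix(c(0.5, 0.5), 1), W = w,
                   Y = matrix(c(0.5, 0.5), 1)))
}

# single perfect expert / perfect panel helpers
perfect_accuracies <- function(n_experts = 1L) {
  data.frame(expert = seq_len(n_experts), gamma1 = 1, gamma2 = 0,
             gamma3 = 1, beta1 = 1, beta2 = 0, beta3 = 1)
}

# exhaustive joint distribution of a small discrete network
exact_joint <- function(bn) {
  nodes <- bn$structure$nodes
  grid <- expand.grid(lapply(bn$arities, function(r) 0:(r - 1L)),
                      KEEP.OUT.ATTRS = FALSE)
  p <- apply(as.matrix(grid), 1L, function(a)
    joint_probability(bn, stats::setNames(a, nodes)))
  cbind(grid, p = p)
}

# directed part of a pdag is acyclic?
is_acyclic_public <- function(h) {
  g <- try(dag(h$nodes, h$arcs), silent = TRUE)
  !inherits(g, "try-error")
}

# orientation state of pair (x, y) in a dag: 1 x->y, 2 y->x, 3 none
edge_dir <- function(g, x, y) {
  a <- amat(g)
  if (a[x, y] == 1L) 1L else if (a[y, x] == 1L) 2L else 3L
}
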