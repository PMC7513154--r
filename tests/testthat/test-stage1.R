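test_that("MIC is 1 for identical variables, small under independence, symmetric", {
  x <- rep(0:1, each = 50)
  expect_equal(mic_score(x, x), 1, tolerance = 1e-6)
  x3 <- rep(0:2, length.out = 90)
  expect_equal(mic_score(x3, x3), 1, tolerance = 1e-6)
  set.seed(1)
  a <- sample(0:1, 5000, replace = TRUE)
  b <- sample(0:1, 5000, replace = TRUE)
  expect_lt(mic_score(a, b), 0.05)
  set.seed(2)
  u <- sample(0:2, 300, replace = TRUE)
  w <- (u + sample(0:1, 300, replace = TRUE)) %% 3
  expect_equal(mic_score(u, w), mic_score(w, u))
  expect_equal(mic_score(rep(0L, 10), rep(0:1, 5)), 0)
})

test_that("G-squared test calibrates under the null and rejects dependence", {
  set.seed(3)
  hits <- 0L
  for (r in 1:100) {
    d <- discrete_dataset(cbind(X = sample(0:1, 500, replace = TRUE),
                                Y = sample(0:1, 500, replace = TRUE)))
    if (ci_test("X", "Y", character(0), d)$independent) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
  # deterministic copy: overwhelming dependence
  x <- sample(0:1, 500, replace = TRUE)
  d2 <- discrete_dataset(cbind(X = x, Y = x))
  tt <- ci_test("X", "Y", character(0), d2)
  expect_lt(tt$p_value, 1e-6)
  expect_equal(tt$df, 1L)
})

test_that("conditioning on a collider induces dependence", {
  d <- forward_sample(collider_bn(), 5000, seed = 4)
  expect_true(ci_test("X", "Y", character(0), d)$independent)
  expect_false(ci_test("X", "Y", "W", d)$independent)
})

test_that("skeleton recovery on a chain prunes the indirect edge", {
  d <- forward_sample(chain3_bn(), 5000, seed = 5)
  sk <- build_skeleton(d, tau = 0.05)
  key <- paste(sk$edges[, 1], sk$edges[, 2])
  expect_setequal(key, c("A B", "B C"))
  expect_named(attr(sk, "sepsets"), "A|C")
  # tau = 1 keeps nothing; tau = 0 without pruning keeps everything
  expect_equal(nrow(build_skeleton(d, tau = 1)$edges), 0L)
  expect_equal(nrow(build_skeleton(d, tau = 0, prune = FALSE)$edges), 3L)
})

test_that("v-structures are oriented and chains are left undirected", {
  d <- forward_sample(collider_bn(), 5000, seed = 4)
  h <- orient_head_to_head(build_skeleton(d, tau = 0.02), d)
  expect_equal(nrow(h$arcs), 2L)
  expect_true(all(h$arcs[, 2] == "W"))
  dc <- forward_sample(chain3_bn(), 5000, seed = 7)
  hc <- orient_head_to_head(build_skeleton(dc, tau = 0.05), dc)
  expect_equal(nrow(hc$arcs), 0L)
  # no unshielded triple: output equals input
  sk1 <- pdag(c("A", "B"), edges = rbind(c("A", "B")))
  h1 <- orient_head_to_head(sk1, forward_sample(chain3_bn(), 100, seed = 8))
  expect_equal(nrow(h1$arcs), 0L)
  expect_equal(nrow(h1$edges), 1L)
})

fused_one <- function(set, ...) {
  base <- list(ce = data.frame(from = character(0), to = character(0),
                               theta = numeric(0)),
               ca = data.frame(x = character(0), y = character(0),
                               theta = numeric(0)),
               ie = data.frame(x = character(0), y = character(0),
                               theta = numeric(0)),
               ia = data.frame(from = character(0), to = character(0),
                               theta = numeric(0)))
  base[[set]] <- data.frame(...)
  structure(base, class = "fused_knowledge")
}

test_that("undirected-graph rules fire with probability theta", {
  h <- pdag(c("A", "B", "C"))
  f1 <- fused_one("ie", x = "A", y = "B", theta = 1)
  set.seed(9)
  expect_equal(nrow(modify_undirected(h, f1)$edges), 1L)
  f0 <- fused_one("ie", x = "A", y = "B", theta = 0)
  expect_equal(nrow(modify_undirected(h, f0)$edges), 0L)
  # empirical firing rate ~ theta
  f8 <- fused_one("ie", x = "A", y = "B", theta = 0.8)
  set.seed(10)
  fired <- replicate(10000, nrow(modify_undirected(h, f8)$edges) == 1L)
  expect_lt(abs(mean(fired) - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
  # explicit absence deletes an existing edge
  he <- pdag(c("A", "B"), edges = rbind(c("A", "B")))
  fd <- fused_one("ca", x = "A", y = "B", theta = 1)
  set.seed(11)
  expect_equal(nrow(modify_undirected(he, fd)$edges), 0L)
})

test_that("partial-graph rules add and delete arcs and never create cycles", {
  h <- pdag(c("A", "B", "C"))
  fa <- fused_one("ce", from = "A", to = "B", theta = 1)
  set.seed(12)
  out <- modify_partial(h, fa)
  expect_equal(unname(out$arcs[1, ]), c("A", "B"))
  hd <- pdag(c("A", "B"), arcs = rbind(c("A", "B")))
  fr <- fused_one("ia", from = "A", to = "B", theta = 1)
  set.seed(13)
  expect_equal(nrow(modify_partial(hd, fr)$arcs), 0L)
  # a cyclic triple of assertions keeps the result acyclic
  fc <- fused_one("ce", from = c("A", "B", "C"), to = c("B", "C", "A"),
                  theta = c(1, 1, 1))
  set.seed(14)
  outc <- modify_partial(pdag(c("A", "B", "C")), fc, log = TRUE)
  expect_lte(nrow(outc$arcs), 2L)
  expect_true(is_acyclic_public(outc))
  lg <- attr(outc, "rule_log")
  expect_equal(nrow(lg), 3L)  # one draw per statement
})

test_that("empty knowledge leaves both rule passes as identities", {
  empty <- fuse_all(knowledge_items(integer(0), character(0), character(0),
                                    integer(0)), default_expert_accuracies())
  h <- pdag(c("A", "B", "C"), arcs = rbind(c("A", "B")),
            edges = rbind(c("B", "C")))
  hu <- pdag(c("A", "B", "C"), edges = rbind(c("B", "C")))
  expect_equal(modify_undirected(hu, empty)$edges, hu$edges)
  out <- modify_partial(h, empty)
  expect_equal(out$arcs, h$arcs)
  expect_equal(out$edges, h$edges)
})

test_that("the stage-1 pipeline output never contains a directed cycle", {
  acc <- default_expert_accuracies()
  g <- load_fixture("fig1")
  bn <- random_cpts(g, seed = 15)
  for (s in 1:10) {
    d <- forward_sample(bn, 300, seed = 100 + s)
    items <- simulate_experts(g, acc, 0.6, "ev", seed = 200 + s)
    set.seed(300 + s)
    fused <- fuse_all(items, acc, nodes = g$nodes)
    h <- initial_structure(d, fused, seed = 400 + s)
    expect_true(is_acyclic_public(h))
  }
})

test_that("perfect full-coverage knowledge pulls stage 1 toward the truth", {
  acc <- perfect_accuracies(3)
  g <- chain3_bn()$structure
  shd_k <- numeric(0); shd_0 <- numeric(0)
  for (s in 1:20) {
    bn6 <- random_cpts(dag(LETTERS[1:6],
                           rbind(c("A", "B"), c("B", "C"), c("C", "D"),
                                 c("D", "E"), c("B", "E"), c("A", "F"))),
                       concentration = 0.3, seed = 500 + s)
    d <- forward_sample(bn6, 800, seed = 600 + s)
    items <- simulate_experts(bn6$structure, acc, 1, "explicit",
                              seed = 700 + s)
    set.seed(800 + s)
    fused <- fuse_all(items, acc, nodes = bn6$structure$nodes)
    hk <- initial_structure(d, fused, seed = 900 + s)
    h0 <- initial_structure(d, NULL, seed = 900 + s)
    # compare completed structures to the truth
    set.seed(1000 + s)
    shd_k[s] <- structural_diff(complete_orientation(hk),
                                bn6$structure)$shd
    set.seed(1000 + s)
    shd_0[s] <- structural_diff(complete_orientation(h0),
                                bn6$structure)$shd
  }
  expect_lte(mean(shd_k), mean(shd_0))
})
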