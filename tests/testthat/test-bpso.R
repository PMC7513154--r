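test_that("random completion keeps arcs, orients edges, and stays acyclic", {
  g <- load_fixture("fig1")
  h <- pdag(g$nodes, arcs = g$arcs)
  expect_identical(complete_orientation(h)$arcs, g$arcs)
  h1 <- pdag(c("A", "B"), edges = rbind(c("A", "B")))
  set.seed(61)
  for (i in 1:20) {
    out <- complete_orientation(h1)
    expect_equal(narcs(out), 1L)  # a single edge is never dropped
  }
  # undirected triangle: all 3 edges kept, always acyclic
  tri <- pdag(c("A", "B", "C"),
              edges = rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  set.seed(62)
  for (i in 1:30) {
    out <- complete_orientation(tri)
    expect_equal(narcs(out), 3L)  # dag() would refuse a cyclic result
  }
})

test_that("acyclicity repair removes arcs on cycles and nothing else", {
  a <- matrix(0L, 3, 3)
  expect_identical(repair_acyclic(a), a)
  a2 <- matrix(0L, 2, 2); a2[1, 2] <- 1L; a2[2, 1] <- 1L
  r2 <- repair_acyclic(a2)
  expect_equal(sum(r2), 1L)
  expect_equal(r2[1, 2], 1L)  # largest row-major index (2,1) removed
  set.seed(63)
  for (i in 1:200) {
    a6 <- matrix(as.integer(stats::runif(36) < 0.4), 6, 6)
    diag(a6) <- 0L
    r6 <- repair_acyclic(a6)
    expect_true(all(r6 <= a6))
    g <- try(dag(paste0("X", 1:6),
                 cbind(paste0("X", which(r6 == 1L, arr.ind = TRUE)[, 1]),
                       paste0("X", which(r6 == 1L, arr.ind = TRUE)[, 2]))),
             silent = TRUE)
    expect_false(inherits(g, "try-error"))
  }
})

test_that("swarm search with zero iterations returns the best initial particle", {
  bn <- chain3_bn()
  d <- forward_sample(bn, 400, seed = 64)
  fn <- make_score_fn(d)
  fit <- bpso_search(fn, pdag(d$nodes), swarm_params(10, 0), seed = 65)
  expect_length(fit$trace, 1L)
  expect_equal(fit$best_score, fn(fit$best))
})

test_that("swarm search finds the exhaustive optimum on 3-variable data", {
  bn <- chain3_bn()
  d <- forward_sample(bn, 800, seed = 66)
  fn <- make_score_fn(d)
  opt <- max(vapply(all_dags(d$nodes), fn, numeric(1)))
  hits <- 0L
  for (s in 1:8) {
    fit <- bpso_search(fn, pdag(d$nodes), swarm_params(20, 40), seed = s)
    expect_true(!is.unsorted(fit$trace))
    expect_gte(opt + 1e-9, fit$best_score)
    if (abs(fit$best_score - opt) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("swarm search is deterministic under a fixed seed and beats its seed", {
  bn <- chain3_bn()
  d <- forward_sample(bn, 300, seed = 67)
  fn <- make_score_fn(d)
  h <- pdag(d$nodes, edges = rbind(c("A", "B")))
  f1 <- bpso_search(fn, h, swarm_params(8, 15), seed = 68)
  f2 <- bpso_search(fn, h, swarm_params(8, 15), seed = 68)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$best$arcs, f2$best$arcs)
  set.seed(69)
  expect_gte(f1$best_score, fn(complete_orientation(h)))
})
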