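acc_panel <- default_expert_accuracies()

test_that("credibility follows the accuracy parameters for every panel row", {
  for (r in seq_len(nrow(acc_panel))) {
    a <- acc_panel[r, ]
    expect_equal(credibility(1, a), a$gamma1)
    expect_equal(credibility(2, a), a$gamma1)
    expect_equal(credibility(3, a), a$gamma3)
    expect_equal(credibility(4, a), a$beta1 + a$beta2)
    expect_equal(credibility(5, a), 1 - a$beta2)
    expect_equal(credibility(6, a), 1 - a$beta2)
    expect_true(all(credibility(1:6, a) >= 0 & credibility(1:6, a) <= 1))
  }
})

test_that("both likelihood trees normalize over their kinds for a grid of accuracies", {
  grid <- expand.grid(a1 = c(0, 0.3, 0.65, 1), a2 = c(0, 0.15, 0.35),
                      a3 = c(0, 0.5, 1))
  grid <- grid[grid$a1 + grid$a2 <= 1, ]
  for (r in seq_len(nrow(grid))) {
    acc <- data.frame(gamma1 = grid$a1[r], gamma2 = grid$a2[r],
                      gamma3 = grid$a3[r], beta1 = grid$a1[r],
                      beta2 = grid$a2[r], beta3 = grid$a3[r])
    for (e in 1:3) {
      pe <- vapply(1:3, knowledge_likelihood_explicit, numeric(1),
                   e = e, acc = acc)
      pv <- vapply(4:6, knowledge_likelihood_vague, numeric(1),
                   e = e, acc = acc)
      expect_true(all(pe >= 0) && all(pv >= 0))
      expect_equal(sum(pe), 1, tolerance = 1e-12)
      expect_equal(sum(pv), 1, tolerance = 1e-12)
    }
  }
  # spot values read straight off the trees
  a <- data.frame(gamma1 = 0.8, gamma2 = 0.1, gamma3 = 0.7,
                  beta1 = 0.65, beta2 = 0.15, beta3 = 0.8)
  expect_equal(knowledge_likelihood_explicit(1, 1, a), 0.8)
  expect_equal(knowledge_likelihood_explicit(1, 3, a), 0.15)  # (1-0.7)/2
  expect_equal(knowledge_likelihood_vague(4, 1, a), 0.65)
  expect_equal(knowledge_likelihood_vague(6, 3, a), 0.4)      # 0.8/2
  expect_error(knowledge_likelihood_explicit(4, 1, a), "explicit")
  expect_error(knowledge_likelihood_vague(1, 1, a), "vague")
})

test_that("fusing a single item returns it unchanged with its credibility", {
  it <- knowledge_items(1, "A", "B", 3)
  set.seed(1)
  fz <- fuse_pair(it, acc_panel)
  expect_equal(fz$kind, 3L)
  expect_equal(fz$theta, 0.7)  # gamma3 of expert 1
})

test_that("unanimous experts fuse to their kind with mean credibility", {
  it <- knowledge_items(c(1, 7), c("A", "A"), c("B", "B"), c(1, 1))
  for (s in 1:5) {
    set.seed(s)
    fz <- fuse_pair(it, acc_panel)
    expect_equal(fz$kind, 1L)
    expect_equal(fz$theta, (0.65 + 0.8) / 2)
  }
})

test_that("roulette selection frequencies match the normalized credibilities", {
  # experts 1 (kind 1, theta 0.65) and 5 (kind 3, theta 0.8)
  it <- knowledge_items(c(1, 5), c("A", "A"), c("B", "B"), c(1, 3))
  expected <- c(0.65, 0, 0.8, 0, 0, 0) / 1.45
  set.seed(42)
  draws <- replicate(10000, fuse_pair(it, acc_panel)$kind)
  obs <- tabulate(draws, 6)
  expect_equal(sum(obs[c(2, 4, 5, 6)]), 0)
  chi <- stats::chisq.test(obs[c(1, 3)], p = expected[c(1, 3)])
  expect_gt(chi$p.value, 0.01)
})

test_that("reversed-pair items are flipped into a common frame before fusion", {
  # kind 1 on (A,B) and kind 2 on (B,A) assert the same arc A -> B
  it <- knowledge_items(c(1, 7), c("A", "B"), c("B", "A"), c(1, 2))
  set.seed(3)
  fz <- fuse_pair(it, acc_panel)
  expect_equal(fz$kind, 1L)
  expect_equal(fz$theta, (0.65 + 0.8) / 2)
})

test_that("fuse_all routes fused kinds into the four partitions", {
  expect_s3_class(fuse_all(knowledge_items(integer(0), character(0),
                                           character(0), integer(0)),
                           acc_panel), "fused_knowledge")
  set.seed(2)
  fk <- fuse_all(knowledge_items(1, "A", "B", 4), acc_panel)
  expect_equal(nrow(fk$ie), 1L)
  expect_equal(nrow(fk$ce) + nrow(fk$ca) + nrow(fk$ia), 0L)
  expect_equal(fk$ie$theta, 0.8)  # beta1 + beta2 of expert 1
  # a "Y is not a parent of X" statement on (X,Y) is stored ordered (Y,X)
  set.seed(2)
  fk2 <- fuse_all(knowledge_items(1, "X", "Y", 6), acc_panel,
                  nodes = c("X", "Y"))
  expect_equal(nrow(fk2$ia), 1L)
  expect_equal(fk2$ia$from, "Y")
  expect_equal(fk2$ia$to, "X")
})

test_that("simulated expert coverage hits round(v * n_pairs) exactly", {
  g <- load_fixture("asia")  # 28 pairs
  for (v in c(0, 0.4, 0.5, 0.6, 1)) {
    items <- simulate_experts(g, acc_panel, v, "explicit", seed = 4)
    npairs <- nrow(unique(items[, c("x", "y")]))
    expect_equal(npairs, floor(v * 28 + 0.5))
    if (v > 0) expect_equal(nrow(items), npairs * 10L)
  }
})

test_that("a perfect expert at full coverage reports the true edge states", {
  g <- load_fixture("fig1")
  items <- simulate_experts(g, perfect_accuracies(), 1, "explicit", seed = 5)
  states <- pair_states(g)
  pairs <- enumerate_node_pairs(g$nodes)
  key <- paste(pairs[, 1], pairs[, 2])
  expect_equal(items$kind, states[match(paste(items$x, items$y), key)])
})

test_that("report histograms match the likelihood trees (chi-square)", {
  # one pair with a true arc, one expert, many replicates
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  acc <- acc_panel[3, ]  # gamma 0.67 / 0.15 / 0.78
  set.seed(6)
  kinds <- replicate(10000,
    simulate_experts(g, acc, 1, "explicit")$kind)
  p_true <- vapply(1:3, knowledge_likelihood_explicit, numeric(1),
                   e = 1, acc = acc)
  chi <- stats::chisq.test(tabulate(kinds, 3), p = p_true)
  expect_gt(chi$p.value, 0.01)
  set.seed(6)
  vk <- replicate(10000, simulate_experts(g, acc, 1, "vague")$kind)
  p_v <- vapply(4:6, knowledge_likelihood_vague, numeric(1),
                e = 1, acc = acc)
  chiv <- stats::chisq.test(tabulate(vk - 3L, 3), p = p_v)
  expect_gt(chiv$p.value, 0.01)
})

test_that("the mixed case pairs one explicit with one vague report per expert", {
  g <- load_fixture("fig1")
  items <- simulate_experts(g, acc_panel, 1, "ev", seed = 8)
  expect_equal(nrow(items), 6 * 10 * 2)
  byexp <- table(items$expert, is_explicit_kind(items$kind))
  expect_true(all(byexp == 6))
})
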