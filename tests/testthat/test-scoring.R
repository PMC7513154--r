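acc_panel <- default_expert_accuracies()

test_that("log-likelihood matches closed forms on one binary variable", {
  d <- discrete_dataset(matrix(c(rep(1L, 7), rep(0L, 3)), ncol = 1,
                               dimnames = list(NULL, "X")))
  g <- dag("X")
  expect_equal(log_likelihood(d, g), 7 * log(0.7) + 3 * log(0.3),
               tolerance = 1e-9)
  expect_equal(bic_score(d, g),
               7 * log(0.7) + 3 * log(0.3) - 0.5 * log(10),
               tolerance = 1e-9)
  # uniform counts: LL = N ln(1/r)
  du <- discrete_dataset(matrix(rep(0:1, 5), ncol = 1,
                                dimnames = list(NULL, "X")))
  expect_equal(log_likelihood(du, dag("X")), 10 * log(0.5), tolerance = 1e-9)
})

test_that("adding an arc never decreases the log-likelihood", {
  bn <- random_cpts(load_fixture("fig1"), seed = 20)
  d <- forward_sample(bn, 300, seed = 21)
  set.seed(22)
  for (i in 1:20) {
    g <- all_dags(c("A", "B", "C", "D"))[[sample.int(543, 1)]]
    free <- which(pair_states(g) == 3L)
    if (length(free) == 0L) next
    pr <- enumerate_node_pairs(g$nodes)[free[1L], ]
    g2 <- try(dag(g$nodes, rbind(g$arcs, pr)), silent = TRUE)
    if (inherits(g2, "try-error")) g2 <- dag(g$nodes, rbind(g$arcs, rev(pr)))
    expect_gte(log_likelihood(d, g2), log_likelihood(d, g) - 1e-9)
  }
})

test_that("BIC agrees with an independently coded implementation", {
  # reference implementation: explicit contingency tables via xtabs
  ref_bic <- function(df, arcs, arities) {
    nodes <- colnames(df)
    tot <- 0
    for (v in nodes) {
      ps <- arcs[arcs[, 2] == v, 1]
      f <- stats::xtabs(~ ., df[, c(v, ps), drop = FALSE])
      m <- as.data.frame(f)
      m <- m[m$Freq > 0, , drop = FALSE]
      grp <- if (length(ps)) interaction(m[, ps, drop = FALSE]) else
        rep(1, nrow(m))
      tot <- tot + sum(m$Freq * log(m$Freq / ave(m$Freq, grp, FUN = sum)))
      tot <- tot - 0.5 * log(nrow(df)) *
        prod(arities[ps]) * (arities[[v]] - 1)
    }
    tot
  }
  set.seed(23)
  for (i in 1:5) {
    g <- all_dags(c("A", "B", "C", "D"))[[sample.int(543, 1)]]
    bn <- random_cpts(g, seed = 30 + i)
    d <- forward_sample(bn, 250, seed = 40 + i)
    df <- as.data.frame(d$records)
    df[] <- lapply(df, factor)
    expect_equal(bic_score(d, g), ref_bic(df, g$arcs, d$arities),
                 tolerance = 1e-6)
  }
})

test_that("BDeu matches numeric quadrature on a one-node model", {
  x <- c(rep(1L, 4), rep(0L, 2))
  d <- discrete_dataset(matrix(x, ncol = 1, dimnames = list(NULL, "X")))
  g <- dag("X")
  for (ess in c(1, 2.5)) {
    a <- ess / 2
    marg <- stats::integrate(function(t)
      t^(4 + a - 1) * (1 - t)^(2 + a - 1) / beta(a, a), 0, 1,
      rel.tol = 1e-10)$value
    expect_equal(bdeu_score(d, g, ess), log(marg), tolerance = 1e-4)
  }
  # no data cannot be represented; a single observation has mass 1/2
  d1 <- discrete_dataset(matrix(0L, 1, 1, dimnames = list(NULL, "X")))
  expect_equal(bdeu_score(d1, g, 1), log(0.5), tolerance = 1e-12)
})

test_that("knowledge penalties read the likelihood trees at the graph's states", {
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  d <- forward_sample(random_cpts(g, seed = 50), 100, seed = 51)
  itE <- knowledge_items(7, "A", "B", 1)   # gamma1 = 0.8
  expect_equal(explicit_penalty(g, itE, acc_panel), log(0.8))
  expect_equal(explicit_penalty(g, NULL, acc_panel), 0)
  itV <- knowledge_items(1, "A", "B", 4)   # beta1 = 0.65
  expect_equal(vague_penalty(g, itV, acc_panel), log(0.65))
  expect_error(explicit_penalty(g, itV, acc_panel), "explicit")
  expect_error(vague_penalty(g, itE, acc_panel), "vague")
  # reversing the asserted pair with the not-parent/not-child swap is neutral
  itV2 <- knowledge_items(1, "B", "A", 5)
  g2 <- dag(c("A", "B"), rbind(c("B", "A")))
  expect_equal(vague_penalty(g, knowledge_items(1, "A", "B", 6), acc_panel),
               vague_penalty(g, itV2, acc_panel))
  expect_equal(vague_penalty(g2, itV2, acc_panel),
               vague_penalty(g, knowledge_items(1, "A", "B", 5), acc_panel))
})

test_that("EVBIC reduces to BIC without knowledge and breaks score equivalence", {
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  gr <- dag(c("A", "B"), rbind(c("B", "A")))
  d <- forward_sample(random_cpts(g, seed = 52), 200, seed = 53)
  expect_equal(evbic_score(d, g)$total, bic_score(d, g), tolerance = 1e-9)
  expect_equal(bic_score(d, g), bic_score(d, gr), tolerance = 1e-9)
  it <- knowledge_items(1, "A", "B", 1)
  diff <- evbic_score(d, g, it, acc_panel)$total -
    evbic_score(d, gr, it, acc_panel)$total
  expect_equal(diff, log(0.65 / 0.15), tolerance = 1e-12)
  # k = 0 removes every vague contribution
  itv <- knowledge_items(1, "A", "B", 5)
  expect_equal(evbic_score(d, g, itv, acc_panel, k = 0)$total,
               bic_score(d, g), tolerance = 1e-12)
  br <- evbic_score(d, g, rbind(it, itv), acc_panel, k = 0.5)
  expect_equal(br$total,
               br$data_term + br$explicit_penalty + 0.5 * br$vague_penalty,
               tolerance = 1e-9)
})

test_that("a confident contradicting expert can move the EVBIC optimum", {
  bn <- chain3_bn(0.8)
  d <- forward_sample(bn, 400, seed = 54)
  alld <- all_dags(c("A", "B", "C"))
  expect_length(alld, 25L)
  strong <- data.frame(expert = 1L, gamma1 = 0.99, gamma2 = 0.005,
                       gamma3 = 0.99, beta1 = 0.99, beta2 = 0.005,
                       beta3 = 0.99)
  it <- knowledge_items(1, "B", "A", 1)  # assert B -> A, against the data
  bic_best <- alld[[which.max(sapply(alld, function(g) bic_score(d, g)))]]
  ev_best <- alld[[which.max(sapply(alld, function(g)
    evbic_score(d, g, it, strong)$total))]]
  expect_equal(edge_dir(bic_best, "A", "B"), 1L)
  expect_equal(edge_dir(ev_best, "A", "B"), 2L)
})

test_that("data scores decompose per node", {
  g <- load_fixture("fig1")
  bn <- random_cpts(g, seed = 55)
  d <- forward_sample(bn, 200, seed = 56)
  g2 <- dag(g$nodes, rbind(c("A", "B"), c("B", "C")))  # drop B -> D
  # only D's local term changes
  delta <- bic_score(d, g) - bic_score(d, g2)
  local <- function(gg) {
    counts <- table(factor(d$records[, "D"], 0:1),
                    if (narcs(gg) == 3) factor(d$records[, "B"], 0:1) else
                      rep(1, 200))
    m <- counts[counts > 0]
    tot <- sum(counts * log(counts / rep(colSums(counts),
                                         each = 2)), na.rm = TRUE)
    tot - 0.5 * log(200) * (if (narcs(gg) == 3) 2 else 1)
  }
  expect_equal(delta, local(g) - local(g2), tolerance = 1e-9)
})

test_that("the fast score closure agrees with the reference scorers", {
  g <- load_fixture("fig1")
  bn <- random_cpts(g, seed = 57)
  d <- forward_sample(bn, 300, seed = 58)
  items <- simulate_experts(g, acc_panel, 1, "ev", seed = 59)
  fn <- make_score_fn(d, items, acc_panel, k = 0.5)
  fx <- make_score_fn(d, items, acc_panel, type = "explicit")
  set.seed(60)
  for (i in 1:10) {
    gg <- all_dags(g$nodes)[[sample.int(543, 1)]]
    expect_equal(fn(gg), evbic_score(d, gg, items, acc_panel)$total,
                 tolerance = 1e-9)
    expect_equal(fx(gg), explicit_accuracy_score(d, gg, items, acc_panel),
                 tolerance = 1e-9)
  }
})
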