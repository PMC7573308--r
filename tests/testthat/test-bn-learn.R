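test_that("BIC score matches the hand-computed single-node case", {
  d <- data.frame(x = factor(rep(c("0", "1"), each = 4)))
  s <- bic_score(bn_dag("x"), d)
  expect_equal(s$total, 8 * log(0.5) - log(8) / 2, tolerance = 1e-12)
  expect_equal(s$total, -6.5849, tolerance = 1e-4)
})

test_that("an uninformative parent costs exactly the penalty increment", {
  # y independent of x, with per-configuration frequencies identical
  d <- data.frame(x = factor(rep(c("0", "1"), each = 8)),
                  y = factor(rep(c("0", "0", "0", "1"), 4)))
  empty <- bic_score(bn_dag(c("x", "y")), d)
  with_arc <- bic_score(bn_dag(c("x", "y"), rbind(c("x", "y"))), d)
  # q_y goes 1 -> 2, r_y - 1 = 1: score drops by (ln N)/2
  expect_equal(with_arc$total - empty$total, -log(16) / 2,
               tolerance = 1e-12)
  expect_equal(with_arc$by_node[["x"]], empty$by_node[["x"]])
})

test_that("BIC equals a naive recount on random DAGs and decomposes", {
  set.seed(41)
  nodes <- c("w", "x", "y", "z")
  for (rep in 1:20) {
    d <- random_discrete_data(300, nodes, nlev = sample(2:3, 1))
    g <- random_dag(nodes)
    s <- bic_score(g, d)
    expect_equal(s$total, naive_bic(g, d), tolerance = 1e-9)
    expect_equal(s$total, sum(s$by_node), tolerance = 1e-12)
  }
})

test_that("tabu search matches exhaustive enumeration on 3-node problems", {
  gs <- all_dags3()
  expect_length(gs, 25L)
  set.seed(55)
  hits <- 0L
  for (rep in 1:100) {
    bn <- bn_model(bn_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C"))),
                   list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1")),
                   list(A = binary_cpt(runif(1, 0.2, 0.8)),
                        B = binary_cpt(runif(2, 0.1, 0.9), "A"),
                        C = binary_cpt(runif(2, 0.1, 0.9), "B")))
    d <- sample_from_bn(bn, 1000, seed = rep)
    best <- max(vapply(gs, function(g) bic_score(g, d)$total, numeric(1)))
    got <- attr(tabu_search(d), "score")
    if (abs(got - best) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("tabu search recovers a strong chain and prunes independence", {
  bn <- bn_model(bn_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C"))),
                 list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1")),
                 list(A = binary_cpt(0.5),
                      B = binary_cpt(c(0.1, 0.9), "A"),
                      C = binary_cpt(c(0.15, 0.85), "B")))
  d <- sample_from_bn(bn, 50000, seed = 19)
  fit <- tabu_search(d)
  best <- max(vapply(all_dags3(), function(g) bic_score(g, d)$total,
                     numeric(1)))
  expect_equal(attr(fit, "score"), best, tolerance = 1e-9)
  expect_identical(skeleton_shd(fit, bn$dag), 0L)

  ind <- random_discrete_data(10000, c("A", "B", "C"))
  empty_fit <- tabu_search(ind)
  expect_identical(nrow(empty_fit$arcs), 0L)
})

test_that("constraints are enforced as hard restrictions", {
  bn <- reference_recovery_network()
  d <- sample_from_bn(bn, 5000, seed = 23)
  cs <- bn_constraints(blacklist = rbind(c("a", "b"), c("b", "a")))
  fit <- tabu_search(d, cs)
  arcs <- paste(fit$arcs[, 1], fit$arcs[, 2], sep = "->")
  expect_false(any(c("a->b", "b->a") %in% arcs))
  wl <- bn_constraints(whitelist = rbind(c("f", "a")))
  fit2 <- tabu_search(d, wl)
  expect_true("f->a" %in% paste(fit2$arcs[, 1], fit2$arcs[, 2], sep = "->"))
  # every returned dag is acyclic and scores consistently with bic_score
  expect_true(is_acyclic(fit))
  expect_equal(attr(fit, "score"), bic_score(fit, d)$total,
               tolerance = 1e-9)
})

test_that("bootstrap arc strengths count presence and orientation", {
  ch <- chain_bn(0.5, c(0.05, 0.95))
  d <- sample_from_bn(ch, 4000, seed = 29)
  s <- bootstrap_arc_strengths(d, params = search_params(seed = 1), R = 30)
  expect_s3_class(s, "bn_arc_strength")
  ab <- s[s$from == "A" & s$to == "B", ]
  ba <- s[s$from == "B" & s$to == "A", ]
  # dependence this strong is found in every resample
  expect_equal(ab$strength, 1)
  expect_equal(ab$strength, ba$strength)
  expect_equal(ab$direction + ba$direction, 1)
  # strengths have granularity 1/R
  expect_true(all(abs(s$strength * 30 - round(s$strength * 30)) < 1e-9))
  # reproducible under the seed
  s2 <- bootstrap_arc_strengths(d, params = search_params(seed = 1), R = 30)
  expect_identical(s, s2)
  expect_error(bootstrap_arc_strengths(d, R = 0), "R")
})

test_that("averaged networks threshold, orient and stay acyclic", {
  skel <- data.frame(from = c("A", "B", "B", "C"),
                     to = c("B", "A", "C", "B"),
                     strength = c(0.9, 0.9, 0.6, 0.6),
                     direction = c(0.8, 0.2, 0.5, 0.5))
  s <- structure(skel, R = 10L, nodes = c("A", "B", "C"),
                 class = c("bn_arc_strength", "data.frame"))
  g85 <- average_network(s, 0.85)
  expect_identical(unname(g85$arcs), matrix(c("A", "B"), 1))
  g50 <- average_network(s, 0.5)
  expect_gte(nrow(g50$arcs), nrow(g85$arcs))  # monotone in threshold
  # direction tie at 0.5 goes to the lexicographically smaller source
  expect_true("B" %in% g50$arcs[, 1] & "C" %in% g50$arcs[, 2])

  # a directed cycle after orientation drops its weakest arc
  rps <- data.frame(
    from = c("A", "B", "B", "C", "C", "A"),
    to = c("B", "A", "C", "B", "A", "C"),
    strength = c(0.9, 0.9, 0.8, 0.8, 0.7, 0.7),
    direction = c(1, 0, 1, 0, 1, 0))
  s3 <- structure(rps, R = 10L, nodes = c("A", "B", "C"),
                  class = c("bn_arc_strength", "data.frame"))
  g <- average_network(s3, 0.5)
  expect_true(is_acyclic(g))
  arcs <- paste(g$arcs[, 1], g$arcs[, 2], sep = "->")
  # the weakest cycle arc (C->A, 0.7) is the one dropped
  expect_setequal(arcs, c("A->B", "B->C"))
  expect_error(average_network(s3, 0), "threshold")
})

test_that("degenerate resampling yields strength and direction one", {
  # two-point data where the learner always finds the same arc
  ch <- chain_bn(0.5, c(0.02, 0.98))
  d <- sample_from_bn(ch, 2000, seed = 31)
  s <- bootstrap_arc_strengths(d, params = search_params(seed = 9), R = 15)
  ab <- s[s$from == "A" & s$to == "B", ]
  expect_equal(ab$strength, 1)
  expect_equal(ab$direction, 1)
})
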