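test_that("CPT fitting gives MLE, Laplace and uniform-fallback rows", {
  d <- data.frame(x = factor(c("1", "1", "1", "0"), levels = c("0", "1")))
  g <- bn_dag("x")
  mle <- fit_cpts(g, d, alpha = 0)
  expect_equal(unname(mle$cpts$x[1, ]), c(0.25, 0.75))
  lap <- fit_cpts(g, d, alpha = 1)
  expect_equal(unname(lap$cpts$x[1, ]), c(2 / 6, 4 / 6))
  # unseen parent configuration -> uniform row with warning
  d2 <- data.frame(a = factor(c("0", "0"), levels = c("0", "1")),
                   b = factor(c("0", "1")))
  g2 <- bn_dag(c("a", "b"), rbind(c("a", "b")))
  expect_warning(m2 <- fit_cpts(g2, d2, alpha = 0), "unobserved")
  expect_equal(unname(m2$cpts$b[2, ]), c(0.5, 0.5))
  expect_error(fit_cpts(g, d, alpha = -1), "alpha")
})

test_that("CPT rows are distributions and models validate shape", {
  bn <- reference_reasoning_network()
  for (v in bn$dag$nodes)
    expect_true(all(abs(rowSums(bn$cpts[[v]]) - 1) < 1e-9), label = v)
  expect_error(bn_model(bn$dag, bn$levels,
                        modifyList(bn$cpts,
                                   list(sex = matrix(c(0.7, 0.7), 1)))),
               "summing to 1")
  bad <- bn$cpts
  bad$diabetes <- bad$diabetes[1:3, ]
  attr(bad$diabetes, "parents") <- "components"
  expect_error(bn_model(bn$dag, bn$levels, bad), "must be")
})

test_that("joint probability multiplies along the factorization", {
  ch <- chain_bn(0.3, c(0.2, 0.5))
  expect_equal(joint_probability(ch, list(A = "1", B = "1")), 0.15)
  expect_equal(joint_probability(ch, list(A = "0", B = "0")), 0.7 * 0.8)
  # normalization over all full assignments
  grid <- expand.grid(A = c("0", "1"), B = c("0", "1"),
                      stringsAsFactors = FALSE)
  tot <- sum(vapply(seq_len(4), function(i)
    joint_probability(ch, as.list(grid[i, ])), numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
  # zero-probability factor annihilates
  z <- bn_model(bn_dag("A"), list(A = c("0", "1")),
                list(A = binary_cpt(0)))
  expect_equal(joint_probability(z, list(A = "1")), 0)
  expect_error(joint_probability(ch, list(A = "2", B = "0")), "unknown")
  expect_error(joint_probability(ch, list(A = "1")), "every node")
})

test_that("exact queries condition, marginalize and detect bad evidence", {
  ch <- chain_bn(0.3, c(0.2, 0.5))
  q <- exact_query(ch, "B", list(A = "1"))
  expect_equal(unname(q$distribution), c(0.5, 0.5))
  marg <- exact_query(ch, "B")
  expect_equal(marg$distribution[["1"]], 0.5 * 0.3 + 0.2 * 0.7)
  expect_equal(sum(marg$distribution), 1, tolerance = 1e-12)
  z <- bn_model(bn_dag("A"), list(A = c("0", "1")), list(A = binary_cpt(0)))
  expect_no_error(exact_query(z, "A", list()))
  two <- bn_model(bn_dag(c("A", "B"), rbind(c("A", "B"))),
                  list(A = c("0", "1"), B = c("0", "1")),
                  list(A = binary_cpt(0), B = binary_cpt(c(0.5, 0.5), "A")))
  expect_error(exact_query(two, "B", list(A = "1")), "zero probability")
  expect_error(exact_query(ch, "B", list(B = "1")), "target")
  expect_error(exact_query(ch, "D", list()), "unknown target")
})

test_that("exact queries equal full-joint-table conditioning", {
  nets <- list(collider_bn(), reference_reasoning_network())
  cases <- list(
    list(net = 1, target = "X", evidence = list(Z = "1")),
    list(net = 1, target = "Y", evidence = list(W = "1", X = "0")),
    list(net = 1, target = "W", evidence = list()),
    list(net = 2, target = "hyperuricemia",
         evidence = list(bmi_group = "obese", components = "0")),
    list(net = 2, target = "diabetes",
         evidence = list(hyperuricemia = "yes", sex = "female")))
  for (cs in cases) {
    bn <- nets[[cs$net]]
    got <- exact_query(bn, cs$target, cs$evidence)$distribution
    want <- joint_table_query(bn, cs$target, cs$evidence)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("likelihood weighting agrees with exact inference", {
  bn <- collider_bn()
  ex <- exact_query(bn, "X", list(W = "1"))
  lw <- lw_query(bn, "X", list(W = "1"), n_samples = 200000, seed = 5)
  expect_lt(abs(lw$distribution[["1"]] - ex$distribution[["1"]]),
            3 * lw$mc_error[["1"]])
  # empty evidence reduces to forward-sampling frequencies
  lw0 <- lw_query(bn, "W", list(), n_samples = 50000, seed = 6)
  d <- sample_from_bn(bn, 50000, seed = 6)
  expect_equal(lw0$distribution[["1"]], mean(d$W == "1"), tolerance = 1e-12)
  # determinism
  expect_equal(lw_query(bn, "X", list(W = "1"), 1000, seed = 8),
               lw_query(bn, "X", list(W = "1"), 1000, seed = 8))
  two <- bn_model(bn_dag(c("A", "B"), rbind(c("A", "B"))),
                  list(A = c("0", "1"), B = c("0", "1")),
                  list(A = binary_cpt(0), B = binary_cpt(c(0.5, 0.5), "A")))
  expect_error(lw_query(two, "B", list(A = "1"), 100, seed = 1),
               "zero probability")
})

test_that("LW coverage of the 3-SE band is calibrated", {
  bn <- collider_bn()
  ex <- exact_query(bn, "Y", list(Z = "1"))$distribution[["1"]]
  inside <- 0L
  for (s in 1:100) {
    lw <- lw_query(bn, "Y", list(Z = "1"), n_samples = 4000, seed = s)
    if (abs(lw$distribution[["1"]] - ex) <= 3 * lw$mc_error[["1"]])
      inside <- inside + 1L
  }
  expect_gte(inside, 99L)
})

test_that("CPT refit on forward samples recovers every entry", {
  bn <- collider_bn()
  d <- sample_from_bn(bn, 100000, seed = 44)
  refit <- fit_cpts(bn$dag, d, alpha = 0)
  for (v in bn$dag$nodes)
    expect_lt(max(abs(bn$cpts[[v]] - refit$cpts[[v]])), 0.01)

  # larger network: entries of adequately populated rows recover too
  hu <- reference_reasoning_network()
  dh <- sample_from_bn(hu, 100000, seed = 45)
  refit_hu <- suppressWarnings(fit_cpts(hu$dag, dh, alpha = 0))
  counts <- table(dh$sex, dh$bmi_group, dh$components, dh$diabetes)
  grid <- expand.grid(s = 1:2, b = 1:3, k = 1:5, dd = 1:2)
  rowcount <- counts[as.matrix(grid)]
  dev <- abs(hu$cpts$hyperuricemia - refit_hu$cpts$hyperuricemia)[, "yes"]
  expect_lt(max(dev[rowcount >= 1000]), 0.05)
})

test_that("reasoning tables order scenarios and are pure", {
  bn <- reference_reasoning_network()
  scen <- list(list(bmi_group = "normal", components = "0"),
               list(),
               list(bmi_group = "normal", components = "0"))
  tab <- reasoning_table(bn, scen)
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$probability[1], 0.05, tolerance = 1e-9)
  expect_identical(tab$probability[1], tab$probability[3])
  expect_identical(tab$evidence[2], "(marginal)")
  # risk is monotone in the component count at fixed BMI group
  probs <- vapply(as.character(0:4), function(k)
    exact_query(bn, "hyperuricemia",
                list(bmi_group = "obese",
                     components = k))$distribution[["yes"]], numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("fitted models serialize to JSON and back identically", {
  bn <- reference_reasoning_network()
  d <- sample_from_bn(bn, 2000, seed = 3)
  # at n = 2000 some of the 60 parent configurations go unseen; the
  # uniform-row fallback warning is expected
  fit <- suppressWarnings(fit_cpts(bn$dag, d))
  path <- withr::local_tempfile(fileext = ".json")
  write_bn_model(fit, path)
  back <- read_bn_model(path)
  expect_identical(back$dag$nodes, fit$dag$nodes)
  expect_equal(back$cpts, fit$cpts, tolerance = 1e-12)
  q1 <- exact_query(fit, "hyperuricemia", list(sex = "female"))
  q2 <- exact_query(back, "hyperuricemia", list(sex = "female"))
  expect_equal(q1$distribution, q2$distribution, tolerance = 1e-12)
})
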