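# Independent oracles used across tests: a table()-based BIC recount, a
# full-joint-table conditioner, exhaustive DAG enumeration for 3 nodes, and
# small hand-built networks.

naive_bic <- function(dag, data) {
  n <- nrow(data)
  ps <- parent_sets(dag)
  total <- 0
  for (v in dag$nodes) {
    x <- factor(data[[v]])
    r <- nlevels(x)
    if (length(ps[[v]])) {
      pa <- interaction(lapply(data[ps[[v]]], factor), drop = FALSE)
      tab <- table(pa, x)
      q <- prod(vapply(data[ps[[v]]],
                       function(z) nlevels(factor(z)), integer(1)))
    } else {
      tab <- matrix(table(x), nrow = 1)
      q <- 1
    }
    ll <- 0
    for (j in seq_len(nrow(tab))) {
      nj <- sum(tab[j, ])
      if (nj > 0) for (k in seq_len(ncol(tab))) {
        njk <- tab[j, k]
        if (njk > 0) ll <- ll + njk * log(njk / nj)
      }
    }
    total <- total + ll - log(n) / 2 * q * (r - 1)
  }
  total
}

# P(target | evidence) by materializing the full joint table
joint_table_query <- function(bn, target, evidence = list()) {
  grid <- expand.grid(bn$levels, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  p <- vapply(seq_len(nrow(grid)), function(i)
    joint_probability(bn, as.list(grid[i, , drop = FALSE])), numeric(1))
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence))
    keep <- keep & grid[[v]] == as.character(evidence[[v]])
  lev <- bn$levels[[target]]
  num <- vapply(lev, function(k)
    sum(p[keep & grid[[target]] == k]), numeric(1))
  num / sum(p[keep])
}

# all 25 DAGs on three labeled nodes
all_dags3 <- function(nodes = c("A", "B", "C")) {
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  out <- list()
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    arcs <- NULL
    st <- c(s1, s2, s3)
    for (i in 1:3) if (st[i] > 0) {
      pr <- pairs[[i]]
      arcs <- rbind(arcs, if (st[i] == 1) c(nodes[pr[1]], nodes[pr[2]])
                    else c(nodes[pr[2]], nodes[pr[1]]))
    }
    g <- tryCatch(bn_dag(nodes, arcs), error = function(e) NULL)
    if (!is.null(g)) out <- c(out, list(g))
  }
  out
}

binary_cpt <- function(p1, parents = NULL) {
  m <- cbind(1 - p1, p1)
  if (!is.null(parents)) attr(m, "parents") <- parents
  m
}

# A -> B chain with binary nodes
chain_bn <- function(pa = 0.3, pb_given = c(0.2, 0.5)) {
  dag <- bn_dag(c("A", "B"), rbind(c("A", "B")))
  bn_model(dag, list(A = c("0", "1"), B = c("0", "1")),
           list(A = binary_cpt(pa), B = binary_cpt(pb_given, "A")))
}

# X -> Z <- Y collider plus Z -> W
collider_bn <- function() {
  dag <- bn_dag(c("X", "Y", "Z", "W"),
                rbind(c("X", "Z"), c("Y", "Z"), c("Z", "W")))
  lv <- list(X = c("0", "1"), Y = c("0", "1"), Z = c("0", "1"),
             W = c("0", "1"))
  # Z rows in (X, Y) order, X varying fastest
  bn_model(dag, lv, list(
    X = binary_cpt(0.4), Y = binary_cpt(0.7),
    Z = binary_cpt(c(0.1, 0.6, 0.5, 0.9), c("X", "Y")),
    W = binary_cpt(c(0.2, 0.8), "Z")))
}

# random DAG over the given nodes (random order, arc probability pr)
random_dag <- function(nodes, pr = 0.5) {
  ord <- sample(nodes)
  arcs <- NULL
  for (i in seq_along(ord)) for (j in seq_len(i - 1L))
    if (runif(1) < pr) arcs <- rbind(arcs, c(ord[j], ord[i]))
  bn_dag(nodes, arcs)
}

# random discrete data frame (independent columns)
random_discrete_data <- function(n, nodes, nlev = 2L) {
  out <- lapply(nodes, function(v)
    factor(sample(seq_len(nlev), n, replace = TRUE)))
  names(out) <- nodes
  as.data.frame(out)
}

# women-only two-arm generator spec used in odds-ratio recovery tests
two_arm_spec <- function(n, or_mho, baseline_p = 0.04, seed = 1L) {
  pp <- cbind(male = c(0.5, 0, 0.5, 0, 0, 0),
              female = c(0.5, 0, 0.5, 0, 0, 0))
  rownames(pp) <- phenotype_levels()
  om <- list(baseline_p = baseline_p,
             log_or = setNames(c(0, 0, log(or_mho), 0, 0, 0),
                               phenotype_levels()))
  generator_spec(n_subjects = n, female_fraction = 1,
                 phenotype_probs_by_sex = pp, or_model = om, seed = seed)
}

minimal_cohort <- function(n = 20, seed = 123) {
  sample_cohort(generator_spec(n_subjects = n, seed = seed))
}
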