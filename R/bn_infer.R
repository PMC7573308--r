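## CPT convention: for a node with parents (p1, ..., pk) in the stored order,
## rows index parent configurations in mixed radix with the FIRST parent
## varying fastest; columns index the node's own levels.  A parentless node
## has a single row.

.cpt_row_index <- function(parent_codes, parent_nlev) {
  if (length(parent_nlev) == 0L)
    return(rep.int(1L, if (is.matrix(parent_codes)) nrow(parent_codes) else 1L))
  if (!is.matrix(parent_codes)) parent_codes <- matrix(parent_codes, nrow = 1L)
  stride <- cumprod(c(1L, parent_nlev[-length(parent_nlev)]))
  as.integer(1L + (parent_codes - 1L) %*% stride)
}

#' Construct a discrete Bayesian network model
#'
#' Bundles a DAG, the level labels of every node, and one conditional
#' probability table per node.  Each CPT is a numeric matrix with one column
#' per level of the node and one row per configuration of its parents (first
#' parent varying fastest; a single row when parentless); rows must sum to 1
#' within 1e-9.  The parent ordering of a CPT may be fixed via its
#' `"parents"` attribute and defaults to the DAG's arc order.
#'
#' @param dag a [bn_dag()].
#' @param levels named list mapping every node to its character level labels.
#' @param cpts named list of CPT matrices, one per node.
#' @return an object of class `bn_model`.
#' @export
bn_model <- function(dag, levels, cpts) {
  if (!inherits(dag, "bn_dag")) stop("'dag' must be a bn_dag")
  if (!setequal(names(levels), dag$nodes) || !setequal(names(cpts), dag$nodes))
    stop("'levels' and 'cpts' must name exactly the DAG's nodes")
  levels <- lapply(levels[dag$nodes], as.character)
  ps <- parent_sets(dag)
  cpts <- cpts[dag$nodes]
  for (v in dag$nodes) {
    cpt <- as.matrix(cpts[[v]])
    parents <- attr(cpts[[v]], "parents")
    if (is.null(parents)) parents <- ps[[v]]
    if (!setequal(parents, ps[[v]]))
      stop("CPT parents of '", v, "' disagree with the DAG")
    q <- prod(vapply(levels[parents], length, integer(1L)))
    r <- length(levels[[v]])
    if (nrow(cpt) != q || ncol(cpt) != r)
      stop("CPT of '", v, "' must be ", q, " x ", r)
    if (any(cpt < 0) || any(cpt > 1) ||
        any(abs(rowSums(cpt) - 1) > 1e-9))
      stop("CPT rows of '", v, "' must be distributions summing to 1")
    attr(cpt, "parents") <- as.character(parents)
    colnames(cpt) <- levels[[v]]
    cpts[[v]] <- cpt
  }
  structure(list(dag = dag, levels = levels, cpts = cpts),
            class = "bn_model")
}

#' @export
print.bn_model <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$dag$nodes), "nodes,",
      nrow(x$dag$arcs), "arcs\n")
  for (v in x$dag$nodes) {
    pa <- attr(x$cpts[[v]], "parents")
    cat("  ", v, " (", length(x$levels[[v]]), " levels",
        if (length(pa)) paste0("; parents: ", paste(pa, collapse = ", ")),
        ")\n", sep = "")
  }
  invisible(x)
}

.model_codes <- function(bn, data) {
  vapply(bn$dag$nodes, function(v) {
    x <- as.character(data[[v]])
    code <- match(x, bn$levels[[v]])
    if (anyNA(code))
      stop("unknown level(s) for '", v, "': ",
           paste(unique(x[is.na(code)]), collapse = ", "))
    code
  }, integer(nrow(data)))
}

#' Fit conditional probability tables on a fixed DAG
#'
#' Maximum-likelihood (or Laplace-smoothed) CPT estimation:
#' \eqn{P(X_i = k \mid j) = (N_{ijk} + \alpha) / (N_{ij\cdot} + \alpha r_i)}.
#' With `alpha = 0`, a parent configuration never observed in the data gets a
#' uniform row and a warning.
#'
#' @param dag a `bn_dag` whose nodes are columns of `data`.
#' @param data complete data frame of factors.
#' @param alpha pseudo-count \eqn{\alpha \ge 0}; 0 gives the MLE, 1 Laplace
#'   smoothing.
#' @return a [bn_model()].
#' @export
fit_cpts <- function(dag, data, alpha = 0) {
  if (!is.numeric(alpha) || alpha < 0) stop("'alpha' must be >= 0")
  data <- .as_discrete(data[dag$nodes])
  levels <- lapply(data, levels)
  ps <- parent_sets(dag)
  codes <- vapply(data, as.integer, integer(nrow(data)))
  cpts <- list()
  for (v in dag$nodes) {
    parents <- ps[[v]]
    r <- length(levels[[v]])
    pnlev <- vapply(levels[parents], length, integer(1L))
    q <- prod(pnlev)
    j <- .cpt_row_index(codes[, parents, drop = FALSE], pnlev)
    cell <- (j - 1L) * r + codes[, v]
    counts <- matrix(tabulate(cell, nbins = q * r), nrow = r)
    cpt <- t(counts) + alpha
    tot <- rowSums(cpt)
    if (any(tot == 0)) {
      warning("node '", v, "': ", sum(tot == 0),
              " unobserved parent configuration(s); using uniform rows")
      cpt[tot == 0, ] <- 1
      tot <- rowSums(cpt)
    }
    cpt <- cpt / tot
    attr(cpt, "parents") <- parents
    cpts[[v]] <- cpt
  }
  bn_model(dag, levels, cpts)
}

## probability of each row of a full code matrix (columns in dag node order)
.joint_prob_codes <- function(bn, codes) {
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = 1L)
  colnames(codes) <- bn$dag$nodes
  p <- rep(1, nrow(codes))
  for (v in bn$dag$nodes) {
    cpt <- bn$cpts[[v]]
    parents <- attr(cpt, "parents")
    pnlev <- vapply(bn$levels[parents], length, integer(1L))
    j <- .cpt_row_index(codes[, parents, drop = FALSE], pnlev)
    p <- p * cpt[cbind(j, codes[, v])]
  }
  p
}

#' Joint probability of a full assignment
#'
#' Evaluates the factorization
#' \eqn{P(X) = \prod_i P(X_i \mid Pa(X_i))} at one complete assignment.
#'
#' @param bn a `bn_model`.
#' @param assignment named list or character vector giving a level for every
#'   node.
#' @return a probability.
#' @export
joint_probability <- function(bn, assignment) {
  assignment <- unlist(assignment)
  if (!setequal(names(assignment), bn$dag$nodes))
    stop("'assignment' must cover every node exactly once")
  codes <- vapply(bn$dag$nodes, function(v) {
    k <- match(assignment[[v]], bn$levels[[v]])
    if (is.na(k))
      stop("unknown level '", assignment[[v]], "' for node '", v, "'")
    k
  }, integer(1L))
  .joint_prob_codes(bn, matrix(codes, nrow = 1L))
}

.check_evidence <- function(bn, target, evidence) {
  evidence <- as.list(evidence)
  if (length(evidence) && (is.null(names(evidence)) ||
                           any(!nzchar(names(evidence)))))
    stop("'evidence' must be a named list")
  bad <- setdiff(names(evidence), bn$dag$nodes)
  if (length(bad)) stop("unknown evidence node(s): ",
                        paste(bad, collapse = ", "))
  if (!target %in% bn$dag$nodes) stop("unknown target node '", target, "'")
  if (target %in% names(evidence))
    stop("the target may not appear in the evidence")
  for (v in names(evidence)) {
    if (is.na(match(as.character(evidence[[v]]), bn$levels[[v]])))
      stop("unknown level '", evidence[[v]], "' for node '", v, "'")
  }
  evidence
}

#' Exact conditional-probability query
#'
#' Computes \eqn{P(target \mid evidence)} by enumerating all completions of
#' the evidence, summing joint probabilities, and normalizing.  Intended for
#' the small discrete networks this package works with (the free state space
#' must not exceed ~5e6 configurations).
#'
#' @param bn a `bn_model`.
#' @param target node whose distribution is queried.
#' @param evidence named list of observed levels (possibly empty).
#' @return a `bn_query` object with the conditional `distribution` over the
#'   target's levels.
#' @export
exact_query <- function(bn, target, evidence = list()) {
  evidence <- .check_evidence(bn, target, evidence)
  nodes <- bn$dag$nodes
  free <- setdiff(nodes, names(evidence))
  sizes <- vapply(bn$levels[free], length, integer(1L))
  if (prod(sizes) > 5e6)
    stop("free state space too large for enumeration")
  grid <- do.call(expand.grid, c(lapply(sizes, seq_len),
                                 KEEP.OUT.ATTRS = FALSE))
  codes <- matrix(1L, nrow(grid), length(nodes),
                  dimnames = list(NULL, nodes))
  for (i in seq_along(free)) codes[, free[i]] <- grid[[i]]
  for (v in names(evidence))
    codes[, v] <- match(as.character(evidence[[v]]), bn$levels[[v]])
  p <- .joint_prob_codes(bn, codes)
  tot <- sum(p)
  if (tot <= 0)
    stop("evidence has zero probability under the model")
  dist <- vapply(seq_along(bn$levels[[target]]), function(k)
    sum(p[codes[, target] == k]), numeric(1L)) / tot
  structure(list(target = target, evidence = evidence,
                 distribution = setNames(dist, bn$levels[[target]]),
                 method = "exact", mc_error = NULL),
            class = "bn_query")
}

#' @export
print.bn_query <- function(x, ...) {
  ev <- if (length(x$evidence))
    paste(names(x$evidence), unlist(x$evidence), sep = " = ",
          collapse = ", ") else "(none)"
  cat("P(", x$target, " | ", ev, ") by ", x$method, ":\n", sep = "")
  print(round(x$distribution, 6))
  if (!is.null(x$mc_error))
    cat("MC standard errors:", paste(signif(x$mc_error, 3), collapse = " "),
        "\n")
  invisible(x)
}

#' Likelihood-weighting query
#'
#' Importance-sampling estimate of \eqn{P(target \mid evidence)}: evidence
#' nodes are clamped and each sample weighted by the product of the evidence
#' nodes' CPT entries given the sampled parents.  Serves as an independent
#' stochastic cross-check of [exact_query()].
#'
#' @inheritParams exact_query
#' @param n_samples number of weighted samples (>= 1).
#' @param seed integer seed; the estimate is reproducible given the seed.
#' @return a `bn_query` with Monte-Carlo standard errors in `mc_error`.
#' @export
lw_query <- function(bn, target, evidence = list(), n_samples = 10000L,
                     seed = 1L) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop("'n_samples' must be a count >= 1")
  evidence <- .check_evidence(bn, target, evidence)
  set.seed(seed)
  nodes <- bn$dag$nodes
  ord <- topological_order(nodes, bn$dag$arcs)
  codes <- matrix(1L, n_samples, length(nodes),
                  dimnames = list(NULL, nodes))
  logw <- numeric(n_samples)
  for (v in ord) {
    cpt <- bn$cpts[[v]]
    parents <- attr(cpt, "parents")
    pnlev <- vapply(bn$levels[parents], length, integer(1L))
    j <- .cpt_row_index(codes[, parents, drop = FALSE], pnlev)
    if (v %in% names(evidence)) {
      k <- match(as.character(evidence[[v]]), bn$levels[[v]])
      codes[, v] <- k
      logw <- logw + log(cpt[cbind(j, k)])
    } else {
      pr <- cpt[j, , drop = FALSE]
      cum <- pr %*% upper.tri(diag(ncol(pr)), diag = TRUE)
      codes[, v] <- 1L + as.integer(rowSums(runif(n_samples) > cum))
      codes[codes[, v] > ncol(pr), v] <- ncol(pr)
    }
  }
  w <- exp(logw)
  W <- sum(w)
  if (W <= 0) stop("evidence has zero probability under the model")
  lev <- bn$levels[[target]]
  dist <- vapply(seq_along(lev), function(k)
    sum(w[codes[, target] == k]), numeric(1L)) / W
  se <- vapply(seq_along(lev), function(k) {
    ind <- as.numeric(codes[, target] == k)
    sqrt(sum((w * (ind - dist[k]))^2)) / W
  }, numeric(1L))
  structure(list(target = target, evidence = evidence,
                 distribution = setNames(dist, lev),
                 method = "likelihood-weighting",
                 mc_error = setNames(se, lev), n_samples = n_samples),
            class = "bn_query")
}

#' Conditional-probability reasoning table
#'
#' Runs [exact_query()] once per evidence scenario and tabulates the
#' probability of the chosen event level, mirroring how reasoning over a
#' fitted network reads out hyperuricemia risk under combinations of BMI
#' group, metabolic-component count, sex and diabetes.
#'
#' @param bn a `bn_model`.
#' @param scenarios list of named evidence lists (an empty list queries the
#'   marginal).
#' @param target node queried (default `"hyperuricemia"`).
#' @param event level of `target` whose probability is reported (default
#'   `"yes"`).
#' @return data frame with one row per scenario: the evidence rendered as
#'   text and the event probability.
#' @export
reasoning_table <- function(bn, scenarios, target = "hyperuricemia",
                            event = "yes") {
  rows <- lapply(scenarios, function(ev) {
    q <- exact_query(bn, target, ev)
    data.frame(evidence = if (length(ev))
      paste(names(ev), unlist(ev), sep = " = ", collapse = ", ")
      else "(marginal)",
      probability = unname(q$distribution[[event]]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Forward-sample records from a Bayesian network
#'
#' Ancestral sampling in a topological order: each node is drawn from its CPT
#' row given its already-sampled parents.  The same seed reproduces the same
#' table.
#'
#' @param bn a `bn_model`.
#' @param n number of records (>= 1).
#' @param seed integer seed.
#' @return data frame of factors with one column per node.
#' @export
sample_from_bn <- function(bn, n, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a count >= 1")
  set.seed(seed)
  nodes <- bn$dag$nodes
  ord <- topological_order(nodes, bn$dag$arcs)
  if (is.null(ord)) stop("network graph is cyclic")
  codes <- matrix(1L, n, length(nodes), dimnames = list(NULL, nodes))
  for (v in ord) {
    cpt <- bn$cpts[[v]]
    parents <- attr(cpt, "parents")
    pnlev <- vapply(bn$levels[parents], length, integer(1L))
    j <- .cpt_row_index(codes[, parents, drop = FALSE], pnlev)
    pr <- cpt[j, , drop = FALSE]
    cum <- pr %*% upper.tri(diag(ncol(pr)), diag = TRUE)
    codes[, v] <- 1L + as.integer(rowSums(runif(n) > cum))
    codes[codes[, v] > ncol(pr), v] <- ncol(pr)
  }
  out <- as.data.frame(lapply(setNames(nodes, nodes), function(v)
    factor(bn$levels[[v]][codes[, v]], levels = bn$levels[[v]])))
  out
}
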