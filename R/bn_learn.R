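## Discrete data are collapsed to distinct configurations with multiplicities
## before scoring: family counts then cost O(#distinct rows) rather than O(n),
## and a nonparametric bootstrap reduces to a multinomial draw on the
## multiplicities.

.as_discrete <- function(data) {
  if (!is.data.frame(data) || ncol(data) < 1L)
    stop("'data' must be a data frame of discrete variables")
  data[] <- lapply(data, function(x) if (is.factor(x)) x else factor(x))
  if (anyNA(data))
    stop("'data' must be complete (no missing values)")
  data
}

.collapse_data <- function(data) {
  data <- .as_discrete(data)
  codes <- vapply(data, as.integer, integer(nrow(data)))
  if (nrow(data) == 1L) codes <- matrix(codes, nrow = 1L)
  key <- do.call(paste, c(as.data.frame(codes), sep = "\r"))
  first <- !duplicated(key)
  configs <- codes[first, , drop = FALSE]
  weights <- as.numeric(tabulate(match(key, key[first]), nbins = sum(first)))
  list(configs = configs, weights = weights,
       levels = lapply(data, levels),
       nlev = vapply(data, nlevels, integer(1L)))
}

#' Search parameters for Tabu structure learning
#'
#' @param tabu_tenure number of iterations for which the pair touched by an
#'   applied move stays tabu (default 10).
#' @param max_iterations hard cap on search iterations.
#' @param max_no_improvement stop after this many consecutive iterations
#'   without improving the incumbent (default 50).
#' @param restarts number of searches; restarts beyond the first start from a
#'   randomly perturbed graph and require a `seed`.
#' @param seed integer seed used for restarts and by callers that resample.
#' @return a validated `bn_search_params` list.
#' @export
search_params <- function(tabu_tenure = 10L, max_iterations = 500L,
                          max_no_improvement = 50L, restarts = 1L,
                          seed = NULL) {
  p <- list(tabu_tenure = as.integer(tabu_tenure),
            max_iterations = as.integer(max_iterations),
            max_no_improvement = as.integer(max_no_improvement),
            restarts = as.integer(restarts), seed = seed)
  for (f in c("tabu_tenure", "max_iterations", "max_no_improvement",
              "restarts"))
    if (is.na(p[[f]]) || p[[f]] < 1L)
      stop("'", f, "' must be a count >= 1")
  structure(p, class = "bn_search_params")
}

.constraint_matrices <- function(nodes, constraints) {
  p <- length(nodes)
  bl <- wl <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(constraints)) {
    if (!inherits(constraints, "bn_constraints"))
      stop("'constraints' must be a bn_constraints object")
    for (m in list(constraints$blacklist, constraints$whitelist))
      if (nrow(m) && any(!(m %in% nodes)))
        stop("constraint endpoints not in data: ",
             paste(setdiff(unique(c(m)), nodes), collapse = ", "))
    if (nrow(constraints$blacklist)) bl[constraints$blacklist] <- TRUE
    if (nrow(constraints$whitelist)) wl[constraints$whitelist] <- TRUE
  }
  list(blacklist = bl, whitelist = wl)
}

#' BIC score of a DAG on discrete data
#'
#' Natural-log BIC, decomposable over nodes: for node \eqn{i} with \eqn{r_i}
#' levels and \eqn{q_i} parent configurations,
#' \deqn{score_i = \sum_{j,k} N_{ijk} \ln(N_{ijk}/N_{ij\cdot})
#'   - \frac{\ln N}{2}\, q_i (r_i - 1),}
#' with \eqn{0 \ln 0 = 0}; the total is the sum over nodes and higher is
#' better.
#'
#' @param dag a `bn_dag` whose nodes are columns of `data`.
#' @param data complete data frame of factors.
#' @return list with elements `total` (numeric) and `by_node` (named numeric
#'   vector of per-node scores).
#' @export
bic_score <- function(dag, data) {
  if (!inherits(dag, "bn_dag")) stop("'dag' must be a bn_dag")
  missing_cols <- setdiff(dag$nodes, names(data))
  if (length(missing_cols))
    stop("data lacks node column(s): ", paste(missing_cols, collapse = ", "))
  cd <- .collapse_data(data[dag$nodes])
  ps <- parent_sets(dag)
  idx <- setNames(seq_along(dag$nodes) - 1L, dag$nodes)
  by_node <- vapply(dag$nodes, function(v)
    .family_bic_cpp(cd$configs, cd$weights, idx[[v]],
                    as.integer(idx[ps[[v]]]), as.integer(cd$nlev)),
    numeric(1L))
  list(total = sum(by_node), by_node = by_node)
}

.learn_one <- function(cd, bl, wl, params, start = NULL) {
  nodes <- names(cd$nlev)
  if (is.null(start)) start <- wl
  res <- .tabu_search_cpp(cd$configs, cd$weights, as.integer(cd$nlev),
                          bl, wl, start,
                          params$tabu_tenure, params$max_iterations,
                          params$max_no_improvement)
  adj <- res$adjacency
  arcs <- which(adj, arr.ind = TRUE)
  arcs <- cbind(from = nodes[arcs[, 1L]], to = nodes[arcs[, 2L]])
  list(arcs = as_arc_matrix(arcs[order(arcs[, 1L], arcs[, 2L]), ,
                                 drop = FALSE]),
       score = res$score)
}

#' Learn a DAG by Tabu search with BIC scoring
#'
#' Local search over single-arc additions, deletions and reversals.  The
#' search starts from the whitelist-only graph; moves creating cycles, adding
#' blacklisted arcs, or removing whitelisted arcs are inadmissible.  Each
#' iteration applies the best admissible neighbour even when it worsens the
#' score; the pair just changed is tabu for `tabu_tenure` iterations unless
#' revisiting it would beat the incumbent (aspiration).  Candidate moves are
#' enumerated lexicographically by (from, to, add < delete < reverse), so the
#' search is deterministic for a single start.
#'
#' @param data complete data frame of factors.
#' @param constraints optional [bn_constraints()].
#' @param params a [search_params()] list.
#' @return the best `bn_dag` found, with the achieved BIC in attribute
#'   `"score"`.
#' @export
tabu_search <- function(data, constraints = NULL, params = search_params()) {
  cd <- .collapse_data(data)
  nodes <- names(cd$nlev)
  cm <- .constraint_matrices(nodes, constraints)
  best <- .learn_one(cd, cm$blacklist, cm$whitelist, params)
  if (params$restarts > 1L) {
    if (is.null(params$seed))
      stop("'seed' is required when restarts > 1")
    set.seed(params$seed)
    p <- length(nodes)
    for (r in seq_len(params$restarts - 1L)) {
      start <- cm$whitelist
      cand <- which(!cm$blacklist & !diag(p) & !start, arr.ind = TRUE)
      cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
      g <- bn_dag(nodes, NULL)
      for (i in seq_len(min(p, nrow(cand)))) {
        u <- nodes[cand[i, 1L]]; v <- nodes[cand[i, 2L]]
        trial <- rbind(g$arcs, c(u, v))
        if (!is.null(topological_order(nodes, trial))) g$arcs <- trial
      }
      start[g$arcs] <- TRUE
      run <- .learn_one(cd, cm$blacklist, cm$whitelist, params, start)
      if (run$score > best$score) best <- run
    }
  }
  out <- bn_dag(nodes, best$arcs)
  attr(out, "score") <- best$score
  out
}

#' Bootstrap arc strengths
#'
#' Learns one network per nonparametric bootstrap resample of the data and
#' tabulates, for every ordered node pair, the fraction of resamples in which
#' the arc appears in either direction (`strength`) and, among those, the
#' fraction oriented this way (`direction`).  Resampling draws `m` records
#' with replacement (default `m = n`) and is reproducible given
#' `params$seed`.
#'
#' @inheritParams tabu_search
#' @param R number of bootstrap resamples (>= 1).
#' @param m resample size; defaults to the number of records.
#' @return a data frame of class `bn_arc_strength` with columns `from`, `to`,
#'   `strength`, `direction` and attributes `R` and `nodes`.
#' @export
bootstrap_arc_strengths <- function(data, constraints = NULL,
                                    params = search_params(), R = 300L,
                                    m = NULL) {
  R <- as.integer(R)
  if (is.na(R) || R < 1L) stop("'R' must be a count >= 1")
  cd <- .collapse_data(data)
  n <- sum(cd$weights)
  if (is.null(m)) m <- n
  if (m > n) stop("'m' must not exceed the number of records")
  nodes <- names(cd$nlev)
  cm <- .constraint_matrices(nodes, constraints)
  p <- length(nodes)
  present <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  if (!is.null(params$seed)) set.seed(params$seed)
  for (r in seq_len(R)) {
    w <- as.numeric(rmultinom(1L, size = m, prob = cd$weights))
    keep <- w > 0
    cdr <- list(configs = cd$configs[keep, , drop = FALSE],
                weights = w[keep], nlev = cd$nlev)
    run <- .learn_one(cdr, cm$blacklist, cm$whitelist, params)
    if (nrow(run$arcs)) present[run$arcs] <- present[run$arcs] + 1L
  }
  pairs <- which(!diag(p), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  either <- present[pairs] + present[pairs[, 2:1, drop = FALSE]]
  out <- data.frame(from = nodes[pairs[, 1L]], to = nodes[pairs[, 2L]],
                    strength = either / R,
                    direction = ifelse(either > 0, present[pairs] / either,
                                       NA_real_),
                    stringsAsFactors = FALSE)
  structure(out, R = R, nodes = nodes,
            class = c("bn_arc_strength", "data.frame"))
}

#' Threshold an arc-strength table into a consensus DAG
#'
#' Keeps every undirected pair whose strength is at least `threshold`,
#' orients it by the majority bootstrap direction (ties go to the
#' lexicographically smaller source), and, if the oriented result is cyclic,
#' drops cycle arcs in increasing strength order until acyclic.
#'
#' @param strengths a `bn_arc_strength` table.
#' @param threshold inclusion threshold in (0, 1]; 0.5 gives the averaged
#'   network, 0.85 the simplified one.
#' @return a `bn_dag`; kept arc strengths are in attribute `"strength"`.
#' @export
average_network <- function(strengths, threshold = 0.5) {
  if (!inherits(strengths, "bn_arc_strength"))
    stop("'strengths' must come from bootstrap_arc_strengths()")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("'threshold' must be in (0, 1]")
  nodes <- attr(strengths, "nodes")
  s <- strengths[strengths$from < strengths$to & strengths$strength >=
                   threshold, , drop = FALSE]
  if (nrow(s)) {
    ## majority orientation; direction is the u->v fraction for the u<v row
    flip <- !is.na(s$direction) & s$direction < 0.5
    arcs <- cbind(from = ifelse(flip, s$to, s$from),
                  to = ifelse(flip, s$from, s$to))
    strength <- s$strength
    ## cycle resolution: drop the weakest cycle arc until a DAG remains
    repeat {
      if (!is.null(topological_order(nodes, as_arc_matrix(arcs)))) break
      on_cycle <- vapply(seq_len(nrow(arcs)), function(i) {
        rest <- as_arc_matrix(arcs[-i, , drop = FALSE])
        .has_path(nodes, rest, arcs[i, 2L], arcs[i, 1L])
      }, logical(1L))
      drop <- which(on_cycle)[order(strength[on_cycle],
                                    arcs[on_cycle, 1L],
                                    arcs[on_cycle, 2L])][1L]
      arcs <- arcs[-drop, , drop = FALSE]
      strength <- strength[-drop]
    }
  } else {
    arcs <- NULL
    strength <- numeric(0)
  }
  out <- bn_dag(nodes, arcs)
  attr(out, "strength") <- strength
  out
}

.has_path <- function(nodes, arcs, s, t) {
  if (s == t) return(TRUE)
  if (nrow(arcs) == 0L) return(FALSE)
  seen <- s
  frontier <- s
  while (length(frontier)) {
    nxt <- unique(arcs[arcs[, 1L] %in% frontier, 2L])
    if (t %in% nxt) return(TRUE)
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  FALSE
}
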