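#' Directed acyclic graphs over named discrete variables
#'
#' `bn_dag()` constructs a directed graph from a node set and an arc list and
#' validates that it is acyclic, has no self-loops, and references only known
#' nodes.  Arcs are given as a two-column `from`/`to` character matrix (or a
#' data frame coercible to one); an empty graph is allowed.
#'
#' @param nodes character vector of node names (unique, non-empty).
#' @param arcs two-column character matrix or data frame of directed arcs;
#'   `NULL` or zero rows for an arc-free graph.
#' @return an object of class `bn_dag`: a list with elements `nodes` and
#'   `arcs` (always a character matrix with columns `from`, `to`).
#' @examples
#' g <- bn_dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' is_acyclic(g)
#' @export
bn_dag <- function(nodes, arcs = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) == 0L || anyDuplicated(nodes) || any(!nzchar(nodes)))
    stop("'nodes' must be a non-empty set of unique, non-empty names")
  arcs <- as_arc_matrix(arcs)
  if (nrow(arcs)) {
    bad <- !(arcs %in% nodes)
    if (any(bad))
      stop("arc endpoints not in node set: ",
           paste(unique(arcs[bad]), collapse = ", "))
    if (any(arcs[, 1L] == arcs[, 2L]))
      stop("self-loops are not allowed")
    if (anyDuplicated(paste(arcs[, 1L], arcs[, 2L], sep = "\r")))
      stop("duplicated arcs")
  }
  g <- structure(list(nodes = nodes, arcs = arcs), class = "bn_dag")
  if (!is_acyclic(g))
    stop("arc set contains a directed cycle")
  g
}

as_arc_matrix <- function(arcs) {
  if (is.null(arcs) || (is.matrix(arcs) && nrow(arcs) == 0L) ||
      (is.data.frame(arcs) && nrow(arcs) == 0L)) {
    m <- matrix(character(), ncol = 2L)
  } else {
    if (is.data.frame(arcs)) arcs <- as.matrix(arcs)
    if (is.character(arcs) && is.null(dim(arcs)) && length(arcs) == 2L)
      arcs <- matrix(arcs, ncol = 2L)
    if (!is.matrix(arcs) || ncol(arcs) != 2L)
      stop("'arcs' must be a two-column from/to matrix")
    m <- matrix(as.character(arcs), ncol = 2L)
  }
  colnames(m) <- c("from", "to")
  m
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("Discrete Bayesian-network structure:", length(x$nodes), "nodes,",
      nrow(x$arcs), "arcs\n")
  if (nrow(x$arcs))
    cat(paste0("  ", x$arcs[, 1L], " -> ", x$arcs[, 2L]), sep = "\n")
  invisible(x)
}

#' Test a directed graph for acyclicity
#'
#' A graph is acyclic iff a topological order of its nodes exists; the check
#' repeatedly removes nodes without incoming arcs (Kahn's algorithm).
#'
#' @param dag a `bn_dag` object.
#' @return `TRUE` if a topological order exists, otherwise `FALSE`.
#' @export
is_acyclic <- function(dag) {
  !is.null(topological_order(dag$nodes, dag$arcs))
}

## Kahn's algorithm; returns NULL when the arc set is cyclic.
topological_order <- function(nodes, arcs) {
  if (nrow(arcs) == 0L) return(nodes)
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(arcs[, 2L])
  indeg[names(tab)] <- as.integer(tab)
  out <- split(arcs[, 2L], factor(arcs[, 1L], levels = nodes))
  order <- character(0)
  queue <- nodes[indeg == 0L]
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (w in out[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) == length(nodes)) order else NULL
}

#' Parent sets of a DAG
#'
#' @param dag a `bn_dag`.
#' @return named list mapping each node to the character vector of its parents.
#' @export
parent_sets <- function(dag) {
  ps <- lapply(setNames(dag$nodes, dag$nodes), function(v)
    dag$arcs[dag$arcs[, 2L] == v, 1L])
  lapply(ps, as.character)
}

#' Arc constraint sets for structure learning
#'
#' Holds a blacklist of forbidden directed arcs and a whitelist of required
#' ones.  The two sets must be disjoint and the whitelist alone acyclic.
#'
#' @param blacklist,whitelist two-column from/to matrices (or `NULL`).
#' @param nodes optional node names used to validate endpoints and the
#'   whitelist's acyclicity.
#' @return a `bn_constraints` object.
#' @export
bn_constraints <- function(blacklist = NULL, whitelist = NULL, nodes = NULL) {
  bl <- as_arc_matrix(blacklist)
  wl <- as_arc_matrix(whitelist)
  key <- function(m) paste(m[, 1L], m[, 2L], sep = "\r")
  if (any(key(wl) %in% key(bl)))
    stop("whitelist and blacklist overlap")
  if (nrow(wl)) {
    wn <- if (is.null(nodes)) unique(c(wl)) else nodes
    if (is.null(topological_order(wn, wl)))
      stop("whitelist arcs alone form a cycle")
  }
  structure(list(blacklist = bl, whitelist = wl), class = "bn_constraints")
}

#' Layering constraints from node roles
#'
#' Builds the blacklist encoding the causal layering used when learning the
#' cohort network: the two exposure-layer nodes (metabolic-syndrome status and
#' obesity level) may not point at each other, and no arc may leave the
#' outcome node (hyperuricemia), so that exposures, demographics and
#' covariates can be directed *to* the outcome but never the reverse.
#'
#' @param roles named character vector mapping every node to one of
#'   `"outcome"`, `"exposure"`, `"demographic"`, `"covariate"`.  Exactly one
#'   node must have the outcome role.
#' @param force_exposures if `TRUE`, whitelists arcs from each exposure and
#'   demographic node into the outcome instead of merely permitting them.
#' @return a `bn_constraints` object.
#' @export
layering_constraints <- function(roles, force_exposures = FALSE) {
  roles <- unlist(roles)
  ok <- c("outcome", "exposure", "demographic", "covariate")
  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    stop("'roles' must be a named vector")
  if (any(!roles %in% ok))
    stop("unknown role(s): ", paste(setdiff(roles, ok), collapse = ", "))
  outcome <- names(roles)[roles == "outcome"]
  if (length(outcome) != 1L)
    stop("exactly one node must have role 'outcome'")
  exposures <- names(roles)[roles == "exposure"]
  others <- setdiff(names(roles), outcome)
  bl <- cbind(from = outcome, to = others)
  if (length(exposures) > 1L) {
    pairs <- t(utils::combn(exposures, 2L))
    bl <- rbind(bl, cbind(from = pairs[, 1L], to = pairs[, 2L]),
                cbind(from = pairs[, 2L], to = pairs[, 1L]))
  }
  wl <- NULL
  if (force_exposures) {
    src <- c(exposures, names(roles)[roles == "demographic"])
    if (length(src)) wl <- cbind(from = src, to = outcome)
  }
  bn_constraints(blacklist = bl, whitelist = wl, nodes = names(roles))
}
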