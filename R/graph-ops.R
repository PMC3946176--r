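# Graph-theoretic machinery for network inferability. Steady-state expression
# profiles from single-gene knock-out/knock-down (KO/KD) experiments reveal
# which genes respond to which perturbation, i.e. directed reachability, but
# cannot discriminate direct from indirect regulation. All digraphs sharing
# the gold standard's transitive closure are therefore indistinguishable from
# such data; the functions below compute that closure (the upper bound on the
# ensemble), a lower bound via a modified transitive reduction that handles
# directed cycles, and the resulting set of non-inferable edges.

#' Strongly connected components and condensation of a digraph
#'
#' Partitions the nodes into strongly connected components (maximal sets of
#' mutually accessible nodes) and builds the condensation: the acyclic graph
#' whose nodes are the components, with an edge between two components
#' whenever some source edge crosses them (duplicates collapsed).
#'
#' @param g A `grn_digraph`.
#' @return An object of class `grn_scc` with elements `components` (list of
#'   character vectors of node labels), `membership` (named integer vector),
#'   and `component_dag` (a `grn_digraph` over component indices, as strings).
#' @export
scc_condense <- function(g) {
  if (length(g$nodes) == 0L) {
    return(structure(list(components = list(),
                          membership = integer(0),
                          component_dag = grn_digraph(character(0))),
                     class = "grn_scc"))
  }
  comp <- igraph::components(as_igraph(g), mode = "strong")
  membership <- comp$membership[g$nodes]
  components <- split(g$nodes, membership)
  names(components) <- NULL
  block_ids <- as.character(sort(unique(membership)))
  if (nrow(g$edges)) {
    bfrom <- as.character(membership[g$edges[, 1L]])
    bto <- as.character(membership[g$edges[, 2L]])
    cross <- bfrom != bto
    dag_edges <- unique(cbind(from = bfrom[cross], to = bto[cross]))
  } else {
    dag_edges <- NULL
  }
  structure(list(components = components,
                 membership = membership,
                 component_dag = grn_digraph(block_ids, dag_edges)),
            class = "grn_scc")
}

#' @export
print.grn_scc <- function(x, ...) {
  sizes <- lengths(x$components)
  cat(sprintf("grn_scc: %d components (sizes: %s)\n",
              length(x$components), paste(sizes, collapse = ", ")))
  invisible(x)
}

# Boolean reachability matrix by Warshall's algorithm; entry (i, j) is TRUE
# iff a directed path of length >= 1 runs from i to j (diagonal TRUE only for
# nodes on a cycle).
reachability <- function(g) {
  R <- adjacency(g)
  n <- nrow(R)
  for (k in seq_len(n)) {
    ik <- R[, k]
    if (any(ik)) R[ik, ] <- R[ik, , drop = FALSE] | rep(R[k, ], each = sum(ik))
  }
  R
}

#' Transitive closure of a digraph
#'
#' The closure has an edge (i, j), i != j, whenever j is reachable from i by
#' a directed path. For a gold-standard regulatory network this is the
#' largest digraph consistent with complete steady-state single-gene KO/KD
#' data: perturbation of i changes the expression of exactly the genes
#' reachable from i.
#'
#' @param g A `grn_digraph`.
#' @return A `grn_digraph` on the same node set. Idempotent.
#' @export
transitive_closure <- function(g) {
  R <- reachability(g)
  diag(R) <- FALSE
  digraph_from_adjacency(R, g$nodes)
}

#' Transitive reduction of an acyclic digraph
#'
#' Returns the unique minimal digraph with the same transitive closure as the
#' input: every edge (u, v) for which an alternative directed path u -> ... -> v
#' exists is pruned. The result is independent of pruning order for DAGs.
#'
#' @param g An acyclic `grn_digraph`.
#' @return A `grn_digraph`; a subgraph of `g`.
#' @export
transitive_reduction_dag <- function(g) {
  R <- reachability(g)
  if (any(diag(R)))
    stop_grn("grn_cyclic_graph_error",
             "transitive reduction requires an acyclic digraph")
  diag(R) <- FALSE
  # edge (u,v) is redundant iff some w has u ~> w and w ~> v
  redundant <- (R %*% R) > 0
  A <- adjacency(g) & !redundant
  digraph_from_adjacency(A, g$nodes)
}

#' Ensemble bounds and non-inferable edges of a gold-standard network
#'
#' All digraphs sharing the gold standard's transitive closure agree equally
#' well with ideal steady-state single-gene KO/KD data. This function bounds
#' that ensemble: the upper bound `upper` is the transitive closure (the
#' largest member); the lower bound `lower` approximates the edges present in
#' every member. The non-inferable edge set is their difference - edges the
#' data can neither confirm nor refute - and is excluded from the
#' inferability-aware confusion matrix.
#'
#' The lower bound is built by a modified transitive reduction that copes
#' with directed cycles: (1) condense the gold standard into its DAG of
#' strong components; (2) transitively reduce that DAG; (3) drop every
#' condensed edge whose tail or head component contains a cycle (size >= 2),
#' because the causal attachment point inside the cycle is unidentifiable;
#' (4) expand components back to genes, keeping both mutual edges of each
#' 2-node component (the 2-cycle is the unique minimal strongly connected
#' digraph on two nodes) and no internal edges of components with three or
#' more nodes.
#'
#' @param gold A `grn_digraph` gold standard (no self-loops).
#' @return An object of class `grn_bounds`: `lower`, `upper`,
#'   `non_inferable` (two-column edge matrices), `gold_size`, and `nodes`.
#' @examples
#' cascade <- grn_digraph(c("A", "B", "C"), c("A", "B", "B", "C"))
#' ensemble_bounds(cascade)
#' @export
ensemble_bounds <- function(gold) {
  stopifnot(inherits(gold, "grn_digraph"))
  if (nrow(gold$edges) && any(gold$edges[, 1L] == gold$edges[, 2L]))
    self_loop_error("gold standard contains a self-loop")
  upper <- transitive_closure(gold)

  scc <- scc_condense(gold)
  sizes <- lengths(scc$components)
  reduced <- transitive_reduction_dag(scc$component_dag)

  lower_edges <- NULL
  if (nrow(reduced$edges)) {
    bfrom <- as.integer(reduced$edges[, 1L])
    bto <- as.integer(reduced$edges[, 2L])
    keep <- sizes[bfrom] == 1L & sizes[bto] == 1L
    if (any(keep)) {
      lower_edges <- cbind(
        from = vapply(scc$components[bfrom[keep]], `[`, character(1), 1L),
        to = vapply(scc$components[bto[keep]], `[`, character(1), 1L))
    }
  }
  for (comp in scc$components[sizes == 2L]) {
    lower_edges <- rbind(lower_edges,
                         cbind(from = comp, to = rev(comp)))
  }
  lower <- grn_digraph(gold$nodes, lower_edges)

  structure(list(lower = lower$edges,
                 upper = upper$edges,
                 non_inferable = edge_setdiff(upper$edges, lower$edges),
                 gold_size = nrow(gold$edges),
                 nodes = gold$nodes),
            class = "grn_bounds")
}

#' @export
print.grn_bounds <- function(x, ...) {
  cat(sprintf(paste0(
    "grn_bounds: gold %d edges; lower bound %d, upper bound %d, ",
    "non-inferable %d\n"),
    x$gold_size, nrow(x$lower), nrow(x$upper), nrow(x$non_inferable)))
  invisible(x)
}

#' @export
summary.grn_bounds <- function(object, ...) {
  n <- length(object$nodes)
  # lower is a subset of gold, so the non-inferable gold fraction is (P-|L|)/P
  data.frame(
    n_nodes = n,
    universe = n * (n - 1L),
    gold = object$gold_size,
    lower = nrow(object$lower),
    upper = nrow(object$upper),
    non_inferable = nrow(object$non_inferable),
    frac_gold_non_inferable =
      if (object$gold_size > 0)
        (object$gold_size - nrow(object$lower)) / object$gold_size
      else NA_real_)
}

#' Enumerate the ensemble of digraphs sharing a transitive closure
#'
#' Exhaustively lists every digraph on the gold standard's node set whose
#' transitive closure equals that of the gold standard, i.e. the full
#' ensemble of networks indistinguishable from ideal steady-state single-gene
#' KO/KD data. Every member is necessarily a subgraph of the closure, so
#' enumeration runs over subsets of closure edges; it is intended as a
#' brute-force reference for small networks.
#'
#' @param gold A `grn_digraph`.
#' @param max_nodes Enumeration guard; networks with more nodes are refused.
#' @return List of `grn_digraph` ensemble members (always includes `gold`).
#' @export
enumerate_closure_class <- function(gold, max_nodes = 5L) {
  n <- length(gold$nodes)
  if (n > max_nodes)
    stop_grn("grn_too_large_error", sprintf(
      "enumeration limited to %d nodes (got %d)", max_nodes, n))
  closure <- transitive_closure(gold)
  ckeys <- edge_keys(closure$edges)
  m <- length(ckeys)
  if (m == 0L) return(list(grn_digraph(gold$nodes)))
  S <- bitwShiftL(1L, m)
  # subset-membership matrix: row s, column e = edge e present in subset s
  present <- matrix(FALSE, S, m)
  for (e in seq_len(m)) {
    present[, e] <- bitwAnd(seq_len(S) - 1L, bitwShiftL(1L, e - 1L)) > 0L
  }
  # vectorised Warshall over all subsets at once
  efrom <- match(closure$edges[, 1L], gold$nodes)
  eto <- match(closure$edges[, 2L], gold$nodes)
  A <- array(FALSE, c(S, n, n))
  for (e in seq_len(m)) A[, efrom[e], eto[e]] <- present[, e]
  for (k in seq_len(n)) for (i in seq_len(n)) {
    aik <- A[, i, k]
    if (any(aik)) for (j in seq_len(n)) {
      A[, i, j] <- A[, i, j] | (aik & A[, k, j])
    }
  }
  target <- adjacency(closure)
  ok <- rep(TRUE, S)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) ok <- ok & (A[, i, j] == target[i, j])
  }
  lapply(which(ok), function(s) {
    grn_digraph(gold$nodes, keys_to_edges(ckeys[present[s, ]]))
  })
}
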