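# Directed graphs without self-loops are the package's basic currency: a
# gold-standard network, an ensemble bound, and a thresholded prediction are
# all grn_digraph objects. Gene labels are opaque case-sensitive strings.

# internal edge-key helpers: an edge (u, v) is keyed as "u<US>v" where <US> is
# the ASCII unit separator, which cannot appear in tab- or comma-separated
# input labels that the readers accept.
.KEY_SEP <- "\x1f"

edge_keys <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) return(character(0))
  paste(edges[, 1L], edges[, 2L], sep = .KEY_SEP)
}

keys_to_edges <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(0), ncol = 2L, dimnames = list(NULL, c("from", "to"))))
  }
  parts <- strsplit(keys, .KEY_SEP, fixed = TRUE)
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("from", "to")
  m
}

as_edge_matrix <- function(edges) {
  if (is.null(edges)) {
    edges <- matrix(character(0), ncol = 2L)
  } else if (is.data.frame(edges)) {
    edges <- as.matrix(edges[, 1:2])
  } else if (is.character(edges) && is.null(dim(edges))) {
    if (length(edges) %% 2L != 0L)
      stop("edge vector must have even length (from, to pairs)")
    edges <- matrix(edges, ncol = 2L, byrow = TRUE)
  }
  edges <- matrix(as.character(edges), ncol = 2L)
  colnames(edges) <- c("from", "to")
  edges
}

#' Construct a directed graph over a fixed gene universe
#'
#' A `grn_digraph` holds an ordered set of node labels and a set of directed
#' edges between them. Self-loops are rejected throughout the package: the
#' benchmark design omits auto-regulatory interactions, so the edge universe
#' of an n-gene network has exactly n(n-1) candidate edges.
#'
#' @param nodes Character vector of node labels (duplicates removed, order
#'   of first appearance kept).
#' @param edges Edges as a two-column character matrix/data frame of
#'   (from, to) pairs, or a flat character vector `c(from1, to1, from2, ...)`.
#'   Duplicate edges are collapsed.
#' @return An object of class `grn_digraph` with elements `nodes` and
#'   `edges` (two-column character matrix).
#' @examples
#' g <- grn_digraph(c("G1", "G2", "G3"), c("G1", "G2", "G2", "G3"))
#' n_edges(g)
#' @export
grn_digraph <- function(nodes, edges = NULL) {
  nodes <- unique(as.character(nodes))
  edges <- as_edge_matrix(edges)
  if (nrow(edges)) {
    missing <- setdiff(c(edges), nodes)
    if (length(missing))
      stop_grn("grn_universe_mismatch_error", paste0(
        "edge endpoints not in node set: ", paste(missing, collapse = ", ")))
    if (any(edges[, 1L] == edges[, 2L]))
      self_loop_error(paste0(
        "self-loops are not allowed: ",
        paste(unique(edges[edges[, 1L] == edges[, 2L], 1L]), collapse = ", ")))
    edges <- keys_to_edges(unique(edge_keys(edges)))
  }
  structure(list(nodes = nodes, edges = edges), class = "grn_digraph")
}

#' @export
print.grn_digraph <- function(x, ...) {
  cat(sprintf("grn_digraph: %d nodes, %d edges (universe %d)\n",
              length(x$nodes), nrow(x$edges),
              length(x$nodes) * (length(x$nodes) - 1L)))
  if (nrow(x$edges)) {
    show <- utils::head(x$edges, 10L)
    cat(paste0("  ", show[, 1L], " -> ", show[, 2L], collapse = "\n"), "\n")
    if (nrow(x$edges) > 10L) cat(sprintf("  ... and %d more\n", nrow(x$edges) - 10L))
  }
  invisible(x)
}

#' Number of nodes / edges of a digraph
#' @param g A `grn_digraph`.
#' @return Integer count.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' All candidate edges of the network universe
#'
#' The universe of an n-node network is every ordered pair of distinct nodes:
#' n(n-1) edges. Confusion matrices, random predictions and curve endpoints
#' are all defined relative to this set.
#'
#' @param g A `grn_digraph` (only its node set is used).
#' @return Two-column character matrix of all ordered non-self pairs.
#' @export
universe_edges <- function(g) {
  n <- length(g$nodes)
  if (n < 2L) return(keys_to_edges(character(0)))
  from <- rep(g$nodes, each = n)
  to <- rep(g$nodes, times = n)
  keep <- from != to
  m <- cbind(from = from[keep], to = to[keep])
  m
}

universe_keys <- function(g) edge_keys(universe_edges(g))

# logical adjacency matrix with dimnames = nodes
adjacency <- function(g) {
  n <- length(g$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) A[g$edges] <- TRUE
  A
}

digraph_from_adjacency <- function(A, nodes = rownames(A)) {
  idx <- which(A, arr.ind = TRUE)
  edges <- cbind(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]])
  grn_digraph(nodes, edges)
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE))
}

# set helpers on edge matrices
edge_setdiff <- function(a, b) keys_to_edges(setdiff(edge_keys(a), edge_keys(b)))
edge_intersect <- function(a, b) keys_to_edges(intersect(edge_keys(a), edge_keys(b)))

#' Test whether two digraphs are identical as labelled graphs
#' @param a,b `grn_digraph` objects.
#' @return Logical.
#' @export
digraph_equal <- function(a, b) {
  setequal(a$nodes, b$nodes) && setequal(edge_keys(a$edges), edge_keys(b$edges))
}
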