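# Independent brute-force oracles. These deliberately avoid the package's
# own closure/reduction code paths: reachability is a hand-rolled BFS on an
# edge list, and ensemble enumeration scans every digraph on the node set.

# BFS reachability: nodes reachable from `start` by paths of length >= 1
bfs_reachable <- function(edges, nodes, start) {
  adj <- split(edges[, 2L], factor(edges[, 1L], levels = nodes))
  seen <- character(0)
  frontier <- adj[[start]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(adj[new], use.names = FALSE))
  }
  seen
}

# closure edge keys via BFS from every node
oracle_closure_keys <- function(g) {
  out <- character(0)
  for (v in g$nodes) {
    reach <- setdiff(bfs_reachable(g$edges, g$nodes, v), v)
    if (length(reach)) out <- c(out, paste(v, reach, sep = "\x1f"))
  }
  sort(out)
}

# all ordered non-self pairs on a node set, as an edge matrix
all_pairs <- function(nodes) {
  n <- length(nodes)
  from <- rep(nodes, each = n)
  to <- rep(nodes, times = n)
  keep <- from != to
  cbind(from = from[keep], to = to[keep])
}

# enumerate every digraph on `nodes` whose BFS closure equals that of `g`;
# returns a list of edge matrices
oracle_closure_class <- function(g) {
  pairs <- all_pairs(g$nodes)
  m <- nrow(pairs)
  target <- oracle_closure_keys(g)
  out <- list()
  for (s in seq_len(2^m) - 1L) {
    pick <- bitwAnd(s, 2^(seq_len(m) - 1L)) > 0
    cand <- pairs[pick, , drop = FALSE]
    keys <- oracle_closure_keys(list(nodes = g$nodes, edges = cand))
    if (identical(keys, target)) out[[length(out) + 1L]] <- cand
  }
  out
}

# random digraph on n nodes with i.i.d. edge probability p
random_digraph <- function(n, p = 0.3) {
  nodes <- LETTERS[seq_len(n)]
  pairs <- all_pairs(nodes)
  grn_digraph(nodes, pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE])
}

edge_key_set <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) return(character(0))
  sort(paste(edges[, 1L], edges[, 2L], sep = "\x1f"))
}

dg <- function(nodes, ...) grn_digraph(nodes, c(...))
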