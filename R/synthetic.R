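# Synthetic study material. The generator builds gold standards from the
# motif catalogue whose inferability properties are known exactly - cascades
# and feed-forward loops carry a non-inferable shortcut, 2-cycles are fully
# inferable, longer cycles are fully non-inferable - and predictions whose
# error content is controlled per channel: "cascade errors" (shortcut edges,
# invisible to the inferability-aware assessment) versus genuine errors
# (edges outside the transitive closure, penalised by both assessments).

#' Specification of a motif-structured synthetic gold standard
#'
#' Motifs are placed on disjoint node groups so the ensemble bounds of the
#' generated network are analytically known: each cascade (A->B->C, 3 nodes)
#' and feed-forward loop (A->B, A->C, B->C; 3 nodes) contributes one
#' non-inferable shortcut; each 2-cycle (2 nodes) is fully inferable; each
#' k-cycle with k >= 3 (k nodes) is fully non-inferable. Remaining node
#' pairs outside any motif group may receive independent Bernoulli extra
#' edges.
#'
#' @param n_nodes Total number of genes.
#' @param n_cascades,n_ffls,n_two_cycles Motif counts.
#' @param k_cycles Integer vector of directed-cycle lengths, each >= 3.
#' @param extra_edge_prob Probability of each non-motif-internal candidate
#'   edge being added (default 0 keeps bounds exactly analytic).
#' @param seed Integer seed.
#' @return Object of class `grn_motif_spec`.
#' @export
motif_spec <- function(n_nodes, n_cascades = 0L, n_ffls = 0L,
                       n_two_cycles = 0L, k_cycles = integer(0),
                       extra_edge_prob = 0, seed = 1L) {
  k_cycles <- as.integer(k_cycles)
  if (length(k_cycles) && any(k_cycles < 3L))
    stop_grn("grn_infeasible_spec_error", "k-cycles must have length >= 3")
  if (extra_edge_prob < 0 || extra_edge_prob > 1)
    stop_grn("grn_infeasible_spec_error", "extra_edge_prob must lie in [0, 1]")
  needed <- 3L * n_cascades + 3L * n_ffls + 2L * n_two_cycles + sum(k_cycles)
  if (needed > n_nodes)
    stop_grn("grn_infeasible_spec_error", sprintf(
      "motifs need %d nodes but only %d available", needed, n_nodes))
  structure(list(n_nodes = as.integer(n_nodes),
                 n_cascades = as.integer(n_cascades),
                 n_ffls = as.integer(n_ffls),
                 n_two_cycles = as.integer(n_two_cycles),
                 k_cycles = k_cycles,
                 extra_edge_prob = extra_edge_prob,
                 seed = as.integer(seed)),
            class = "grn_motif_spec")
}

#' Generate a synthetic gold-standard network from a motif specification
#'
#' @param spec A `grn_motif_spec`.
#' @return A `grn_digraph`, deterministic per `spec$seed`.
#' @export
generate_gold <- function(spec) {
  stopifnot(inherits(spec, "grn_motif_spec"))
  nodes <- sprintf("G%d", seq_len(spec$n_nodes))
  cursor <- 0L
  take <- function(k) {
    out <- nodes[cursor + seq_len(k)]
    cursor <<- cursor + k
    out
  }
  edges <- NULL
  grouped <- character(0)
  group_key <- character(0) # internal ordered pairs of each motif group
  add_group <- function(members, new_edges) {
    edges <<- rbind(edges, new_edges)
    grouped <<- c(grouped, members)
    pairs <- expand.grid(members, members, stringsAsFactors = FALSE)
    pairs <- pairs[pairs[, 1L] != pairs[, 2L], ]
    group_key <<- c(group_key, paste(pairs[, 1L], pairs[, 2L], sep = .KEY_SEP))
  }
  for (i in seq_len(spec$n_cascades)) {
    v <- take(3L)
    add_group(v, cbind(from = v[1:2], to = v[2:3]))
  }
  for (i in seq_len(spec$n_ffls)) {
    v <- take(3L)
    add_group(v, cbind(from = c(v[1L], v[1L], v[2L]), to = c(v[2L], v[3L], v[3L])))
  }
  for (i in seq_len(spec$n_two_cycles)) {
    v <- take(2L)
    add_group(v, cbind(from = v, to = rev(v)))
  }
  for (k in spec$k_cycles) {
    v <- take(k)
    add_group(v, cbind(from = v, to = c(v[-1L], v[1L])))
  }
  if (spec$extra_edge_prob > 0) {
    uni <- universe_edges(grn_digraph(nodes))
    ukeys <- edge_keys(uni)
    candidate <- !(ukeys %in% c(group_key, edge_keys(edges)))
    extra <- with_seed(spec$seed,
                       candidate & stats::runif(length(ukeys)) < spec$extra_edge_prob)
    edges <- rbind(edges, uni[extra, , drop = FALSE])
  }
  grn_digraph(nodes, edges)
}

#' Generate a ranked prediction with controlled error content
#'
#' Starts from a perfect submission (the gold edges ranked first, remaining
#' universe edges after them in random order) and corrupts the top block:
#' for each gold edge, with probability `cascade_error_rate` it is replaced
#' in the top block by an unused non-inferable edge (a shortcut-type error
#' the data cannot refute) and with probability `flip_rate` by an unused
#' edge outside the transitive closure (a genuine error). Displaced gold
#' edges queue immediately after the top block, ahead of the random
#' remainder, so a prediction corrupted only through the non-inferable
#' channel still ranks every inferable gold edge above every refutable
#' non-edge.
#'
#' @param gold A `grn_digraph`.
#' @param cascade_error_rate,flip_rate Per-edge corruption probabilities;
#'   their sum must not exceed 1.
#' @param seed Integer seed.
#' @return A `grn_ranking` over the full edge universe.
#' @export
generate_prediction <- function(gold, cascade_error_rate = 0, flip_rate = 0,
                                seed = 1L) {
  stopifnot(cascade_error_rate >= 0, flip_rate >= 0)
  if (cascade_error_rate + flip_rate > 1)
    stop_grn("grn_infeasible_spec_error",
             "cascade_error_rate + flip_rate must not exceed 1")
  bounds <- ensemble_bounds(gold)
  gkeys <- edge_keys(gold$edges)
  ekeys <- setdiff(edge_keys(bounds$non_inferable), gkeys)
  ukeys <- universe_keys(gold)
  outside <- setdiff(ukeys, edge_keys(bounds$upper))

  with_seed(seed, {
    gkeys <- sample(gkeys)
    ekeys <- sample(ekeys)
    outside_pool <- sample(outside)
    u <- stats::runif(length(gkeys))
    block <- gkeys
    displaced <- character(0)
    for (i in seq_along(gkeys)) {
      if (u[i] < cascade_error_rate) {
        if (length(ekeys)) { # no shortcut left: keep the gold edge
          block[i] <- ekeys[1L]
          ekeys <- ekeys[-1L]
          displaced <- c(displaced, gkeys[i])
        }
      } else if (u[i] < cascade_error_rate + flip_rate && length(outside_pool)) {
        block[i] <- outside_pool[1L]
        outside_pool <- outside_pool[-1L]
        displaced <- c(displaced, gkeys[i])
      }
    }
    rest <- sample(setdiff(ukeys, c(block, displaced)))
    keys <- c(block, displaced, rest)
    edges <- keys_to_edges(keys)
    ranked_edge_list(edges[, 1L], edges[, 2L],
                     confidence = rev(seq_along(keys)) / length(keys))
  })
}
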