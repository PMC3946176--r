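# Empirical-null scoring. Following the benchmark's procedure, a large set
# of random predictions is generated per gold standard; the AUC at the
# 100*(1-alpha)-th percentile of the resulting null sample, AUC_alpha, is the
# threshold an uninformative method would only exceed with probability alpha.
# A submission's score per network and metric is AUC / AUC_alpha, so a score
# below 1 means "not better than random"; per-metric scores are averaged over
# the M networks of a subchallenge and the overall score is the mean of the
# two metric means.

# deterministic sub-seed for a (network, metric) stream so adding networks
# never perturbs existing nulls; kept below 2^31
derive_seed <- function(seed, network_id, metric) {
  h <- sum(utf8ToInt(paste(network_id, metric, sep = "/")) *
             seq_along(utf8ToInt(paste(network_id, metric, sep = "/"))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Uniformly random ranked prediction over a network's edge universe
#'
#' @param g A `grn_digraph`; its node set defines the n(n-1)-edge universe.
#' @param seed Integer seed; the same seed always yields the same ranking.
#' @return A `grn_ranking` that permutes the whole universe uniformly at
#'   random, with strictly decreasing confidences.
#' @export
random_ranking <- function(g, seed) {
  uni <- universe_edges(g)
  if (nrow(uni) == 0L) parse_error("edge universe is empty")
  ord <- with_seed(seed, sample.int(nrow(uni)))
  ranked_edge_list(uni[ord, 1L], uni[ord, 2L],
                   confidence = rev(seq_len(nrow(uni))) / nrow(uni))
}

#' Empirical null distribution of an AUC metric under random prediction
#'
#' Generates `n_reps` uniformly random full-universe rankings, assesses each
#' with [curves_and_auc()], and records the chosen metric. The null threshold
#' `auc_alpha` is the 100*(1-alpha)-th percentile of the sample (linear
#' interpolation between order statistics).
#'
#' @inheritParams curves_and_auc
#' @param metric `"auroc"` or `"aupr"`.
#' @param n_reps Number of random predictions (the benchmark's full run used
#'   100000; tests use scaled-down sizes).
#' @param alpha Acceptable p-value for the threshold, in (0, 1).
#' @param seed Master seed; the stream is derived from it together with the
#'   network id and metric, so adding networks to a study leaves existing
#'   nulls untouched.
#' @param network_id Label naming the network's RNG stream.
#' @return Object of class `grn_null`: `metric`, `aucs`, `alpha`,
#'   `auc_alpha`, `seed`, `n_reps`.
#' @export
null_distribution <- function(gold, bounds = NULL,
                              mode = c("inferable", "classic"),
                              metric = c("auroc", "aupr"),
                              n_reps = 100000L, alpha = 0.05, seed = 1L,
                              network_id = "net") {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  stopifnot(n_reps >= 1L, alpha > 0, alpha < 1)
  stream <- derive_seed(seed, network_id, metric)
  uni <- universe_edges(gold)
  aucs <- with_seed(stream, {
    vapply(seq_len(n_reps), function(i) {
      ord <- sample.int(nrow(uni))
      rk <- ranked_edge_list(uni[ord, 1L], uni[ord, 2L],
                             confidence = rev(seq_len(nrow(uni))) / nrow(uni))
      a <- curves_and_auc(rk, gold, bounds, mode)
      if (metric == "auroc") a$auroc else a$aupr
    }, numeric(1))
  })
  structure(list(metric = metric, aucs = aucs, alpha = alpha,
                 auc_alpha = unname(stats::quantile(aucs, 1 - alpha, type = 7)),
                 seed = seed, n_reps = n_reps),
            class = "grn_null")
}

#' @export
print.grn_null <- function(x, ...) {
  cat(sprintf("grn_null (%s): %d reps, mean %.4f, AUC_%.2g = %.4f\n",
              x$metric, x$n_reps, mean(x$aucs), x$alpha, x$auc_alpha))
  invisible(x)
}

null_threshold <- function(null) {
  if (inherits(null, "grn_null")) null$auc_alpha else as.numeric(null)
}

#' Score a submission against per-network null thresholds
#'
#' @param aucs Named list, one entry per network id, each a numeric vector
#'   with elements `auroc` and `aupr`.
#' @param nulls Named list parallel to `aucs`; each entry a list with
#'   elements `auroc` and `aupr` that are either `grn_null` objects or bare
#'   `auc_alpha` numbers.
#' @return Object of class `grn_score`: `per_network` (data frame of scores),
#'   `mean_auroc_score`, `mean_aupr_score`, `overall`, `M`.
#' @export
score_submission <- function(aucs, nulls) {
  ids <- names(aucs)
  if (is.null(ids) || !all(ids %in% names(nulls)))
    parse_error("every network needs both AUCs and null thresholds")
  rows <- lapply(ids, function(id) {
    a <- aucs[[id]]
    thr_roc <- null_threshold(nulls[[id]]$auroc)
    thr_pr <- null_threshold(nulls[[id]]$aupr)
    if (thr_roc == 0 || thr_pr == 0)
      stop_grn("grn_zero_null_error", "null threshold AUC_alpha is zero")
    data.frame(network_id = id,
               auroc = unname(a[["auroc"]]), aupr = unname(a[["aupr"]]),
               auroc_score = unname(a[["auroc"]]) / thr_roc,
               aupr_score = unname(a[["aupr"]]) / thr_pr,
               stringsAsFactors = FALSE)
  })
  per_network <- do.call(rbind, rows)
  mean_auroc_score <- mean(per_network$auroc_score)
  mean_aupr_score <- mean(per_network$aupr_score)
  structure(list(per_network = per_network,
                 mean_auroc_score = mean_auroc_score,
                 mean_aupr_score = mean_aupr_score,
                 overall = (mean_auroc_score + mean_aupr_score) / 2,
                 M = nrow(per_network)),
            class = "grn_score")
}

#' @export
print.grn_score <- function(x, ...) {
  cat(sprintf("grn_score over %d networks: AUROC score %.4f, AUPR score %.4f, overall %.4f\n",
              x$M, x$mean_auroc_score, x$mean_aupr_score, x$overall))
  invisible(x)
}

#' Rank teams by overall score
#'
#' @param scores Named list of `grn_score` objects (names are team labels).
#' @return Data frame with columns `team`, `overall`, `rank`, ordered from
#'   best to worst; ties are broken by team label so the result does not
#'   depend on input order.
#' @export
rank_teams <- function(scores) {
  stopifnot(length(scores) >= 1L, !is.null(names(scores)))
  overall <- vapply(scores, function(s) s$overall, numeric(1))
  ord <- order(-overall, names(scores))
  data.frame(team = names(scores)[ord], overall = unname(overall[ord]),
             rank = seq_along(scores), stringsAsFactors = FALSE)
}

#' Spearman rank correlation between two team orderings
#'
#' @param ranking_a,ranking_b Character vectors listing the same teams from
#'   best to worst.
#' @return List with `rho` and the two-sided `p_value`.
#' @export
spearman_rank <- function(ranking_a, ranking_b) {
  if (!setequal(ranking_a, ranking_b) ||
      length(ranking_a) != length(ranking_b) ||
      anyDuplicated(ranking_a) || anyDuplicated(ranking_b))
    stop_grn("grn_mismatched_teams_error",
             "rankings must order the same set of teams exactly once each")
  teams <- sort(ranking_a)
  ra <- match(teams, ranking_a)
  rb <- match(teams, ranking_b)
  ct <- suppressWarnings(stats::cor.test(ra, rb, method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
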