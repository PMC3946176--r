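# End-to-end benchmark evaluation: assess every (team, network) ranked list,
# build per-network empirical nulls, score teams and rank them.

#' Evaluate a set of submissions against gold-standard networks
#'
#' For each team and network the ranked list is assessed with
#' [curves_and_auc()] under the chosen mode; per-network null thresholds are
#' built with [null_distribution()] (one RNG stream per network and metric,
#' derived from the master seed); team scores and the final ranking follow
#' the AUC / AUC_alpha scoring.
#'
#' @param golds Named list of gold-standard `grn_digraph` objects (names are
#'   network ids).
#' @param predictions Named list (team label -> named list of `grn_ranking`,
#'   one per network id).
#' @inheritParams curves_and_auc
#' @inheritParams null_distribution
#' @return Object of class `grn_evaluation`: `scores` (named list of
#'   `grn_score`), `ranking` (data frame), `aucs`, `nulls`, `config`.
#' @export
evaluate_submissions <- function(golds, predictions,
                                 mode = c("inferable", "classic"),
                                 alpha = 0.05, n_reps = 1000L, seed = 1L,
                                 truncation = c("expected-tail", "strict")) {
  mode <- match.arg(mode)
  truncation <- match.arg(truncation)
  stopifnot(length(golds) >= 1L, !is.null(names(golds)),
            length(predictions) >= 1L, !is.null(names(predictions)))
  ids <- names(golds)
  bounds <- lapply(golds, ensemble_bounds)

  nulls <- lapply(ids, function(id) {
    lapply(stats::setNames(c("auroc", "aupr"), c("auroc", "aupr")),
           function(metric) {
             null_distribution(golds[[id]], bounds[[id]], mode = mode,
                               metric = metric, n_reps = n_reps,
                               alpha = alpha, seed = seed, network_id = id)
           })
  })
  names(nulls) <- ids

  aucs <- lapply(predictions, function(team_preds) {
    if (!all(ids %in% names(team_preds)))
      parse_error("every team must predict every network")
    res <- lapply(ids, function(id) {
      a <- curves_and_auc(team_preds[[id]], golds[[id]], bounds[[id]],
                          mode = mode, truncation = truncation)
      c(auroc = a$auroc, aupr = a$aupr)
    })
    names(res) <- ids
    res
  })

  scores <- lapply(aucs, score_submission, nulls = nulls)
  structure(list(scores = scores,
                 ranking = rank_teams(scores),
                 aucs = aucs, nulls = nulls, bounds = bounds,
                 config = list(mode = mode, alpha = alpha, n_reps = n_reps,
                               seed = seed, truncation = truncation)),
            class = "grn_evaluation")
}

#' @export
print.grn_evaluation <- function(x, ...) {
  cat(sprintf("grn_evaluation (%s mode, alpha %.3g, %d null reps, seed %d)\n",
              x$config$mode, x$config$alpha, x$config$n_reps, x$config$seed))
  print(x$ranking)
  invisible(x)
}
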