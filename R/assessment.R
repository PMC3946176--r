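# Inferability-aware assessment of ranked edge predictions. The classic
# confusion matrix judges every candidate edge of the universe against the
# gold standard. The redefined matrix excludes the non-inferable edges: a
# predicted edge counts as a true positive only if it lies in the ensemble
# lower bound, as a false positive only if it lies outside the upper bound,
# and edges between the bounds contribute to no cell, so a method is neither
# rewarded nor penalised for guesses the data cannot adjudicate.

# resolve the positive and negative edge-key sets for a mode
assessment_sets <- function(gold, bounds, mode) {
  mode <- match.arg(mode, c("inferable", "classic"))
  ukeys <- universe_keys(gold)
  if (mode == "classic") {
    pos <- edge_keys(gold$edges)
    neg <- setdiff(ukeys, pos)
    excluded <- character(0)
  } else {
    if (is.null(bounds))
      stop_grn("grn_missing_bounds_error",
               "inferable mode requires ensemble bounds")
    pos <- edge_keys(bounds$lower)
    excluded <- edge_keys(bounds$non_inferable)
    neg <- setdiff(ukeys, edge_keys(bounds$upper))
  }
  list(universe = ukeys, positives = pos, negatives = neg,
       excluded = excluded, mode = mode)
}

#' Confusion matrix for an edge-set prediction
#'
#' @param pred_edges Predicted edges: a two-column matrix/data frame of
#'   (from, to) pairs, a flat character vector, or a `grn_digraph`.
#' @param gold Gold-standard `grn_digraph`; its node set defines the
#'   universe of n(n-1) candidate edges.
#' @param bounds `grn_bounds` from [ensemble_bounds()]; required for
#'   `mode = "inferable"`.
#' @param mode `"classic"` scores against the gold standard over the whole
#'   universe; `"inferable"` scores against the ensemble bounds, with
#'   non-inferable edges excluded from every cell.
#' @return Object of class `grn_confusion` with integer `tp`, `fp`, `tn`,
#'   `fn` and the `mode` used. In classic mode the four cells sum to n(n-1);
#'   in inferable mode to n(n-1) minus the number of non-inferable edges.
#' @export
build_confusion <- function(pred_edges, gold, bounds = NULL,
                            mode = c("inferable", "classic")) {
  mode <- match.arg(mode)
  if (inherits(pred_edges, "grn_digraph")) pred_edges <- pred_edges$edges
  pred <- unique(edge_keys(as_edge_matrix(pred_edges)))
  sets <- assessment_sets(gold, bounds, mode)
  if (!all(pred %in% sets$universe))
    stop_grn("grn_universe_mismatch_error",
             "prediction contains edges outside the gold-standard universe")
  tp <- sum(pred %in% sets$positives)
  fp <- sum(pred %in% sets$negatives)
  fn <- length(sets$positives) - tp
  tn <- length(sets$negatives) - fp
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, mode = mode),
            class = "grn_confusion")
}

#' @export
print.grn_confusion <- function(x, ...) {
  cat(sprintf("grn_confusion (%s): TP %d  FP %d  FN %d  TN %d\n",
              x$mode, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' ROC and precision-recall curves with AUCs for a ranked edge list
#'
#' Sweeps the ranked list: at each prefix length k the first k edges form the
#' predicted network and the confusion matrix is computed under the chosen
#' mode. True positive rate is TP/P', false positive rate FP/N' and precision
#' TP/(TP+FP), where P' and N' are the positive and negative set sizes of the
#' mode (inferable mode: P' = |lower bound|, N' = universe minus upper
#' bound). Areas are trapezoidal. If the list ranks fewer edges than the
#' universe, the default policy extends the curves by the expected path of a
#' uniformly random ordering of the unranked edges; `truncation = "strict"`
#' instead rejects incomplete lists.
#'
#' @param ranking A `grn_ranking`.
#' @inheritParams build_confusion
#' @param truncation Policy for lists shorter than the universe.
#' @return Object of class `grn_assessment`: `roc` and `pr` curve data
#'   frames, `auroc`, `aupr`, per-prefix counts, and bookkeeping fields.
#' @export
curves_and_auc <- function(ranking, gold, bounds = NULL,
                           mode = c("inferable", "classic"),
                           truncation = c("expected-tail", "strict")) {
  mode <- match.arg(mode)
  truncation <- match.arg(truncation)
  stopifnot(inherits(ranking, "grn_ranking"))
  if (nrow(ranking) == 0L) parse_error("ranking is empty")
  sets <- assessment_sets(gold, bounds, mode)
  keys <- ranking_keys(ranking)
  if (!all(keys %in% sets$universe))
    stop_grn("grn_universe_mismatch_error",
             "ranking contains edges outside the gold-standard universe")
  P <- length(sets$positives)
  N <- length(sets$negatives)
  if (P == 0L || N == 0L)
    stop_grn("grn_degenerate_gold_error", sprintf(
      "degenerate assessment: P' = %d, N' = %d", P, N))

  tp <- cumsum(keys %in% sets$positives)
  fp <- cumsum(keys %in% sets$negatives)
  L <- length(keys)

  if (L < length(sets$universe)) {
    if (truncation == "strict")
      stop_grn("grn_incomplete_ranking_error", sprintf(
        "ranking covers %d of %d universe edges", L, length(sets$universe)))
    # expected-value tail: the unranked edges appended in uniformly random
    # order contribute positives and negatives at a constant expected rate
    p_rem <- P - tp[L]
    n_rem <- N - fp[L]
    r <- p_rem + n_rem
    if (r > 0L) {
      t_steps <- seq_len(r)
      tp <- c(tp, tp[L] + t_steps * (p_rem / r))
      fp <- c(fp, fp[L] + t_steps * (n_rem / r))
    }
  }

  tpr <- tp / P
  fpr <- fp / N
  denom <- tp + fp
  prec <- ifelse(denom > 0, tp / denom, NA_real_)

  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  keep <- !is.na(prec)
  # anchor the PR curve at recall 0 with the precision of the first prefix
  # that counts any edge
  first_prec <- if (any(keep)) prec[which(keep)[1L]] else NA_real_
  pr <- data.frame(recall = c(0, tpr[keep]), precision = c(first_prec, prec[keep]))

  structure(list(roc = roc, pr = pr,
                 auroc = trapezoid_auc(roc$fpr, roc$tpr),
                 aupr = trapezoid_auc(pr$recall, pr$precision),
                 tp = tp, fp = fp, n_positives = P, n_negatives = N,
                 n_ranked = L, mode = mode,
                 network_id = attr(ranking, "network_id")),
            class = "grn_assessment")
}

trapezoid_auc <- function(x, y) {
  if (length(x) < 2L || anyNA(y)) return(NA_real_)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' @export
print.grn_assessment <- function(x, ...) {
  cat(sprintf("grn_assessment (%s): AUROC %.4f  AUPR %.4f  (P' %d, N' %d, %d ranked)\n",
              x$mode, x$auroc, x$aupr, x$n_positives, x$n_negatives, x$n_ranked))
  invisible(x)
}

#' @export
plot.grn_assessment <- function(x, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = sprintf("ROC (%s mode), AUROC = %.3f", x$mode, x$auroc),
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey50")
  } else {
    graphics::plot(x$pr$recall, x$pr$precision, type = "l",
                   xlab = "Recall", ylab = "Precision",
                   main = sprintf("PR (%s mode), AUPR = %.3f", x$mode, x$aupr),
                   xlim = c(0, 1), ylim = c(0, 1), ...)
  }
  invisible(x)
}

#' Fractions of classic errors that are non-inferable
#'
#' Thresholds a ranked list at the gold-standard size P (its top-P edges form
#' the predicted network), computes the classic false positives and false
#' negatives against the gold standard, and reports which fraction of each
#' error set falls among the non-inferable edges. Fractions with an empty
#' error set are undefined and reported as `NA`.
#'
#' @param ranking A `grn_ranking` with at least P entries.
#' @inheritParams build_confusion
#' @return List with `frac_fp_noninf`, `frac_fn_noninf`, `n_fp`, `n_fn`.
#' @export
fraction_noninferable_errors <- function(ranking, gold, bounds) {
  P <- nrow(gold$edges)
  if (nrow(ranking) < P)
    stop_grn("grn_short_ranking_error", sprintf(
      "ranking has %d entries; need at least the gold size %d", nrow(ranking), P))
  pred <- ranking_keys(ranking)[seq_len(P)]
  gkeys <- edge_keys(gold$edges)
  ekeys <- edge_keys(bounds$non_inferable)
  fp <- setdiff(pred, gkeys)
  fn <- setdiff(gkeys, pred)
  list(frac_fp_noninf = if (length(fp)) mean(fp %in% ekeys) else NA_real_,
       frac_fn_noninf = if (length(fn)) mean(fn %in% ekeys) else NA_real_,
       n_fp = length(fp), n_fn = length(fn))
}

#' False negatives common to every submission
#'
#' Thresholds each ranked list at the gold size P and intersects their false
#' negative sets: gold edges that no submission recovered. Reports which
#' fraction of these consensus misses is non-inferable - errors that no
#' method, including a community consensus, could have avoided with the data
#' at hand.
#'
#' @param rankings List of `grn_ranking`, each of length >= P.
#' @inheritParams build_confusion
#' @return List with `common_fn` (edge matrix) and `frac_noninf`
#'   (`NA` if no common false negative exists).
#' @export
common_false_negatives <- function(rankings, gold, bounds) {
  stopifnot(length(rankings) >= 1L)
  P <- nrow(gold$edges)
  gkeys <- edge_keys(gold$edges)
  common <- gkeys
  for (r in rankings) {
    if (nrow(r) < P)
      stop_grn("grn_short_ranking_error",
               "every ranking must list at least the gold size")
    pred <- ranking_keys(r)[seq_len(P)]
    common <- intersect(common, setdiff(gkeys, pred))
  }
  ekeys <- edge_keys(bounds$non_inferable)
  list(common_fn = keys_to_edges(common),
       frac_noninf = if (length(common)) mean(common %in% ekeys) else NA_real_)
}
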