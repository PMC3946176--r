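chain3 <- function() dg(c("A", "B", "C"), "A", "B", "B", "C")

test_that("confusion matrices follow the classic and inferability-aware definitions", {
  gold <- chain3()
  b <- ensemble_bounds(gold)
  pred <- matrix(c("A", "B", "A", "C"), 2, 2, byrow = TRUE)

  classic <- build_confusion(pred, gold, mode = "classic")
  expect_equal(unclass(classic)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 3L))

  inf <- build_confusion(pred, gold, b, mode = "inferable")
  expect_equal(unclass(inf)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 0L, fn = 1L, tn = 3L)) # A->C non-inferable

  none <- build_confusion(NULL, gold, b, mode = "inferable")
  expect_equal(none$tn, 3L) # universe minus upper bound
  expect_equal(none$fn, nrow(b$lower))
  expect_equal(none$tp + none$fp, 0L)

  all_edges <- universe_edges(gold)
  full <- build_confusion(all_edges, gold, b, mode = "inferable")
  expect_equal(full$tp, nrow(b$lower))
  expect_equal(full$fp, 6L - nrow(b$upper))
  expect_equal(full$fn + full$tn, 0L)

  expect_error(build_confusion(pred, gold, mode = "inferable"),
               class = "grn_missing_bounds_error")
  expect_error(build_confusion(matrix(c("A", "Z"), 1), gold, b),
               class = "grn_universe_mismatch_error")
})

test_that("confusion cells are conserved in both modes", {
  set.seed(3)
  for (i in 1:20) {
    g <- random_digraph(5, 0.35)
    b <- ensemble_bounds(g)
    uni <- universe_edges(g)
    pred <- uni[stats::runif(nrow(uni)) < 0.4, , drop = FALSE]
    cc <- build_confusion(pred, g, mode = "classic")
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, nrow(uni))
    ci <- build_confusion(pred, g, b, mode = "inferable")
    expect_equal(ci$tp + ci$fp + ci$tn + ci$fn,
                 nrow(uni) - nrow(b$non_inferable))
  }
})

test_that("perfect and closure rankings achieve the expected AUCs", {
  gold <- chain3()
  b <- ensemble_bounds(gold)

  perfect <- ranked_edge_list(gold$edges[, 1L], gold$edges[, 2L], 2:1)
  for (mode in c("classic", "inferable")) {
    a <- curves_and_auc(perfect, gold, b, mode)
    expect_equal(a$auroc, 1.0)
    expect_equal(a$aupr, 1.0)
  }

  cl <- transitive_closure(gold)
  closure_rank <- ranked_edge_list(cl$edges[, 1L], cl$edges[, 2L],
                                   seq_len(nrow(cl$edges)))
  ai <- curves_and_auc(closure_rank, gold, b, "inferable")
  expect_equal(ai$auroc, 1.0)
  expect_equal(ai$aupr, 1.0)
  ac <- curves_and_auc(closure_rank, gold, b, "classic")
  expect_lt(ac$aupr, 1.0)
})

test_that("curve sweep matches a hand-stepped confusion table", {
  gold <- chain3()
  b <- ensemble_bounds(gold)
  rk <- ranked_edge_list(c("A", "A", "B", "B", "C", "C"),
                         c("C", "B", "C", "A", "A", "B"), 6:1)
  a <- curves_and_auc(rk, gold, b, "inferable")
  # hand-stepped: A->C excluded; TP 0,1,2,2,2,2; FP 0,0,0,1,2,3
  expect_equal(a$tp, c(0, 1, 2, 2, 2, 2))
  expect_equal(a$fp, c(0, 0, 0, 1, 2, 3))
  expect_equal(a$auroc, 1.0)
  expect_equal(a$aupr, 1.0)
})

test_that("curve invariants hold along random rankings", {
  set.seed(9)
  for (i in 1:15) {
    g <- random_digraph(5, 0.3)
    b <- ensemble_bounds(g)
    if (nrow(b$lower) == 0L) next
    rk <- random_ranking(g, seed = i)
    a <- curves_and_auc(rk, g, b, "inferable")
    expect_true(all(diff(a$tp) >= 0) && all(diff(a$fp) >= 0))
    expect_true(all(diff(a$roc$fpr) >= 0))
    expect_gte(min(a$roc$tpr), 0); expect_lte(max(a$roc$tpr), 1)

    # permuting non-inferable edges among their own positions changes nothing
    keys <- paste(rk$from, rk$to, sep = "\x1f")
    epos <- which(keys %in% paste(b$non_inferable[, 1], b$non_inferable[, 2],
                                  sep = "\x1f"))
    if (length(epos) >= 2L) {
      keys2 <- keys
      keys2[epos] <- keys[sample(epos)]
      parts <- do.call(rbind, strsplit(keys2, "\x1f", fixed = TRUE))
      rk2 <- ranked_edge_list(parts[, 1], parts[, 2], rk$confidence)
      a2 <- curves_and_auc(rk2, g, b, "inferable")
      expect_equal(a2$auroc, a$auroc)
      expect_equal(a2$aupr, a$aupr)
    }

    # bounds with empty non-inferable set make the two modes coincide
    trivial <- list(lower = g$edges, upper = g$edges,
                    non_inferable = g$edges[0, , drop = FALSE],
                    gold_size = n_edges(g), nodes = g$nodes)
    class(trivial) <- "grn_bounds"
    ai <- curves_and_auc(rk, g, trivial, "inferable")
    ac <- curves_and_auc(rk, g, mode = "classic")
    expect_equal(ai$auroc, ac$auroc)
    expect_equal(ai$aupr, ac$aupr)
  }
})

test_that("reversed perfect ranking scores AUROC 0 in both modes", {
  gold <- chain3()
  b <- ensemble_bounds(gold)
  uni <- universe_edges(gold)
  gkeys <- paste(gold$edges[, 1], gold$edges[, 2], sep = "\x1f")
  ukeys <- paste(uni[, 1], uni[, 2], sep = "\x1f")
  worst_keys <- c(setdiff(ukeys, gkeys), gkeys)
  parts <- do.call(rbind, strsplit(worst_keys, "\x1f", fixed = TRUE))
  worst <- ranked_edge_list(parts[, 1], parts[, 2], rev(seq_along(worst_keys)))
  expect_equal(curves_and_auc(worst, gold, b, "inferable")$auroc, 0)
  expect_equal(curves_and_auc(worst, gold, mode = "classic")$auroc, 0)
})

test_that("degenerate and strict-truncation cases raise structured errors", {
  cyc3 <- dg(c("A", "B", "C"), "A", "B", "B", "C", "C", "A")
  b <- ensemble_bounds(cyc3) # lower bound empty -> P' = 0
  rk <- random_ranking(cyc3, 1)
  expect_error(curves_and_auc(rk, cyc3, b, "inferable"),
               class = "grn_degenerate_gold_error")

  gold <- chain3()
  bb <- ensemble_bounds(gold)
  short <- ranked_edge_list("A", "B", 1)
  expect_error(curves_and_auc(short, gold, bb, "inferable",
                              truncation = "strict"),
               class = "grn_incomplete_ranking_error")
  # expected tail keeps the curve endpoint at (1, 1)
  a <- curves_and_auc(short, gold, bb, "inferable")
  expect_equal(utils::tail(a$roc$fpr, 1), 1)
  expect_equal(utils::tail(a$roc$tpr, 1), 1)
})

test_that("error fractions attribute classic errors to the non-inferable set", {
  gold <- chain3()
  b <- ensemble_bounds(gold)

  rk <- ranked_edge_list(c("A", "B", "A", "B", "C", "C"),
                         c("C", "A", "B", "C", "A", "B"), 6:1)
  fr <- fraction_noninferable_errors(rk, gold, b)
  expect_equal(fr$frac_fp_noninf, 0.5) # A->C in E-bar, B->A outside upper
  expect_equal(fr$frac_fn_noninf, 0)
  expect_equal(fr$n_fp, 2L)

  perfect <- ranked_edge_list(gold$edges[, 1], gold$edges[, 2], 2:1)
  fp0 <- fraction_noninferable_errors(perfect, gold, b)
  expect_true(is.na(fp0$frac_fp_noninf) && is.na(fp0$frac_fn_noninf))

  ffl <- dg(c("A", "B", "C"), "A", "B", "A", "C", "B", "C")
  bf <- ensemble_bounds(ffl)
  rk2 <- ranked_edge_list(c("A", "B", "C", "A", "B", "C"),
                          c("B", "C", "A", "C", "A", "B"), 6:1)
  fr2 <- fraction_noninferable_errors(rk2, ffl, bf)
  expect_equal(fr2$frac_fp_noninf, 0) # C->A outside the closure
  expect_equal(fr2$frac_fn_noninf, 1) # missed A->C is the shortcut

  expect_error(fraction_noninferable_errors(ranked_edge_list("A", "B", 1),
                                            gold, b),
               class = "grn_short_ranking_error")
})

test_that("common false negatives intersect across submissions", {
  gold <- chain3()
  b <- ensemble_bounds(gold)
  # both rankings rank B->C outside their top-2
  r1 <- ranked_edge_list(c("A", "A", "B", "B", "C", "C"),
                         c("B", "C", "A", "C", "A", "B"), 6:1)
  r2 <- ranked_edge_list(c("A", "C", "B", "B", "A", "C"),
                         c("B", "A", "A", "C", "C", "B"), 6:1)
  res <- common_false_negatives(list(r1, r2), gold, b)
  expect_equal(unname(res$common_fn[, 1:2, drop = FALSE]), rbind(c("B", "C")))
  expect_equal(res$frac_noninf, 0)

  single <- common_false_negatives(list(r1), gold, b)
  fr <- fraction_noninferable_errors(r1, gold, b)
  expect_equal(nrow(single$common_fn), fr$n_fn)

  perfect <- ranked_edge_list(gold$edges[, 1], gold$edges[, 2], 2:1)
  none <- common_false_negatives(list(r1, perfect), gold, b)
  expect_equal(nrow(none$common_fn), 0L)
  expect_true(is.na(none$frac_noninf))
})
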