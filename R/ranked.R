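# A submission to the benchmark is a ranked list of candidate edges, ordered
# by the submitter's confidence that each edge exists.

#' Construct a ranked edge list
#'
#' @param from,to Character vectors of edge tails and heads.
#' @param confidence Numeric confidences; entries are stably re-sorted into
#'   non-increasing confidence order, preserving the input order among ties
#'   (submitted-list semantics: ties keep file order).
#' @param network_id Optional label of the network the list predicts.
#' @return Object of class `grn_ranking`: a data frame with columns `from`,
#'   `to`, `confidence`, plus a `network_id` attribute.
#' @export
ranked_edge_list <- function(from, to, confidence = rev(seq_along(from)),
                             network_id = NA_character_) {
  from <- as.character(from)
  to <- as.character(to)
  confidence <- as.numeric(confidence)
  if (length(to) != length(from) || length(confidence) != length(from))
    parse_error("from, to and confidence must have equal length")
  if (any(is.na(confidence)))
    parse_error("confidences must be numeric and non-missing")
  if (any(from == to))
    self_loop_error("ranked list contains a self-loop")
  keys <- paste(from, to, sep = .KEY_SEP)
  if (anyDuplicated(keys))
    stop_grn("grn_duplicate_edge_error", paste0(
      "duplicate edge in ranked list: ",
      paste(unique(gsub(.KEY_SEP, " -> ", keys[duplicated(keys)], fixed = TRUE)),
            collapse = ", ")))
  ord <- order(-confidence, seq_along(confidence))
  out <- data.frame(from = from[ord], to = to[ord],
                    confidence = confidence[ord],
                    stringsAsFactors = FALSE)
  attr(out, "network_id") <- network_id
  class(out) <- c("grn_ranking", "data.frame")
  out
}

#' @export
print.grn_ranking <- function(x, ...) {
  cat(sprintf("grn_ranking: %d entries (network %s)\n",
              nrow(x), attr(x, "network_id")))
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("  ... and %d more\n", nrow(x) - 5L))
  invisible(x)
}

ranking_keys <- function(ranking) {
  paste(ranking$from, ranking$to, sep = .KEY_SEP)
}
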