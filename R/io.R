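# Readers and writers for the benchmark's file dialects. Gold standards are
# edge lists "regulator<SEP>target<SEP>{0,1}"; predictions are ranked lists
# "regulator<SEP>target<SEP>confidence". Both tab- and comma-separated input
# is accepted (delimiter sniffed from the first data line); tabs are written.
# Unix and Windows line endings are both accepted on read.

read_delim_lines <- function(path) {
  if (!file.exists(path)) parse_error(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

sniff_delim <- function(line) if (grepl("\t", line, fixed = TRUE)) "\t" else ","

split_fields <- function(lines, lineno, n_fields) {
  if (length(lines) == 0L) return(NULL)
  delim <- sniff_delim(lines[[1L]])
  parts <- strsplit(lines, delim, fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad))
    parse_error(sprintf("line %d: expected %d %s-separated fields",
                        lineno[bad[1L]], n_fields,
                        if (delim == "\t") "tab" else "comma"))
  matrix(trimws(unlist(parts)), ncol = n_fields, byrow = TRUE)
}

#' Read a gold-standard network file
#'
#' Each line is `regulator<TAB>target<TAB>{0,1}`: 1 marks a gold edge, 0
#' marks a known absent edge (its endpoints still join the gene universe).
#' The gene universe is the union of all labels seen and any labels supplied
#' via `genes`.
#'
#' @param path File path (tab- or comma-separated).
#' @param genes Optional character vector of additional universe members;
#'   required for an empty file.
#' @return A `grn_digraph`.
#' @export
read_gold_standard <- function(path, genes = NULL) {
  parsed <- read_delim_lines(path)
  fields <- split_fields(parsed$lines, parsed$lineno, 3L)
  if (is.null(fields)) {
    if (is.null(genes))
      parse_error("empty gold-standard file and no explicit gene universe")
    return(grn_digraph(genes))
  }
  bad <- which(!fields[, 3L] %in% c("0", "1"))
  if (length(bad))
    parse_error(sprintf("line %d: third column must be 0 or 1 (got '%s')",
                        parsed$lineno[bad[1L]], fields[bad[1L], 3L]))
  pos <- fields[, 3L] == "1"
  loops <- pos & fields[, 1L] == fields[, 2L]
  if (any(loops))
    self_loop_error(sprintf("line %d: self-loop '%s' in gold standard",
                            parsed$lineno[which(loops)[1L]],
                            fields[which(loops)[1L], 1L]))
  nodes <- unique(c(genes, fields[, 1L], fields[, 2L]))
  grn_digraph(nodes, fields[pos, 1:2, drop = FALSE])
}

#' Read a ranked prediction file
#'
#' Each line is `regulator<TAB>target<TAB>confidence`. Entries are stably
#' re-sorted into non-increasing confidence (file order kept among ties);
#' duplicate edges are an error.
#'
#' @param path File path (tab- or comma-separated).
#' @param network_id Optional label for the predicted network.
#' @return A `grn_ranking`.
#' @export
read_prediction <- function(path, network_id = NA_character_) {
  parsed <- read_delim_lines(path)
  fields <- split_fields(parsed$lines, parsed$lineno, 3L)
  if (is.null(fields)) parse_error(paste0("empty prediction file: ", path))
  conf <- suppressWarnings(as.numeric(fields[, 3L]))
  bad <- which(is.na(conf))
  if (length(bad))
    parse_error(sprintf("line %d: confidence '%s' is not numeric",
                        parsed$lineno[bad[1L]], fields[bad[1L], 3L]))
  ranked_edge_list(fields[, 1L], fields[, 2L], conf, network_id = network_id)
}

#' Write a gold standard / edge set as a tab-separated edge list
#'
#' Positives are written as `from<TAB>to<TAB>1`. With `universe = TRUE` the
#' remaining universe edges follow with a 0 in the third column, so the gene
#' universe survives a round trip.
#'
#' @param g A `grn_digraph`.
#' @param path Output path.
#' @param universe Also write absent universe edges as 0-lines.
#' @export
write_gold_standard <- function(g, path, universe = TRUE) {
  lines <- character(0)
  if (nrow(g$edges))
    lines <- paste(g$edges[, 1L], g$edges[, 2L], "1", sep = "\t")
  if (universe) {
    rest <- edge_setdiff(universe_edges(g), g$edges)
    if (nrow(rest))
      lines <- c(lines, paste(rest[, 1L], rest[, 2L], "0", sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked prediction as a tab-separated list
#' @param ranking A `grn_ranking`.
#' @param path Output path.
#' @export
write_prediction <- function(ranking, path) {
  writeLines(paste(ranking$from, ranking$to,
                   format(ranking$confidence, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   sep = "\t"), path)
  invisible(path)
}

#' Write submission scores as a tab-separated report
#'
#' One row per team: per-network AUROC and AUPR scores, the two metric
#' means, the overall score and the rank. Optionally also writes a
#' structured key-value file (`key<TAB>value` lines) of the same numbers.
#'
#' @param scores Named list of `grn_score` objects (names = team labels).
#' @param path Output path for the table.
#' @param keyvalue_path Optional path for the key-value rendition.
#' @return The ranking data frame, invisibly.
#' @export
write_scores <- function(scores, path, keyvalue_path = NULL) {
  if (length(scores) == 0L) parse_error("no scores to write")
  ranking <- rank_teams(scores)
  ids <- scores[[1L]]$per_network$network_id
  rows <- lapply(ranking$team, function(team) {
    s <- scores[[team]]
    pn <- s$per_network[match(ids, s$per_network$network_id), ]
    vals <- c(stats::setNames(pn$auroc_score, paste0("auroc_score_", ids)),
              stats::setNames(pn$aupr_score, paste0("aupr_score_", ids)),
              mean_auroc_score = s$mean_auroc_score,
              mean_aupr_score = s$mean_aupr_score,
              overall = s$overall,
              rank = ranking$rank[ranking$team == team])
    c(team = team, vapply(vals, function(v) format(v, digits = 15), character(1)))
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(keyvalue_path)) {
    kv <- unlist(lapply(seq_len(nrow(tab)), function(i) {
      paste(paste(tab[i, "team"], colnames(tab)[-1L], sep = "."),
            tab[i, -1L], sep = "\t")
    }))
    writeLines(kv, keyvalue_path)
  }
  invisible(ranking)
}

#' Read back a score report written by [write_scores()]
#' @param path Path to the tab-separated report.
#' @return Data frame with team column and numeric score columns.
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in setdiff(names(df), "team")) df[[col]] <- as.numeric(df[[col]])
  df
}
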