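# Helpers around the DREAM 4 In Silico Network Challenge, the benchmark the
# inferability-aware assessment was designed for: 10-gene and 100-gene
# subchallenges, five GeneNetWeaver-generated gold standards each.

#' Reported ensemble bound sizes of the DREAM 4 gold standards
#'
#' Returns the per-network edge counts reported for the DREAM 4 In Silico
#' Network Challenge gold standards: gold-standard size, ensemble lower and
#' upper bound sizes, and the number of non-inferable edges. These are
#' reference numbers shipped with the package (the gold-standard files
#' themselves are distributed by the DREAM project and are not bundled); they
#' support consistency checks such as non_inferable = upper - lower and the
#' mean non-inferable fraction of the 100-gene gold standards.
#'
#' @return Data frame with columns `size`, `network`, `gold`, `lower`,
#'   `upper`, `non_inferable`.
#' @export
dream4_bound_sizes <- function() {
  utils::read.delim(system.file("extdata", "dream4_bound_sizes.tsv",
                                package = "grnscore", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Recompute ensemble bound sizes from DREAM 4 gold-standard files
#'
#' Reads each gold-standard edge-list file of a subchallenge from `dir`
#' (files named like the DREAM 4 release,
#' `insilico_size<size>_<k>_goldstandard.tsv`), runs [ensemble_bounds()] and
#' tabulates the computed sizes in the same layout as
#' [dream4_bound_sizes()]. The gold-standard files must be obtained from the
#' DREAM project and placed in `dir` by the user.
#'
#' @param dir Directory containing the gold-standard files.
#' @param size Subchallenge size (10 or 100).
#' @param networks Network indices to process.
#' @return Data frame with columns `size`, `network`, `gold`, `lower`,
#'   `upper`, `non_inferable`.
#' @export
dream4_recompute_bounds <- function(dir, size = 10L, networks = 1:5) {
  rows <- lapply(networks, function(k) {
    path <- file.path(dir, sprintf("insilico_size%d_%d_goldstandard.tsv",
                                   size, k))
    gold <- read_gold_standard(path)
    b <- ensemble_bounds(gold)
    data.frame(size = size, network = k, gold = b$gold_size,
               lower = nrow(b$lower), upper = nrow(b$upper),
               non_inferable = nrow(b$non_inferable))
  })
  do.call(rbind, rows)
}
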