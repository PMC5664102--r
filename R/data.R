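# Bundled reference results: the published four-tissue (bone, dentin,
# nerve, vessel) co-regeneration analysis on the STRING v9.1 human
# network. The full-scale inputs (the 2.4M-edge network and the curated
# seed lists) are external and version-dependent; these tables carry the
# final per-pair inferred gene records and the per-stage gene counts, and
# serve as inputs to the summary layer.

#' Reference inferred co-regeneration gene records
#'
#' Per-pair records of the genes inferred for the six pairs of the four
#' tissues bone, dentin, nerve and vessel (Ensembl protein IDs with gene
#' symbols, betweenness, permutation FDR, betweenness ratio, Min-Max
#' interaction score). FDR values reported as `<1/n` are parsed to 0 in
#' the numeric `fdr` column; the printed form is kept in `fdr_display`.
#'
#' @return data.frame with columns `pair_label`, `gene`, `symbol`,
#'   `betweenness`, `fdr`, `fdr_display`, `betweenness_ratio`,
#'   `minmax_score`.
#' @export
regen4_inferred <- function() {
  path <- system.file("extdata", "regen4", "inferred_genes.tsv",
                      package = "ppibridge", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = list(fdr = "character"))
  df$fdr_display <- df$fdr
  df$fdr <- ifelse(grepl("^<", df$fdr), 0, suppressWarnings(as.numeric(df$fdr)))
  df[, c("pair_label", "gene", "symbol", "betweenness", "fdr",
         "fdr_display", "betweenness_ratio", "minmax_score")]
}

#' Reference per-stage gene counts
#'
#' For each of the six tissue pairs: the number of shortest-path genes
#' from the searching procedure, of candidates surviving the permutation
#' FDR filter, and of finally inferred genes.
#'
#' @return data.frame with columns `pair_label`,
#'   `n_shortest_path_genes`, `n_candidates`, `n_inferred`.
#' @export
regen4_stage_counts <- function() {
  path <- system.file("extdata", "regen4", "stage_counts.tsv",
                      package = "ppibridge", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
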