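# Testing procedure: degree-preserving random seed-set pairs and the
# permutation false discovery rate.

#' Permutation test configuration
#'
#' @param n_replicates number of random set pairs to draw (default 1000).
#' @param seed integer root seed. Each replicate derives its own substream
#'   from `(seed, replicate index)`, so results do not depend on execution
#'   order and identical inputs give bit-identical results.
#' @param fdr_threshold significance cutoff on the permutation FDR,
#'   applied strictly (`fdr < threshold`); default 0.05.
#' @return a `permutation_config` list.
#' @export
permutation_config <- function(n_replicates = 1000L, seed = 1L,
                               fdr_threshold = 0.05) {
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_replicates >= 1L, fdr_threshold >= 0, fdr_threshold <= 1)
  structure(list(n_replicates = n_replicates, seed = as.integer(seed),
                 fdr_threshold = fdr_threshold),
            class = "permutation_config")
}

# Evaluate `expr` with the global RNG saved/restored, seeded by `seed`.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Substream seeds for replicates 1..n, a pure function of the root seed.
.replicate_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(2147483646L, n))
}

# Nodes grouped by degree: list indexed by degree value (character key).
.degree_bins <- function(network) {
  split(seq_along(network$nodes), network$degree)
}

# Draw one degree-matched random set (integer indices) given the template
# degree counts (named integer vector, names are degree values). Uses the
# current RNG state.
.sample_matched_idx <- function(bins, deg_counts) {
  out <- integer(sum(deg_counts))
  at <- 0L
  for (d in names(deg_counts)) {
    pool <- bins[[d]]
    k <- deg_counts[[d]]
    if (is.null(pool) || length(pool) < k) {
      stop(sprintf(
        "cannot draw %d node(s) of degree %s: only %d in the network",
        k, d, length(pool)))
    }
    draw <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), k)]
    out[(at + 1L):(at + k)] <- draw
    at <- at + k
  }
  out
}

#' Draw a degree-matched random gene set
#'
#' Returns a set of distinct network nodes whose degree multiset exactly
#' equals the degree multiset of the template's mapped members: for every
#' degree value, the random set contains as many nodes of that degree as
#' the template does. Sampling is uniform without replacement within each
#' degree bin and driven by the current RNG state (call `set.seed()` first
#' for reproducibility).
#'
#' @param network an [interaction_network].
#' @param template a [map_gene_set()] object giving the degree template.
#' @return character vector of node identifiers.
#' @export
sample_degree_matched <- function(network, template) {
  stopifnot(inherits(template, "gene_set"))
  idx <- .node_index(network, template$mapped, "seed gene")
  deg_counts <- table(network$degree[idx])
  bins <- .degree_bins(network)
  network$nodes[.sample_matched_idx(bins, deg_counts)]
}

#' Permutation FDR for observed shortest-path genes
#'
#' For each replicate, draws two random sets degree-matched to the mapped
#' members of `setC` and `setCprime` respectively, reruns the identical
#' cross-pair shortest-path search on them, and records each observed
#' gene's replicate betweenness (0 when the gene lies on no replicate
#' path). The permutation FDR of a gene is `Delta / n_replicates`, where
#' `Delta` counts replicates whose betweenness is strictly greater than
#' the observed value; ties do not count. A high FDR means the gene is
#' recovered by many unrelated set pairs and is not specific to the seed
#' sets under study.
#'
#' @param network an [interaction_network].
#' @param setC,setCprime the seed sets that produced `observed`.
#' @param observed a [search_all_pairs()] result for `(setC, setCprime)`
#'   on the same network.
#' @param config a [permutation_config()].
#' @param all_paths logical, forwarded to the replicate searches; must
#'   match how `observed` was computed.
#' @return an object of class `fdr_result`: named vectors `fdr` and
#'   `exceed_counts` over the observed genes, plus `n_replicates`.
#' @export
permutation_fdr <- function(network, setC, setCprime, observed,
                            config = permutation_config(),
                            all_paths = FALSE) {
  stopifnot(inherits(observed, "path_search_result"),
            inherits(config, "permutation_config"))
  obs_genes <- names(observed$betweenness)
  obs_idx <- .node_index(network, obs_genes, "observed gene")
  obs_val <- as.vector(observed$betweenness)

  degC <- table(network$degree[.node_index(network, setC$mapped)])
  degCp <- table(network$degree[.node_index(network, setCprime$mapped)])
  bins <- .degree_bins(network)

  seeds <- .replicate_seeds(config$seed, config$n_replicates)
  exceed <- integer(length(obs_genes))
  for (i in seq_len(config$n_replicates)) {
    rep_bet <- .with_seed(seeds[i], {
      ci <- .sample_matched_idx(bins, degC)
      cip <- .sample_matched_idx(bins, degCp)
      .search_pairs(network, ci, cip, all_paths = all_paths)$bet
    })
    exceed <- exceed + (rep_bet[obs_idx] > obs_val)
  }
  structure(
    list(fdr = setNames(exceed / config$n_replicates, obs_genes),
         exceed_counts = setNames(exceed, obs_genes),
         n_replicates = config$n_replicates),
    class = "fdr_result"
  )
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("<fdr_result> %d genes, %d replicates, %d below 0.05\n",
              length(x$fdr), x$n_replicates, sum(x$fdr < 0.05)))
  invisible(x)
}

#' Select candidate genes by permutation FDR
#'
#' Genes with `fdr < threshold`, strictly: a gene at exactly the threshold
#' is excluded.
#'
#' @param observed a [search_all_pairs()] result.
#' @param fdr an [permutation_fdr()] result covering all observed genes.
#' @param threshold FDR cutoff (default 0.05).
#' @return character vector of candidate gene identifiers (in the
#'   observed-betweenness order).
#' @export
select_candidates <- function(observed, fdr, threshold = 0.05) {
  stopifnot(inherits(observed, "path_search_result"),
            inherits(fdr, "fdr_result"))
  genes <- names(observed$betweenness)
  if (!length(genes)) return(character(0))
  missing <- setdiff(genes, names(fdr$fdr))
  if (length(missing)) {
    stop("FDR result does not cover observed gene(s): ",
         paste(missing, collapse = ", "))
  }
  genes[fdr$fdr[genes] < threshold]
}

#' Write the per-pair candidate table
#'
#' TSV with columns `gene`, `betweenness`, `exceed_count`, `fdr`.
#'
#' @param observed a [search_all_pairs()] result.
#' @param fdr a matching [permutation_fdr()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fdr_result <- function(observed, fdr, path) {
  genes <- names(observed$betweenness)
  df <- data.frame(gene = genes,
                   betweenness = as.vector(observed$betweenness),
                   exceed_count = as.vector(fdr$exceed_counts[genes]),
                   fdr = as.vector(fdr$fdr[genes]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
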