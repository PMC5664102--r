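# Screening procedure: betweenness-ratio rule, Min-Max interaction-score
# rule, final inference flags, and cross-pair summarization.

#' Screening thresholds
#'
#' Boundary semantics follow the rules literally: a candidate is inferred
#' when its betweenness ratio is strictly greater than `br_min` AND its
#' Min-Max interaction score is greater than or equal to `minmax_min`
#' (400 is the conventional STRING medium-confidence cutoff), AND its
#' permutation FDR is strictly below `fdr_max`.
#'
#' @param br_min exclusive lower bound on the betweenness ratio
#'   (default 0.01).
#' @param minmax_min inclusive lower bound on the Min-Max interaction
#'   score (default 400); 0 disables the rule.
#' @param fdr_max exclusive upper bound on the permutation FDR
#'   (default 0.05).
#' @return a `screening_thresholds` list.
#' @export
screening_thresholds <- function(br_min = 0.01, minmax_min = 400L,
                                 fdr_max = 0.05) {
  stopifnot(br_min >= 0, br_min <= 1,
            minmax_min == 0L || (minmax_min >= 150L && minmax_min <= 999L))
  structure(list(br_min = br_min, minmax_min = as.integer(minmax_min),
                 fdr_max = fdr_max),
            class = "screening_thresholds")
}

#' Betweenness ratio
#'
#' The betweenness of a gene divided by the number of possible cross-set
#' shortest paths, `|C| * |C'|` (mapped set sizes). Under the default
#' one-path-per-pair search this is the fraction of seed pairs whose
#' shortest path passes through the gene, and lies in `[0, 1]`.
#'
#' @param betweenness non-negative path count.
#' @param n_source,n_target mapped sizes of the two seed sets (>= 1).
#' @return numeric ratio.
#' @export
betweenness_ratio <- function(betweenness, n_source, n_target) {
  stopifnot(all(betweenness >= 0), n_source >= 1, n_target >= 1)
  betweenness / (n_source * n_target)
}

#' Min-Max direct interaction score
#'
#' For each seed side, the maximum combined score of a direct edge between
#' the gene and any mapped member of that side (0 when the gene has no
#' direct edge into the side); the Min-Max score is the minimum of the two
#' side-maxima. It is high only when the gene interacts confidently with
#' BOTH seed sets simultaneously.
#'
#' @param network an [interaction_network].
#' @param gene node identifier.
#' @param setC,setCprime [map_gene_set()] objects.
#' @return integer score (0 when either side has no direct edge).
#' @export
min_max_score <- function(network, gene, setC, setCprime) {
  g <- .node_index(network, gene)
  nb <- network$adj_nbr[[g]]
  sc <- network$adj_s[[g]]
  side_max <- function(side) {
    idx <- .node_index(network, side$mapped, "seed gene")
    hit <- nb %in% idx
    if (any(hit)) max(sc[hit]) else 0L
  }
  min(side_max(setC), side_max(setCprime))
}

#' Assemble candidate records for one seed-set pair
#'
#' One row per candidate gene (the observed genes passing the FDR filter)
#' with its full metric profile: betweenness, permutation FDR, betweenness
#' ratio (mapped-size denominator) and Min-Max interaction score.
#'
#' @param network an [interaction_network].
#' @param setC,setCprime the seed sets.
#' @param observed a [search_all_pairs()] result for the pair.
#' @param fdr a matching [permutation_fdr()] result.
#' @param thresholds a [screening_thresholds()] object (used for the FDR
#'   cutoff and carried through to [screen()]).
#' @param symbols optional named character vector mapping identifiers to
#'   display symbols.
#' @return data.frame with columns `gene`, `symbol`, `betweenness`, `fdr`,
#'   `betweenness_ratio`, `minmax_score`, `inferred` (all `inferred` flags
#'   set by [screen()]).
#' @export
candidate_records <- function(network, setC, setCprime, observed, fdr,
                              thresholds = screening_thresholds(),
                              symbols = NULL) {
  genes <- select_candidates(observed, fdr, thresholds$fdr_max)
  if (is.null(symbols)) symbols <- c(setC$symbol, setCprime$symbol)
  sym <- if (length(symbols)) unname(symbols[genes]) else rep(NA_character_, length(genes))
  sym[is.na(sym)] <- ""
  mm <- vapply(genes, function(g) min_max_score(network, g, setC, setCprime),
               numeric(1))
  df <- data.frame(
    gene = genes,
    symbol = sym,
    betweenness = as.vector(observed$betweenness[genes]),
    fdr = as.vector(fdr$fdr[genes]),
    betweenness_ratio = betweenness_ratio(
      as.vector(observed$betweenness[genes]),
      observed$n_source, observed$n_target),
    minmax_score = as.integer(mm),
    stringsAsFactors = FALSE
  )
  screen(df, thresholds)
}

#' Apply the screening rules to candidate records
#'
#' Sets the `inferred` flag of each record to the conjunction
#' `fdr < fdr_max  AND  betweenness_ratio > br_min  AND
#' minmax_score >= minmax_min`, and sorts records by descending
#' betweenness ratio, ties broken by identifier. The operation is
#' idempotent and independent of the input row order.
#'
#' @param candidates data.frame with columns `gene`, `fdr`,
#'   `betweenness_ratio`, `minmax_score` (extra columns pass through).
#' @param thresholds a [screening_thresholds()] object.
#' @return the same data.frame with a logical `inferred` column, sorted.
#' @export
screen <- function(candidates, thresholds = screening_thresholds()) {
  stopifnot(is.data.frame(candidates))
  need <- c("gene", "fdr", "betweenness_ratio", "minmax_score")
  if (!all(need %in% names(candidates))) {
    stop("candidates must have columns: ", paste(need, collapse = ", "))
  }
  candidates$inferred <-
    candidates$fdr < thresholds$fdr_max &
    candidates$betweenness_ratio > thresholds$br_min &
    candidates$minmax_score >= thresholds$minmax_min
  o <- .corder(-candidates$betweenness_ratio, candidates$gene)
  out <- candidates[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize inferred genes across seed-set pairs
#'
#' Inverts a per-pair map of inferred genes into a per-gene membership map
#' and tabulates how many genes were inferred for exactly k pairs.
#'
#' @param per_pair_inferred named list: pair label -> character vector of
#'   inferred gene identifiers. Labels must be distinct.
#' @return an object of class `cross_pair_summary` with `membership`
#'   (named list gene -> sorted pair labels), `counts_by_multiplicity`
#'   (named integer vector, k -> number of genes in exactly k pairs) and a
#'   tidy `table` data.frame (`gene`, `n_pairs`, `pairs`).
#' @export
cross_pair_summary <- function(per_pair_inferred) {
  stopifnot(is.list(per_pair_inferred))
  labels <- names(per_pair_inferred)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("per_pair_inferred must be a named list with distinct pair labels")
  }
  genes <- .csort(unique(unlist(per_pair_inferred, use.names = FALSE)))
  membership <- lapply(setNames(genes, genes), function(g) {
    .csort(labels[vapply(per_pair_inferred, function(v) g %in% v, logical(1))])
  })
  n_pairs <- lengths(membership)
  counts <- if (length(genes)) table(n_pairs) else table(integer(0))
  counts <- setNames(as.integer(counts), names(counts))
  tab <- data.frame(
    gene = genes,
    n_pairs = as.integer(n_pairs),
    pairs = vapply(membership, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  tab <- tab[.corder(-tab$n_pairs, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(membership = membership, counts_by_multiplicity = counts,
         table = tab),
    class = "cross_pair_summary"
  )
}

#' @export
print.cross_pair_summary <- function(x, ...) {
  cat(sprintf("<cross_pair_summary> %d genes across %s\n",
              length(x$membership),
              paste(sprintf("%s pair(s): %d", names(x$counts_by_multiplicity),
                            x$counts_by_multiplicity), collapse = ", ")))
  invisible(x)
}

# Render an FDR of 0 as "<1/n" for human-readable reports; the raw value
# stays in the TSVs.
.format_fdr <- function(fdr, n_replicates) {
  ifelse(fdr == 0, sprintf("<%g", 1 / n_replicates), format(fdr))
}
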