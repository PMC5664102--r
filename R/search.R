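# Searching procedure: one minimum-weight path per cross-set seed pair,
# inner-node extraction, and path-count betweenness.

# Reconstruct the lexicographically smallest minimum-weight path from s to
# t given dt = exact Dijkstra distances from t to every node (undirected
# network, so dist(t, v) == dist(v, t)). Greedy step: from the current node
# u, move to the smallest-index neighbour v on some optimal continuation,
# i.e. with dt[v] == dt[u] - w(u, v). Choosing the smallest feasible next
# node at every step yields the bytewise-smallest optimal node sequence.
# All quantities are sums of integer weights, so `==` is exact.
.reconstruct_path <- function(network, s, t, dt) {
  path <- integer(32L)
  path[1L] <- s
  len <- 1L
  u <- s
  while (u != t) {
    nb <- network$adj_nbr[[u]]
    hit <- which(dt[nb] == dt[u] - network$adj_w[[u]])
    if (!length(hit)) stop("internal error: broken shortest-path invariant")
    u <- nb[hit[1L]]  # neighbours sorted ascending => lexicographic choice
    len <- len + 1L
    if (len > length(path)) path <- c(path, integer(length(path)))
    path[len] <- u
  }
  path[seq_len(len)]
}

# Distances from each node in `from_idx` to all nodes (matrix
# |from_idx| x n). Dijkstra on the integer weights.
.dist_from <- function(network, from_idx) {
  igraph::distances(network$graph, v = from_idx,
                    weights = igraph::E(network$graph)$weight,
                    algorithm = "dijkstra")
}

#' Weighted shortest path between two nodes
#'
#' Dijkstra shortest path on edge weights `w = 1000 - S`. Among co-optimal
#' paths the tie is broken deterministically: the lexicographically
#' (bytewise) smallest node sequence is returned, so results are identical
#' across platforms and runs.
#'
#' @param network an [interaction_network].
#' @param source,target node identifiers; must differ.
#' @return a list with `nodes` (identifier sequence from source to target)
#'   and `total_weight` (sum of edge weights), or `NULL` when no path
#'   exists.
#' @export
shortest_path <- function(network, source, target) {
  if (identical(source, target)) {
    stop("source and target must differ (identical-endpoint pairs are skipped)")
  }
  s <- .node_index(network, source)
  t <- .node_index(network, target)
  dt <- .dist_from(network, t)[1L, ]
  if (!is.finite(dt[s])) return(NULL)
  idx <- .reconstruct_path(network, s, t, dt)
  list(nodes = network$nodes[idx], total_weight = unname(dt[s]))
}

# Core pair search on integer node indices. Returns the full betweenness
# vector (length n, seed positions zeroed) plus pair bookkeeping. When
# `all_paths` is TRUE every co-optimal path of a pair contributes (counted
# via the shortest-path DAG, sigma_s(v) * sigma_t(v) paths through v);
# the default counts the single tie-broken path per pair.
.search_pairs <- function(network, src_idx, tgt_idx, all_paths = FALSE) {
  n <- length(network$nodes)
  bet <- numeric(n)
  seeds <- union(src_idx, tgt_idx)
  attempted <- 0L
  connected <- 0L
  skipped <- 0L
  D <- .dist_from(network, tgt_idx)
  for (ti in seq_along(tgt_idx)) {
    t <- tgt_idx[ti]
    dt <- D[ti, ]
    for (s in src_idx) {
      if (s == t) next
      attempted <- attempted + 1L
      if (!is.finite(dt[s])) {
        skipped <- skipped + 1L
        next
      }
      connected <- connected + 1L
      if (all_paths) {
        ds <- .dist_from(network, s)[1L, ]
        on_dag <- which(is.finite(ds) & is.finite(dt) & ds + dt == dt[s])
        sig_s <- .path_counts(network, s, ds, on_dag)
        sig_t <- .path_counts(network, t, dt, on_dag)
        inner <- setdiff(on_dag, c(s, t))
        bet[inner] <- bet[inner] + sig_s[inner] * sig_t[inner]
      } else {
        path <- .reconstruct_path(network, s, t, dt)
        if (length(path) > 2L) {
          inner <- path[-c(1L, length(path))]
          bet[inner] <- bet[inner] + 1
        }
      }
    }
  }
  bet[seeds] <- 0
  list(bet = bet, n_pairs_attempted = attempted,
       n_pairs_connected = connected, n_pairs_skipped = skipped)
}

# Number of optimal paths from root to each node of the shortest-path DAG,
# by dynamic programming in increasing distance-from-root order.
.path_counts <- function(network, root, droot, on_dag) {
  sig <- numeric(length(droot))
  sig[root] <- 1
  for (v in on_dag[order(droot[on_dag])]) {
    if (v == root) next
    nb <- network$adj_nbr[[v]]
    pred <- nb[droot[nb] + network$adj_w[[v]] == droot[v]]
    sig[v] <- sum(sig[pred])
  }
  sig
}

#' Search shortest paths between every cross-pair of two seed sets
#'
#' For every ordered pair `(s, t)` with `s` in the mapped members of `setC`
#' and `t` in the mapped members of `setCprime` (skipping `s == t`), finds
#' the minimum-weight path and increments the betweenness count of every
#' inner node (endpoints excluded). Nodes belonging to either mapped seed
#' set are excluded from the betweenness map: the purpose of the search is
#' to discover genes outside the seed sets. Disconnected pairs are skipped
#' and counted, not treated as errors.
#'
#' @param network an [interaction_network].
#' @param setC,setCprime [map_gene_set()] objects mapped onto `network`.
#' @param all_paths logical; if `TRUE`, every co-optimal path of a pair
#'   contributes to betweenness instead of the single tie-broken path.
#'   Default `FALSE`: one path per pair, so betweenness is bounded by the
#'   number of connected pairs and the betweenness ratio by 1.
#' @return an object of class `path_search_result`: `pair_label`,
#'   `betweenness` (named vector over non-seed inner nodes, sorted by
#'   descending betweenness then identifier), `n_source`, `n_target`
#'   (mapped sizes) and pair bookkeeping counts.
#' @export
search_all_pairs <- function(network, setC, setCprime, all_paths = FALSE) {
  stopifnot(inherits(setC, "gene_set"), inherits(setCprime, "gene_set"))
  src_idx <- .node_index(network, setC$mapped, "seed gene")
  tgt_idx <- .node_index(network, setCprime$mapped, "seed gene")
  res <- .search_pairs(network, src_idx, tgt_idx, all_paths = all_paths)
  keep <- which(res$bet > 0)
  bet <- setNames(res$bet[keep], network$nodes[keep])
  o <- .corder(-bet, names(bet))
  structure(
    list(
      pair_label = c(setC$label, setCprime$label),
      betweenness = bet[o],
      n_source = length(setC$mapped),
      n_target = length(setCprime$mapped),
      n_pairs_attempted = res$n_pairs_attempted,
      n_pairs_connected = res$n_pairs_connected,
      n_pairs_skipped = res$n_pairs_skipped
    ),
    class = "path_search_result"
  )
}

#' @export
print.path_search_result <- function(x, ...) {
  cat(sprintf(
    "<path_search_result> %s-%s: %d x %d seeds, %d/%d pairs connected, %d shortest-path genes\n",
    x$pair_label[1L], x$pair_label[2L], x$n_source, x$n_target,
    x$n_pairs_connected, x$n_pairs_attempted, length(x$betweenness)
  ))
  invisible(x)
}

#' Write the per-pair shortest-path gene table
#'
#' TSV with columns `gene` and `betweenness`, sorted by descending
#' betweenness then identifier.
#'
#' @param result a [search_all_pairs()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_search_result <- function(result, path) {
  df <- data.frame(gene = names(result$betweenness),
                   betweenness = as.vector(result$betweenness),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
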