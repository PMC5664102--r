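# Independent oracle: exhaustive enumeration of all simple paths between
# two nodes, by depth-first search over the adjacency lists. Returns the
# minimum total weight and the bytewise-smallest node sequence among the
# minimum-weight paths, or NULL when no path exists. Only usable on tiny
# graphs; deliberately independent of the Dijkstra-based implementation.
brute_force_shortest <- function(network, source, target) {
  n <- length(network$nodes)
  s <- match(source, network$nodes)
  t <- match(target, network$nodes)
  stopifnot(!is.na(s), !is.na(t), s != t)
  best_w <- Inf
  best_paths <- list()
  visited <- logical(n)
  dfs <- function(u, path, w) {
    if (u == t) {
      if (w < best_w) {
        best_w <<- w
        best_paths <<- list(path)
      } else if (w == best_w) {
        best_paths[[length(best_paths) + 1L]] <<- path
      }
      return(invisible())
    }
    nb <- network$adj_nbr[[u]]
    ws <- network$adj_w[[u]]
    for (k in seq_along(nb)) {
      v <- nb[k]
      if (!visited[v]) {
        visited[v] <<- TRUE
        dfs(v, c(path, v), w + ws[k])
        visited[v] <<- FALSE
      }
    }
  }
  visited[s] <- TRUE
  dfs(s, s, 0)
  if (!length(best_paths)) return(NULL)
  seqs <- vapply(best_paths, function(p)
    paste(network$nodes[p], collapse = "\r"), character(1))
  lex <- best_paths[[order(seqs, method = "radix")[1L]]]
  list(total_weight = best_w,
       nodes = network$nodes[lex],
       n_optimal = length(best_paths))
}

# A small network from a compact edge string "A-B:900,B-C:400,..."
net_from_string <- function(txt) {
  parts <- strsplit(strsplit(txt, ",")[[1]], "[-:]")
  interaction_network(data.frame(
    node_a = vapply(parts, `[`, character(1), 1L),
    node_b = vapply(parts, `[`, character(1), 2L),
    score = as.integer(vapply(parts, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  ))
}

# A mapped gene set without touching files
gset <- function(ids, label, network) {
  suppressWarnings(map_gene_set(ids, label, network))
}
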