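#' @import data.table
#' @importFrom stats setNames
#' @importFrom utils write.table read.delim
NULL

.onLoad <- function(libname, pkgname) {
  # data.table is used internally; keep its threading modest so runs are
  # well-behaved on single-CPU machines.
  if (requireNamespace("data.table", quietly = TRUE)) {
    data.table::setDTthreads(1L)
  }
  invisible(NULL)
}

# Canonical sort used everywhere an ordering must be platform-independent:
# radix sorting compares bytes (C locale), so node identifiers order the
# same way on every system regardless of locale settings.
.csort <- function(x) sort(x, method = "radix")
.corder <- function(...) order(..., method = "radix")

#' Construct an interaction network from an edge table
#'
#' Builds the undirected, confidence-weighted protein-protein interaction
#' network used throughout the package. Each edge carries an integer
#' combined score `S` (STRING convention, 150--999) and a derived weight
#' `w = 1000 - S`, so that high-confidence interactions become short edges
#' and Dijkstra shortest paths preferentially traverse confident
#' interactions.
#'
#' Reciprocal duplicate rows (`a,b` and `b,a`) collapse to a single
#' undirected edge keeping the maximum score; self-loop rows are dropped
#' (a self-loop can never be part of a simple path between distinct
#' endpoints).
#'
#' @param edges a data.frame with columns `node_a`, `node_b`, `score`
#'   (integer combined scores).
#' @param min_score optional integer; edges with `score < min_score` are
#'   discarded before construction.
#' @return an object of class `interaction_network`: the igraph graph plus
#'   node index, canonical edge table and adjacency lists.
#' @export
interaction_network <- function(edges, min_score = NULL) {
  stopifnot(is.data.frame(edges))
  cols <- c("node_a", "node_b", "score")
  if (!all(cols %in% names(edges))) {
    stop("`edges` must have columns node_a, node_b, score")
  }
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  s <- edges$score
  if (!is.numeric(s) || any(is.na(s)) || any(s != round(s))) {
    stop("scores must be integers")
  }
  s <- as.integer(s)
  if (length(a) && (min(s) < 1L || max(s) > 999L)) {
    stop("scores must lie in [1, 999] so that weights 1000 - S are positive")
  }
  if (!is.null(min_score)) {
    keep <- s >= as.integer(min_score)
    a <- a[keep]; b <- b[keep]; s <- s[keep]
  }
  keep <- a != b
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  if (!length(a)) stop("empty network: no edges left after filtering")

  dt <- data.table(a = pmin(a, b), b = pmax(a, b), score = s)
  dt <- dt[, list(score = max(score)), by = c("a", "b")]
  data.table::setorderv(dt, c("a", "b"))
  dt[, "weight" := 1000L - dt$score]

  nodes <- .csort(unique(c(dt$a, dt$b)))
  n <- length(nodes)
  ai <- match(dt$a, nodes)
  bi <- match(dt$b, nodes)

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  g <- igraph::add_edges(g, rbind(ai, bi))
  g <- igraph::set_edge_attr(g, "score", value = dt$score)
  g <- igraph::set_edge_attr(g, "weight", value = dt$weight)

  # Adjacency lists with neighbours in ascending index order (== byte order
  # of identifiers): the shortest-path tie-break relies on this ordering.
  from <- c(ai, bi)
  to <- c(bi, ai)
  w <- rep.int(dt$weight, 2L)
  sc <- rep.int(dt$score, 2L)
  o <- order(from, to)
  f <- factor(from[o], levels = seq_len(n))
  adj_nbr <- unname(split(to[o], f))
  adj_w <- unname(split(w[o], f))
  adj_s <- unname(split(sc[o], f))

  structure(
    list(
      graph = g,
      nodes = nodes,
      edges = as.data.frame(dt[, c("a", "b", "score", "weight")]),
      adj_nbr = adj_nbr,
      adj_w = adj_w,
      adj_s = adj_s,
      degree = lengths(adj_nbr)
    ),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network> %d nodes, %d edges, scores %d-%d\n",
    length(x$nodes), nrow(x$edges), min(x$edges$score), max(x$edges$score)
  ))
  invisible(x)
}

#' Number of nodes / edges of an interaction network
#' @param network an `interaction_network`.
#' @return integer count.
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Parse a STRING-format protein links file
#'
#' Reads a whitespace-delimited protein links file in the STRING dialect:
#' one header line (`protein1 protein2 combined_score`) followed by rows
#' `proteinA proteinB score`. Gzip-compressed files are read transparently.
#' A generic 3-column edge-list TSV with a header is accepted with the same
#' semantics. STRING files list each interaction in both directions; the
#' two rows collapse to one undirected edge keeping the maximum score.
#'
#' @param path path to the links file (optionally `.gz`).
#' @param min_score optional integer; rows with a combined score below this
#'   value are excluded. `NULL` (default) keeps the full file.
#' @return an [interaction_network].
#' @export
parse_string_links <- function(path, min_score = NULL) {
  if (!file.exists(path)) stop("cannot read interaction file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  if (length(lines) < 1L) stop("empty network: file has no rows")
  body <- lines[-1L]  # header line required by the dialect
  nonblank <- which(nzchar(trimws(body)))
  if (!length(nonblank)) stop("empty network: file has no data rows")
  fields <- strsplit(trimws(body[nonblank]), "[ \t]+")
  nf <- lengths(fields)
  # 3 columns (protein1 protein2 combined_score) or 4 (the canonical
  # edge-list dialect written by write_edge_list, with a weight column
  # that is redundant and ignored on input)
  if (any(nf < 3L | nf > 4L)) {
    first <- which(nf < 3L | nf > 4L)[1L]
    stop(sprintf("malformed row at line %d: expected 3 or 4 columns, found %d",
                 nonblank[first] + 1L, nf[first]))
  }
  na <- vapply(fields, `[`, character(1), 1L)
  nb <- vapply(fields, `[`, character(1), 2L)
  sc <- vapply(fields, `[`, character(1), 3L)
  ok <- grepl("^[0-9]+$", sc)
  if (!all(ok)) {
    first <- which(!ok)[1L]
    stop(sprintf("malformed row at line %d: score '%s' is not an integer",
                 nonblank[first] + 1L, sc[first]))
  }
  interaction_network(
    data.frame(node_a = na, node_b = nb, score = as.integer(sc),
               stringsAsFactors = FALSE),
    min_score = min_score
  )
}

#' Write a network as a canonical edge-list TSV
#'
#' One row per undirected edge with columns `node_a`, `node_b`, `score`,
#' `weight`, `node_a < node_b` bytewise, rows sorted. Re-parsing the file
#' with [parse_string_links()] reproduces the network exactly.
#'
#' @param network an `interaction_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Unweighted node degree
#'
#' The count of incident edges of a node. Degree is the invariant preserved
#' by the permutation null: random seed sets are drawn so that their degree
#' multiset matches the template set exactly.
#'
#' @param network an `interaction_network`.
#' @param nodes character vector of node identifiers; `NULL` returns all
#'   degrees named by node.
#' @return named integer vector of degrees.
#' @export
node_degree <- function(network, nodes = NULL) {
  if (is.null(nodes)) {
    return(setNames(network$degree, network$nodes))
  }
  idx <- match(nodes, network$nodes)
  if (anyNA(idx)) {
    stop("unknown node(s): ", paste(nodes[is.na(idx)], collapse = ", "))
  }
  setNames(network$degree[idx], nodes)
}

.node_index <- function(network, nodes, what = "node") {
  idx <- match(nodes, network$nodes)
  if (anyNA(idx)) {
    stop(sprintf("unknown %s(s): %s", what,
                 paste(nodes[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Map a requested gene set onto the network
#'
#' Partitions a list of requested identifiers into those present in the
#' network (`mapped`) and those absent (`dropped`). Duplicates are removed
#' keeping first-occurrence order. Every downstream quantity that depends
#' on a set size -- the number of attempted seed pairs, the betweenness
#' ratio denominator, the degree template of the permutation null -- uses
#' the mapped members only.
#'
#' @param requested character vector of identifiers, or a data.frame as
#'   returned by [read_gene_set()] (column `id`, optional column `symbol`).
#' @param label short label for the set (e.g. a tissue name).
#' @param network an `interaction_network`.
#' @return an object of class `gene_set` with fields `label`, `requested`,
#'   `mapped`, `dropped` and a `symbol` lookup (named character vector,
#'   possibly empty).
#' @export
map_gene_set <- function(requested, label, network) {
  symbols <- character(0)
  if (is.data.frame(requested)) {
    ids <- as.character(requested$id)
    if (!is.null(requested$symbol)) {
      has <- !is.na(requested$symbol) & nzchar(requested$symbol)
      symbols <- setNames(as.character(requested$symbol[has]), ids[has])
    }
    requested <- ids
  }
  requested <- as.character(requested)
  if (!length(requested)) stop("requested gene set is empty")
  uniq <- requested[!duplicated(requested)]
  present <- uniq %in% network$nodes
  mapped <- uniq[present]
  dropped <- uniq[!present]
  if (length(dropped)) {
    warning(sprintf(
      "gene set '%s': %d identifier(s) not in network, dropped: %s",
      label, length(dropped), paste(dropped, collapse = ", ")
    ), call. = FALSE)
  }
  if (!length(mapped)) {
    stop(sprintf("no seed genes of set '%s' are present in the network", label))
  }
  structure(
    list(label = label, requested = uniq, mapped = mapped,
         dropped = dropped, symbol = symbols),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> '%s': %d requested, %d mapped, %d dropped\n",
              x$label, length(x$requested), length(x$mapped),
              length(x$dropped)))
  invisible(x)
}

#' Read a seed gene-set file
#'
#' Plain text, one identifier per line; `#` starts a comment; blank lines
#' are ignored. A second tab-separated column, when present, carries a
#' display symbol (e.g. an HGNC gene symbol alongside an Ensembl protein
#' ID).
#'
#' @param path path to the file.
#' @return data.frame with columns `id` and `symbol` (`NA` when absent).
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("cannot read gene set file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("gene set file has no identifiers: ", path)
  parts <- strsplit(lines, "\t")
  id <- vapply(parts, `[`, character(1), 1L)
  symbol <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_,
                   character(1))
  data.frame(id = trimws(id), symbol = trimws(symbol), stringsAsFactors = FALSE)
}

#' @rdname read_gene_set
#' @param ids character vector of identifiers to write.
#' @param symbols optional character vector of display symbols, same length.
#' @export
write_gene_set <- function(ids, path, symbols = NULL) {
  lines <- if (is.null(symbols)) ids else paste(ids, symbols, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
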