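# Reproducible synthetic networks with the structure the method assumes:
# two seed modules joined by planted high-confidence bridge nodes, plus a
# low-confidence noise web, and plain random score networks.

#' Specification for a planted-bridge fixture
#'
#' Describes a network in which every source seed connects to every bridge
#' node and every bridge to every target seed with `strong_score` edges,
#' while `n_noise_nodes` background nodes attach to the rest of the
#' network through `weak_score` edges with probability `noise_edge_prob`
#' per node pair. Because `strong_score > weak_score`, the two-edge
#' source-bridge-target route (weight `2 * (1000 - strong_score)`) beats
#' any route through the noise web (at least `2 * (1000 - weak_score)`),
#' so the bridges are the ground-truth shortest-path genes.
#'
#' @param n_source_seeds,n_target_seeds seed module sizes (default 3 and 4).
#' @param n_bridges number of planted bridge nodes (default 1).
#' @param n_noise_nodes number of background nodes (default 80); the noise
#'   web gives seeds and bridges realistic degrees so that degree-matched
#'   permutation draws have nodes to choose from.
#' @param strong_score,weak_score integer combined scores in `[150, 999]`
#'   with `strong_score > weak_score` (defaults 900 and 300).
#' @param noise_edge_prob probability of each noise edge (default 0.05).
#' @param seed RNG seed for the noise web (default 1).
#' @return a `bridge_fixture_spec` list.
#' @export
bridge_fixture_spec <- function(n_source_seeds = 3L, n_target_seeds = 4L,
                                n_bridges = 1L, n_noise_nodes = 80L,
                                strong_score = 900L, weak_score = 300L,
                                noise_edge_prob = 0.05, seed = 1L) {
  spec <- list(
    n_source_seeds = as.integer(n_source_seeds),
    n_target_seeds = as.integer(n_target_seeds),
    n_bridges = as.integer(n_bridges),
    n_noise_nodes = as.integer(n_noise_nodes),
    strong_score = as.integer(strong_score),
    weak_score = as.integer(weak_score),
    noise_edge_prob = noise_edge_prob,
    seed = as.integer(seed)
  )
  stopifnot(spec$n_source_seeds >= 1L, spec$n_target_seeds >= 1L,
            spec$n_bridges >= 0L, spec$n_noise_nodes >= 0L,
            spec$strong_score >= 150L, spec$strong_score <= 999L,
            spec$weak_score >= 150L, spec$weak_score <= 999L,
            spec$noise_edge_prob >= 0, spec$noise_edge_prob <= 1)
  # Dominance: the planted two-edge route must beat the cheapest
  # conceivable noise route (also two edges, but at weak confidence).
  if (2L * (1000L - spec$strong_score) >= 2L * (1000L - spec$weak_score)) {
    stop("strong_score must exceed weak_score so bridge routes dominate")
  }
  structure(spec, class = "bridge_fixture_spec")
}

#' Generate a planted-bridge network with its seed sets
#'
#' @param spec a [bridge_fixture_spec()].
#' @return a list with `network` ([interaction_network]), `set_source` and
#'   `set_target` ([map_gene_set()] objects labelled "source"/"target"),
#'   and `bridges` (character vector of ground-truth bridge identifiers).
#' @export
planted_bridge_network <- function(spec = bridge_fixture_spec()) {
  stopifnot(inherits(spec, "bridge_fixture_spec"))
  src <- sprintf("src%03d", seq_len(spec$n_source_seeds))
  tgt <- sprintf("tgt%03d", seq_len(spec$n_target_seeds))
  brg <- if (spec$n_bridges > 0L) sprintf("brg%03d", seq_len(spec$n_bridges)) else character(0)
  nse <- if (spec$n_noise_nodes > 0L) sprintf("nse%03d", seq_len(spec$n_noise_nodes)) else character(0)

  a <- character(0); b <- character(0); s <- integer(0)
  if (length(brg)) {
    sb <- expand.grid(a = src, b = brg, stringsAsFactors = FALSE)
    bt <- expand.grid(a = brg, b = tgt, stringsAsFactors = FALSE)
    a <- c(sb$a, bt$a); b <- c(sb$b, bt$b)
    s <- rep.int(spec$strong_score, length(a))
  }
  if (length(nse)) {
    others <- c(src, tgt, brg)
    # candidate pairs with at least one noise endpoint
    nn <- if (length(nse) >= 2L) t(utils::combn(nse, 2L)) else matrix(character(0), ncol = 2L)
    no <- expand.grid(a = nse, b = others, stringsAsFactors = FALSE)
    cand_a <- c(nn[, 1L], no$a)
    cand_b <- c(nn[, 2L], no$b)
    pick <- .with_seed(spec$seed,
                       stats::runif(length(cand_a)) < spec$noise_edge_prob)
    a <- c(a, cand_a[pick]); b <- c(b, cand_b[pick])
    s <- c(s, rep.int(spec$weak_score, sum(pick)))
  }
  if (!length(a)) stop("fixture spec produced no edges")
  net <- interaction_network(
    data.frame(node_a = a, node_b = b, score = s, stringsAsFactors = FALSE))
  # seeds disconnected from everything (possible only with n_bridges = 0
  # and sparse noise) are dropped by mapping, with the usual warning
  set_source <- suppressWarnings(map_gene_set(src, "source", net))
  set_target <- suppressWarnings(map_gene_set(tgt, "target", net))
  list(network = net, set_source = set_source, set_target = set_target,
       bridges = brg)
}

#' Generate an Erdos-Renyi random network with uniform scores
#'
#' Each unordered node pair receives an edge with probability `edge_prob`;
#' edge scores are drawn uniformly over the full combined-score range
#' `[150, 999]`. Nodes left without any edge do not appear in the network
#' (nodes exist only as interaction endpoints).
#'
#' @param n_nodes number of candidate nodes (>= 2).
#' @param edge_prob edge probability in `(0, 1]`.
#' @param seed RNG seed.
#' @return an [interaction_network].
#' @export
random_score_network <- function(n_nodes, edge_prob, seed = 1L) {
  stopifnot(n_nodes >= 2L, edge_prob > 0, edge_prob <= 1)
  nodes <- sprintf("n%04d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2L))
  .with_seed(as.integer(seed), {
    pick <- stats::runif(nrow(pairs)) < edge_prob
    if (!any(pick)) stop("empty network: no edges drawn; raise edge_prob")
    score <- sample(150:999, sum(pick), replace = TRUE)
    interaction_network(data.frame(
      node_a = pairs[pick, 1L], node_b = pairs[pick, 2L],
      score = score, stringsAsFactors = FALSE))
  })
}
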