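test_that("confident detours beat weak direct edges", {
  # A-B score 900 (weight 100) vs A-C-B at score 999 each (weight 1 + 1):
  # both simple paths enumerated by the oracle; the two-edge route wins.
  net <- net_from_string("A-B:900,A-C:999,C-B:999")
  p <- shortest_path(net, "A", "B")
  oracle <- brute_force_shortest(net, "A", "B")
  expect_equal(p$total_weight, 2)
  expect_equal(p$nodes, c("A", "C", "B"))
  expect_equal(p$total_weight, oracle$total_weight)
  expect_equal(p$nodes, oracle$nodes)
})

test_that("single edges and disconnected pairs behave as contracted", {
  net <- net_from_string("A-B:993")
  p <- shortest_path(net, "A", "B")
  expect_equal(p$nodes, c("A", "B"))
  expect_equal(p$total_weight, 7)

  two <- net_from_string("A-B:900,C-D:900")
  expect_null(shortest_path(two, "A", "C"))

  expect_error(shortest_path(net, "A", "A"), "must differ")
  expect_error(shortest_path(net, "A", "Z"), "unknown")
})

test_that("ties break to the lexicographically smallest node sequence", {
  # two co-optimal routes A-x-B and A-m-B; "m" < "x" bytewise
  net <- net_from_string("A-x:800,x-B:800,A-m:800,m-B:800")
  p <- shortest_path(net, "A", "B")
  expect_equal(p$nodes, c("A", "m", "B"))
  oracle <- brute_force_shortest(net, "A", "B")
  expect_equal(oracle$n_optimal, 2L)
  expect_equal(p$nodes, oracle$nodes)
})

test_that("Dijkstra agrees with exhaustive enumeration on random graphs", {
  for (s in 1:30) {
    net <- random_score_network(7, 0.35, seed = 1000 + s)
    nodes <- net$nodes
    for (a in nodes) for (b in nodes) {
      if (a >= b) next
      p <- shortest_path(net, a, b)
      oracle <- brute_force_shortest(net, a, b)
      if (is.null(oracle)) {
        expect_null(p)
      } else {
        expect_equal(p$total_weight, oracle$total_weight)
        expect_equal(p$nodes, oracle$nodes)  # including the tie-break
      }
    }
  }
})

test_that("path weight is symmetric in its endpoints", {
  net <- random_score_network(20, 0.25, seed = 5)
  nodes <- net$nodes[1:8]
  for (a in nodes[1:4]) for (b in nodes[5:8]) {
    f <- shortest_path(net, a, b)
    r <- shortest_path(net, b, a)
    expect_identical(is.null(f), is.null(r))
    if (!is.null(f)) expect_equal(f$total_weight, r$total_weight)
  }
})

test_that("cross-pair search counts inner nodes only", {
  net <- net_from_string("a-x:500,x-b:500")
  r <- search_all_pairs(net, gset("a", "C", net), gset("b", "Cp", net))
  expect_equal(r$betweenness, c(x = 1))
  expect_equal(r$n_pairs_connected, 1L)

  # direct strong edge: the optimal path has no inner node
  net2 <- net_from_string("a-b:999,a-x:600,x-b:600")
  r2 <- search_all_pairs(net2, gset("a", "C", net2), gset("b", "Cp", net2))
  expect_length(r2$betweenness, 0L)
  expect_equal(r2$n_pairs_connected, 1L)
})

test_that("seed genes never appear in the betweenness map", {
  # path a1-a2-b: a2 is a seed of C and the inner node of the (a1, b) path
  net <- net_from_string("a1-a2:900,a2-b:900")
  r <- search_all_pairs(net, gset(c("a1", "a2"), "C", net),
                        gset("b", "Cp", net))
  expect_false(any(names(r$betweenness) %in% c("a1", "a2", "b")))
  expect_length(r$betweenness, 0L)
})

test_that("a planted bridge collects one path per seed pair", {
  fx <- planted_bridge_network(bridge_fixture_spec(
    n_source_seeds = 3, n_target_seeds = 4, n_bridges = 1,
    n_noise_nodes = 0, strong_score = 999, weak_score = 300,
    noise_edge_prob = 0, seed = 1))
  r <- search_all_pairs(fx$network, fx$set_source, fx$set_target)
  expect_equal(r$betweenness, c(brg001 = 12))
  expect_equal(r$n_pairs_attempted, 12L)
  expect_equal(r$n_pairs_connected, 12L)
  # confirmed by exhaustive enumeration on this <= 10-node instance
  oracle <- brute_force_shortest(fx$network, "src001", "tgt004")
  expect_equal(oracle$nodes, c("src001", "brg001", "tgt004"))
})

test_that("betweenness is bounded by the number of connected pairs", {
  net <- random_score_network(40, 0.12, seed = 17)
  C <- gset(net$nodes[1:4], "C", net)
  Cp <- gset(net$nodes[35:40], "Cp", net)
  r <- search_all_pairs(net, C, Cp)
  expect_true(all(r$betweenness <= r$n_pairs_connected))
  expect_lte(r$n_pairs_connected, r$n_source * r$n_target)
  expect_equal(r$n_pairs_connected + r$n_pairs_skipped, r$n_pairs_attempted)
})

test_that("overlapping seed sets skip identical-endpoint pairs", {
  net <- net_from_string("a-x:800,x-b:800,a-s:800,s-b:800,s-x:800")
  C <- gset(c("a", "s"), "C", net)
  Cp <- gset(c("b", "s"), "Cp", net)
  r <- search_all_pairs(net, C, Cp)
  expect_equal(r$n_pairs_attempted, 2L * 2L - 1L)
  # the shared gene s is a seed, so it cannot be a shortest-path gene
  expect_false("s" %in% names(r$betweenness))
})

test_that("removing a full-betweenness bridge lengthens or cuts every path", {
  fx <- planted_bridge_network(bridge_fixture_spec(
    n_source_seeds = 2, n_target_seeds = 2, n_bridges = 1,
    n_noise_nodes = 10, strong_score = 950, weak_score = 300,
    noise_edge_prob = 0.3, seed = 2))
  r <- search_all_pairs(fx$network, fx$set_source, fx$set_target)
  expect_equal(unname(r$betweenness["brg001"]), 4)
  pruned <- fx$network$edges
  pruned <- pruned[pruned$a != "brg001" & pruned$b != "brg001", ]
  net2 <- interaction_network(data.frame(node_a = pruned$a, node_b = pruned$b,
                                         score = pruned$score))
  for (s in fx$set_source$mapped) for (t in fx$set_target$mapped) {
    before <- shortest_path(fx$network, s, t)
    after <- if (all(c(s, t) %in% net2$nodes)) shortest_path(net2, s, t) else NULL
    expect_true(is.null(after) || after$total_weight > before$total_weight)
  }
})

test_that("betweenness is independent of the roles of the two sets", {
  net <- random_score_network(30, 0.2, seed = 23)
  C <- gset(net$nodes[1:3], "C", net)
  Cp <- gset(net$nodes[25:30], "Cp", net)
  r1 <- search_all_pairs(net, C, Cp)
  r2 <- search_all_pairs(net, Cp, C)
  expect_equal(r1$betweenness, r2$betweenness)
})

test_that("the all-paths mode counts every co-optimal path", {
  net <- net_from_string("A-x:800,x-B:800,A-m:800,m-B:800")
  C <- gset("A", "C", net)
  Cp <- gset("B", "Cp", net)
  single <- search_all_pairs(net, C, Cp)
  expect_equal(single$betweenness, c(m = 1))
  all_mode <- search_all_pairs(net, C, Cp, all_paths = TRUE)
  expect_equal(all_mode$betweenness, c(m = 1, x = 1))
})

test_that("the per-pair gene table is written sorted and re-readable", {
  fx <- planted_bridge_network(bridge_fixture_spec(seed = 6))
  r <- search_all_pairs(fx$network, fx$set_source, fx$set_target)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_search_result(r, f)
  df <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(names(df), c("gene", "betweenness"))
  expect_equal(df$betweenness, sort(df$betweenness, decreasing = TRUE))
  expect_equal(setNames(df$betweenness, df$gene)[names(r$betweenness)],
               r$betweenness)
})
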