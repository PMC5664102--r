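test_that("degree-matched draws preserve the template degree multiset", {
  net <- random_score_network(100, 0.08, seed = 31)
  template <- gset(net$nodes[c(1, 5, 9, 20, 33, 47)], "C", net)
  tmpl_deg <- sort(unname(node_degree(net, template$mapped)))
  set.seed(1)
  for (i in 1:50) {
    draw <- sample_degree_matched(net, template)
    expect_false(anyDuplicated(draw) > 0)
    expect_equal(sort(unname(node_degree(net, draw))), tmpl_deg)
  }
})

test_that("a node with a unique degree is always drawn for its bin", {
  # hub is the only node of degree 5
  net <- net_from_string(paste0(
    "hub-l1:500,hub-l2:500,hub-l3:500,hub-l4:500,hub-l5:500,l1-l2:500"))
  template <- gset("hub", "C", net)
  set.seed(42)
  for (i in 1:5) {
    expect_identical(sample_degree_matched(net, template), "hub")
  }
})

test_that("degree-matched sampling is reproducible from the seed", {
  net <- random_score_network(100, 0.08, seed = 31)
  template <- gset(net$nodes[1:6], "C", net)
  set.seed(7); d1 <- sample_degree_matched(net, template)
  set.seed(7); d2 <- sample_degree_matched(net, template)
  expect_identical(d1, d2)
  set.seed(8); d3 <- sample_degree_matched(net, template)
  expect_false(identical(d1, d3))
})

test_that("permutation FDR is Delta / n and lies on the replicate grid", {
  fx <- planted_bridge_network(bridge_fixture_spec(seed = 12))
  r <- search_all_pairs(fx$network, fx$set_source, fx$set_target)
  cfg <- permutation_config(n_replicates = 40, seed = 3)
  fdr <- permutation_fdr(fx$network, fx$set_source, fx$set_target, r, cfg)
  expect_setequal(names(fdr$fdr), names(r$betweenness))
  expect_true(all(fdr$fdr >= 0 & fdr$fdr <= 1))
  expect_equal(as.vector(fdr$fdr),
               as.vector(fdr$exceed_counts) / fdr$n_replicates)
  expect_true(all(fdr$exceed_counts == round(fdr$exceed_counts)))
})

test_that("replicate betweenness ties do not count as exceedances", {
  # without noise, every degree-1 node is a seed, so each replicate set
  # is a re-draw among the seeds themselves; replicate betweenness of the
  # bridge can never strictly exceed the observed 12, hence FDR = 0
  fx <- planted_bridge_network(bridge_fixture_spec(
    n_source_seeds = 3, n_target_seeds = 4, n_bridges = 1,
    n_noise_nodes = 0, strong_score = 999, weak_score = 300,
    noise_edge_prob = 0, seed = 1))
  r <- search_all_pairs(fx$network, fx$set_source, fx$set_target)
  fdr <- permutation_fdr(fx$network, fx$set_source, fx$set_target, r,
                         permutation_config(n_replicates = 50, seed = 9))
  expect_equal(unname(fdr$fdr["brg001"]), 0)
  expect_equal(unname(fdr$exceed_counts["brg001"]), 0L)
})

test_that("the permutation FDR is deterministic in (inputs, seed)", {
  net <- random_score_network(60, 0.1, seed = 44)
  C <- gset(net$nodes[1:5], "C", net)
  Cp <- gset(net$nodes[50:55], "Cp", net)
  r <- search_all_pairs(net, C, Cp)
  cfg <- permutation_config(n_replicates = 30, seed = 101)
  f1 <- permutation_fdr(net, C, Cp, r, cfg)
  f2 <- permutation_fdr(net, C, Cp, r, cfg)
  expect_identical(f1, f2)
  f3 <- permutation_fdr(net, C, Cp, r,
                        permutation_config(n_replicates = 30, seed = 102))
  expect_false(identical(f1$fdr, f3$fdr))
})

test_that("the permutation leaves the caller's RNG stream untouched", {
  fx <- planted_bridge_network(bridge_fixture_spec(seed = 12))
  r <- search_all_pairs(fx$network, fx$set_source, fx$set_target)
  set.seed(555)
  before <- .Random.seed
  permutation_fdr(fx$network, fx$set_source, fx$set_target, r,
                  permutation_config(n_replicates = 5, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("candidate selection applies the FDR threshold strictly", {
  observed <- structure(
    list(pair_label = c("C", "Cp"),
         betweenness = c(x = 9, y = 8, z = 2),
         n_source = 3L, n_target = 3L,
         n_pairs_attempted = 9L, n_pairs_connected = 9L,
         n_pairs_skipped = 0L),
    class = "path_search_result")
  fdr <- structure(
    list(fdr = c(x = 0.049, y = 0.05, z = 0.2),
         exceed_counts = c(x = 49L, y = 50L, z = 200L),
         n_replicates = 1000L),
    class = "fdr_result")
  expect_equal(select_candidates(observed, fdr, 0.05), "x")

  fdr$fdr[] <- 0
  expect_equal(select_candidates(observed, fdr, 0.05), c("x", "y", "z"))

  empty <- observed
  empty$betweenness <- setNames(numeric(0), character(0))
  expect_equal(select_candidates(empty, fdr, 0.05), character(0))

  missing <- structure(list(fdr = c(x = 0), exceed_counts = c(x = 0L),
                            n_replicates = 10L), class = "fdr_result")
  expect_error(select_candidates(observed, missing), "does not cover")
})

test_that("a planted bridge survives the permutation filter", {
  fx <- planted_bridge_network(bridge_fixture_spec(seed = 4))
  r <- search_all_pairs(fx$network, fx$set_source, fx$set_target)
  fdr <- permutation_fdr(fx$network, fx$set_source, fx$set_target, r,
                         permutation_config(n_replicates = 200, seed = 21))
  expect_lt(fdr$fdr[["brg001"]], 0.05)
  expect_true("brg001" %in% select_candidates(r, fdr))
})

test_that("the candidate TSV carries betweenness, counts and FDR", {
  fx <- planted_bridge_network(bridge_fixture_spec(seed = 4))
  r <- search_all_pairs(fx$network, fx$set_source, fx$set_target)
  fdr <- permutation_fdr(fx$network, fx$set_source, fx$set_target, r,
                         permutation_config(n_replicates = 20, seed = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fdr_result(r, fdr, f)
  df <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(names(df), c("gene", "betweenness", "exceed_count", "fdr"))
  expect_equal(df$fdr, df$exceed_count / 20)
})
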