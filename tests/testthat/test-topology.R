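test_that("directed clustering: complete digraph and stars", {
  k3 <- complete_digraph(letters[1:3])
  printed <- directed_clustering(k3, variant = "printed_formula")
  expect_true(all(abs(printed$per_node - 1 / 6) < 1e-12))
  fag <- directed_clustering(k3, variant = "fagiolo")
  expect_true(all(abs(fag$per_node - 1) < 1e-12))

  # directed 3-cycle: one cyclic triangle, no reciprocated edges
  cyc <- cycle_digraph(letters[1:3])
  fc <- directed_clustering(cyc, variant = "fagiolo")
  expect_true(all(fc$per_node > 0))
  pc <- directed_clustering(cyc, variant = "printed_formula")
  # each node sees its two neighbors joined by exactly one directed link
  expect_true(all(abs(pc$per_node - 1 / 2) < 1e-12))

  # out-star: no neighbor-neighbor links, both variants 0
  star <- connectome(data.frame(from = "h", to = paste0("s", 1:5)))
  expect_equal(directed_clustering(star, "fagiolo")$mean, 0)
  expect_equal(directed_clustering(star, "printed_formula")$mean, 0)
})

test_that("global efficiency: complete graph, cycle closed form", {
  expect_equal(global_efficiency(complete_digraph(letters[1:6])), 1.0)
  # directed n-cycle: distances 1..n-1 from each node
  n <- 6
  expect_equal(global_efficiency(cycle_digraph(letters[1:n])),
               sum(1 / (1:(n - 1))) / (n - 1))
  # brute force on a random SCC
  cc <- er_connectome(20, 0.3, seed = 2)
  gs <- connectocore:::largest_scc(as_igraph(cc))
  d <- igraph::distances(gs, mode = "out", weights = NA)
  nn <- nrow(d)
  brute <- sum(1 / d[row(d) != col(d)]) / (nn * (nn - 1))
  expect_equal(global_efficiency(cc), brute)
  # a single node has no defined efficiency
  expect_true(is.na(global_efficiency(connectome(
    data.frame(from = "a", to = "b")))))
})

test_that("betweenness ratio: full set, symmetry, brute-force hub", {
  cyc <- cycle_digraph(letters[1:5])
  expect_equal(betweenness_ratio(cyc, letters[1:5]), 1.0)
  # vertex-transitive: every singleton ratio is 1
  for (v in letters[1:5]) expect_equal(betweenness_ratio(cyc, v), 1.0)

  # line with a shortcut, strongly connected via a return edge
  et <- data.frame(from = c("a", "b", "c", "d", "a", "e"),
                   to = c("b", "c", "d", "e", "c", "a"))
  cc <- connectome(et)
  g <- as_igraph(cc)
  # exhaustive sigma_st count
  nodes <- igraph::V(g)$name
  btw <- stats::setNames(rep(0, length(nodes)), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    sp <- igraph::all_shortest_paths(g, from = s, to = t, mode = "out")$res
    if (length(sp) == 0) next
    for (p in sp) {
      inner <- setdiff(igraph::V(g)$name[as.integer(p)], c(s, t))
      btw[inner] <- btw[inner] + 1 / length(sp)
    }
  }
  for (v in nodes) {
    expect_equal(betweenness_ratio(cc, v), btw[v] / mean(btw),
                 ignore_attr = TRUE, info = v)
  }
  expect_error(betweenness_ratio(cc, "zz"), "strongly")
})

test_that("weighted set sizes reconstruct the global betweenness mean", {
  cc <- er_connectome(40, 0.2, seed = 6)
  gs <- connectocore:::largest_scc(as_igraph(cc))
  scc_nodes <- igraph::V(gs)$name
  set.seed(1)
  grp <- split(scc_nodes, sample(rep(1:3, length.out = length(scc_nodes))))
  total <- sum(vapply(grp, function(s)
    length(s) * betweenness_ratio(cc, s), numeric(1)))
  expect_equal(total, length(scc_nodes))
})

test_that("consensus Louvain recovers planted blocks, handles edge cases", {
  blocks <- rbind(
    expand.grid(from = paste0("a", 1:5), to = paste0("a", 1:5),
                stringsAsFactors = FALSE),
    expand.grid(from = paste0("b", 1:5), to = paste0("b", 1:5),
                stringsAsFactors = FALSE),
    data.frame(from = "a1", to = "b1"))
  blocks <- blocks[blocks$from != blocks$to, ]
  cc <- connectome(blocks)
  pt <- consensus_louvain(cc, n_runs = 20, seed = 1)
  expect_equal(pt$n_communities, 2L)
  memb <- pt$membership
  expect_length(unique(memb[paste0("a", 1:5)]), 1L)
  expect_length(unique(memb[paste0("b", 1:5)]), 1L)

  # edgeless graph: singletons
  e <- connectome(NULL, nodes = paste0("n", 1:4))
  expect_equal(consensus_louvain(e, n_runs = 3)$n_communities, 4L)

  # determinism under a fixed seed
  p1 <- consensus_louvain(cc, n_runs = 10, seed = 42)
  p2 <- consensus_louvain(cc, n_runs = 10, seed = 42)
  expect_identical(p1$membership, p2$membership)
})

test_that("directed modularity follows the printed formula", {
  cc <- er_connectome(30, 0.15, seed = 9)
  memb <- stats::setNames(rep(1L, n_nodes(cc)), node_ids(cc))
  m <- n_edges(cc)
  kin <- sum(degree_sequence(cc, "in"))
  kout <- sum(degree_sequence(cc, "out"))
  expect_equal(directed_modularity(cc, memb),
               1 - kin * kout / (2 * m^2))
  expect_equal(directed_modularity(cc, memb, variant = "standard"),
               1 - kin * kout / m^2)
  # gamma = 0 leaves only the coverage term, bounded by 1
  set.seed(3)
  memb2 <- stats::setNames(sample(1:3, n_nodes(cc), TRUE), node_ids(cc))
  q0 <- directed_modularity(cc, memb2, gamma = 0)
  expect_lte(q0, 1)

  # block partition beats a random bisection on the two-K5 toy
  blocks <- rbind(
    expand.grid(from = paste0("a", 1:5), to = paste0("a", 1:5),
                stringsAsFactors = FALSE),
    expand.grid(from = paste0("b", 1:5), to = paste0("b", 1:5),
                stringsAsFactors = FALSE),
    data.frame(from = "a1", to = "b1"))
  b2 <- connectome(blocks[blocks$from != blocks$to, ])
  good <- stats::setNames(rep(1:2, each = 5), node_ids(b2))
  set.seed(7)
  rand <- stats::setNames(sample(rep(1:2, 5)), node_ids(b2))
  expect_gt(directed_modularity(b2, good), directed_modularity(b2, rand))
  expect_error(directed_modularity(b2, good[1:5]), "missing")
})

test_that("topology summary covers connectivity flags and determinism", {
  k4 <- complete_digraph(letters[1:4])
  s <- summarize_topology(k4, n_nulls_clustering = 2,
                          n_nulls_modularity = 2, n_runs_louvain = 3,
                          seed = 1)
  expect_equal(s$density, 1)
  expect_true(s$strongly_connected)
  expect_true(s$weakly_connected)
  expect_equal(s$global_efficiency, 1)

  dyads <- connectome(data.frame(from = c("a", "b", "c", "d"),
                                 to = c("b", "a", "d", "c")))
  sd_ <- summarize_topology(dyads, n_nulls_clustering = 0,
                            n_nulls_modularity = 0, n_runs_louvain = 2)
  expect_false(sd_$strongly_connected)
  expect_false(sd_$weakly_connected)

  cc <- generate_planted_core(planted_spec_t(5))
  a <- summarize_topology(cc, n_nulls_clustering = 2,
                          n_nulls_modularity = 2, n_runs_louvain = 3,
                          seed = 11)
  b <- summarize_topology(cc, n_nulls_clustering = 2,
                          n_nulls_modularity = 2, n_runs_louvain = 3,
                          seed = 11)
  expect_identical(a, b)
  expect_true(!s$strongly_connected || s$weakly_connected)
})

test_that("degree-strength correlation hits its closed cases", {
  cc <- rand_connectome(30, 0.2, seed = 13)
  expect_equal(degree_strength_spearman(cc), 1.0)       # all weights equal
  expect_equal(degree_strength_spearman(binarize(cc)), 1.0)
  # hand-built inversion: degree rises 1, 2, 3 while strength falls
  et <- data.frame(from = c("a", "b", "b", "c", "c", "c"),
                   to   = c("x1", "x1", "x2", "x1", "x2", "x3"),
                   weight = c(30, 10, 10, 4, 3, 3))
  inv <- connectome(et)
  deg <- degree_sequence(inv, "all")[c("a", "b", "c")]
  str_ <- igraph::strength(as_igraph(inv), mode = "all")[c("a", "b", "c")]
  expect_equal(unname(stats::cor(deg, str_, method = "spearman")), -1.0)
})

test_that("targeted attack ratios behave at their fixed points", {
  cc <- generate_planted_core(planted_spec_t(8))
  none <- targeted_attack(cc, character())
  expect_equal(none$clustering_ratio, 1.0)
  expect_equal(none$efficiency_ratio, 1.0)

  # removing an isolated node changes nothing
  et <- edge_table(cc)
  cc_iso <- connectome(et, nodes = c(node_ids(cc), "loner"))
  iso <- targeted_attack(cc_iso, "loner")
  expect_equal(iso$efficiency_ratio, 1.0)

  core <- frontier_dcores(dcore_matrix(cc))$core_nodes
  att <- targeted_attack(cc, core)
  expect_lt(att$efficiency_ratio, 1)
})
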