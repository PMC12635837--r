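test_that("neighbor sets follow chains, cycles and the two-hop oracle", {
  chain <- connectome(data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_setequal(neighbor_set(chain, "c", "predecessors", 1L), "b")
  expect_setequal(neighbor_set(chain, "c", "predecessors", 2L), "a")
  cyc <- cycle_digraph(c("a", "b", "c"))
  expect_setequal(neighbor_set(cyc, "a", "successors", 2L), "c")
  expect_error(neighbor_set(chain, character(), "successors"), "empty")

  for (s in 1:3) {
    cc <- rand_connectome(50, 0.08, seed = 160 + s)
    set.seed(s)
    seeds <- sample(node_ids(cc), 5)
    for (dir in c("predecessors", "successors")) for (ord in 1:2) {
      expect_setequal(neighbor_set(cc, seeds, dir, ord),
                      brute_neighbors(cc, seeds, dir, ord))
    }
  }
})

test_that("order 2 composes order 1 and seed exclusion is a flag", {
  cc <- rand_connectome(40, 0.1, seed = 19)
  set.seed(4)
  seeds <- sample(node_ids(cc), 4)
  one <- neighbor_set(cc, seeds, "successors", 1L, exclude_seeds = FALSE)
  two <- neighbor_set(cc, seeds, "successors", 2L, exclude_seeds = FALSE)
  expect_setequal(two, neighbor_set(cc, one, "successors", 1L,
                                    exclude_seeds = FALSE))
  with_seeds <- neighbor_set(cc, seeds, "successors", 1L,
                             exclude_seeds = FALSE)
  without <- neighbor_set(cc, seeds, "successors", 1L, exclude_seeds = TRUE)
  expect_setequal(without, setdiff(with_seeds, seeds))
})

test_that("type frequencies normalize and default to unassigned", {
  cc <- connectome(data.frame(from = c("a", "b", "c", "d"),
                              to = c("b", "c", "d", "a")),
                   types = c(a = "KC", b = "KC", c = "MBON"))
  pr <- type_frequencies(c("a", "b", "c", "d"), cc)
  expect_equal(sum(pr$freq), 1)
  expect_equal(unname(pr$freq["KC"]), 0.5)
  expect_equal(unname(pr$freq["unassigned"]), 0.25)
  # fixed vocabulary keeps absent types in n
  pr2 <- type_frequencies(c("a", "b"), cc,
                          vocabulary = c("KC", "MBON", "MBIN", "unassigned"))
  expect_equal(pr2$n_types, 4L)
  expect_equal(unname(pr2$freq["MBIN"]), 0)
})

test_that("Shannon and Simpson diversity hit their boundary values", {
  mk <- function(p, vocab = names(p)) {
    structure(list(counts = stats::setNames(as.integer(p * 1000),
                                            names(p)),
                   freq = p, n_types = length(vocab), n_neurons = 1000L),
              class = "composition_profile")
  }
  uni4 <- mk(c(a = .25, b = .25, c = .25, d = .25))
  expect_equal(shannon_diversity(uni4), 1.0)
  expect_equal(simpson_diversity(uni4), 1.0)
  expect_equal(simpson_diversity(uni4, form = "as_printed"), 1.0)

  single <- mk(c(a = 1))
  expect_equal(shannon_diversity(single), 0)
  one_of4 <- mk(c(a = 1, b = 0, c = 0, d = 0))
  expect_equal(simpson_diversity(one_of4, form = "as_printed"), 4)
  expect_equal(simpson_diversity(one_of4), 0.25)

  p3 <- mk(c(a = .5, b = .25, c = .25))
  expect_equal(shannon_diversity(p3), 1.5 * log(2) / log(3),
               tolerance = 1e-12)
  p24 <- mk(c(a = .5, b = .5, c = 0, d = 0))
  expect_equal(simpson_diversity(p24, form = "as_printed"), 2.0)

  # permutation invariance and maximal-iff-uniform
  perm <- mk(c(d = .25, b = .25, a = .25, c = .25))
  expect_equal(shannon_diversity(perm), shannon_diversity(uni4))
  skew <- mk(c(a = .7, b = .1, c = .1, d = .1))
  expect_lt(shannon_diversity(skew), 1)
  expect_lt(simpson_diversity(skew), 1)
})

test_that("type matrix applies the two-case normalization", {
  # X (2 nodes), Y (3 nodes), 3 X->Y edges: P_XY = 3/6
  cc <- connectome(data.frame(from = c("x1", "x1", "x2"),
                              to = c("y1", "y2", "y3")),
                   types = c(x1 = "X", x2 = "X",
                             y1 = "Y", y2 = "Y", y3 = "Y"))
  tm <- type_connectivity_matrix(cc)
  expect_equal(tm$P["X", "Y"], 0.5, ignore_attr = TRUE)
  expect_equal(tm$E_counts["X", "Y"], 3L, ignore_attr = TRUE)
  # complete digraph of one type: diagonal P = 1
  k4 <- complete_digraph(letters[1:4])
  tm4 <- type_connectivity_matrix(k4)
  expect_equal(unname(tm4$P["unassigned", "unassigned"]), 1.0)
  # singleton type: diagonal undefined, not divide-by-zero
  solo <- connectome(data.frame(from = "s", to = "t"),
                     types = c(s = "S", t = "T"))
  tms <- type_connectivity_matrix(solo)
  expect_true(is.na(tms$P["S", "S"]))
})

test_that("type matrix conserves edge counts against per-type degrees", {
  cc <- assign_type_labels(rand_connectome(80, 0.08, seed = 23),
                           c(a = .4, b = .3, c = .3), seed = 24)
  tm <- type_connectivity_matrix(cc)
  expect_equal(sum(tm$E_counts), n_edges(cc))
  tp <- node_types(cc)
  dout <- degree_sequence(cc, "out")
  din <- degree_sequence(cc, "in")
  for (lab in tm$labels) {
    expect_equal(sum(tm$E_counts[lab, ]),
                 sum(dout[names(tp)[tp == lab]]), ignore_attr = TRUE)
    expect_equal(sum(tm$E_counts[, lab]),
                 sum(din[names(tp)[tp == lab]]), ignore_attr = TRUE)
  }
})

test_that("type-level s-core ranks the heavy block above the light one", {
  # 4 types: two heavily interconnected, two weakly attached
  P <- matrix(0, 4, 4, dimnames = list(c("H1", "H2", "L1", "L2"),
                                       c("H1", "H2", "L1", "L2")))
  P["H1", "H2"] <- P["H2", "H1"] <- 0.8
  P["L1", "H1"] <- P["L2", "H2"] <- 0.1
  P["L1", "L2"] <- 0.05
  tm <- structure(list(labels = rownames(P), P = P,
                       E_counts = P * 0, N_counts = rep(10L, 4)),
                  class = "type_matrix")
  lv <- type_score(tm, "all")
  expect_gt(min(lv[c("H1", "H2")]), max(lv[c("L1", "L2")]))
  # single-type matrix: that type at the (only) max level
  solo <- structure(list(labels = "A",
                         P = matrix(0.5, 1, 1,
                                    dimnames = list("A", "A")),
                         E_counts = matrix(1L, 1, 1),
                         N_counts = c(A = 5L)),
                    class = "type_matrix")
  expect_named(type_score(solo, "all"), "A")
})
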