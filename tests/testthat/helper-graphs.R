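# Toy graphs and independent brute-force oracles used across the suite.

# complete digraph on the given node names (no self-loops)
complete_digraph <- function(nodes) {
  eg <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  connectome(eg[eg$from != eg$to, ])
}

# directed cycle a -> b -> ... -> a
cycle_digraph <- function(nodes) {
  connectome(data.frame(from = nodes, to = nodes[c(2:length(nodes), 1L)]))
}

# Erdos-Renyi directed graph via the block generator (all blocks equal)
er_connectome <- function(n, p, seed) {
  generate_planted_core(synthetic_spec(
    n_nodes = n, type_proportions = c(A = 1), n_core = 0L,
    p_core_core = p, p_core_periph = p, p_periph_periph = p, seed = seed))
}

planted_spec_t <- function(seed) {
  # the reference planted-core study condition used throughout the suite
  synthetic_spec(n_nodes = 200L,
                 type_proportions = c(A = 0.4, B = 0.3, C = 0.3),
                 n_core = 20L, core_label = "core",
                 p_core_core = 0.6, p_core_periph = 0.05,
                 p_periph_periph = 0.01, seed = seed)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Brute-force D-core: union of all node subsets S in which every node has
# in-degree >= k and out-degree >= l inside S (feasible sets are closed
# under union, so the union is the unique maximal one). Exponential; n <= 12.
brute_dcore <- function(x, k, l) {
  et <- edge_table(x)
  nodes <- node_ids(x)
  n <- length(nodes)
  best <- character()
  for (mask in seq_len(2^n) - 1L) {
    S <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    if (length(S) == 0L) next
    inS <- et$from %in% S & et$to %in% S
    din <- table(factor(et$to[inS], levels = S))
    dout <- table(factor(et$from[inS], levels = S))
    if (all(din >= k) && all(dout >= l)) best <- union(best, S)
  }
  sort(best)
}

# Brute-force rich-club coefficient from the raw edge table
brute_rcc <- function(x, direction, k) {
  et <- edge_table(x)
  deg <- if (direction == "in") {
    table(factor(et$to, levels = node_ids(x)))
  } else {
    table(factor(et$from, levels = node_ids(x)))
  }
  club <- names(deg)[deg > k]
  if (length(club) < 2L) return(NA_real_)
  m <- sum(et$from %in% club & et$to %in% club)
  m / (length(club) * (length(club) - 1))
}

# Brute-force two-hop neighbor search on the edge table
brute_neighbors <- function(x, seeds, direction, order) {
  et <- edge_table(x)
  step <- function(S) {
    if (direction == "predecessors") unique(et$from[et$to %in% S])
    else unique(et$to[et$from %in% S])
  }
  out <- step(seeds)
  if (order == 2L) out <- step(out)
  setdiff(out, seeds)
}

rand_connectome <- function(n, p, seed, weights = FALSE) {
  cc <- er_connectome(n, p, seed)
  if (weights) {
    g <- as_igraph(cc)
    set.seed(seed + 1L)
    igraph::E(g)$weight <- 1 + stats::rpois(igraph::ecount(g), 3)
    cc$graph <- g
  }
  cc
}
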