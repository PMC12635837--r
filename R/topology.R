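#' Directed clustering coefficients
#'
#' Two variants are exposed. `"fagiolo"` (default) is the standard directed
#' clustering used by the common graph libraries: with S = A + t(A),
#' C_i = (S^3)_ii / (2 (d_i (d_i - 1) - 2 d_i^bi)), where d_i = k_in + k_out
#' and d_i^bi = (A^2)_ii counts reciprocated neighbors. `"printed_formula"`
#' computes C_i = L_i / (k_i (k_i - 1)) with L_i the number of directed links
#' among the (distinct) neighbors of i and k_i = k_in + k_out; this literal
#' form is kept for auditability. Nodes with k_i <= 1 (or zero denominator)
#' get clustering 0.
#'
#' @param x a `connectome` (computed on the binarized adjacency).
#' @param variant `"fagiolo"` or `"printed_formula"`.
#' @return list with `per_node` (named numeric vector) and `mean`.
#' @export
directed_clustering <- function(x, variant = c("fagiolo",
                                               "printed_formula")) {
  variant <- match.arg(variant)
  g <- as_igraph(x)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (n == 0L) return(list(per_node = numeric(), mean = NA_real_))
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A@x[] <- 1
  dtot <- Matrix::rowSums(A) + Matrix::colSums(A)
  cc <- numeric(n)
  if (variant == "fagiolo") {
    S <- A + Matrix::t(A)
    tri <- Matrix::diag(S %*% S %*% S)
    dbi <- Matrix::diag(A %*% A)
    denom <- 2 * (dtot * (dtot - 1) - 2 * dbi)
    ok <- denom > 0
    cc[ok] <- tri[ok] / denom[ok]
  } else {
    out_nb <- igraph::adjacent_vertices(g, igraph::V(g), mode = "out")
    in_nb <- igraph::adjacent_vertices(g, igraph::V(g), mode = "in")
    for (i in seq_len(n)) {
      ki <- dtot[i]
      if (ki <= 1) next
      nb <- setdiff(unique(c(as.integer(out_nb[[i]]),
                             as.integer(in_nb[[i]]))), i)
      if (length(nb) < 2L) next
      Li <- sum(A[nb, nb, drop = FALSE])
      cc[i] <- Li / (ki * (ki - 1))
    }
  }
  list(per_node = stats::setNames(cc, nm), mean = mean(cc))
}

largest_scc <- function(g) {
  comp <- igraph::components(g, mode = "strong")
  big <- which.max(comp$csize)
  igraph::induced_subgraph(g, which(comp$membership == big))
}

#' Global efficiency of the largest strongly connected component
#'
#' E_global = 1 / (N (N - 1)) * sum over ordered pairs of 1 / d_ij with
#' directed shortest-path lengths, computed on the largest strongly connected
#' component (SCC) where every pair is reachable.
#'
#' @param x a `connectome`.
#' @return the efficiency in (0, 1], or `NA` if the largest SCC has fewer
#'   than 2 nodes.
#' @export
global_efficiency <- function(x) {
  gs <- largest_scc(as_igraph(x))
  n <- igraph::vcount(gs)
  if (n < 2L) return(NA_real_)
  d <- igraph::distances(gs, mode = "out", weights = NA)
  sum(1 / d[upper.tri(d) | lower.tri(d)]) / (n * (n - 1))
}

#' Betweenness-centrality ratio of a node set
#'
#' Mean betweenness centrality of the given nodes divided by the mean over
#' the whole network; both means are taken over the largest strongly
#' connected component (betweenness is computed there), and the node set is
#' intersected with it. A ratio above 1 marks a set that carries more
#' shortest-path traffic than the average neuron.
#'
#' @param x a `connectome`.
#' @param nodes character vector of node ids.
#' @return the ratio (1 when `nodes` covers the whole component).
#' @export
betweenness_ratio <- function(x, nodes) {
  gs <- largest_scc(as_igraph(x))
  keep <- intersect(nodes, igraph::V(gs)$name)
  if (length(keep) == 0L)
    stop("none of the given nodes lie in the largest strongly ",
         "connected component")
  btw <- igraph::betweenness(gs, directed = TRUE, weights = NA)
  names(btw) <- igraph::V(gs)$name
  mean(btw[keep]) / mean(btw)
}

#' Consensus Louvain community detection
#'
#' Runs the Louvain algorithm `n_runs` times on the (symmetrized) graph with
#' shuffled vertex orders, counts how often every node pair lands in the same
#' community, cuts pairs co-occurring in less than
#' `cooccurrence_threshold` of the runs, and clusters the resulting weighted
#' co-occurrence graph once more to obtain the consensus partition.
#'
#' @param x a `connectome`.
#' @param n_runs number of base runs (default 100).
#' @param resolution Louvain resolution parameter.
#' @param cooccurrence_threshold minimum co-occurrence frequency kept
#'   (default 0.5, majority rule).
#' @param seed integer seed.
#' @return object of class `partition_result`: list with `membership` (named
#'   integer vector), `n_communities`, `n_runs`, `resolution`,
#'   `cooccurrence_threshold`.
#' @export
consensus_louvain <- function(x, n_runs = 100L, resolution = 1.0,
                              cooccurrence_threshold = 0.5, seed = NULL) {
  g <- as_igraph(x)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (!is.null(seed)) set.seed(seed)
  if (igraph::ecount(g) == 0L) {
    memb <- stats::setNames(seq_len(n), nm)
    return(structure(list(membership = memb, n_communities = n,
                          n_runs = n_runs, resolution = resolution,
                          cooccurrence_threshold = cooccurrence_threshold),
                     class = "partition_result"))
  }
  gu <- igraph::as_undirected(g, mode = "collapse",
                              edge.attr.comb = list(weight = "sum"))
  co <- matrix(0L, n, n)
  for (r in seq_len(n_runs)) {
    perm <- sample.int(n)
    gp <- igraph::permute(gu, perm)
    cl <- igraph::cluster_louvain(gp, weights = NA,
                                  resolution = resolution)
    # old vertex j became vertex perm[j] in the permuted graph
    memb <- as.integer(igraph::membership(cl))[perm]
    co <- co + outer(memb, memb, "==")
  }
  co <- co / n_runs
  co[co < cooccurrence_threshold] <- 0
  diag(co) <- 0
  gc_ <- igraph::graph_from_adjacency_matrix(co, mode = "undirected",
                                             weighted = TRUE)
  final <- igraph::cluster_louvain(gc_, resolution = resolution)
  memb <- stats::setNames(as.integer(igraph::membership(final)), nm)
  structure(list(membership = memb,
                 n_communities = length(unique(memb)),
                 n_runs = n_runs, resolution = resolution,
                 cooccurrence_threshold = cooccurrence_threshold),
            class = "partition_result")
}

#' Directed modularity of a partition
#'
#' Q = sum over communities c of (L_c / m - gamma * k_c^in k_c^out / (2 m^2))
#' where L_c counts intracommunity directed edges, m the total edge count and
#' k_c^in/k_c^out the community degree sums (the `"printed"` variant; the
#' common directed convention with denominator m^2 is available as
#' `"standard"`).
#'
#' @param x a `connectome`.
#' @param membership named integer vector covering every node.
#' @param gamma resolution parameter.
#' @param variant null-term denominator convention.
#' @return the modularity value.
#' @export
directed_modularity <- function(x, membership, gamma = 1.0,
                                variant = c("printed", "standard")) {
  variant <- match.arg(variant)
  g <- as_igraph(x)
  nm <- igraph::V(g)$name
  if (!all(nm %in% names(membership)))
    stop("membership is missing node(s): ",
         paste(utils::head(setdiff(nm, names(membership)), 5L),
               collapse = ", "))
  memb <- membership[nm]
  m <- igraph::ecount(g)
  if (m == 0L) return(NA_real_)
  el <- igraph::as_edgelist(g, names = TRUE)
  kin <- igraph::degree(g, mode = "in", loops = FALSE)
  kout <- igraph::degree(g, mode = "out", loops = FALSE)
  names(kin) <- names(kout) <- nm
  denom <- if (variant == "printed") 2 * m^2 else m^2
  Q <- 0
  for (c_ in unique(memb)) {
    inside <- names(memb)[memb == c_]
    Lc <- sum(el[, 1L] %in% inside & el[, 2L] %in% inside)
    Q <- Q + Lc / m -
      gamma * sum(kin[inside]) * sum(kout[inside]) / denom
  }
  Q
}

#' Whole-graph topology summary
#'
#' Computes the summary fields used to compare connectomes side by side:
#' node and edge counts, density, mean directed clustering and its
#' normalization against degree-preserving null models, consensus-Louvain
#' directed modularity and its null normalization, strong/weak connectivity,
#' the Spearman correlation between unweighted and weighted degrees, and
#' global efficiency (largest SCC). Normalized fields are
#' observed / mean-over-nulls (ratio of means).
#'
#' @param x a `connectome`.
#' @param n_nulls_clustering,n_nulls_modularity null-ensemble sizes.
#' @param n_runs_louvain base runs for the consensus partition.
#' @param resolution Louvain resolution.
#' @param seed integer seed.
#' @return a `topology_summary` list.
#' @export
summarize_topology <- function(x, n_nulls_clustering = 10L,
                               n_nulls_modularity = 5L,
                               n_runs_louvain = 20L, resolution = 1.0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as_igraph(x)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  cl_obs <- directed_clustering(x)$mean
  part <- consensus_louvain(x, n_runs = n_runs_louvain,
                            resolution = resolution)
  Q_obs <- directed_modularity(x, part$membership, gamma = resolution)
  cl_null <- Q_null <- NA_real_
  if (m >= 2L) {
    cls <- vapply(seq_len(n_nulls_clustering), function(i)
      directed_clustering(degree_preserving_swap(x))$mean, numeric(1L))
    cl_null <- mean(cls)
    Qs <- vapply(seq_len(n_nulls_modularity), function(i) {
      xr <- degree_preserving_swap(x)
      pr <- consensus_louvain(xr, n_runs = 1L, resolution = resolution)
      directed_modularity(xr, pr$membership, gamma = resolution)
    }, numeric(1L))
    Q_null <- mean(Qs)
  }
  structure(list(
    N = n, E = m,
    density = graph_density(x),
    mean_clustering = cl_obs,
    mean_clustering_normalized = if (is.na(cl_null) || cl_null == 0)
      NA_real_ else cl_obs / cl_null,
    Q = Q_obs,
    Q_normalized = if (is.na(Q_null) || Q_null == 0) NA_real_
      else Q_obs / Q_null,
    strongly_connected = n > 0 && igraph::is_connected(g, mode = "strong"),
    weakly_connected = n > 0 && igraph::is_connected(g, mode = "weak"),
    degree_strength_spearman = degree_strength_spearman(x),
    global_efficiency = global_efficiency(x)),
    class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<topology_summary> N = %d, E = %d, d = %.4g\n",
    "  <C> = %.4g (normalized %.4g), Q = %.4g (normalized %.4g)\n",
    "  SC = %s, WC = %s, r_s = %.3f, E_global = %.4g\n"),
    x$N, x$E, x$density, x$mean_clustering, x$mean_clustering_normalized,
    x$Q, x$Q_normalized, x$strongly_connected, x$weakly_connected,
    x$degree_strength_spearman, x$global_efficiency))
  invisible(x)
}

#' Spearman correlation of unweighted and weighted degree
#'
#' @param x a weighted `connectome`.
#' @return Spearman rank correlation between total degree and total strength
#'   over nodes; `NA` when either vector is constant.
#' @export
degree_strength_spearman <- function(x) {
  g <- as_igraph(x)
  deg <- igraph::degree(g, mode = "all", loops = FALSE)
  str <- igraph::strength(g, mode = "all", loops = FALSE)
  if (length(deg) < 2L || stats::sd(deg) == 0 || stats::sd(str) == 0)
    return(NA_real_)
  stats::cor(deg, str, method = "spearman")
}

#' Targeted-attack summary
#'
#' Removes the given node set simultaneously and reports the ratio of the
#' mean directed clustering (entire graph) and of the global efficiency
#' (largest strongly connected component) after versus before removal.
#'
#' @param x a `connectome`.
#' @param nodes node ids to remove.
#' @return list with `clustering_ratio`, `efficiency_ratio`, `removed`.
#' @export
targeted_attack <- function(x, nodes) {
  g <- as_igraph(x)
  nodes <- intersect(nodes, igraph::V(g)$name)
  cl_before <- directed_clustering(x)$mean
  eff_before <- global_efficiency(x)
  ga <- igraph::delete_vertices(g, nodes)
  xa <- new_connectome(ga)
  cl_after <- if (igraph::vcount(ga) > 0L) directed_clustering(xa)$mean
              else NA_real_
  eff_after <- if (igraph::vcount(ga) > 1L) global_efficiency(xa)
               else NA_real_
  list(clustering_ratio = if (!is.na(cl_before) && cl_before > 0)
         cl_after / cl_before else NA_real_,
       efficiency_ratio = if (!is.na(eff_before) && eff_before > 0)
         eff_after / eff_before else NA_real_,
       removed = nodes)
}
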