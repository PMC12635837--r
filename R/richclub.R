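#' Directed rich-club coefficient at one threshold
#'
#' RCC(k) = M_{>k} / (N_{>k} (N_{>k} - 1)), where N_{>k} is the number of
#' nodes with in- (or out-) degree strictly greater than k and M_{>k} the
#' number of directed edges with both endpoints among them: the density of
#' the club of high-degree nodes.
#'
#' @param x a `connectome`.
#' @param direction `"in"` or `"out"`: which degree defines club membership.
#' @param k degree threshold (strict).
#' @return the coefficient in [0, 1], or `NA` when fewer than two nodes
#'   exceed the threshold (the curve skips such points).
#' @export
rcc <- function(x, direction = c("in", "out"), k) {
  direction <- match.arg(direction)
  g <- as_igraph(x)
  deg <- igraph::degree(g, mode = direction, loops = FALSE)
  club <- which(deg > k)
  if (length(club) < 2L) return(NA_real_)
  m <- igraph::ecount(igraph::induced_subgraph(g, club))
  m / (length(club) * (length(club) - 1))
}

#' Degree-preserving randomization
#'
#' Rewires the graph by repeated directed edge swaps that keep every node's
#' in- and out-degree exactly, introducing no self-loops or parallel edges
#' (igraph's degree-sequence-preserving rewiring). The result is binarized:
#' null models are used for binary rich-club, clustering and modularity
#' normalization.
#'
#' @param x a `connectome` with at least 2 edges.
#' @param n_swaps number of attempted swaps (default 10 x E, a standard
#'   mixing heuristic).
#' @param seed integer seed.
#' @return a rewired `connectome`.
#' @export
degree_preserving_swap <- function(x, n_swaps = NULL, seed = NULL) {
  g <- as_igraph(x)
  if (igraph::ecount(g) < 2L)
    stop("graph has fewer than 2 edges; nothing to swap")
  if (is.null(n_swaps)) n_swaps <- 10L * igraph::ecount(g)
  if (!is.null(seed)) set.seed(seed)
  gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = n_swaps))
  if (igraph::ecount(gr) > 0L) igraph::E(gr)$weight <- 1
  new_connectome(gr)
}

#' Normalized rich-club curve
#'
#' Computes the raw RCC over all thresholds k with N_{>k} >= 2 and divides by
#' the mean RCC of `n_nulls` independent degree-preserving randomizations;
#' normalized values above 1 indicate denser-than-chance interconnection of
#' the high-degree club. Points where the null mean is zero are reported as
#' `NA`, never as 0 or Inf.
#'
#' @param x a `connectome`.
#' @param direction `"in"` or `"out"`.
#' @param n_nulls size of the null ensemble (default 100).
#' @param n_swaps attempted swaps per null (default 10 x E).
#' @param seed integer seed for the ensemble.
#' @return a data frame of class `rich_club_curve` with columns `k`, `raw`,
#'   `null_mean`, `null_sd`, `normalized`, and attributes `direction`,
#'   `n_nulls`, `seed`.
#' @export
normalized_rcc <- function(x, direction = c("in", "out"), n_nulls = 100L,
                           n_swaps = NULL, seed = NULL) {
  direction <- match.arg(direction)
  g <- as_igraph(x)
  deg <- igraph::degree(g, mode = direction, loops = FALSE)
  ks <- 0:max(0L, max(deg) - 1L)
  nk <- vapply(ks, function(k) sum(deg > k), integer(1L))
  ks <- ks[nk >= 2L]
  if (length(ks) == 0L) {
    out <- data.frame(k = integer(), raw = numeric(), null_mean = numeric(),
                      null_sd = numeric(), normalized = numeric())
    return(structure(out, class = c("rich_club_curve", "data.frame"),
                     direction = direction, n_nulls = n_nulls, seed = seed))
  }
  raw <- vapply(ks, function(k) rcc(x, direction, k), numeric(1L))
  if (!is.null(seed)) set.seed(seed)
  nulls <- matrix(NA_real_, nrow = n_nulls, ncol = length(ks))
  for (i in seq_len(n_nulls)) {
    xr <- degree_preserving_swap(x, n_swaps = n_swaps)
    nulls[i, ] <- vapply(ks, function(k) rcc(xr, direction, k), numeric(1L))
  }
  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2L, stats::sd)
  normalized <- ifelse(is.na(null_mean) | null_mean == 0, NA_real_,
                       raw / null_mean)
  out <- data.frame(k = ks, raw = raw, null_mean = null_mean,
                    null_sd = null_sd, normalized = normalized)
  structure(out, class = c("rich_club_curve", "data.frame"),
            direction = direction, n_nulls = n_nulls, seed = seed)
}

#' Rich-club membership
#'
#' Two membership rules used for adult-style and larval-style reporting:
#' `"above_first_crossing"` takes all nodes whose direction-degree exceeds
#' the smallest threshold k at which the normalized RCC rises above 1;
#' `"top_fraction"` takes the ceiling(f N) highest-degree nodes, ties broken
#' by eigenvector centrality (right eigenvector of the binarized adjacency,
#' power iteration) in descending order.
#'
#' @param curve a `rich_club_curve` (used by the crossing rule).
#' @param x the `connectome` the curve was computed on.
#' @param rule membership rule.
#' @param fraction top fraction f in (0, 1] for `"top_fraction"`.
#' @param direction override the curve's direction (defaults to it).
#' @return character vector of member node ids (empty, with a warning, if
#'   the curve never crosses 1 under the crossing rule).
#' @export
rc_membership <- function(curve, x,
                          rule = c("above_first_crossing", "top_fraction"),
                          fraction = NULL, direction = NULL) {
  rule <- match.arg(rule)
  if (is.null(direction)) direction <- attr(curve, "direction")
  g <- as_igraph(x)
  deg <- igraph::degree(g, mode = direction, loops = FALSE)
  nm <- igraph::V(g)$name
  if (rule == "above_first_crossing") {
    cross <- curve$k[!is.na(curve$normalized) & curve$normalized > 1]
    if (length(cross) == 0L) {
      warning("normalized rich-club curve never rises above 1; ",
              "empty membership")
      return(character())
    }
    return(nm[deg > min(cross)])
  }
  if (is.null(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` in (0, 1] is required for rule = 'top_fraction'")
  n_take <- ceiling(fraction * length(nm))
  ev <- eigenvector_scores(g)
  ord <- order(-deg, -ev)
  nm[ord[seq_len(n_take)]]
}

# right eigenvector centrality of the binarized adjacency by power iteration
eigenvector_scores <- function(g, tol = 1e-10, max_iter = 10000L) {
  n <- igraph::vcount(g)
  if (n == 0L) return(numeric())
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A@x[] <- 1
  v <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    w <- as.numeric(A %*% v)
    s <- sum(abs(w))
    if (s == 0) return(stats::setNames(rep(0, n), igraph::V(g)$name))
    w <- w / s
    if (max(abs(w - v)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  stats::setNames(v, igraph::V(g)$name)
}

#' Density of an induced subgraph
#'
#' Directed density E_S / (|S| (|S| - 1)) of the subgraph induced by `nodes`.
#'
#' @param x a `connectome`.
#' @param nodes character vector of node ids (>= 2).
#' @return density in [0, 1].
#' @export
subgraph_density <- function(x, nodes) {
  g <- as_igraph(x)
  nodes <- intersect(nodes, igraph::V(g)$name)
  if (length(nodes) < 2L) stop("need at least 2 nodes for a density")
  m <- igraph::ecount(igraph::induced_subgraph(g, nodes))
  m / (length(nodes) * (length(nodes) - 1))
}
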