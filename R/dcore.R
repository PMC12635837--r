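#' D-core of a directed graph
#'
#' The D-core(k, l) is the unique maximal subgraph in which every node has
#' in-degree >= k and out-degree >= l within the subgraph. It is obtained by
#' iteratively pruning nodes violating either bound until none remain; the
#' result does not depend on pruning order.
#'
#' @param x a `connectome`.
#' @param k minimum in-degree (>= 0).
#' @param l minimum out-degree (>= 0).
#' @return character vector of member node ids (possibly empty).
#' @export
dcore <- function(x, k, l) {
  stopifnot(k >= 0, l >= 0)
  g <- as_igraph(x)
  prune_dcore(g, k, l)
}

prune_dcore <- function(g, k, l) {
  repeat {
    if (igraph::vcount(g) == 0L) break
    din <- igraph::degree(g, mode = "in", loops = FALSE)
    dout <- igraph::degree(g, mode = "out", loops = FALSE)
    bad <- which(din < k | dout < l)
    if (length(bad) == 0L) break
    g <- igraph::delete_vertices(g, bad)
  }
  igraph::V(g)$name
}

#' D-core matrix
#'
#' Computes the grid of D-core sizes dc[k, l] for 0 <= k <= k_max + 1 and
#' 0 <= l <= l_max + 1, where k_max is the largest k with a non-empty
#' D-core(k, 0) and l_max the largest l with a non-empty D-core(0, l); the
#' extra row and column are therefore all zero. Cores are nested, so each row
#' is computed by pruning the previous cell's subgraph rather than restarting.
#'
#' @param x a `connectome`.
#' @param keep_membership store the member node set of every non-empty cell
#'   (default TRUE; turn off to save memory on large graphs).
#' @return a `dcore_matrix`: list with `sizes` (integer matrix, dimnames are
#'   the k and l values as strings), `membership` (named list `"k,l"` ->
#'   character vector, when kept), `k_max`, `l_max`, `n_nodes`.
#' @export
dcore_matrix <- function(x, keep_membership = TRUE) {
  g0 <- as_igraph(x)
  n <- igraph::vcount(g0)

  # scan column l = 0 upward in k to find k_max, keeping nested subgraphs
  col_graphs <- list()
  g <- g0
  k <- 0L
  repeat {
    nodes <- prune_dcore(g, k, 0L)
    if (length(nodes) == 0L) break
    g <- igraph::induced_subgraph(g, nodes)
    col_graphs[[k + 1L]] <- g
    k <- k + 1L
  }
  k_max <- k - 1L                      # -1 when the graph is edgeless/empty
  # scan row k = 0 upward in l to find l_max
  g <- g0
  l <- 0L
  repeat {
    nodes <- prune_dcore(g, 0L, l)
    if (length(nodes) == 0L) break
    g <- igraph::induced_subgraph(g, nodes)
    l <- l + 1L
  }
  l_max <- l - 1L

  nk <- max(k_max, 0L) + 2L            # rows k = 0..k_max+1
  nl <- max(l_max, 0L) + 2L
  sizes <- matrix(0L, nrow = nk, ncol = nl,
                  dimnames = list(k = as.character(0:(nk - 1L)),
                                  l = as.character(0:(nl - 1L))))
  membership <- if (keep_membership) list() else NULL
  if (n > 0L && k_max >= 0L) {
    for (ki in 0:k_max) {
      g <- col_graphs[[ki + 1L]]
      for (li in 0:(nl - 1L)) {
        nodes <- prune_dcore(g, ki, li)
        if (length(nodes) == 0L) break
        g <- igraph::induced_subgraph(g, nodes)
        sizes[ki + 1L, li + 1L] <- length(nodes)
        if (keep_membership)
          membership[[paste(ki, li, sep = ",")]] <- nodes
      }
    }
  } else if (n > 0L) {
    # edgeless graph: only the (0, 0) cell is populated
    sizes[1L, 1L] <- n
    if (keep_membership) membership[["0,0"]] <- igraph::V(g0)$name
  }
  structure(list(sizes = sizes, membership = membership,
                 k_max = k_max, l_max = l_max, n_nodes = n),
            class = "dcore_matrix")
}

#' @export
print.dcore_matrix <- function(x, ...) {
  cat(sprintf("<dcore_matrix> %d nodes, k_max = %d, l_max = %d\n",
              x$n_nodes, x$k_max, x$l_max))
  invisible(x)
}

#' Frontier D-cores and the structural core
#'
#' The frontier D-cores are the last non-empty cells of the D-core matrix
#' with respect to increasing k and l: the non-empty cells (k, l) not
#' dominated by any other non-empty cell (k', l') with k' >= k and l' >= l.
#' Being the innermost, most densely interconnected D-cores, the union of
#' their members serves as the structural core of the network.
#'
#' @param m a `dcore_matrix` computed with `keep_membership = TRUE`.
#' @return list with `cells` (two-column integer matrix of (k, l) frontier
#'   cells) and `core_nodes` (character vector, union of frontier members).
#' @export
frontier_dcores <- function(m) {
  stopifnot(inherits(m, "dcore_matrix"))
  if (is.null(m$membership))
    stop("dcore_matrix was computed without membership; ",
         "rerun dcore_matrix(keep_membership = TRUE)")
  nz <- which(m$sizes > 0L, arr.ind = TRUE)
  if (nrow(nz) == 0L)
    return(list(cells = matrix(integer(), 0L, 2L,
                               dimnames = list(NULL, c("k", "l"))),
                core_nodes = character()))
  kl <- cbind(k = nz[, 1L] - 1L, l = nz[, 2L] - 1L)
  keep <- vapply(seq_len(nrow(kl)), function(i) {
    dom <- kl[, 1L] >= kl[i, 1L] & kl[, 2L] >= kl[i, 2L]
    dom[i] <- FALSE
    !any(dom)
  }, logical(1L))
  cells <- kl[keep, , drop = FALSE]
  core <- unique(unlist(m$membership[paste(cells[, 1L], cells[, 2L],
                                           sep = ",")],
                        use.names = FALSE))
  list(cells = cells, core_nodes = core)
}

#' k-core and s-core decompositions
#'
#' Both use the same generalized peeling kernel: repeatedly remove the
#' node(s) of minimal score (total degree for the k-core, total strength for
#' the s-core), assigning each removed node the running maximum of the
#' minimal score seen so far. For integer degrees this reproduces the
#' classical core number; for weights it is the s-core level, the largest
#' strength threshold whose s-core still contains the node. With uniform
#' weights w the s-core levels equal w times the k-core numbers.
#'
#' @param x a `connectome` (weights are required and must be positive for
#'   `score_numbers`).
#' @param mode degree/strength direction: `"all"` (in + out, the default),
#'   `"in"` or `"out"`.
#' @return named numeric vector node id -> core level, with attribute
#'   `variant`.
#' @export
kcore_numbers <- function(x, mode = c("all", "in", "out")) {
  mode <- match.arg(mode)
  lv <- peel_core_levels(as_igraph(x), mode = mode, weighted = FALSE)
  attr(lv, "variant") <- paste0("kcore_", mode, "_degree")
  lv
}

#' @rdname kcore_numbers
#' @export
score_numbers <- function(x, mode = c("all", "in", "out")) {
  mode <- match.arg(mode)
  g <- as_igraph(x)
  if (igraph::ecount(g) > 0L && any(igraph::E(g)$weight <= 0))
    stop("s-core requires positive edge weights")
  lv <- peel_core_levels(g, mode = mode, weighted = TRUE)
  attr(lv, "variant") <- paste0("score_", mode, "_strength")
  lv
}

# Generalized core peeling: remove minimal-score nodes, level = running max
# of the minimal score at removal time.
peel_core_levels <- function(g, mode = "all", weighted = FALSE) {
  nm <- igraph::V(g)$name
  levels <- stats::setNames(numeric(length(nm)), nm)
  level <- 0
  while (igraph::vcount(g) > 0L) {
    s <- if (weighted) {
      igraph::strength(g, mode = mode, loops = FALSE)
    } else {
      igraph::degree(g, mode = mode, loops = FALSE)
    }
    level <- max(level, min(s))
    drop <- which(s <= level)
    levels[igraph::V(g)$name[drop]] <- level
    g <- igraph::delete_vertices(g, drop)
  }
  levels
}
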