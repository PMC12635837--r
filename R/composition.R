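#' Predecessor/successor neighbor sets
#'
#' Neurons presynaptic to a seed set are its predecessors; postsynaptic ones
#' its successors. Order 1 is the union of direct neighbors of the seeds in
#' the chosen direction; order 2 applies the same step to the order-1 set
#' (predecessors-of-predecessors, successors-of-successors). Neighbors are
#' counted as distinct neurons (set semantics).
#'
#' @param x a `connectome`.
#' @param seeds non-empty character vector of seed node ids.
#' @param direction `"predecessors"` or `"successors"`.
#' @param order 1 or 2.
#' @param exclude_seeds drop the seeds from the returned set (default TRUE:
#'   profiles describe the core's external interface).
#' @return character vector of neighbor node ids.
#' @export
neighbor_set <- function(x, seeds,
                         direction = c("predecessors", "successors"),
                         order = 1L, exclude_seeds = TRUE) {
  direction <- match.arg(direction)
  if (length(seeds) == 0L) stop("seed set is empty")
  g <- as_igraph(x)
  seeds <- intersect(seeds, igraph::V(g)$name)
  if (length(seeds) == 0L) stop("no seeds present in the graph")
  mode <- if (direction == "predecessors") "in" else "out"
  step <- function(nodes) {
    nb <- igraph::adjacent_vertices(g, nodes, mode = mode)
    unique(igraph::V(g)$name[unique(unlist(lapply(nb, as.integer)))])
  }
  res <- step(seeds)
  if (order == 2L) res <- step(res)
  else if (order != 1L) stop("order must be 1 or 2")
  if (exclude_seeds) res <- setdiff(res, seeds)
  res
}

#' Cell-type frequency profile of a neuron set
#'
#' @param nodes character vector of node ids.
#' @param x a `connectome` supplying the type annotation (unannotated nodes
#'   count as `"unassigned"`).
#' @param vocabulary optional fixed label list; by default the vocabulary is
#'   all types present in the connectome's annotation (so rarely-seen types
#'   still enter the diversity denominator n).
#' @return object of class `composition_profile`: list with `counts`,
#'   `freq` (normalized, sums to 1), `n_types` (vocabulary size n),
#'   `n_neurons` (N).
#' @export
type_frequencies <- function(nodes, x, vocabulary = NULL) {
  tp <- node_types(x)
  labs <- tp[intersect(nodes, names(tp))]
  if (is.null(vocabulary)) vocabulary <- sort(unique(unname(tp)))
  counts <- table(factor(labs, levels = vocabulary))
  counts <- stats::setNames(as.integer(counts), names(counts))
  N <- sum(counts)
  freq <- if (N > 0L) counts / N else counts * 0
  structure(list(counts = counts, freq = freq,
                 n_types = length(vocabulary), n_neurons = N),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %d neurons over %d types\n",
              x$n_neurons, x$n_types))
  top <- sort(x$freq[x$freq > 0], decreasing = TRUE)
  cat("  ", paste(sprintf("%s %.3f", names(utils::head(top, 8L)),
                          utils::head(top, 8L)), collapse = ", "), "\n")
  invisible(x)
}

#' Normalized Shannon diversity
#'
#' H = -sum(p_i log p_i) / log(n): entropy of the type frequencies divided by
#' its maximum over n types, so H in [0, 1] with 1 at the uniform profile.
#' n = 1 gives 0 by convention.
#'
#' @param profile a `composition_profile`.
#' @return diversity in [0, 1].
#' @export
shannon_diversity <- function(profile) {
  p <- profile$freq[profile$freq > 0]
  n <- profile$n_types
  if (n < 2L || length(p) == 0L) return(0)
  -sum(p * log(p)) / log(n)
}

#' Simpson diversity
#'
#' The raw form S = n * sum(p_i^2) is always >= 1 and decreases toward 1 with
#' increasing evenness; its reciprocal 1 / (n * sum(p_i^2)) lies in (0, 1]
#' and increases with diversity (1 at the uniform profile), matching the
#' reading that higher values mean greater diversity. Default:
#' `"inverse_normalized"`.
#'
#' @param profile a `composition_profile`.
#' @param form `"inverse_normalized"` or `"as_printed"`.
#' @return the index.
#' @export
simpson_diversity <- function(profile,
                              form = c("inverse_normalized", "as_printed")) {
  form <- match.arg(form)
  p <- profile$freq
  n <- profile$n_types
  if (n < 1L || profile$n_neurons == 0L) return(NA_real_)
  s <- n * sum(p^2)
  if (form == "as_printed") s else 1 / s
}

#' Type-wise connection-probability matrix
#'
#' E_ij counts directed edges from neurons of type i to neurons of type j;
#' the probability matrix normalizes by the number of possible connections,
#' P_ij = E_ij / (N_i N_j) off the diagonal and P_ii = E_ii / (N_i (N_i - 1))
#' on it (types with a single neuron get `NA` there, not a division by
#' zero). The matrix, read as a weighted digraph over types, supports the
#' type-level s-core.
#'
#' @param x a `connectome` (every node labeled; `"unassigned"` is a label).
#' @return object of class `type_matrix`: list with `labels`, `P`,
#'   `E_counts`, `N_counts`.
#' @export
type_connectivity_matrix <- function(x) {
  g <- as_igraph(x)
  tp <- igraph::V(g)$type
  labels <- sort(unique(tp))
  Ncnt <- stats::setNames(as.integer(table(factor(tp, levels = labels))),
                          labels)
  el <- igraph::as_edgelist(g, names = FALSE)
  Ecnt <- table(factor(tp[el[, 1L]], levels = labels),
                factor(tp[el[, 2L]], levels = labels))
  Ecnt <- matrix(as.integer(Ecnt), nrow = length(labels),
                 dimnames = list(from = labels, to = labels))
  poss <- outer(Ncnt, Ncnt)
  diag(poss) <- Ncnt * (Ncnt - 1L)
  P <- Ecnt / poss
  P[poss == 0] <- NA_real_
  structure(list(labels = labels, P = P, E_counts = Ecnt, N_counts = Ncnt),
            class = "type_matrix")
}

#' s-core levels of the cell-type network
#'
#' Treats the type connection-probability matrix as a weighted digraph over
#' types (weights P_ij) and runs the s-core peeling for the in-strength,
#' out-strength or total-strength variant.
#'
#' @param tm a `type_matrix`.
#' @param mode `"in"`, `"out"` or `"all"`.
#' @param include_diagonal include the within-type weight as a self-loop
#'   (default FALSE; strengths are over distinct types).
#' @return named numeric vector type -> s-core level, with attribute
#'   `variant`.
#' @export
type_score <- function(tm, mode = c("all", "in", "out"),
                       include_diagonal = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(tm, "type_matrix"))
  W <- tm$P
  W[is.na(W)] <- 0
  if (!include_diagonal) diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                           weighted = TRUE)
  lv <- peel_core_levels(g, mode = mode, weighted = TRUE)
  attr(lv, "variant") <- paste0("type_score_", mode, "_strength")
  lv
}
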