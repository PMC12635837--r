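#' Specification for a synthetic planted-core connectome
#'
#' Describes a labeled directed random graph with a densely interconnected
#' planted core confined to one cell type, emulating the structure that the
#' core-periphery analyses assume: independent-edge block probabilities
#' within the core, between core and periphery, and within the periphery,
#' plus a label distribution for the periphery.
#'
#' @param n_nodes total number of neurons.
#' @param type_proportions named numeric vector of periphery cell-type
#'   proportions (must sum to 1 within 1e-9).
#' @param n_core number of planted core neurons.
#' @param core_label cell-type label carried by every core neuron.
#' @param p_core_core,p_core_periph,p_periph_periph block edge probabilities
#'   in [0, 1]; `p_core_periph` applies in both directions.
#' @param seed integer seed making generation reproducible.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_nodes, type_proportions,
                           n_core, core_label = "core",
                           p_core_core, p_core_periph, p_periph_periph,
                           seed = 1L) {
  p <- c(p_core_core, p_core_periph, p_periph_periph)
  if (any(p < 0 | p > 1)) stop("block probabilities must lie in [0, 1]")
  if (n_core > n_nodes) stop("n_core must not exceed n_nodes")
  if (abs(sum(type_proportions) - 1) > 1e-9)
    stop("type_proportions must sum to 1")
  structure(list(n_nodes = as.integer(n_nodes),
                 type_proportions = type_proportions,
                 n_core = as.integer(n_core), core_label = core_label,
                 p_core_core = p_core_core, p_core_periph = p_core_periph,
                 p_periph_periph = p_periph_periph,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# sample m ordered pairs without replacement from rows x cols, optionally
# excluding the diagonal (rows and cols then index the same node set)
sample_block_edges <- function(rows, cols, p, same_set = FALSE) {
  nr <- length(rows); nc <- length(cols)
  npairs <- if (same_set) nr * (nr - 1L) else nr * nc
  if (npairs <= 0L || p <= 0) return(NULL)
  m <- stats::rbinom(1L, npairs, p)
  if (m == 0L) return(NULL)
  idx <- sample.int(npairs, m)
  if (same_set) {
    r <- (idx - 1L) %/% (nr - 1L) + 1L
    o <- (idx - 1L) %% (nr - 1L) + 1L
    c_ <- o + (o >= r)
    cbind(rows[r], rows[c_])
  } else {
    r <- (idx - 1L) %/% nc + 1L
    c_ <- (idx - 1L) %% nc + 1L
    cbind(rows[r], cols[c_])
  }
}

#' Generate a planted-core connectome
#'
#' Samples every ordered node pair independently with the block probability
#' given by core membership, producing a directed simple graph without
#' self-loops. The first `n_core` nodes form the planted core and carry
#' `core_label`; periphery labels are drawn i.i.d. from `type_proportions`.
#'
#' @param spec a [synthetic_spec()].
#' @return a `connectome` with attribute `planted_core` (character vector of
#'   core node ids).
#' @export
generate_planted_core <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  ids <- sprintf("n%05d", seq_len(n))
  core <- ids[seq_len(spec$n_core)]
  periph <- setdiff(ids, core)

  el <- rbind(sample_block_edges(core, core, spec$p_core_core,
                                 same_set = TRUE),
              sample_block_edges(core, periph, spec$p_core_periph),
              sample_block_edges(periph, core, spec$p_core_periph),
              sample_block_edges(periph, periph, spec$p_periph_periph,
                                 same_set = TRUE))
  edges <- if (is.null(el)) NULL else
    data.frame(from = el[, 1L], to = el[, 2L], weight = 1,
               stringsAsFactors = FALSE)
  types <- stats::setNames(rep(spec$core_label, n), ids)
  if (length(periph) > 0L) {
    types[periph] <- sample(names(spec$type_proportions), length(periph),
                            replace = TRUE, prob = spec$type_proportions)
  }
  cc <- connectome(edges, nodes = ids, types = types)
  attr(cc, "planted_core") <- core
  cc
}

#' Degree-model constructors
#'
#' `degree_model_weibull` is the discrete stretched exponential
#' P(k) proportional to k^(beta - 1) exp(-lambda k^beta);
#' `degree_model_powerlaw` is the discrete power law P(k) proportional to
#' k^(-alpha). Both live on the integer support x_min .. k_cap (the cap is
#' supplied at sampling time; degrees cannot exceed N - 1).
#'
#' @param lambda,beta Weibull rate-like scale (> 0) and shape (> 0).
#' @param alpha power-law exponent (> 1; smaller values are not
#'   normalizable).
#' @param x_min smallest attainable degree.
#' @return a `degree_model` list.
#' @export
degree_model_weibull <- function(lambda, beta, x_min = 1L) {
  stopifnot(lambda > 0, beta > 0, x_min >= 1)
  structure(list(family = "weibull", lambda = lambda, beta = beta,
                 x_min = as.integer(x_min)), class = "degree_model")
}

#' @rdname degree_model_weibull
#' @export
degree_model_powerlaw <- function(alpha, x_min = 1L) {
  if (alpha <= 1) stop("power-law exponent alpha must exceed 1")
  stopifnot(x_min >= 1)
  structure(list(family = "powerlaw", alpha = alpha,
                 x_min = as.integer(x_min)), class = "degree_model")
}

degree_model_mass <- function(model, k_cap) {
  k <- model$x_min:k_cap
  logm <- switch(model$family,
    weibull = (model$beta - 1) * log(k) - model$lambda * k^model$beta,
    powerlaw = -model$alpha * log(k))
  logm <- logm - max(logm)
  m <- exp(logm)
  stats::setNames(m / sum(m), k)
}

#' Mean of a capped discrete degree model by direct summation
#'
#' @param model a `degree_model`.
#' @param k_cap support cap.
#' @return the exact mean of the normalized mass function.
#' @export
degree_model_mean <- function(model, k_cap) {
  m <- degree_model_mass(model, k_cap)
  sum(as.numeric(names(m)) * m)
}

#' Sample an i.i.d. integer degree sequence
#'
#' Inverse-CDF sampling from the normalized mass of the model over
#' x_min .. k_cap.
#'
#' @param model a `degree_model`.
#' @param n sequence length (>= 1).
#' @param seed integer seed.
#' @param k_cap support cap (default n - 1, since a degree cannot exceed
#'   N - 1; forced to at least x_min).
#' @param even_sum if TRUE and the sampled sum is odd, one entry is nudged by
#'   +/-1 within the support so two sequences can be paired stub-for-stub.
#' @return integer vector of length n.
#' @export
sample_degree_sequence <- function(model, n, seed = NULL, k_cap = NULL,
                                   even_sum = FALSE) {
  stopifnot(inherits(model, "degree_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(k_cap)) k_cap <- max(n - 1L, model$x_min)
  k_cap <- max(k_cap, model$x_min)
  m <- degree_model_mass(model, k_cap)
  supp <- as.integer(names(m))
  ks <- supp[findInterval(stats::runif(n), cumsum(m)) + 1L]
  if (even_sum && sum(ks) %% 2L == 1L) {
    i <- which(ks < k_cap)[1L]
    if (is.na(i)) {
      ks[1L] <- ks[1L] - 1L
    } else {
      ks[i] <- ks[i] + 1L
    }
  }
  ks
}

#' Directed configuration-model graph by stub matching
#'
#' Pairs out-stubs with in-stubs uniformly at random; self-loops and parallel
#' edges arising from the matching are dropped (not rewired) and their counts
#' recorded, the standard simple-graph projection of the configuration model.
#'
#' @param in_seq,out_seq non-negative integer sequences of equal length with
#'   equal sums.
#' @param seed integer seed.
#' @return a `connectome` with attributes `dropped_selfloops` and
#'   `dropped_parallel`.
#' @export
directed_configuration_graph <- function(in_seq, out_seq, seed = NULL) {
  if (length(in_seq) != length(out_seq))
    stop("in_seq and out_seq must have the same length")
  if (sum(in_seq) != sum(out_seq))
    stop("stub sums differ: sum(in_seq) = ", sum(in_seq),
         ", sum(out_seq) = ", sum(out_seq))
  if (!is.null(seed)) set.seed(seed)
  n <- length(in_seq)
  ids <- sprintf("n%05d", seq_len(n))
  heads <- rep(ids, in_seq)
  tails <- rep(ids, out_seq)
  if (length(heads) > 0L) heads <- sample(heads)
  from <- tails
  to <- heads
  loops <- from == to
  key <- paste(from, to, sep = "\r")
  dup <- duplicated(key) & !loops
  keep <- !loops & !dup
  edges <- if (any(keep))
    data.frame(from = from[keep], to = to[keep], weight = 1,
               stringsAsFactors = FALSE) else NULL
  cc <- connectome(edges, nodes = ids)
  attr(cc, "dropped_selfloops") <- sum(loops)
  attr(cc, "dropped_parallel") <- sum(dup)
  cc
}

#' Assign i.i.d. cell-type labels
#'
#' @param x a `connectome`.
#' @param proportions named numeric vector of label probabilities.
#' @param seed integer seed.
#' @return the relabelled `connectome`.
#' @export
assign_type_labels <- function(x, proportions, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as_igraph(x)
  igraph::V(g)$type <- sample(names(proportions), igraph::vcount(g),
                              replace = TRUE,
                              prob = proportions / sum(proportions))
  x$graph <- g
  x
}
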