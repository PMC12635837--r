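#' Directed connectome container
#'
#' A `connectome` wraps a directed [igraph][igraph::igraph-package] graph in
#' which vertices are neurons (identified by opaque string ids, never
#' reindexed), the vertex attribute `type` carries a cell-type label
#' (`"unassigned"` when unknown) and the edge attribute `weight` carries a
#' positive integer synapse count. Parallel records are always aggregated on
#' construction, so each ordered pair (u, v) appears at most once.
#'
#' @param edges data frame with columns `from`, `to` and optionally `weight`
#'   (default 1). Duplicate (from, to) rows are summed.
#' @param nodes optional character vector of node ids; endpoints of `edges`
#'   are added automatically.
#' @param types optional named character vector mapping node id to cell-type
#'   label; missing nodes get `"unassigned"`.
#' @param selfloops `"dropped"` (default) removes self-loops and records the
#'   count; `"kept"` retains them. Core and rich-club denominators assume
#'   i != j, hence the default.
#' @return an object of class `connectome`.
#' @export
connectome <- function(edges, nodes = NULL, types = NULL,
                       selfloops = c("dropped", "kept")) {
  selfloops <- match.arg(selfloops)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  if (!all(c("from", "to") %in% names(edges)))
    stop("`edges` must have columns `from` and `to`")
  if (is.null(edges$weight)) edges$weight <- 1
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  w <- edges$weight
  if (any(!is.finite(w)) || any(w <= 0))
    stop("all edge weights must be positive finite numbers; offending rows: ",
         paste(utils::head(which(!is.finite(w) | w <= 0), 5L), collapse = ", "))

  n_loops <- 0L
  if (selfloops == "dropped") {
    loop <- edges$from == edges$to
    n_loops <- sum(loop)
    edges <- edges[!loop, , drop = FALSE]
  }
  # aggregate parallel records
  if (nrow(edges) > 0L) {
    key <- paste(edges$from, edges$to, sep = "\r")
    wsum <- tapply(edges$weight, key, sum)
    uk <- names(wsum)
    sp <- strsplit(uk, "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(sp, `[[`, "", 1L),
                        to = vapply(sp, `[[`, "", 2L),
                        weight = as.numeric(wsum),
                        stringsAsFactors = FALSE)
  }
  all_nodes <- unique(c(as.character(nodes), edges$from, edges$to))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = all_nodes))
  tp <- rep("unassigned", length(all_nodes))
  names(tp) <- all_nodes
  if (!is.null(types)) {
    hit <- intersect(names(types), all_nodes)
    lab <- as.character(types[hit])
    lab[is.na(lab) | lab == ""] <- "unassigned"
    tp[hit] <- lab
  }
  igraph::V(g)$type <- unname(tp[igraph::V(g)$name])
  new_connectome(g, selfloops_dropped = n_loops)
}

new_connectome <- function(graph, selfloops_dropped = 0L) {
  stopifnot(igraph::is_directed(graph))
  structure(list(graph = graph,
                 selfloops_dropped = as.integer(selfloops_dropped)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  g <- x$graph
  cat(sprintf("<connectome> %d neurons, %d directed edges, density %.4g\n",
              igraph::vcount(g), igraph::ecount(g), graph_density(x)))
  tt <- table(igraph::V(g)$type)
  cat("  types:", paste(sprintf("%s (%d)", names(tt), tt), collapse = ", "),
      "\n")
  if (x$selfloops_dropped > 0L)
    cat("  self-loops dropped:", x$selfloops_dropped, "\n")
  invisible(x)
}

#' Accessors for connectome objects
#'
#' @param x a `connectome`.
#' @return `as_igraph` the underlying igraph; `n_nodes`/`n_edges` counts;
#'   `node_ids` a character vector; `node_types` a named character vector;
#'   `edge_table` a data frame (from, to, weight); `graph_density` the
#'   directed density E / (N (N - 1)).
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "connectome"))
  x$graph
}

#' @rdname as_igraph
#' @export
n_nodes <- function(x) igraph::vcount(as_igraph(x))

#' @rdname as_igraph
#' @export
n_edges <- function(x) igraph::ecount(as_igraph(x))

#' @rdname as_igraph
#' @export
node_ids <- function(x) igraph::V(as_igraph(x))$name

#' @rdname as_igraph
#' @export
node_types <- function(x) {
  g <- as_igraph(x)
  stats::setNames(igraph::V(g)$type, igraph::V(g)$name)
}

#' @rdname as_igraph
#' @export
edge_table <- function(x) {
  g <- as_igraph(x)
  if (igraph::ecount(g) == 0L)
    return(data.frame(from = character(), to = character(),
                      weight = numeric()))
  el <- igraph::as_edgelist(g, names = TRUE)
  data.frame(from = el[, 1L], to = el[, 2L],
             weight = igraph::E(g)$weight, stringsAsFactors = FALSE)
}

#' @rdname as_igraph
#' @export
graph_density <- function(x) {
  n <- n_nodes(x)
  if (n < 2L) return(NA_real_)
  n_edges(x) / (n * (n - 1))
}

#' Column-name dialects for synapse tables
#'
#' Connectome releases name their edge-list columns differently; a dialect
#' maps the logical roles (source, target, weight) onto file columns.
#' `dialect_larval()` matches the larval whole-brain supplementary tables,
#' `dialect_flywire()` the FlyWire adult exports.
#'
#' @param source,target,weight column names in the file; `weight = NA` means
#'   no weight column (all synapse counts taken as 1).
#' @return a named list usable as the `dialect` argument of
#'   [read_edge_table()].
#' @export
edge_dialect <- function(source = "source", target = "target",
                         weight = "weight") {
  list(source = source, target = target, weight = weight)
}

#' @rdname edge_dialect
#' @export
dialect_larval <- function() {
  edge_dialect("presynaptic", "postsynaptic", "synapses")
}

#' @rdname edge_dialect
#' @export
dialect_flywire <- function() {
  edge_dialect("pre_root_id", "post_root_id", "syn_count")
}

#' Read a synapse edge table
#'
#' Reads a delimited text file of directed synaptic connections and builds a
#' `connectome`. Duplicate (source, target) records are summed into a single
#' weighted edge; self-loops are handled per `selfloops` (dropped by default
#' and counted).
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, otherwise
#'   comma-separated.
#' @param dialect column-name mapping, see [edge_dialect()].
#' @param selfloops `"dropped"` or `"kept"`.
#' @param min_weight minimum aggregated synapse count for an edge to be kept
#'   (default 1, i.e. any synapse makes an edge).
#' @return a `connectome`.
#' @export
read_edge_table <- function(path, dialect = edge_dialect(),
                            selfloops = c("dropped", "kept"),
                            min_weight = 1) {
  selfloops <- match.arg(selfloops)
  tab <- read_delim_auto(path)
  need <- c(dialect$source, dialect$target)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("edge table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  wcol <- dialect$weight
  if (!is.null(wcol) && !is.na(wcol) && wcol %in% names(tab)) {
    w <- suppressWarnings(as.numeric(tab[[wcol]]))
    bad <- which(is.na(w) | w <= 0)
    if (length(bad))
      stop("non-positive or non-numeric weight in row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
  } else {
    w <- rep(1, nrow(tab))
  }
  edges <- data.frame(from = as.character(tab[[dialect$source]]),
                      to = as.character(tab[[dialect$target]]),
                      weight = w, stringsAsFactors = FALSE)
  cc <- connectome(edges, selfloops = selfloops)
  if (min_weight > 1) {
    g <- as_igraph(cc)
    drop <- which(igraph::E(g)$weight < min_weight)
    cc$graph <- igraph::delete_edges(g, drop)
  }
  cc
}

#' Read a node annotation table
#'
#' @param path delimited text file with a node-id column and a label column.
#' @param id_col,label_col column names.
#' @return named character vector node id -> cell-type label; empty labels
#'   become `"unassigned"`. Duplicated ids with conflicting labels raise an
#'   error naming the offenders.
#' @export
read_annotations <- function(path, id_col = "node_id", label_col = "label") {
  tab <- read_delim_auto(path)
  miss <- setdiff(c(id_col, label_col), names(tab))
  if (length(miss))
    stop("annotation table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  ids <- as.character(tab[[id_col]])
  labs <- as.character(tab[[label_col]])
  labs[is.na(labs) | labs == ""] <- "unassigned"
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    conf <- dup[vapply(dup, function(d)
      length(unique(labs[ids == d])) > 1L, logical(1L))]
    if (length(conf))
      stop("conflicting labels for node id(s): ",
           paste(utils::head(conf, 10L), collapse = ", "))
    keep <- !duplicated(ids)
    ids <- ids[keep]; labs <- labs[keep]
  }
  stats::setNames(labs, ids)
}

#' Attach cell-type labels to a connectome
#'
#' @param x a `connectome`.
#' @param annotation named character vector as from [read_annotations()].
#'   Nodes absent from it keep/get `"unassigned"`.
#' @return the relabelled `connectome`.
#' @export
set_node_types <- function(x, annotation) {
  g <- as_igraph(x)
  nm <- igraph::V(g)$name
  tp <- rep("unassigned", length(nm))
  hit <- nm %in% names(annotation)
  lab <- as.character(annotation[nm[hit]])
  lab[is.na(lab) | lab == ""] <- "unassigned"
  tp[hit] <- lab
  igraph::V(g)$type <- tp
  x$graph <- g
  x
}

#' Binarize a connectome
#'
#' Sets every synapse count to 1, keeping the node and edge sets intact; the
#' binary adjacency A with A_ij = 1 marking the presence of a synapse from
#' neuron i to neuron j is the object on which degree, core and rich-club
#' analyses operate.
#'
#' @param x a `connectome`.
#' @return a binarized copy; the input is not modified.
#' @export
binarize <- function(x) {
  g <- as_igraph(x)
  if (igraph::ecount(g) > 0L) igraph::E(g)$weight <- 1
  x$graph <- g
  x
}

#' Write a connectome to disk
#'
#' @param x a `connectome`.
#' @param path output path.
#' @param format `"edge-csv"` writes a source,target,weight CSV readable by
#'   [read_edge_table()] (labels are not stored; round-trips reproduce the
#'   graph up to label defaults); `"graphml"` writes GraphML including the
#'   `type` vertex attribute.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path, format = c("edge-csv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge-csv") {
    et <- edge_table(x)
    names(et) <- c("source", "target", "weight")
    utils::write.csv(et, path, row.names = FALSE, quote = FALSE)
  } else {
    igraph::write_graph(as_igraph(x), path, format = "graphml")
  }
  invisible(path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    colClasses = "character")
}
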