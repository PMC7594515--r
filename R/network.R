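#' Construct a network topology
#'
#' A `network_topology` is an ordered set of named nodes together with an
#' undirected edge set over them. It is the structural input of the network
#' regression model: only node pairs joined by an edge contribute an edge
#' feature (the indicator \eqn{I_{ij}} is 1 exactly for pairs in the edge
#' set).
#'
#' @param edges A data frame (or two-column character matrix) whose first two
#'   columns name the endpoints of each undirected edge.
#' @param nodes Optional character vector of node names. Defaults to the
#'   endpoint names in order of first appearance. Extra names add isolated
#'   nodes; every endpoint must be present.
#'
#' @details Edges are stored with endpoint indices `i < j` relative to the
#'   node order, which is authoritative for all downstream matrices.
#'   Duplicate edges (in either orientation) are collapsed with a warning;
#'   self-loops are an error.
#'
#' @return An object of class `network_topology`: a list with `nodes`
#'   (character) and `edges` (a tibble with integer columns `i`, `j`).
#' @examples
#' net <- network_topology(data.frame(from = c("A", "B"), to = c("B", "C")))
#' net
#' indicator_matrix(net)
#' @export
network_topology <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L || nrow(edges) == 0L) {
    abort("`edges` must have at least one row and two columns (endpoints).")
  }
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  if (anyNA(from) || anyNA(to) || any(from == "") || any(to == "")) {
    abort("Edge endpoints must be non-missing, non-empty node names.")
  }
  loops <- which(from == to)
  if (length(loops) > 0L) {
    abort(sprintf(
      "Self-loop not allowed: node '%s' (edge %d).", from[loops[1L]], loops[1L]
    ))
  }
  seen <- unique(c(rbind(from, to)))
  if (is.null(nodes)) {
    nodes <- seen
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) abort("`nodes` contains duplicated names.")
    missing <- setdiff(seen, nodes)
    if (length(missing) > 0L) {
      abort(sprintf(
        "Edge endpoints not in `nodes`: %s", paste(missing, collapse = ", ")
      ))
    }
  }
  i <- match(from, nodes)
  j <- match(to, nodes)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  key <- paste(i, j)
  if (anyDuplicated(key)) {
    warn(sprintf(
      "Collapsed %d duplicate edge(s).", sum(duplicated(key))
    ))
    keep <- !duplicated(key)
    i <- i[keep]; j <- j[keep]
  }
  ord <- order(i, j)
  structure(
    list(
      nodes = nodes,
      edges = tibble(i = as.integer(i[ord]), j = as.integer(j[ord]))
    ),
    class = "network_topology"
  )
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf(
    "<network_topology: %d nodes, %d edges>\n", length(x$nodes), nrow(x$edges)
  ))
  cat("nodes: ", paste(utils::head(x$nodes, 8L), collapse = ", "),
      if (length(x$nodes) > 8L) ", ..." else "", "\n", sep = "")
  cat("edges: ", paste(utils::head(edge_names(x), 5L), collapse = ", "),
      if (nrow(x$edges) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Edge labels of a topology
#'
#' @param topology A [network_topology()].
#' @param sep Separator between endpoint names.
#' @return Character vector, one label per edge, in edge order.
#' @examples
#' edge_names(insulin_resistance_network())[1:3]
#' @export
edge_names <- function(topology, sep = "~") {
  stopifnot(inherits(topology, "network_topology"))
  paste0(topology$nodes[topology$edges$i], sep, topology$nodes[topology$edges$j])
}

#' Adjacency indicator matrix
#'
#' Returns the symmetric p x p indicator matrix with entry 1 when the node
#' pair is an edge of the topology and 0 otherwise (zero diagonal). This is
#' the \eqn{I_{ij}} that gates edge terms in the network regression.
#'
#' @inheritParams edge_names
#' @return Integer matrix with node names as dimnames.
#' @export
indicator_matrix <- function(topology) {
  stopifnot(inherits(topology, "network_topology"))
  p <- length(topology$nodes)
  m <- matrix(0L, p, p, dimnames = list(topology$nodes, topology$nodes))
  idx <- cbind(topology$edges$i, topology$edges$j)
  m[idx] <- 1L
  m[idx[, 2:1, drop = FALSE]] <- 1L
  m
}

#' Read an undirected edge list from a text file
#'
#' Parses a whitespace- or tab-delimited edge list with two node names per
#' line. Lines starting with `#` and blank lines are ignored. Duplicate
#' edges (either orientation) are collapsed with a warning; self-loops are
#' rejected with the offending line number.
#'
#' @param path Path to the edge-list file.
#' @return A [network_topology()] with nodes in first-appearance order.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B", "B C"), f)
#' read_edge_list(f)
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  dat <- lines[keep]
  if (length(dat) == 0L) abort(sprintf("Empty edge list: %s", path))
  parts <- strsplit(trimws(dat), "\\s+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Line %d of %s does not have exactly two fields.",
      which(keep)[bad[1L]], path
    ))
  }
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  loops <- which(from == to)
  if (length(loops) > 0L) {
    abort(sprintf(
      "Self-loop at line %d of %s: '%s'.",
      which(keep)[loops[1L]], path, from[loops[1L]]
    ))
  }
  network_topology(data.frame(from = from, to = to))
}

#' Write a topology as a plain-text edge list
#'
#' The inverse of [read_edge_list()]: one `from to` pair per line, in edge
#' order. Reading the file back reproduces an identical topology.
#'
#' @inheritParams edge_names
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(topology, path) {
  stopifnot(inherits(topology, "network_topology"))
  writeLines(edge_names(topology, sep = "\t"), path)
  invisible(path)
}

#' Convert a topology to an igraph graph
#'
#' Convenience bridge for visualization or export (e.g. GraphML via
#' `igraph::write_graph()`). Requires the igraph package.
#'
#' @inheritParams edge_names
#' @return An undirected `igraph` graph with the same nodes and edges.
#' @export
as_igraph <- function(topology) {
  stopifnot(inherits(topology, "network_topology"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("Package 'igraph' is required for as_igraph().")
  }
  el <- cbind(topology$nodes[topology$edges$i], topology$nodes[topology$edges$j])
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Simulation topology: insulin-resistance pathway stand-in
#'
#' The packaged 26-node, 37-edge undirected topology used throughout the
#' simulation study, with nodes labelled `X1`...`X26`. It is a synthetic
#' stand-in transcription with the node and edge counts of the KEGG
#' insulin-resistance pathway (the simulation conclusions are insensitive to
#' the exact wiring because effecting nodes and edges are drawn at random);
#' it is connected and contains the edge `X4~X10` used in worked examples.
#'
#' @return A [network_topology()] with 26 nodes and 37 edges.
#' @examples
#' net <- insulin_resistance_network()
#' length(net$nodes)
#' nrow(net$edges)
#' @export
insulin_resistance_network <- function() {
  path <- system.file("extdata", "insulin_resistance_edges.tsv",
                      package = "pminr", mustWork = TRUE)
  net <- read_edge_list(path)
  # node order X1..X26 regardless of first appearance in the file
  ord <- paste0("X", 1:26)
  stopifnot(setequal(net$nodes, ord))
  network_topology(
    data.frame(from = net$nodes[net$edges$i], to = net$nodes[net$edges$j]),
    nodes = ord
  )
}
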