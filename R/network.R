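#' Build an interaction network from an edge table
#'
#' Constructs an undirected, simple protein-protein interaction network from a
#' two-column table of protein identifiers. Self-loops are dropped (with a
#' warning reporting how many) and duplicate or reversed edge records are
#' collapsed, so the result always satisfies the simple-graph invariants the
#' analysis assumes. Identifiers are opaque, case-sensitive strings; no
#' database-specific validation is applied.
#'
#' @param edges two-column character matrix or data frame; each row one
#'   interaction record.
#' @param nodes optional character vector of node ids to include even when
#'   they appear in no edge (isolated proteins are permitted).
#' @param name label stored as the graph's `name` attribute.
#' @return an undirected simple [igraph::igraph] graph.
#' @export
interaction_network <- function(edges, nodes = NULL, name = "network") {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) < 2L) {
    stop("`edges` must have two columns of protein ids", call. = FALSE)
  }
  edges <- matrix(as.character(edges[, 1:2]), ncol = 2L)
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop record(s)", sum(loops)), call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  ids <- unique(c(edges[, 1L], edges[, 2L], as.character(nodes)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(ids, igraph::V(g)$name)),
                            name = setdiff(ids, igraph::V(g)$name))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g$name <- name
  g
}

#' Read an interaction network from an edge-list file
#'
#' Reads a delimited two-column edge list (TSV by default). Lines starting
#' with `#` are ignored; an optional single header line can be skipped with
#' `header = TRUE`. Cleaning is as in [interaction_network()]: self-loops
#' dropped, duplicate and reversed pairs collapsed, ids kept verbatim.
#'
#' @param source path to the file, or a connection.
#' @param delimiter field separator, default tab.
#' @param header if `TRUE`, the first non-comment line is discarded.
#' @param name network label.
#' @return an undirected simple igraph graph.
#' @export
read_edge_list <- function(source, delimiter = "\t", header = FALSE,
                           name = "network") {
  lines <- readLines(source)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty edge list input", call. = FALSE)
  if (header) idx <- idx[-1L]
  if (length(idx) == 0L) stop("edge list has a header but no records", call. = FALSE)
  parts <- strsplit(lines[idx], delimiter, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge record at line %d: fewer than 2 fields",
                 idx[bad[1L]]), call. = FALSE)
  }
  edges <- t(vapply(parts, function(p) trimws(p[1:2]), character(2L)))
  if (any(!nzchar(edges))) {
    bad <- which(rowSums(!nzchar(edges)) > 0L)[1L]
    stop(sprintf("malformed edge record at line %d: blank protein id",
                 idx[bad]), call. = FALSE)
  }
  interaction_network(edges, name = name)
}

#' Write a network as a two-column edge list
#'
#' @param net igraph network.
#' @param path output file path.
#' @param delimiter field separator.
#' @export
write_edge_list <- function(net, path, delimiter = "\t") {
  el <- igraph::as_edgelist(net, names = TRUE)
  utils::write.table(el, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a network to GraphML
#'
#' Nodes carry a `role` attribute (DP/IP/other) when a disease annotation is
#' supplied, so downstream viewers can colour the subnetwork structure.
#'
#' @param net igraph network.
#' @param path output path.
#' @param annotation optional disease annotation (see
#'   [read_disease_annotation()]); adds per-node roles.
#' @export
write_graphml <- function(net, path, annotation = NULL) {
  if (!is.null(annotation)) {
    # subnetworks legitimately lack some annotated proteins; no warning here
    roles <- suppressWarnings(classify_nodes(net, annotation))
    igraph::V(net)$role <- roles$role[match(igraph::V(net)$name, roles$node)]
  }
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

# internal: validate membership and return node ids as character
check_nodes <- function(net, ids) {
  ids <- as.character(ids)
  missing <- setdiff(ids, igraph::V(net)$name)
  if (length(missing) > 0L) {
    stop(sprintf("unknown node(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  ids
}
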