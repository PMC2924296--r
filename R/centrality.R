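#' Node degree
#'
#' Number of distinct neighbours of a protein in the network (self-loops are
#' never present, see [interaction_network()]).
#'
#' @param net igraph network.
#' @param i protein id (character). If omitted, degrees of all nodes are
#'   returned as a named vector.
#' @return integer degree(s).
#' @export
node_degree <- function(net, i = NULL) {
  if (is.null(i)) {
    d <- igraph::degree(net, loops = FALSE)
    return(stats::setNames(as.integer(d), igraph::V(net)$name))
  }
  i <- check_nodes(net, i)
  as.integer(igraph::degree(net, v = i, loops = FALSE))
}

#' Normalized degree
#'
#' Degree divided by the maximum possible number of neighbours, `N - 1`,
#' giving a size-independent value in `[0, 1]` suitable for comparing
#' networks of different size.
#'
#' @inheritParams node_degree
#' @return numeric in `[0, 1]`.
#' @export
normalized_degree <- function(net, i = NULL) {
  n <- igraph::vcount(net)
  if (n < 2L) stop("normalized degree undefined for N < 2", call. = FALSE)
  node_degree(net, i) / (n - 1L)
}

#' Betweenness centrality
#'
#' Sum over unordered node pairs \{j, k\} (both distinct from i) of the
#' fraction of equally shortest j-k paths that pass through i. Pairs in
#' different components contribute zero.
#'
#' @inheritParams node_degree
#' @return non-negative numeric.
#' @export
node_betweenness <- function(net, i = NULL) {
  if (is.null(i)) {
    b <- igraph::betweenness(net, directed = FALSE)
    return(stats::setNames(as.numeric(b), igraph::V(net)$name))
  }
  i <- check_nodes(net, i)
  as.numeric(igraph::betweenness(net, v = i, directed = FALSE))
}

#' Normalized betweenness
#'
#' Betweenness divided by its maximum `(N - 1)(N - 2) / 2` (attained by the
#' centre of a star), giving a value in `[0, 1]`.
#'
#' @inheritParams node_degree
#' @return numeric in `[0, 1]`.
#' @export
normalized_betweenness <- function(net, i = NULL) {
  n <- igraph::vcount(net)
  if (n < 3L) stop("normalized betweenness undefined for N < 3", call. = FALSE)
  node_betweenness(net, i) / ((n - 1) * (n - 2) / 2)
}

#' Centrality table with ranks
#'
#' Per-node degree, normalized degree, betweenness and normalized
#' betweenness, each with a rank (1 = largest; ties share the best
#' applicable rank, i.e. "competition" ranking).
#'
#' @param net igraph network with at least 3 nodes.
#' @return data frame with columns `node`, `D`, `nD`, `nD_rank`, `B`, `nB`,
#'   `nB_rank`, ordered by decreasing `nD`.
#' @export
centrality_table <- function(net) {
  if (igraph::vcount(net) < 3L) {
    stop("centrality table requires N >= 3", call. = FALSE)
  }
  d <- node_degree(net)
  nd <- normalized_degree(net)
  b <- node_betweenness(net)
  nb <- normalized_betweenness(net)
  out <- data.frame(
    node = names(d),
    D = unname(d),
    nD = unname(nd),
    nD_rank = competition_rank(unname(nd)),
    B = unname(b),
    nB = unname(nb),
    nB_rank = competition_rank(unname(nb)),
    stringsAsFactors = FALSE
  )
  out[order(-out$nD, out$node), , drop = FALSE]
}

# competition ("1224") ranking, largest value gets rank 1
competition_rank <- function(x) {
  as.integer(rank(-x, ties.method = "min"))
}

#' Write a centrality table as TSV
#'
#' @param tab result of [centrality_table()].
#' @param path output path.
#' @export
write_centrality_table <- function(tab, path) {
  utils::write.table(format_numeric_cols(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# internal: fixed significant digits for TSV output
format_numeric_cols <- function(df, digits = 6L) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], digits)
  }
  df
}
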