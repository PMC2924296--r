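#' Deterministic toy disease network
#'
#' A 13-node toy PPI network with two disease proteins and a fixed mediation
#' structure, used throughout the tests and documentation: a red disease
#' protein (degree 3) and a black one (degree 7) share two interacting
#' partners -- green (degree 2) and yellow (degree 5) -- which mediate the
#' two-step indirect effects between them; one blue node neighbours only
#' red, five blue nodes only black, and three white nodes hang off yellow
#' (so the whites are not interacting partners of any disease protein).
#'
#' @return list with `network` (igraph, 13 nodes / 13 edges), `annotation`
#'   (a `disease_annotation`: red has disease `"X"`, black disease `"Y"`)
#'   and `expected`, a named list of hand-checkable quantities: one-step
#'   effects red->green (1/2) and green->black (1/7), pathway strengths
#'   red-green-black (1/14) and red-yellow-black (1/35), two-step effects
#'   red->black (1/10) and black->red (7/30), their summed mutual dependence
#'   (1/3), and mediator contributions for yellow (1/15 + 1/35) and green
#'   (5/21).
#' @export
toy_disease_network <- function() {
  edges <- rbind(
    c("red", "green"), c("red", "yellow"), c("red", "blue1"),
    c("black", "green"), c("black", "yellow"),
    c("black", "blue2"), c("black", "blue3"), c("black", "blue4"),
    c("black", "blue5"), c("black", "blue6"),
    c("yellow", "white1"), c("yellow", "white2"), c("yellow", "white3")
  )
  net <- interaction_network(edges, name = "toy")
  ann <- disease_annotation(c("red", "black"), c("X", "Y"))
  expected <- list(
    one_step_red_green = 1 / 2,
    one_step_green_black = 1 / 7,
    pathway_red_green_black = 1 / 14,
    pathway_red_yellow_black = 1 / 35,
    two_step_red_black = 1 / 10,
    two_step_black_red = 7 / 30,
    mutual_dependence = 1 / 3,
    m2_yellow = 1 / 15 + 1 / 35,
    m2_green = 5 / 21
  )
  list(network = net, annotation = ann, expected = expected)
}

#' Random planted-disease network
#'
#' Generates an Erdos-Renyi G(n, p) interaction network with disease labels
#' planted on disjoint random node subsets, fully reproducible from `seed`.
#' A testing surrogate for real PPI + disease-annotation data.
#'
#' @param n_nodes number of proteins.
#' @param edge_prob edge probability in (0, 1].
#' @param labels character vector of disease labels.
#' @param dp_per_label integer vector (recycled) of disease proteins per
#'   label; the subsets are disjoint, so their sum must not exceed
#'   `n_nodes`.
#' @param seed integer seed; same arguments give identical output.
#' @return list with `network` (igraph; nodes named `P001`, `P002`, ...)
#'   and `annotation` (a `disease_annotation`).
#' @export
random_disease_network <- function(n_nodes, edge_prob, labels = c("X", "Y"),
                                   dp_per_label = 1L, seed = 1L) {
  if (edge_prob <= 0 || edge_prob > 1) {
    stop("edge_prob must be in (0, 1]", call. = FALSE)
  }
  dp_per_label <- rep_len(as.integer(dp_per_label), length(labels))
  if (sum(dp_per_label) > n_nodes) {
    stop("more disease proteins requested than nodes", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  ids <- sprintf("P%03d", seq_len(n_nodes))
  g <- igraph::sample_gnp(n_nodes, edge_prob, directed = FALSE)
  igraph::V(g)$name <- ids
  net <- interaction_network(igraph::as_edgelist(g, names = TRUE),
                             nodes = ids, name = "random")
  picked <- sample(ids, sum(dp_per_label))
  grp <- rep(labels, dp_per_label)
  list(network = net,
       annotation = disease_annotation(picked, grp))
}

#' Brute-force n-step effect by walk enumeration
#'
#' Independent oracle for [effect_matrix()]: explicitly enumerates every
#' walk of length `n` from `source` to `receiver` and sums, over walks, the
#' product of receiver-degree reciprocals along the walk. Guarded to small
#' problems (`n <= 5`, `N <= 13`) because enumeration is combinatorial.
#'
#' @param net igraph network with at most 13 nodes.
#' @param source,receiver protein ids.
#' @param n walk length, at most 5.
#' @return numeric effect value.
#' @export
brute_force_effect <- function(net, source, receiver, n) {
  if (igraph::vcount(net) > 13L || n > 5L) {
    stop("brute-force guard: requires N <= 13 and n <= 5", call. = FALSE)
  }
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  ids <- check_nodes(net, c(source, receiver))
  d <- node_degree(net)
  nbrs <- lapply(stats::setNames(igraph::V(net)$name, igraph::V(net)$name),
                 function(v) igraph::neighbors(net, v)$name)
  total <- 0
  walk <- function(at, steps_left, weight) {
    if (steps_left == 0L) {
      if (at == ids[2L]) total <<- total + weight
      return(invisible())
    }
    for (nxt in nbrs[[at]]) {
      walk(nxt, steps_left - 1L, weight / d[[nxt]])
    }
  }
  walk(ids[1L], as.integer(n), 1)
  total
}

# internal: all shortest simple paths between two nodes by iterative
# deepening over path length; returns list of node-id vectors (possibly
# empty when disconnected)
enumerate_geodesics <- function(nbrs, from, to) {
  n_nodes <- length(nbrs)
  for (len in seq_len(n_nodes - 1L)) {
    found <- list()
    dfs <- function(path, at) {
      depth <- length(path) - 1L
      if (depth == len) {
        if (at == to) found[[length(found) + 1L]] <<- path
        return(invisible())
      }
      for (nxt in nbrs[[at]]) {
        if (!(nxt %in% path)) dfs(c(path, nxt), nxt)
      }
    }
    dfs(from, from)
    if (length(found) > 0L) return(found)
  }
  list()
}

#' Brute-force betweenness by shortest-path enumeration
#'
#' Independent oracle for [node_betweenness()]: for every pair of other
#' nodes, enumerates all equally shortest paths by explicit search and
#' accumulates the fraction passing through `i`. Guarded to `N <= 13`.
#'
#' @param net igraph network with at most 13 nodes.
#' @param i protein id.
#' @return non-negative numeric.
#' @export
brute_force_betweenness <- function(net, i) {
  if (igraph::vcount(net) > 13L) {
    stop("brute-force guard: requires N <= 13", call. = FALSE)
  }
  i <- check_nodes(net, i)
  ids <- igraph::V(net)$name
  nbrs <- lapply(stats::setNames(ids, ids),
                 function(v) igraph::neighbors(net, v)$name)
  others <- setdiff(ids, i)
  total <- 0
  if (length(others) < 2L) return(0)
  for (a in seq_len(length(others) - 1L)) {
    for (b in seq(a + 1L, length(others))) {
      paths <- enumerate_geodesics(nbrs, others[a], others[b])
      if (length(paths) == 0L) next
      through <- sum(vapply(paths, function(p) i %in% p, TRUE))
      total <- total + through / length(paths)
    }
  }
  total
}

#' Write the toy fixture files to a directory
#'
#' Emits the toy network edge list (`toy_edges.tsv`), its disease
#' annotation (`toy_annotation.tsv`) and the expected hand-checkable values
#' (`toy_expected.tsv`), for demonstrations and round-trip tests.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_toy_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- toy_disease_network()
  paths <- c(edges = file.path(dir, "toy_edges.tsv"),
             annotation = file.path(dir, "toy_annotation.tsv"),
             expected = file.path(dir, "toy_expected.tsv"))
  write_edge_list(toy$network, paths[["edges"]])
  utils::write.table(as.data.frame(toy$annotation), paths[["annotation"]],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  exp_df <- data.frame(quantity = names(toy$expected),
                       value = signif(unlist(toy$expected), 6L))
  utils::write.table(exp_df, paths[["expected"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
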