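#' One-step effect of one protein on a neighbour
#'
#' The direct effect of `source` on `receiver` is `1 / D_receiver` when the
#' two interact and 0 otherwise: an interaction partner is assumed to spread
#' its influence evenly over all of the receiver's neighbours, so the
#' magnitude is set by the receiver's degree. Direction matters: the effect
#' of j on i and the effect of i on j generally differ.
#'
#' @param net igraph network.
#' @param source,receiver protein ids.
#' @return numeric in `[0, 1]`.
#' @export
one_step_effect <- function(net, source, receiver) {
  ids <- check_nodes(net, c(source, receiver))
  if (!igraph::are_adjacent(net, ids[1L], ids[2L])) return(0)
  1 / node_degree(net, ids[2L])
}

#' Two-step pathway effect through one mediator
#'
#' Indirect effects are multiplicative along a pathway: the effect of
#' `source` on `receiver` through `mediator` is the product of the two
#' one-step effects, `(1/D_mediator) * (1/D_receiver)` when the mediator
#' interacts with both endpoints, else 0.
#'
#' @param net igraph network.
#' @param source,mediator,receiver three distinct protein ids.
#' @return numeric in `[0, 1]`.
#' @export
pathway_effect <- function(net, source, mediator, receiver) {
  ids <- check_nodes(net, c(source, mediator, receiver))
  if (anyDuplicated(ids)) {
    stop("source, mediator and receiver must be distinct", call. = FALSE)
  }
  one_step_effect(net, ids[1L], ids[2L]) * one_step_effect(net, ids[2L], ids[3L])
}

# internal: one-step effect matrix A with A[i, j] = 1/D_i if i ~ j else 0.
# Rows index receivers, columns sources; rows of non-isolated nodes sum to 1.
one_step_matrix <- function(net, sparse = igraph::vcount(net) > 3000L) {
  adj <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  d <- Matrix::rowSums(adj)
  inv <- ifelse(d > 0, 1 / d, 0)
  a <- Matrix::Diagonal(x = inv) %*% adj
  dimnames(a) <- list(igraph::V(net)$name, igraph::V(net)$name)
  if (!sparse) a <- as.matrix(a)
  a
}

#' n-step effect matrix
#'
#' The n-step effect of source j on receiver i sums, over every walk of
#' length `n` from j to i, the product of one-step effects along the walk
#' (multiplicative within a pathway, additive across pathways). This equals
#' the n-th power of the one-step matrix, so each receiver row of a
#' non-isolated node sums to exactly 1 for every `n` (the receiver's unit of
#' influence is conserved). Walks may revisit nodes, so diagonal entries are
#' generally nonzero for even `n`; summary indices exclude them.
#'
#' @param net igraph network.
#' @param n number of steps, `>= 1`.
#' @param sparse use sparse matrices; default for networks above 3000 nodes.
#'   Dense and sparse paths give identical results.
#' @return an object of class `effect_matrix`: list with `values` (matrix,
#'   rows = receivers, columns = sources), `nodes`, and `n`.
#' @export
effect_matrix <- function(net, n = 2L, sparse = igraph::vcount(net) > 3000L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("step count n must be >= 1", call. = FALSE)
  a1 <- one_step_matrix(net, sparse = sparse)
  a <- a1
  if (n > 1L) for (m in seq_len(n - 1L)) a <- a %*% a1
  if (sparse) {
    structure(list(values = a, nodes = rownames(a), n = n),
              class = "effect_matrix")
  } else {
    structure(list(values = as.matrix(a), nodes = rownames(a), n = n),
              class = "effect_matrix")
  }
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat(sprintf("<effect_matrix> %d-step effects over %d proteins\n",
              x$n, length(x$nodes)))
  cat("rows = receivers, columns = sources; a[i, j] = effect of j on i\n")
  invisible(x)
}

#' Extract effect values from an effect matrix
#'
#' @param em an `effect_matrix`.
#' @param source,receiver protein ids (vectors allowed; recycled pairwise).
#' @return numeric vector of `a^n[receiver, source]` values.
#' @export
effect_value <- function(em, source, receiver) {
  stopifnot(inherits(em, "effect_matrix"))
  missing <- setdiff(c(source, receiver), em$nodes)
  if (length(missing) > 0L) {
    stop(sprintf("unknown node(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  as.numeric(em$values[cbind(receiver, source)])
}

#' Summed mutual dependence of two proteins
#'
#' `a^n_ij + a^n_ji`: the two directed n-step effects between i and j added
#' together, a symmetric measure of how strongly the pair is indirectly
#' coupled.
#'
#' @param net igraph network.
#' @param i,j distinct protein ids.
#' @param n number of steps.
#' @return non-negative numeric.
#' @export
mutual_dependence <- function(net, i, j, n = 2L) {
  ids <- check_nodes(net, c(i, j))
  if (ids[1L] == ids[2L]) stop("i and j must be distinct", call. = FALSE)
  em <- effect_matrix(net, n)
  effect_value(em, ids[1L], ids[2L]) + effect_value(em, ids[2L], ids[1L])
}

#' Topological importance of a protein
#'
#' The total n-step topological importance TI^n of protein j is the sum of
#' its effects on all other nodes. Two conventions are supported:
#' `"exact_n"` (default) sums only effects mediated by walks of exactly `n`
#' steps; `"cumulative_mean"` averages the per-step totals over step lengths
#' 1..n, as in part of the index's prior literature. Self-effects (diagonal
#' entries) are excluded in both modes.
#'
#' @param net igraph network.
#' @param j protein id; if omitted, TI of every node is returned as a named
#'   vector.
#' @param n number of steps, `>= 1`.
#' @param mode `"exact_n"` or `"cumulative_mean"`.
#' @return non-negative numeric.
#' @export
topological_importance <- function(net, j = NULL, n = 2L,
                                   mode = c("exact_n", "cumulative_mean")) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("step count n must be >= 1", call. = FALSE)
  ti_step <- function(m) {
    a <- effect_matrix(net, m)$values
    idx <- cbind(seq_len(nrow(a)), seq_len(nrow(a)))
    as.numeric(Matrix::colSums(a)) - as.numeric(a[idx])
  }
  ti <- if (mode == "exact_n") {
    ti_step(n)
  } else {
    Reduce(`+`, lapply(seq_len(n), ti_step)) / n
  }
  ti <- stats::setNames(as.numeric(ti), igraph::V(net)$name)
  if (is.null(j)) return(ti)
  ti[[check_nodes(net, j)]]
}

#' Aggregate effect of one disease-protein set on another
#'
#' Sums the n-step effects of every source-set protein on every
#' receiver-set protein, skipping self-pairs (a protein annotated to both
#' diseases never contributes its self-effect). The result is directional:
#' the influence of the sources on the receivers. It is zero exactly when no
#' n-step walk links the two sets. Higher values mean many (or strong)
#' n-step pathways between the two disease modules.
#'
#' @param net igraph network.
#' @param sources,receivers non-empty character vectors of protein ids.
#' @param n number of steps.
#' @param source_label,receiver_label labels stored in the result.
#' @return object of class `disease_pair_effect`: list with `value` (the
#'   aggregate A^n), `contributions` (matrix receivers x sources), `n` and
#'   the two labels.
#' @export
set_effect <- function(net, sources, receivers, n = 2L,
                       source_label = "D1", receiver_label = "D2") {
  if (length(sources) == 0L || length(receivers) == 0L) {
    stop("source and receiver sets must be non-empty", call. = FALSE)
  }
  sources <- unique(check_nodes(net, sources))
  receivers <- unique(check_nodes(net, receivers))
  em <- effect_matrix(net, n)
  contrib <- as.matrix(em$values[receivers, sources, drop = FALSE])
  shared <- intersect(sources, receivers)
  if (length(shared) > 0L) contrib[cbind(shared, shared)] <- 0
  structure(list(value = sum(contrib), contributions = contrib, n = em$n,
                 source_label = source_label, receiver_label = receiver_label),
            class = "disease_pair_effect")
}

#' @export
print.disease_pair_effect <- function(x, ...) {
  cat(sprintf("<disease_pair_effect> A^%d (%s -> %s) = %.6g over %d x %d pairs\n",
              x$n, x$source_label, x$receiver_label, x$value,
              ncol(x$contributions), nrow(x$contributions)))
  invisible(x)
}

#' Two-direction mediator contribution (M2)
#'
#' Quantifies the role of protein k in mediating two-step pathways between i
#' and j, counting both directions: the i-to-j pathway through k plus the
#' j-to-i pathway through k. When k interacts with both endpoints this is
#' `(1/D_k)(1/D_j) + (1/D_k)(1/D_i)`; otherwise 0.
#'
#' @param net igraph network.
#' @param k mediator protein id.
#' @param i,j endpoint protein ids; all three distinct.
#' @return non-negative numeric.
#' @export
mediator_contribution <- function(net, k, i, j) {
  ids <- check_nodes(net, c(k, i, j))
  if (anyDuplicated(ids)) stop("k, i and j must be distinct", call. = FALSE)
  pathway_effect(net, ids[2L], ids[1L], ids[3L]) +
    pathway_effect(net, ids[3L], ids[1L], ids[2L])
}

#' Mediator table between two disease-protein sets
#'
#' For every cross pair (i in `set1`, j in `set2`) lists the mediators k --
#' common interaction partners of i and j in the analysis network,
#' regardless of their own disease status (a disease protein may itself
#' mediate) -- with the per-pair contribution M2_k(i, j), the pairwise
#' two-step strengths in each direction, and each mediator's grand total
#' over all pairs, which is the ranking statistic. Degrees are taken in the
#' network passed in, so the caller controls whether mediation is scored in
#' the full PPI network or in a subnetwork.
#'
#' @param net igraph analysis network.
#' @param set1,set2 non-empty character vectors of protein ids. Shared
#'   proteins give self-pairs, which are skipped with a warning.
#' @param set1_label,set2_label labels stored in the result.
#' @return object of class `mediator_table`: list with `pairs` (long data
#'   frame i, j, k, M2), `pair_strengths` (data frame i, j, a2_ij, a2_ji,
#'   total; a2_ij is the two-step effect of j on i), `totals` (data frame
#'   mediator, M2_total) and the labels.
#' @export
mediator_table <- function(net, set1, set2,
                           set1_label = "D1", set2_label = "D2") {
  if (length(set1) == 0L || length(set2) == 0L) {
    stop("both protein sets must be non-empty", call. = FALSE)
  }
  set1 <- unique(check_nodes(net, set1))
  set2 <- unique(check_nodes(net, set2))
  if (length(intersect(set1, set2)) > 0L) {
    warning("sets overlap; self-pairs are skipped", call. = FALSE)
  }
  d <- node_degree(net)
  nbrs <- lapply(stats::setNames(igraph::V(net)$name, igraph::V(net)$name),
                 function(v) igraph::neighbors(net, v)$name)
  rows <- list()
  strengths <- list()
  for (i in set1) {
    for (j in set2) {
      if (i == j) next
      common <- setdiff(intersect(nbrs[[i]], nbrs[[j]]), c(i, j))
      # a2_ij: effect of j on i over two steps = sum_k (1/D_i)(1/D_k)
      a2_ij <- if (length(common)) sum(1 / (d[i] * d[common])) else 0
      a2_ji <- if (length(common)) sum(1 / (d[j] * d[common])) else 0
      strengths[[length(strengths) + 1L]] <- data.frame(
        i = i, j = j, a2_ij = unname(a2_ij), a2_ji = unname(a2_ji),
        total = unname(a2_ij + a2_ji), stringsAsFactors = FALSE)
      if (length(common)) {
        m2 <- (1 / d[common]) * (1 / d[i] + 1 / d[j])
        rows[[length(rows) + 1L]] <- data.frame(
          i = i, j = j, k = common, M2 = unname(m2), stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = character(), j = character(), k = character(),
               M2 = numeric(), stringsAsFactors = FALSE)
  pair_strengths <- if (length(strengths)) do.call(rbind, strengths) else
    data.frame(i = character(), j = character(), a2_ij = numeric(),
               a2_ji = numeric(), total = numeric(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  rownames(pair_strengths) <- NULL
  tot <- if (nrow(pairs)) {
    agg <- stats::aggregate(M2 ~ k, data = pairs, FUN = sum)
    data.frame(mediator = agg$k, M2_total = agg$M2, stringsAsFactors = FALSE)
  } else {
    data.frame(mediator = character(), M2_total = numeric(),
               stringsAsFactors = FALSE)
  }
  ord <- order(-tot$M2_total, tot$mediator)
  structure(list(pairs = pairs, pair_strengths = pair_strengths,
                 totals = tot[ord, , drop = FALSE],
                 set1 = set1, set2 = set2,
                 set1_label = set1_label, set2_label = set2_label),
            class = "mediator_table")
}

#' @export
print.mediator_table <- function(x, ...) {
  cat(sprintf("<mediator_table> %s vs %s: %d mediator(s) over %d linked pair(s)\n",
              x$set1_label, x$set2_label, nrow(x$totals),
              sum(x$pair_strengths$total > 0)))
  if (nrow(x$totals)) {
    utils::head(x$totals, 10L) |> print(row.names = FALSE)
  }
  invisible(x)
}

#' Write mediator-table outputs as TSV files
#'
#' Emits four files mirroring the standard presentation of cross-disease
#' mediation results: a wide matrix of comma-joined mediator ids (rows =
#' `set2` proteins, columns = `set1` proteins), a wide matrix of summed
#' two-direction strengths (4 significant digits), the long per-pathway
#' table (i, j, k, M2) and the mediator ranking (mediator, M2_total, rank).
#'
#' @param mt a `mediator_table`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_mediator_table <- function(mt, dir, prefix = "mediators") {
  stopifnot(inherits(mt, "mediator_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cell <- function(i, j, what) {
    sel <- mt$pairs$i == i & mt$pairs$j == j
    if (what == "ids") paste(sort(mt$pairs$k[sel]), collapse = ",")
    else {
      s <- mt$pair_strengths
      v <- s$total[s$i == i & s$j == j]
      if (length(v) == 0L || v == 0) "" else format(signif(v, 4L))
    }
  }
  wide <- function(what) {
    m <- outer(mt$set2, mt$set1,
               Vectorize(function(j, i) cell(i, j, what)))
    dimnames(m) <- list(mt$set2, mt$set1)
    m
  }
  paths <- c(
    ids = file.path(dir, paste0(prefix, "_identity.tsv")),
    strength = file.path(dir, paste0(prefix, "_strength.tsv")),
    long = file.path(dir, paste0(prefix, "_pathways.tsv")),
    ranking = file.path(dir, paste0(prefix, "_ranking.tsv"))
  )
  utils::write.table(wide("ids"), paths[["ids"]], sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(wide("strength"), paths[["strength"]], sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(format_numeric_cols(mt$pairs), paths[["long"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ranking <- rank_mediators(mt)
  utils::write.table(format_numeric_cols(ranking), paths[["ranking"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write an effect matrix as TSV
#'
#' @param em an `effect_matrix`.
#' @param path output path.
#' @export
write_effect_matrix <- function(em, path) {
  stopifnot(inherits(em, "effect_matrix"))
  m <- signif(as.matrix(em$values), 6L)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
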