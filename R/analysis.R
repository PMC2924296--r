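#' Rank mediators by total mediation strength
#'
#' Orders the mediators of a [mediator_table()] by decreasing grand-total
#' M2, breaking ties by protein id (lexicographic), and returns the top
#' `top` of them.
#'
#' @param mt a `mediator_table`.
#' @param top number of mediators to keep; default all.
#' @return data frame with columns `mediator`, `M2_total`, `rank`
#'   (competition ranking on M2_total).
#' @export
rank_mediators <- function(mt, top = Inf) {
  stopifnot(inherits(mt, "mediator_table"))
  if (top < 1) stop("top must be >= 1", call. = FALSE)
  out <- mt$totals
  out <- out[order(-out$M2_total, out$mediator), , drop = FALSE]
  out$rank <- competition_rank(out$M2_total)
  rownames(out) <- NULL
  utils::head(out, n = if (is.finite(top)) as.integer(top) else nrow(out))
}

#' Most influenced (or most influential) protein of a set pair
#'
#' Given the contribution matrix of a [set_effect()] result, returns the
#' receiver with the largest summed incoming effect (`side = "receiver"`,
#' the row sums) or the source with the largest summed outgoing effect
#' (`side = "source"`, the column sums). When every contribution is zero no
#' protein is influenced at all and `NA` is returned with a warning.
#'
#' @param pair_effect a `disease_pair_effect`.
#' @param side `"receiver"` or `"source"`.
#' @return a protein id, or `NA_character_` if the contribution matrix is
#'   all zero. The summed effect is attached as attribute `"effect"`.
#' @export
most_influenced <- function(pair_effect, side = c("receiver", "source")) {
  stopifnot(inherits(pair_effect, "disease_pair_effect"))
  side <- match.arg(side)
  m <- pair_effect$contributions
  if (length(m) == 0L) stop("contribution matrix is empty", call. = FALSE)
  tot <- if (side == "receiver") rowSums(m) else colSums(m)
  if (all(tot == 0)) {
    warning("no effect reaches either set; no protein is influenced",
            call. = FALSE)
    return(NA_character_)
  }
  best <- names(tot)[order(-tot, names(tot))][1L]
  structure(best, effect = unname(tot[best]))
}

#' Decompose the influence on one protein by source disease
#'
#' For a target protein and several labeled source sets, computes each
#' set's aggregate n-step effect on the target and its percentage share of
#' the total, answering "where does the indirect influence on this protein
#' come from?". The target itself is dropped from any source set that
#' contains it (with a warning). When no set has any effect the percentage
#' shares are undefined and returned as `NA` with `defined = FALSE`.
#'
#' @param net igraph network.
#' @param target protein id.
#' @param source_sets named list of character vectors (label -> proteins).
#' @param n number of steps.
#' @return object of class `influence_breakdown`: data frame with columns
#'   `label`, `contribution`, `percent`, plus attributes `target` and
#'   `defined`.
#' @export
influence_decomposition <- function(net, target, source_sets, n = 2L) {
  target <- check_nodes(net, target)
  if (is.null(names(source_sets)) || any(!nzchar(names(source_sets)))) {
    stop("source_sets must be a named list", call. = FALSE)
  }
  if (any(vapply(source_sets, function(s) target %in% s, TRUE))) {
    warning("target protein removed from overlapping source set(s)",
            call. = FALSE)
    source_sets <- lapply(source_sets, setdiff, y = target)
  }
  em <- effect_matrix(net, n)
  contrib <- vapply(source_sets, function(s) {
    s <- check_nodes(net, s)
    if (length(s) == 0L) return(0)
    sum(effect_value(em, s, rep(target, length(s))))
  }, numeric(1L))
  total <- sum(contrib)
  defined <- total > 0
  out <- data.frame(label = names(source_sets),
                    contribution = unname(contrib),
                    percent = if (defined) 100 * unname(contrib) / total
                              else NA_real_,
                    stringsAsFactors = FALSE)
  structure(out, target = target, defined = defined,
            class = c("influence_breakdown", "data.frame"))
}

#' Read a functional term / P-value table
#'
#' Reads a flat enrichment export with columns `protein_id`, `category`,
#' `term`, `count`, `p_value` (tab-separated, `#` comments ignored). Only
#' the protein id and P-value are required downstream; extra columns are
#' kept.
#'
#' @param source path or connection.
#' @param delimiter field separator.
#' @return data frame with at least `protein_id` and `p_value` columns.
#' @export
read_term_table <- function(source, delimiter = "\t") {
  df <- utils::read.delim(source, sep = delimiter, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "p_value")
  if (!all(need %in% names(df))) {
    stop("term table must have columns protein_id and p_value", call. = FALSE)
  }
  if (any(df$p_value <= 0 | df$p_value > 1)) {
    stop("P-values must lie in (0, 1]", call. = FALSE)
  }
  df
}

#' Average enrichment P-value of a protein (avP)
#'
#' The arithmetic mean of the enrichment P-values of every functional term
#' annotated to the protein, across all term categories.
#'
#' @param table term table (see [read_term_table()]).
#' @param protein protein id with at least one term row.
#' @return numeric in (0, 1].
#' @export
average_term_pvalue <- function(table, protein) {
  p <- table$p_value[table$protein_id == protein]
  if (length(p) == 0L) {
    stop(sprintf("no term rows for protein %s", protein), call. = FALSE)
  }
  mean(p)
}

#' Correlation between mediation strength and another node property
#'
#' Pearson or Spearman rank-order correlation, with the input checks the
#' mediation-vs-centrality and mediation-vs-avP comparisons need: equal
#' lengths of at least 3 and non-constant vectors. Spearman uses average
#' ranks for ties.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @param method `"pearson"` or `"spearman"`.
#' @return coefficient in `[-1, 1]`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(x, y, method = method)
}

#' Write an influence breakdown as TSV
#'
#' @param breakdown an `influence_breakdown`.
#' @param path output path.
#' @export
write_influence_breakdown <- function(breakdown, path) {
  df <- as.data.frame(breakdown)
  df <- cbind(target = attr(breakdown, "target"), df)
  utils::write.table(format_numeric_cols(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
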