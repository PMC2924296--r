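#' Read a disease annotation table
#'
#' Reads a two-column TSV mapping protein ids to disease-class labels (one
#' row per protein/label pair; a protein may carry several labels, e.g. a
#' gene implicated in both obesity and diabetes). `#`-prefixed comment lines
#' are ignored and duplicate rows collapsed.
#'
#' @param source path or connection.
#' @param delimiter field separator, default tab.
#' @return data frame of class `disease_annotation` with columns
#'   `protein_id` and `label`.
#' @export
read_disease_annotation <- function(source, delimiter = "\t") {
  lines <- readLines(source)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    warning("empty disease annotation", call. = FALSE)
    return(disease_annotation(character(), character()))
  }
  parts <- strsplit(lines[idx], delimiter, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed annotation record at line %d", idx[bad[1L]]),
         call. = FALSE)
  }
  id <- trimws(vapply(parts, `[`, "", 1L))
  lab <- trimws(vapply(parts, `[`, "", 2L))
  blank <- which(!nzchar(id) | !nzchar(lab))
  if (length(blank) > 0L) {
    stop(sprintf("blank protein id or label at line %d", idx[blank[1L]]),
         call. = FALSE)
  }
  disease_annotation(id, lab)
}

#' Construct a disease annotation in code
#'
#' @param protein_id character vector of protein ids.
#' @param label parallel character vector of disease-class labels (a single
#'   label is recycled).
#' @return data frame of class `disease_annotation`.
#' @export
disease_annotation <- function(protein_id, label) {
  if (length(label) == 1L) label <- rep(label, length(protein_id))
  stopifnot(length(protein_id) == length(label))
  df <- unique(data.frame(protein_id = as.character(protein_id),
                          label = as.character(label),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("disease_annotation", "data.frame")
  df
}

#' Disease-protein sets per label
#'
#' @param ann a `disease_annotation`.
#' @return named list: for each label, the character vector of its proteins.
#' @export
annotation_sets <- function(ann) {
  split(ann$protein_id, ann$label)
}

#' Classify network nodes as DP, IP or other
#'
#' A node with at least one disease label is a disease protein (DP) -- never
#' an IP, even when it also neighbours other DPs. A non-disease node
#' adjacent to at least one DP is an interacting partner (IP); the rest are
#' `other`. Annotated proteins absent from the network are ignored with a
#' warning.
#'
#' @param ppi igraph PPI network.
#' @param ann a `disease_annotation`.
#' @return data frame with columns `node`, `role` (`"DP"`, `"IP"` or
#'   `"other"`) and `labels` (comma-joined, empty for non-DPs).
#' @export
classify_nodes <- function(ppi, ann) {
  nodes <- igraph::V(ppi)$name
  absent <- setdiff(unique(ann$protein_id), nodes)
  if (length(absent) > 0L) {
    warning(sprintf("%d annotated protein(s) not in the network; ignored",
                    length(absent)), call. = FALSE)
  }
  dp <- intersect(unique(ann$protein_id), nodes)
  ip <- if (length(dp) > 0L) {
    setdiff(unique(unlist(igraph::adjacent_vertices(ppi, dp) |>
                            lapply(function(v) v$name))), dp)
  } else character()
  role <- ifelse(nodes %in% dp, "DP", ifelse(nodes %in% ip, "IP", "other"))
  labs <- vapply(nodes, function(v) {
    paste(sort(unique(ann$label[ann$protein_id == v])), collapse = ",")
  }, "")
  data.frame(node = nodes, role = role, labels = unname(labs),
             stringsAsFactors = FALSE)
}

#' Build the DPIP subnetwork
#'
#' The DPIP network contains the disease proteins (DPs) and their
#' interacting partners (IPs), but only the DP-DP and DP-IP interactions:
#' every edge has at least one DP endpoint, so it contains no IP-IP links.
#'
#' @param ppi igraph PPI network.
#' @param ann a `disease_annotation` with at least one protein present in
#'   `ppi`.
#' @return igraph network named `"DPIP"`.
#' @export
build_dpip <- function(ppi, ann) {
  roles <- suppressWarnings(classify_nodes(ppi, ann))
  dp <- roles$node[roles$role == "DP"]
  if (length(dp) == 0L) {
    stop("no disease protein present in the network", call. = FALSE)
  }
  ip <- roles$node[roles$role == "IP"]
  el <- igraph::as_edgelist(ppi, names = TRUE)
  keep <- el[, 1L] %in% dp | el[, 2L] %in% dp
  g <- interaction_network(el[keep, , drop = FALSE], nodes = c(dp, ip),
                           name = "DPIP")
  g
}

#' Build the IP subnetwork
#'
#' The IP network contains only the interacting partners and the
#' interactions among them. It is not a subgraph of the DPIP network: the
#' IP-IP links kept here are exactly the ones the DPIP network excludes.
#'
#' @inheritParams build_dpip
#' @return igraph network named `"IP"` (possibly empty, with a warning).
#' @export
build_ip <- function(ppi, ann) {
  roles <- suppressWarnings(classify_nodes(ppi, ann))
  ip <- roles$node[roles$role == "IP"]
  if (length(ip) == 0L) {
    warning("no interacting partners; IP network is empty", call. = FALSE)
    return(interaction_network(matrix(character(), ncol = 2L), name = "IP"))
  }
  el <- igraph::as_edgelist(ppi, names = TRUE)
  keep <- el[, 1L] %in% ip & el[, 2L] %in% ip
  interaction_network(el[keep, , drop = FALSE], nodes = ip, name = "IP")
}

#' Classify how pairs of diseases are linked
#'
#' For each unordered pair of disease labels reports `"direct"` when any PPI
#' edge joins their protein sets, `"indirect"` when the sets are joined only
#' through a two-step path (a shared neighbour), and `"unlinked"` otherwise.
#' Proteins annotated to both diseases are reported in `shared` and excluded
#' from the path test.
#'
#' @param ppi igraph PPI network.
#' @param ann a `disease_annotation` with at least two labels.
#' @return data frame with columns `label1`, `label2`, `linkage`, `shared`.
#' @export
disease_pair_linkage <- function(ppi, ann) {
  sets <- annotation_sets(ann)
  sets <- lapply(sets, intersect, y = igraph::V(ppi)$name)
  if (length(sets) < 2L) {
    stop("need at least two disease labels", call. = FALSE)
  }
  labs <- names(sets)
  dist <- igraph::distances(ppi)
  out <- list()
  for (a in seq_len(length(labs) - 1L)) {
    for (b in seq(a + 1L, length(labs))) {
      s1 <- sets[[a]]; s2 <- sets[[b]]
      shared <- intersect(s1, s2)
      s1x <- setdiff(s1, shared); s2x <- setdiff(s2, shared)
      d <- if (length(s1x) && length(s2x)) {
        min(dist[s1x, s2x, drop = FALSE])
      } else Inf
      linkage <- if (d <= 1) "direct" else if (d <= 2) "indirect" else "unlinked"
      out[[length(out) + 1L]] <- data.frame(
        label1 = labs[a], label2 = labs[b], linkage = linkage,
        shared = paste(sort(shared), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
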