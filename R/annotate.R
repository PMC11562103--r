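#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene IDs. IDs are uppercased and trimmed on load so membership
#' tests are exact-string after case normalization.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(toupper(trimws(parts[-(1:2)])))
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

#' Gene-set signature counts per cluster
#'
#' Entry `(c, s)` is the number of genes of cluster `c` belonging to set
#' `s`; genes in several sets are counted in each. A `total` row gives the
#' column sums.
#'
#' @param partition A `cluster_partition` or a named label vector over
#'   gene IDs.
#' @param sets Named list of gene-ID vectors (e.g. from [read_gmt()]).
#' @return Integer matrix, clusters (+ total) x sets.
#' @export
signature_counts <- function(partition, sets) {
  labels <- if (inherits(partition, "cluster_partition")) partition$labels else partition
  genes <- toupper(names(labels))
  sets <- lapply(sets, toupper)
  if (!any(genes %in% unique(unlist(sets))))
    warning("no overlap between partition genes and any gene set")
  lev <- names(sort(table(labels), decreasing = TRUE))
  counts <- sapply(sets, function(s) {
    inset <- genes %in% s
    vapply(lev, function(cl) sum(inset & labels == cl), integer(1))
  })
  counts <- rbind(counts, total = colSums(counts))
  storage.mode(counts) <- "integer"
  counts
}

#' Cross-tabulate two cluster partitions
#'
#' Counts and row percentages of a reference partition against another
#' partition over the shared gene universe, plus the best-match percentage
#' per reference cluster (reproducibility of that cluster in the other
#' partition). Optionally, merged super-clusters of the reference can be
#' scored the same way.
#'
#' @param p_ref,p_other `cluster_partition`s or named label vectors.
#' @param merged Optional named list of reference-cluster groups, e.g.
#'   `list(combined = c("C1", "C2"))`, each scored against the best single
#'   merged counterpart in the other partition.
#' @return List of class `cross_tab`: `counts`, `row_pct`, `best_match`
#'   (named vector of max row percentages), `n_shared`, and `merged_match`
#'   when requested.
#' @export
cross_tabulate <- function(p_ref, p_other, merged = NULL) {
  lab_r <- if (inherits(p_ref, "cluster_partition")) p_ref$labels else p_ref
  lab_o <- if (inherits(p_other, "cluster_partition")) p_other$labels else p_other
  shared <- intersect(names(lab_r), names(lab_o))
  if (length(shared) == 0) stop("partitions share no gene IDs")
  lr <- lab_r[shared]; lo <- lab_o[shared]
  ord_r <- names(sort(table(lr), decreasing = TRUE))
  ord_o <- names(sort(table(lo), decreasing = TRUE))
  counts <- table(factor(lr, ord_r), factor(lo, ord_o))
  counts <- unclass(counts)
  row_pct <- 100 * counts / rowSums(counts)
  best <- apply(row_pct, 1, max)
  out <- list(counts = counts, row_pct = row_pct, best_match = best,
              n_shared = length(shared))
  if (!is.null(merged)) {
    out$merged_match <- vapply(merged, function(grp) {
      sel <- lr %in% grp
      tab <- table(lo[sel])
      100 * max(tab) / sum(sel)
    }, numeric(1))
  }
  class(out) <- "cross_tab"
  out
}

#' @export
print.cross_tab <- function(x, ...) {
  cat("Cross-tabulation over", x$n_shared, "shared genes\n")
  print(x$counts)
  cat("Best-match row percentages:\n")
  print(round(x$best_match, 1))
  invisible(x)
}

#' Attach clinical attributes to a patient network
#'
#' Builds an igraph graph from a patient adjacency matrix and annotates
#' each node with clinical attributes (e.g. stage, vital state, MYCN
#' status, MKI, diagnostic category). Missing or unmatched values are
#' encoded `"unknown"`.
#'
#' @param graph Binary patient adjacency matrix with sample IDs as
#'   dimnames.
#' @param clinical `data.frame` whose first column (or a `sample_id`
#'   column) holds sample IDs; remaining columns become node attributes.
#' @return An `igraph` object with node attributes set.
#' @export
overlay_attributes <- function(graph, clinical) {
  g <- igraph::graph_from_adjacency_matrix(graph != 0, mode = "undirected")
  idcol <- if ("sample_id" %in% names(clinical)) "sample_id" else names(clinical)[1]
  ids <- as.character(clinical[[idcol]])
  pos <- match(igraph::V(g)$name, ids)
  unmatched <- sum(is.na(pos))
  if (unmatched > 0)
    message(unmatched, " patient node(s) without clinical records; attributes set to 'unknown'")
  for (col in setdiff(names(clinical), idcol)) {
    v <- as.character(clinical[[col]])[pos]
    v[is.na(v) | v == ""] <- "unknown"
    g <- igraph::set_vertex_attr(g, col, value = v)
  }
  g
}

#' Export a network with node attributes as GraphML
#'
#' Writes an adjacency or GTOM matrix as a GraphML graph. For a weighted
#' (GTOM) matrix, edges carry the overlap as weight and only pairs with
#' weight at least `min_weight` become edges. Optionally hides low-degree
#' nodes at export time only (display convention; computations are never
#' filtered).
#'
#' @param m Symmetric adjacency (binary) or GTOM (weighted) matrix.
#' @param file Output path.
#' @param node_attrs Optional named list / data.frame of per-node
#'   attributes (cluster label, clinical fields...), aligned with
#'   `rownames(m)`.
#' @param min_weight Edge threshold for weighted matrices (default: any
#'   positive off-diagonal entry of a binary matrix).
#' @param min_degree Hide nodes with fewer connections at export (default 0
#'   = keep all).
#' @return Invisibly, the igraph object written.
#' @export
write_graphml <- function(m, file, node_attrs = NULL, min_weight = NULL,
                          min_degree = 0) {
  w <- m
  diag(w) <- 0
  if (!is.null(min_weight)) w[w < min_weight] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
  if (!is.null(node_attrs)) {
    node_attrs <- as.data.frame(node_attrs, stringsAsFactors = FALSE)
    for (col in names(node_attrs))
      g <- igraph::set_vertex_attr(g, col, value = as.character(node_attrs[[col]]))
  }
  if (min_degree > 0)
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) < min_degree])
  igraph::write_graph(g, file, format = "graphml")
  invisible(g)
}
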