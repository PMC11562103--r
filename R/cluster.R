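#' Hierarchical module detection on a GTOM matrix
#'
#' Agglomerative clustering on the dissimilarity `1 - t` (the standard
#' topological-overlap dissimilarity), cut to `n_clusters` groups.
#' `linkage = "ward"` uses Ward's minimum-variance criterion
#' (`hclust` method `ward.D2`); `"average"` uses UPGMA. Cluster IDs are
#' assigned in order of decreasing size (`"C1"` is the largest), which is
#' also the canonical order used by [total_score()].
#'
#' @param t GTOM matrix (symmetric, unit diagonal).
#' @param n_clusters Number of modules, `2 <= n_clusters <= d`.
#' @param linkage `"ward"` (default) or `"average"`.
#' @return An object of class `cluster_partition`: list with `labels`
#'   (named character vector), `n_clusters`, `sizes`, `ratios`,
#'   `canonical_order`, `linkage`, and the `hclust` tree.
#' @export
cluster_gtom <- function(t, n_clusters, linkage = c("ward", "average")) {
  linkage <- match.arg(linkage)
  d <- nrow(t)
  if (n_clusters > d) stop("n_clusters exceeds the number of nodes")
  if (n_clusters < 2) stop("n_clusters must be at least 2")
  diss <- stats::as.dist(1 - t)
  tree <- stats::hclust(diss, method = if (linkage == "ward") "ward.D2" else "average")
  raw <- stats::cutree(tree, k = n_clusters)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(paste0("C", seq_along(sizes)), names(sizes))
  labels <- unname(relabel[as.character(raw)])
  names(labels) <- rownames(t)
  sizes <- sort(table(labels), decreasing = TRUE)
  structure(list(labels = labels,
                 n_clusters = as.integer(n_clusters),
                 sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 ratios = as.numeric(sizes) / d,
                 canonical_order = names(sizes),
                 linkage = linkage,
                 tree = tree),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("Cluster partition (", x$linkage, " linkage): ", x$n_clusters,
      " clusters over ", length(x$labels), " nodes\n", sep = "")
  print(x$sizes)
  invisible(x)
}

#' Silhouette diagnostics over candidate cluster counts
#'
#' Mean silhouette width on the dissimilarity `1 - t` for each candidate
#' module count — a reference for choosing the cluster number, not an
#' automatic selector.
#'
#' @param t GTOM matrix.
#' @param range Candidate counts, a subset of `2..(d - 1)`.
#' @param linkage Passed to [cluster_gtom()].
#' @return `data.frame` with columns `n_clusters` and `silhouette`.
#' @export
cluster_count_diagnostics <- function(t, range = 2:8, linkage = "ward") {
  d <- nrow(t)
  if (any(range < 2 | range > d - 1)) stop("range must lie within [2, d - 1]")
  diss <- stats::as.dist(1 - t)
  out <- vapply(range, function(k) {
    part <- cluster_gtom(t, k, linkage)
    sil <- cluster::silhouette(as.integer(factor(part$labels)), diss)
    mean(sil[, "sil_width"])
  }, numeric(1))
  data.frame(n_clusters = as.integer(range), silhouette = out)
}

# population SD (divide by m) of cluster sizes
.size_sd <- function(sizes) {
  m <- mean(sizes)
  sqrt(mean((sizes - m)^2))
}

#' Scan the network-construction parameter grid
#'
#' For every combination of correlation cutoff, GTOM order `k` and cluster
#' count: build the adjacency matrix, compute GTOM(k), cluster, and record
#' the composite total score together with the standard deviation
#' (population convention) of the cluster sizes. High total score with low
#' size SD indicates a partition with several distinct cores plus attached
#' subnetworks rather than one giant or fragmented cluster.
#'
#' @param x Genes x samples expression matrix (already denoised if desired).
#' @param cutoffs Correlation cutoffs to scan.
#' @param ks GTOM orders to scan.
#' @param n_clusters_list Cluster counts to scan.
#' @param linkage Passed to [cluster_gtom()].
#' @param corr Optional precomputed gene correlation matrix (to avoid
#'   recomputation across grid points).
#' @return `data.frame` of class `scan_record` with one row per grid point:
#'   `cutoff`, `k`, `n_clusters`, `total_score`, `size_sd`, `cluster_sizes`
#'   (comma-separated, descending).
#' @export
parameter_scan <- function(x, cutoffs = seq(0.5, 0.9, by = 0.02),
                           ks = 0:3, n_clusters_list = c(4, 5),
                           linkage = "ward", corr = NULL) {
  if (length(cutoffs) == 0 || length(ks) == 0 || length(n_clusters_list) == 0)
    stop("empty scan grid")
  if (is.null(corr)) corr <- correlation_matrix(x, "pearson", "genes")
  rows <- list()
  for (cut in cutoffs) {
    a <- adjacency_from_correlation(corr, cut)
    for (k in ks) {
      t <- gtom(a, k)
      for (nc in n_clusters_list) {
        part <- cluster_gtom(t, nc, linkage)
        g <- cluster_gtom_scores(t, part$labels)
        s <- total_score(g, part$ratios)
        rows[[length(rows) + 1]] <- data.frame(
          cutoff = cut, k = as.integer(k), n_clusters = as.integer(nc),
          total_score = s, size_sd = .size_sd(part$sizes),
          cluster_sizes = paste(part$sizes, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scan_record", class(out))
  out
}
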