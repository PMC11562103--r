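#' Pearson or Spearman correlation matrix
#'
#' Correlations between genes (rows) or between samples (columns) of an
#' expression matrix. Constant rows, which have undefined correlation, are
#' assigned correlation 0 to every partner (diagonal stays 1) with a
#' warning — this keeps the node universe aligned across configurations
#' instead of silently dropping genes.
#'
#' @param x Genes x samples numeric matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @param axis Correlate `"genes"` (rows) or `"samples"` (columns).
#' @return Symmetric correlation matrix with unit diagonal, attribute
#'   `corr_method`.
#' @export
correlation_matrix <- function(x, method = c("pearson", "spearman"),
                               axis = c("genes", "samples")) {
  method <- match.arg(method)
  axis <- match.arg(axis)
  m <- if (axis == "genes") t(x) else x
  if (ncol(m) < 2) stop("need at least 2 entities to correlate")
  if (nrow(m) < 3) stop("need at least 3 observations per correlated pair")
  sds <- apply(m, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(m, method = method))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant row(s); correlations set to 0")
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  diag(cc) <- 1
  cc <- (cc + t(cc)) / 2
  attr(cc, "corr_method") <- method
  cc
}

#' Threshold a correlation matrix into a binary adjacency matrix
#'
#' Signed rule: nodes are connected iff their correlation is at least
#' `cutoff` (the boundary value is included; anti-correlated pairs are never
#' connected). Self-edges are excluded.
#'
#' @param c Symmetric correlation matrix.
#' @param cutoff Threshold in (0, 1).
#' @return Binary symmetric matrix with zero diagonal, attribute `cutoff`.
#' @export
adjacency_from_correlation <- function(c, cutoff) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  a <- (c >= cutoff) * 1
  diag(a) <- 0
  attr(a, "cutoff") <- cutoff
  a
}

#' Nodes reachable within a path-length bound
#'
#' For each node `i`, the set `N(i)` of nodes (excluding `i`) whose graph
#' distance from `i` is at most `path_len`, computed by repeated boolean
#' adjacency expansion (equivalent to breadth-first search truncated at
#' depth `path_len`).
#'
#' @param a Binary symmetric adjacency matrix, zero diagonal.
#' @param path_len Maximum path length, `>= 1`.
#' @return Binary matrix `R` with `R[i, j] = 1` iff `j` is in `N(i)`.
#' @export
reachable_sets <- function(a, path_len) {
  stopifnot(path_len >= 1)
  a <- (a != 0) * 1
  diag(a) <- 0
  r <- a
  p <- a
  step <- 1
  while (step < path_len) {
    p <- (p %*% a > 0) * 1
    rn <- ((r + p) > 0) * 1
    diag(rn) <- 0
    if (all(rn == r)) break  # transitive closure reached early
    r <- rn
    step <- step + 1
  }
  diag(r) <- 0
  r
}

#' Generalized topological overlap matrix GTOM(k)
#'
#' Overlap of order-(k+1) neighborhoods: for nodes `i != j`,
#' \deqn{t_{ij} = \frac{|N_{k+1}(i) \cap N_{k+1}(j)| + a_{ij}}
#'   {\min(|N_{k+1}(i)|, |N_{k+1}(j)|) + 1 - a_{ij}},}
#' with unit diagonal, where `N_{k+1}(i)` is the set of nodes reachable
#' from `i` within a path of length `k + 1`. GTOM(0) uses direct neighbor
#' sets; larger `k` credits nodes that share multi-step neighborhoods even
#' when not directly connected. Two mutually unreachable isolated nodes get
#' overlap 0.
#'
#' @param a Binary symmetric adjacency matrix, zero diagonal.
#' @param k Neighborhood order offset, integer `>= 0`.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal, attributes
#'   `order_k` and `cutoff` (propagated from `a` if present).
#' @export
gtom <- function(a, k = 0) {
  stopifnot(k >= 0)
  a <- (a != 0) * 1
  diag(a) <- 0
  r <- reachable_sets(a, k + 1)
  sizes <- rowSums(r)
  overlap <- r %*% r            # |N(i) ∩ N(j)| for symmetric binary r
  minsz <- outer(sizes, sizes, pmin)
  t <- (overlap + a) / (minsz + 1 - a)
  diag(t) <- 1
  dimnames(t) <- dimnames(a)
  attr(t, "order_k") <- as.integer(k)
  attr(t, "cutoff") <- attr(a, "cutoff")
  t
}

.resolve_nodes <- function(t, idx) {
  if (is.character(idx)) {
    pos <- match(idx, rownames(t))
    if (anyNA(pos)) stop("unknown node(s): ", paste(idx[is.na(pos)], collapse = ", "))
    pos
  } else as.integer(idx)
}

#' Mean overlap between two node groups (GTOMscore)
#'
#' Mean of `t[i, j]` over ordered pairs `(i, j)` in `C x D` with `i != j`.
#' With a binary adjacency matrix in place of `t`, this is the cross-group
#' edge density.
#'
#' @param t GTOM matrix (or adjacency matrix) over a common node universe.
#' @param group_c,group_d Node indices or names; non-empty.
#' @return Scalar mean overlap.
#' @export
gtom_score <- function(t, group_c, group_d) {
  ci <- .resolve_nodes(t, group_c)
  di <- .resolve_nodes(t, group_d)
  if (length(ci) == 0 || length(di) == 0) stop("empty group")
  sub <- t[ci, di, drop = FALSE]
  shared <- intersect(ci, di)
  n_pairs <- length(ci) * length(di) - length(shared)
  if (n_pairs == 0) stop("no ordered pairs with i != j between the groups")
  tot <- sum(sub) - sum(diag(t)[shared])
  tot / n_pairs
}

#' Within-minus-cross overlap difference (GTOMdiff)
#'
#' `gtom_score(A, A) - gtom_score(A, B)`: how much more connected group A
#' is internally than to group B. High values indicate good separation.
#' Note the asymmetry: A is the reference group.
#'
#' @param t GTOM or adjacency matrix.
#' @param group_a Reference group, at least 2 nodes.
#' @param group_b Comparison group, at least 1 node.
#' @return Scalar difference.
#' @export
gtom_diff <- function(t, group_a, group_b) {
  if (length(group_a) < 2) stop("group A needs at least 2 nodes")
  gtom_score(t, group_a, group_a) - gtom_score(t, group_a, group_b)
}

#' Pairwise cluster GTOMscores
#'
#' The `m x m` matrix `G` with `G[i, j]` the mean overlap between clusters
#' `i` and `j` (within-cluster on the diagonal), in the canonical order of
#' the supplied labels (see [cluster_gtom()]: clusters sorted by descending
#' size).
#'
#' @param t GTOM matrix.
#' @param labels Cluster label per node, or a `cluster_partition`.
#' @return Named symmetric matrix of mean overlaps.
#' @export
cluster_gtom_scores <- function(t, labels) {
  if (inherits(labels, "cluster_partition")) labels <- labels$labels
  lev <- names(sort(table(labels), decreasing = TRUE))
  m <- length(lev)
  g <- matrix(NA_real_, m, m, dimnames = list(lev, lev))
  idx <- split(seq_along(labels), factor(labels, levels = lev))
  for (i in seq_len(m)) for (j in i:m) {
    if (i == j && length(idx[[i]]) < 2) { g[i, j] <- 1; next }
    s <- gtom_score(t, idx[[i]], idx[[j]])
    g[i, j] <- s; g[j, i] <- s
  }
  g
}

#' Composite total score of a cluster partition
#'
#' Given the pairwise cluster overlap matrix `G` and the cluster size
#' ratios `r`, the total score is
#' \deqn{S = \frac{1}{d_C} \sum_{i<j} r_i r_j \{ G_{ii} G_{jj} (1 - G_{ij})
#'   + G_{ii} (1 - G_{jj}) G_{ij} \},}
#' with `d_C = m(m-1)/2` the number of cluster pairs. The first term
#' rewards pairs of distinct well-connected cores; the second rewards
#' weakly self-connected subnetworks strongly attached to a core. The
#' summand is asymmetric in `(i, j)`, so the cluster order matters: the
#' canonical order is by descending cluster size. `symmetrized = TRUE`
#' averages the summand over both orientations instead.
#'
#' @param gtom_scores `m x m` matrix of pairwise cluster overlaps in
#'   canonical order, entries in `[0, 1]`.
#' @param cluster_ratios Size ratios `r_i`, summing to 1.
#' @param symmetrized Use the orientation-averaged form (default `FALSE`).
#' @return Scalar total score.
#' @export
total_score <- function(gtom_scores, cluster_ratios, symmetrized = FALSE) {
  g <- gtom_scores
  r <- cluster_ratios
  m <- nrow(g)
  if (m < 2) stop("need at least 2 clusters")
  if (length(r) != m) stop("ratio length must match cluster count")
  if (abs(sum(r) - 1) > 1e-8) stop("cluster ratios must sum to 1")
  if (any(g < -1e-12 | g > 1 + 1e-12)) stop("overlap scores must lie in [0, 1]")
  s <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    term <- g[i, i] * g[j, j] * (1 - g[i, j]) + g[i, i] * (1 - g[j, j]) * g[i, j]
    if (symmetrized) {
      term2 <- g[j, j] * g[i, i] * (1 - g[i, j]) + g[j, j] * (1 - g[i, i]) * g[i, j]
      term <- (term + term2) / 2
    }
    s <- s + r[i] * r[j] * term
  }
  s / (m * (m - 1) / 2)
}
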