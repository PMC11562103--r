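# Shared fixtures and independent oracles used across the test files.

# path graph 1-2-3 (the worked example used for hand-checked GTOM values)
path3_adjacency <- function() {
  a <- matrix(0, 3, 3, dimnames = list(paste0("n", 1:3), paste0("n", 1:3)))
  a[1, 2] <- a[2, 1] <- 1
  a[2, 3] <- a[3, 2] <- 1
  a
}

# Erdos-Renyi adjacency for property tests
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# Independent brute-force GTOM oracle: explicit BFS per node, literal
# formula with R set objects. Deliberately shares no code with gtom().
bfs_neighborhood <- function(a, start, depth) {
  n <- nrow(a)
  dist <- rep(Inf, n)
  dist[start] <- 0
  frontier <- start
  d <- 0
  while (length(frontier) > 0 && d < depth) {
    nxt <- unique(unlist(lapply(frontier, function(v) which(a[v, ] != 0))))
    nxt <- nxt[dist[nxt] == Inf]
    dist[nxt] <- d + 1
    frontier <- nxt
    d <- d + 1
  }
  setdiff(which(dist <= depth), start)
}

gtom_oracle <- function(a, k) {
  n <- nrow(a)
  nb <- lapply(seq_len(n), function(i) bfs_neighborhood(a, i, k + 1))
  t <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- length(intersect(nb[[i]], nb[[j]])) + a[i, j]
    den <- min(length(nb[[i]]), length(nb[[j]])) + 1 - a[i, j]
    t[i, j] <- num / den
  }
  t
}

# drop all attributes except dim, for exact matrix comparison
bare_matrix <- function(m) {
  out <- as.numeric(m)
  dim(out) <- dim(m)
  out
}

# Literal two-term re-implementation of the total score over enumerated pairs
total_score_oracle <- function(g, r) {
  m <- nrow(g)
  acc <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i >= j) next
    acc <- acc + r[i] * r[j] *
      (g[i, i] * g[j, j] * (1 - g[i, j]) + g[i, i] * (1 - g[j, j]) * g[i, j])
  }
  acc / (m * (m - 1) / 2)
}

# small planted study used by several files (cheap: ~300 TFs, 60 samples)
small_planted <- function(seed = 1, ...) {
  spec <- synthetic_spec(
    n_tfs = 300, n_samples_major = 45, n_samples_minor = 15,
    module_layout = default_module_layout(300), seed = seed, ...)
  generate_planted_expression(spec)
}

# adjusted Rand index via mclust (independent of the package's clustering)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# default full-size study conditions shared by the acceptance tests
study_spec <- function(seed, noise_sd = 0) {
  synthetic_spec(noise_sd = noise_sd, seed = seed)
}

# cache of full-size studies so several test blocks can share one generation
.study_cache <- new.env(parent = emptyenv())
get_study <- function(seed, noise_sd = 0) {
  key <- paste0("s", seed, "_n", noise_sd)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- generate_planted_expression(study_spec(seed, noise_sd))
  .study_cache[[key]]
}

# module recovery ARI at a given GTOM order under the default pipeline settings
recovery_ari <- function(x, truth_labels, k, cutoff = 0.7, n_clusters = 5) {
  cc <- correlation_matrix(x, "pearson", "genes")
  a <- adjacency_from_correlation(cc, cutoff)
  part <- cluster_gtom(gtom(a, k), n_clusters)
  ari(part$labels, truth_labels)
}

# externally supplied differential-gene list scattered across all modules in
# the proportions reported for the reference cohort's DESeq2 screen
scattered_de_list <- function(truth_labels, seed) {
  frac <- c(core1 = 0.117, bridge1 = 0.215, bridge2 = 0.162,
            core2 = 0.182, isolated = 0.153)
  set.seed(seed)
  unlist(lapply(names(frac), function(m) {
    ids <- names(truth_labels)[truth_labels == m]
    sample(ids, round(frac[[m]] * length(ids)))
  }), use.names = FALSE)
}
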