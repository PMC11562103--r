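#' Patient correlation network from a TF subset
#'
#' Spearman correlations between samples, computed over the expression of a
#' given TF subset, thresholded into a binary patient adjacency matrix.
#' Spearman is used because expression levels are heavy-tailed, making rank
#' correlation the robust choice for patient similarity.
#'
#' @param x Genes x samples expression matrix.
#' @param tf_subset Gene IDs (or row indices) defining the subset;
#'   at least 3.
#' @param cutoff Correlation threshold in (0, 1), boundary inclusive.
#' @return Binary patient adjacency matrix (zero diagonal), attribute
#'   `cutoff`.
#' @export
patient_network <- function(x, tf_subset, cutoff) {
  if (is.character(tf_subset)) {
    missing_ids <- setdiff(tf_subset, rownames(x))
    if (length(missing_ids))
      stop("TF subset IDs absent from the matrix: ",
           paste(utils::head(missing_ids, 10), collapse = ", "))
  }
  sub <- x[tf_subset, , drop = FALSE]
  if (nrow(sub) < 3) stop("TF subset must contain at least 3 genes")
  cc <- correlation_matrix(sub, method = "spearman", axis = "samples")
  adjacency_from_correlation(cc, cutoff)
}

#' Group-separation score of a patient network
#'
#' Edge density within the reference group minus the cross-density between
#' the two groups (the within-minus-cross difference evaluated on the raw
#' adjacency matrix, i.e. at overlap order zero the neighborhoods are not
#' consulted). Positive values mean the reference group is more tightly
#' interconnected than it is connected to the other group. The score is
#' asymmetric; `reference` names the group whose internal density anchors
#' it.
#'
#' @param a Binary patient adjacency matrix.
#' @param groups Group label per patient (named by sample ID, or in column
#'   order of `a`); exactly 2 distinct labels, each group of size >= 2.
#' @param reference Label of the reference group (default `"4"`).
#' @param symmetric If `TRUE`, use the mean of both within-group densities
#'   minus the cross-density instead.
#' @return Scalar separation score.
#' @export
separation_score <- function(a, groups, reference = "4", symmetric = FALSE) {
  if (!is.null(names(groups)) && !is.null(rownames(a)))
    groups <- groups[rownames(a)]
  if (length(groups) != nrow(a)) stop("group labels do not match the network")
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two patient groups required")
  if (!reference %in% lev) stop("reference group not present")
  other <- setdiff(lev, reference)
  ia <- which(groups == reference)
  ib <- which(groups == other)
  if (length(ia) < 2 || length(ib) < 2) stop("both groups need at least 2 patients")
  if (!symmetric) return(gtom_diff(a, ia, ib))
  within <- (gtom_score(a, ia, ia) + gtom_score(a, ib, ib)) / 2
  within - gtom_score(a, ia, ib)
}

#' Separation as a function of the patient-correlation cutoff
#'
#' Evaluates [separation_score()] on the patient network of a TF subset
#' for each cutoff in a grid. The Spearman correlations are computed once;
#' only the thresholding varies.
#'
#' @inheritParams patient_network
#' @param groups Group label per sample.
#' @param cutoffs Increasing cutoff grid (default 0.50 to 0.95 by 0.01).
#' @param subset_name Label stored with the curve.
#' @param reference,symmetric Passed to [separation_score()].
#' @return `data.frame` of class `separation_curve` with columns `subset`,
#'   `cutoff`, `separation` (NA where a group has no within-pairs, which
#'   cannot occur for groups of size >= 2 but is kept for safety).
#' @export
separation_curve <- function(x, tf_subset, groups,
                             cutoffs = seq(0.50, 0.95, by = 0.01),
                             subset_name = "subset",
                             reference = "4", symmetric = FALSE) {
  if (is.unsorted(cutoffs, strictly = TRUE)) stop("cutoffs must be strictly increasing")
  sub <- x[tf_subset, , drop = FALSE]
  if (nrow(sub) < 3) stop("TF subset must contain at least 3 genes")
  cc <- correlation_matrix(sub, method = "spearman", axis = "samples")
  sep <- vapply(cutoffs, function(cut) {
    a <- adjacency_from_correlation(cc, cut)
    tryCatch(separation_score(a, groups, reference, symmetric),
             error = function(e) NA_real_)
  }, numeric(1))
  out <- data.frame(subset = subset_name, cutoff = cutoffs, separation = sep,
                    stringsAsFactors = FALSE)
  class(out) <- c("separation_curve", class(out))
  out
}

#' Q3 expression filter
#'
#' Retains genes whose median expression across samples exceeds the
#' empirical 25th percentile of the per-gene medians (linear-interpolation
#' quantile, boundary exclusive) — i.e. removes the bottom quarter of
#' genes by median expression.
#'
#' @param x Genes x samples expression matrix with at least 4 genes.
#' @return Character vector of retained gene IDs.
#' @export
q3_filter <- function(x) {
  if (nrow(x) < 4) stop("need at least 4 genes")
  med <- apply(x, 1, stats::median)
  q25 <- stats::quantile(med, 0.25, type = 7, names = FALSE)
  keep <- med > q25
  if (!any(med != med[1])) {
    warning("all per-gene medians are equal; retaining every gene")
    keep <- rep(TRUE, nrow(x))
  }
  rownames(x)[keep]
}

#' Differentially expressed TF subset (two-group screen)
#'
#' Per-gene Welch two-sample t-test on `log1p` expression between the two
#' patient groups, Benjamini-Hochberg adjustment, keeping genes with
#' adjusted p below `alpha`. A pre-computed external gene list (e.g. from a
#' dedicated differential-expression tool) can be passed through verbatim
#' via `external`.
#'
#' @param x Genes x samples expression matrix.
#' @param groups Group label per sample (2 levels, each of size >= 2).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param external Optional character vector of gene IDs returned as-is
#'   (intersected with the matrix rows).
#' @return Character vector of selected gene IDs.
#' @export
de_subset <- function(x, groups, alpha = 0.01, external = NULL) {
  if (!is.null(external)) return(intersect(external, rownames(x)))
  if (!is.null(names(groups)) && !is.null(colnames(x)))
    groups <- groups[colnames(x)]
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  i1 <- which(groups == lev[1]); i2 <- which(groups == lev[2])
  if (length(i1) < 2 || length(i2) < 2) stop("both groups need at least 2 samples")
  lx <- log1p(x)
  m1 <- rowMeans(lx[, i1, drop = FALSE]); m2 <- rowMeans(lx[, i2, drop = FALSE])
  v1 <- apply(lx[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(lx[, i2, drop = FALSE], 1, stats::var)
  n1 <- length(i1); n2 <- length(i2)
  se2 <- v1 / n1 + v2 / n2
  degenerate <- se2 <= 0
  if (any(degenerate))
    warning(sum(degenerate), " gene(s) with zero variance in both groups excluded")
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate] <- NA
  padj <- stats::p.adjust(p, method = "BH")
  rownames(x)[!is.na(padj) & padj < alpha]
}
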