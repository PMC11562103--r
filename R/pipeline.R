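#' Configuration of a full network-analysis run
#'
#' Collects every tunable of the pipeline with the defaults used throughout
#' the package: correlation cutoff 0.7, GTOM order 2, five clusters, Ward
#' linkage, patient cutoffs 0.50-0.95.
#'
#' @param input Path to a gene-by-sample TSV, or an in-memory expression
#'   matrix.
#' @param unit Expression unit of the input.
#' @param tf_list Optional TF ID vector or file path; when given, the
#'   matrix is restricted to it before denoising.
#' @param convert_to_tpm Apply [convert_log2fpkm_to_tpm()] first (for
#'   log2(1+FPKM) inputs).
#' @param log1p Apply `log1p` before gene-gene correlation (off by
#'   default: correlations are taken on the expression scale).
#' @param recode Apply RECODE denoising.
#' @param ell Optional fixed RECODE dimension (default: elbow selection).
#' @param cutoff TF-TF correlation cutoff.
#' @param k GTOM order.
#' @param n_clusters Number of TF modules.
#' @param linkage `"ward"` or `"average"`.
#' @param patient_cutoffs Cutoff grid for patient separation curves.
#' @param groups Optional named group label per sample (needed for
#'   separation curves).
#' @param clinical Optional clinical attribute `data.frame`.
#' @param seed Seed recorded in the manifest (the deterministic stages do
#'   not consume randomness).
#' @param output_dir Where [run_full_pipeline()] writes its artifacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(input, unit = "arbitrary", tf_list = NULL,
                       convert_to_tpm = FALSE, log1p = FALSE,
                       recode = TRUE, ell = NULL,
                       cutoff = 0.7, k = 2, n_clusters = 5,
                       linkage = "ward",
                       patient_cutoffs = seq(0.50, 0.95, by = 0.01),
                       groups = NULL, clinical = NULL,
                       seed = 1, output_dir = NULL) {
  structure(list(input = input, unit = unit, tf_list = tf_list,
                 convert_to_tpm = convert_to_tpm, log1p = log1p,
                 recode = recode, ell = ell, cutoff = cutoff, k = k,
                 n_clusters = n_clusters, linkage = linkage,
                 patient_cutoffs = patient_cutoffs, groups = groups,
                 clinical = clinical, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full coexpression-network pipeline
#'
#' Executes, in order: read input, optional unit conversion, TF
#' restriction, optional RECODE denoising, TF Pearson correlation,
#' thresholded adjacency, GTOM(k), hierarchical module detection,
#' pairwise-cluster scores and total score, and (when sample groups are
#' supplied) per-module patient Spearman networks with separation curves.
#' When `cfg$output_dir` is set, every table and matrix is written there
#' together with a JSON manifest echoing the resolved configuration.
#'
#' @param cfg A [run_config()].
#' @return List of class `pipeline_result` with elements `expression`
#'   (post-processing matrix), `recode_ell`, `correlation`, `adjacency`,
#'   `gtom`, `partition`, `cluster_scores`, `total_score`, `size_sd`,
#'   `separation` (list of curves, or NULL), and `config`.
#' @export
run_full_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  x <- .stage("read", {
    if (is.character(cfg$input)) read_expression(cfg$input, unit = cfg$unit)
    else expression_matrix(as.matrix(cfg$input), unit = cfg$unit)
  })
  if (cfg$convert_to_tpm) x <- .stage("convert", convert_log2fpkm_to_tpm(x))
  if (!is.null(cfg$tf_list)) x <- .stage("restrict", restrict_to_tf_list(x, cfg$tf_list))
  ell_used <- NULL
  if (cfg$recode) {
    res <- .stage("recode", apply_recode(x, ell = cfg$ell, return_details = TRUE))
    x <- res$x
    ell_used <- res$ell
  }
  xc <- if (cfg$log1p) log1p(pmax(x, 0)) else x
  cc <- .stage("correlation", correlation_matrix(xc, "pearson", "genes"))
  a <- .stage("adjacency", adjacency_from_correlation(cc, cfg$cutoff))
  t <- .stage("gtom", gtom(a, cfg$k))
  part <- .stage("cluster", cluster_gtom(t, cfg$n_clusters, cfg$linkage))
  g <- .stage("scores", cluster_gtom_scores(t, part$labels))
  s <- total_score(g, part$ratios)

  separation <- NULL
  if (!is.null(cfg$groups)) {
    separation <- .stage("separate", {
      lapply(stats::setNames(nm = part$canonical_order), function(cl) {
        ids <- names(part$labels)[part$labels == cl]
        if (length(ids) < 3) return(NULL)
        separation_curve(x, ids, cfg$groups, cfg$patient_cutoffs,
                         subset_name = cl)
      })
    })
  }

  out <- list(expression = x, recode_ell = ell_used, correlation = cc,
              adjacency = a, gtom = t, partition = part,
              cluster_scores = g, total_score = s,
              size_sd = .size_sd(part$sizes),
              separation = separation, config = cfg)
  class(out) <- "pipeline_result"
  if (!is.null(cfg$output_dir)) .write_pipeline_outputs(out, cfg$output_dir)
  out
}

.write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  part <- res$partition
  utils::write.csv(data.frame(gene_id = names(part$labels), cluster = part$labels),
                   file.path(dir, "clusters.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$cluster_scores),
                   file.path(dir, "cluster_gtom_scores.csv"))
  write_graphml(res$adjacency, file.path(dir, "tf_network.graphml"),
                node_attrs = data.frame(cluster = part$labels))
  if (!is.null(res$separation)) {
    curves <- do.call(rbind, res$separation[!vapply(res$separation, is.null, logical(1))])
    utils::write.csv(curves, file.path(dir, "separation_curves.csv"), row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("gtomnet")),
    config = cfg[setdiff(names(cfg), c("clinical", "groups", "input"))],
    input = if (is.character(cfg$input)) cfg$input else "in-memory matrix",
    recode_ell = res$recode_ell,
    total_score = res$total_score,
    size_sd = res$size_sd,
    cluster_sizes = as.list(part$sizes))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("gtomnet pipeline result\n")
  cat("  genes x samples:", nrow(x$expression), "x", ncol(x$expression), "\n")
  if (!is.null(x$recode_ell)) cat("  RECODE ell:", x$recode_ell, "\n")
  cat("  cutoff:", x$config$cutoff, " GTOM order:", x$config$k, "\n")
  cat("  clusters:", paste(sprintf("%s=%d", names(x$partition$sizes),
                                   x$partition$sizes), collapse = ", "), "\n")
  cat("  total score:", signif(x$total_score, 4),
      " size SD:", signif(x$size_sd, 4), "\n")
  invisible(x)
}
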