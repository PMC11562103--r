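#' Default planted-module layout
#'
#' Five transcription-factor modules whose relative sizes follow the
#' cluster-size proportions observed in the neuroblastoma TF network that
#' motivates the package: two strongly intra-correlated cores, two weakly
#' intra-correlated bridge modules each coupled to a core, and a pool of
#' essentially uncorrelated TFs.
#'
#' @param n_tfs Total number of TFs; module sizes are scaled proportionally
#'   (remainder absorbed by the isolated pool).
#' @return A `data.frame` with columns `module_id`, `size`,
#'   `role` (`core`/`bridge`/`isolated`) and `attached_core`.
#' @export
default_module_layout <- function(n_tfs = 1500) {
  prop <- c(core1 = 556, bridge1 = 298, bridge2 = 68, core2 = 209, isolated = 400) / 1531
  sizes <- floor(prop * n_tfs)
  sizes["isolated"] <- n_tfs - sum(sizes[names(sizes) != "isolated"])
  data.frame(
    module_id = names(sizes),
    size = as.integer(sizes),
    role = c("core", "bridge", "bridge", "core", "isolated"),
    attached_core = c(NA, "core1", "core1", NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic planted-module expression study
#'
#' Defines a latent-factor Gaussian model with block-correlated TF modules
#' and two patient groups (majority "4", minority "4S") that differ only
#' through designated modules. Defaults emulate the shape of a 148-tumor
#' cohort: 127 vs 21 samples and roughly 1,500 TFs.
#'
#' Each TF carries a baseline level, a loading on its module's latent factor
#' (bridge TFs additionally load on the attached core's factor), an
#' idiosyncratic residual, and optional isotropic measurement noise of
#' standard deviation `noise_sd`. For modules named in
#' `differential_modules` the coupling to the module differs between the
#' groups: minority-group samples receive a per-TF offset
#' `effect_size * loading_j * w_j`, where `w_j` is a fixed heterogeneous
#' response (random sign, magnitude uniform on 0.3-1.7) drawn once per TF.
#' Genes more strongly coupled to the module thus respond more, in
#' gene-specific directions, which is what creates a detectable mean
#' difference per gene and a group-specific expression profile for the
#' minority samples.
#'
#' @param n_tfs Number of TFs.
#' @param n_samples_major,n_samples_minor Group sizes (stage-4 / stage-4S analogs).
#' @param module_layout Layout data frame, see [default_module_layout()].
#' @param within_module_corr Named vector of target within-module Pearson
#'   correlations per role (`core`, `bridge`, `isolated`).
#' @param bridge_to_core_corr Target correlation between a bridge TF and the
#'   TFs of its attached core.
#' @param differential_modules Module IDs whose group coupling differs.
#' @param effect_size Scale of the minority-group coupling offset, in units
#'   of the module loading (0 disables the group difference).
#' @param noise_sd Isotropic measurement-noise standard deviation. The
#'   default 0 gives the noise-free study conditions; 0.5 is the package's
#'   reference stress calibration for the denoising studies (it pushes the
#'   observed within-core correlations below the 0.7 network cutoff, which
#'   is the regime where denoising matters).
#' @param baseline_mean Named vector of baseline expression means per role;
#'   the isolated pool sits lower, mimicking low-expression TFs.
#' @param baseline_sd Standard deviation of per-TF baseline levels; this
#'   spread is what makes between-patient expression profiles correlated.
#' @param loading_jitter Half-width of the uniform per-TF loading multiplier
#'   (loadings vary in `1 +/- loading_jitter`).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_tfs = 1500,
                           n_samples_major = 127,
                           n_samples_minor = 21,
                           module_layout = default_module_layout(n_tfs),
                           within_module_corr = c(core = 0.78, bridge = 0.66, isolated = 0.05),
                           bridge_to_core_corr = 0.45,
                           differential_modules = c("bridge1", "isolated"),
                           effect_size = 1.25,
                           noise_sd = 0,
                           baseline_mean = c(core = 6, bridge = 6, isolated = 3),
                           baseline_sd = 2,
                           loading_jitter = 0.15,
                           seed = 1) {
  stopifnot(n_tfs >= 1, n_samples_major >= 1, n_samples_minor >= 1,
            effect_size >= 0, noise_sd >= 0, baseline_sd >= 0,
            loading_jitter >= 0, loading_jitter < 1)
  req <- c("module_id", "size", "role", "attached_core")
  if (!all(req %in% names(module_layout))) stop("module_layout lacks required columns")
  if (sum(module_layout$size) != n_tfs)
    stop("module sizes sum to ", sum(module_layout$size), ", expected n_tfs = ", n_tfs)
  if (!all(module_layout$role %in% c("core", "bridge", "isolated")))
    stop("module roles must be core, bridge or isolated")
  bad <- module_layout$role == "bridge" &
    !(module_layout$attached_core %in% module_layout$module_id[module_layout$role == "core"])
  if (any(bad)) stop("bridge module(s) without a valid attached core")
  if (!all(c("core", "bridge", "isolated") %in% names(within_module_corr)))
    stop("within_module_corr must name core, bridge and isolated")
  if (any(within_module_corr <= 0 | within_module_corr >= 1))
    stop("within_module_corr values must lie in (0,1)")
  if (within_module_corr["core"] <= within_module_corr["bridge"])
    stop("cores must be more strongly intra-correlated than bridges")
  if (bridge_to_core_corr <= 0 || bridge_to_core_corr >= 1)
    stop("bridge_to_core_corr must lie in (0,1)")
  if (bridge_to_core_corr^2 >= within_module_corr["bridge"] * within_module_corr["core"])
    stop("bridge_to_core_corr too large for the requested within-module correlations")
  unknown <- setdiff(differential_modules, module_layout$module_id)
  if (length(unknown)) stop("unknown differential module(s): ", paste(unknown, collapse = ", "))
  structure(list(
    n_tfs = n_tfs, n_samples_major = n_samples_major,
    n_samples_minor = n_samples_minor, module_layout = module_layout,
    within_module_corr = within_module_corr,
    bridge_to_core_corr = bridge_to_core_corr,
    differential_modules = differential_modules, effect_size = effect_size,
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, loading_jitter = loading_jitter,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Per-module substream seed: changing one module's size leaves the draws of
# every other module untouched.
.substream_seed <- function(seed, i, phase) {
  (as.double(seed) * 97 + i * 10007 + phase * 524287) %% 2147483629
}

#' Generate a planted-module expression matrix with ground truth
#'
#' Draws the latent-factor model described in [synthetic_spec()]: module
#' factors across samples, per-TF loadings and baselines, idiosyncratic
#' residuals, and isotropic measurement noise. The matrix is shifted by a
#' single affine constant so all values are non-negative (TPM-like);
#' correlations are unaffected.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with `expression` (genes x samples matrix) and `truth`
#'   (list: `tf_module_labels`, `patient_group_labels`, `latent_factors`).
#' @export
generate_planted_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lay <- spec$module_layout
  n <- spec$n_samples_major + spec$n_samples_minor
  d <- spec$n_tfs
  groups <- c(rep("4", spec$n_samples_major), rep("4S", spec$n_samples_minor))
  sample_ids <- sprintf("P%03d", seq_len(n))
  names(groups) <- sample_ids

  rho <- spec$within_module_corr
  rho_core_of <- function(id) rho[["core"]]

  # module latent factors, each in its own substream
  factors <- matrix(0, nrow(lay), n, dimnames = list(lay$module_id, sample_ids))
  for (i in seq_len(nrow(lay))) {
    set.seed(.substream_seed(spec$seed, i, 1))
    factors[i, ] <- stats::rnorm(n)
  }

  x <- matrix(0, d, n)
  gene_ids <- character(d)
  labels <- character(d)
  response <- numeric(d)
  row0 <- 0
  for (i in seq_len(nrow(lay))) {
    m <- lay$size[i]
    role <- lay$role[i]
    rows <- row0 + seq_len(m)
    row0 <- row0 + m
    gene_ids[rows] <- sprintf("TF_%s_%03d", lay$module_id[i], seq_len(m))
    labels[rows] <- lay$module_id[i]

    set.seed(.substream_seed(spec$seed, i, 2))
    u <- stats::runif(m, 1 - spec$loading_jitter, 1 + spec$loading_jitter)
    mu <- stats::rnorm(m, spec$baseline_mean[[role]], spec$baseline_sd)

    if (role == "bridge") {
      beta <- spec$bridge_to_core_corr / sqrt(rho_core_of(lay$attached_core[i]))
      alpha <- sqrt(rho[["bridge"]] - beta^2)
      signal_var <- rho[["bridge"]]
      f_own <- factors[lay$module_id[i], ]
      f_att <- factors[lay$attached_core[i], ]
      block <- outer(u * alpha, f_own) + outer(u * beta, f_att)
    } else {
      r <- rho[[role]]
      signal_var <- r
      block <- outer(u * sqrt(r), factors[lay$module_id[i], ])
    }
    if (lay$module_id[i] %in% spec$differential_modules && spec$effect_size > 0) {
      set.seed(.substream_seed(spec$seed, i, 3))
      w <- sample(c(-1, 1), m, replace = TRUE) * stats::runif(m, 0.3, 1.7)
      resp <- spec$effect_size * u * sqrt(signal_var) * w
      response[rows] <- resp
      block[, groups == "4S"] <- block[, groups == "4S"] + resp
    }
    set.seed(.substream_seed(spec$seed, i, 4))
    idio_sd <- sqrt(1 - signal_var)
    block <- block + matrix(stats::rnorm(m * n, sd = idio_sd), m, n)
    if (spec$noise_sd > 0)
      block <- block + matrix(stats::rnorm(m * n, sd = spec$noise_sd), m, n)
    x[rows, ] <- block + mu
  }

  lo <- min(x)
  if (lo < 0) x <- x - lo  # affine shift preserves all correlations
  dimnames(x) <- list(gene_ids, sample_ids)
  names(labels) <- gene_ids
  names(response) <- gene_ids
  list(
    expression = expression_matrix(x, unit = "arbitrary"),
    truth = list(tf_module_labels = labels,
                 patient_group_labels = groups,
                 latent_factors = factors,
                 differential_response = response)
  )
}

#' Write a synthetic study to disk
#'
#' Expression as gene-by-sample TSV, ground truth as a CSV sidecar, and the
#' generating specification as JSON.
#'
#' @param sim Result of [generate_planted_expression()].
#' @param spec The generating `synthetic_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_study <- function(sim, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_expr <- file.path(dir, "expression.tsv")
  p_truth <- file.path(dir, "truth.csv")
  p_spec <- file.path(dir, "spec.json")
  write_expression(sim$expression, p_expr)
  truth_df <- data.frame(
    id = c(names(sim$truth$tf_module_labels), names(sim$truth$patient_group_labels)),
    kind = c(rep("tf", length(sim$truth$tf_module_labels)),
             rep("sample", length(sim$truth$patient_group_labels))),
    label = c(unname(sim$truth$tf_module_labels), unname(sim$truth$patient_group_labels))
  )
  utils::write.csv(truth_df, p_truth, row.names = FALSE)
  sp <- unclass(spec)
  sp$module_layout <- as.data.frame(sp$module_layout)
  jsonlite::write_json(sp, p_spec, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(expression = p_expr, truth = p_truth, spec = p_spec))
}

#' Generate an exactly low-rank noiseless expression matrix
#'
#' Fixture generator for denoising identity tests: the returned matrix has a
#' sample covariance of exactly the requested rank (its centered part is a
#' product of a `d x rank` loading matrix and a `rank x n` centered factor
#' matrix).
#'
#' @param d,n Genes and samples.
#' @param rank Requested covariance rank; must satisfy
#'   `1 <= rank <= min(n - 1, d)`.
#' @param seed Integer seed.
#' @return Expression matrix (non-negative, arbitrary units).
#' @export
generate_lowrank_noiseless <- function(d, n, rank, seed = 1) {
  stopifnot(d >= 1, n >= 2)
  if (rank < 1 || rank > min(n - 1, d))
    stop("rank must lie in [1, min(n - 1, d)] = [1, ", min(n - 1, d), "]")
  set.seed(as.integer(seed))
  a <- matrix(stats::rnorm(d * rank), d, rank)
  f <- matrix(stats::rnorm(rank * n), rank, n)
  f <- f - rowMeans(f)
  x <- a %*% f
  x <- x - min(x)
  dimnames(x) <- list(paste0("g", seq_len(d)), paste0("s", seq_len(n)))
  expression_matrix(x, unit = "arbitrary")
}
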