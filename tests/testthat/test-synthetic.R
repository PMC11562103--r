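test_that("synthetic_spec validates its invariants", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  lay <- default_module_layout(1500)
  expect_equal(sum(lay$size), 1500)
  # size mismatch
  bad <- lay; bad$size[1] <- bad$size[1] + 1
  expect_error(synthetic_spec(module_layout = bad), "sum")
  # cores must beat bridges
  expect_error(synthetic_spec(
    within_module_corr = c(core = 0.5, bridge = 0.6, isolated = 0.05)),
    "strongly")
  # bridge without a core to attach to
  lonely <- data.frame(module_id = c("b", "i"), size = c(750, 750),
                       role = c("bridge", "isolated"),
                       attached_core = c(NA, NA))
  expect_error(synthetic_spec(module_layout = lonely), "attached")
  expect_error(synthetic_spec(bridge_to_core_corr = 0.9), "too large")
})

test_that("generation is deterministic and labels cover everything", {
  sp <- synthetic_spec(n_tfs = 200, n_samples_major = 30, n_samples_minor = 10,
                       module_layout = default_module_layout(200), seed = 7)
  s1 <- generate_planted_expression(sp)
  s2 <- generate_planted_expression(sp)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$truth, s2$truth)
  expect_equal(length(s1$truth$tf_module_labels), 200)
  expect_equal(unname(table(s1$truth$patient_group_labels)[c("4", "4S")]),
               c(30L, 10L), ignore_attr = TRUE)
  expect_setequal(names(s1$truth$tf_module_labels), rownames(s1$expression))
  expect_true(all(s1$expression >= 0))
})

test_that("noiseless single-factor module gives |r| = 1 and corr matches target", {
  # one core of 12 TFs, no idiosyncratic noise possible only in the limit;
  # instead check the planted-correlation closed form empirically:
  # r_ij ~ within_module_corr for a core at n large, over replicates
  target <- 0.8
  est <- vapply(1:20, function(s) {
    lay <- data.frame(module_id = c("core1", "isolated"), size = c(40, 10),
                      role = c("core", "isolated"), attached_core = NA)
    sp <- synthetic_spec(n_tfs = 50, n_samples_major = 120, n_samples_minor = 30,
                         module_layout = lay,
                         within_module_corr = c(core = target, bridge = 0.5,
                                                isolated = 0.05),
                         differential_modules = character(0),
                         loading_jitter = 0.15, seed = s)
    sim <- generate_planted_expression(sp)
    cc <- correlation_matrix(sim$expression, "pearson", "genes")
    i <- which(sim$truth$tf_module_labels == "core1")
    mean(cc[i, i][upper.tri(cc[i, i])])
  }, numeric(1))
  expect_lt(abs(mean(est) - target), 0.05)
})

test_that("within-module correlations exceed between-module correlations", {
  diffs <- vapply(1:10, function(s) {
    sim <- small_planted(seed = s)
    cc <- correlation_matrix(sim$expression, "pearson", "genes")
    tr <- sim$truth$tf_module_labels
    mods <- c("core1", "core2", "bridge1", "bridge2")
    within <- mean(vapply(mods, function(m) {
      i <- which(tr == m); mean(cc[i, i][upper.tri(cc[i, i])])
    }, numeric(1)))
    between <- mean(cc[tr == "core1", tr == "core2"])
    within - between
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("group mean differences exist only in differential modules", {
  # Only bridge1 differential; the isolated pool (near-zero loadings, hence
  # effectively independent genes) is the clean null for the uniformity
  # check. Genes of a non-differential core share a latent factor, so their
  # per-replicate p-values are mutually dependent; their null behaviour is
  # asserted through the rejection rate instead.
  sim <- small_planted(seed = 3, differential_modules = "bridge1")
  x <- sim$expression
  gr <- sim$truth$patient_group_labels
  tr <- sim$truth$tf_module_labels
  p <- apply(x, 1, function(v) stats::t.test(v[gr == "4"], v[gr == "4S"])$p.value)
  expect_gt(stats::ks.test(p[tr == "isolated"], "punif")$p.value, 0.05)
  rates <- vapply(4:9, function(s) {
    simb <- small_planted(seed = s, differential_modules = "bridge1")
    xb <- simb$expression
    gb <- simb$truth$patient_group_labels
    tb <- simb$truth$tf_module_labels
    null_rows <- names(tb)[!(tb %in% "bridge1")]
    pb <- apply(xb[null_rows, ], 1, function(v)
      stats::t.test(v[gb == "4"], v[gb == "4S"])$p.value)
    mean(pb < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.05)
  # differential module: strong signal in many genes
  expect_gt(mean(p[tr == "bridge1"] < 0.01), 0.5)
})

test_that("low-rank generator enforces its rank contract", {
  lr <- generate_lowrank_noiseless(2, 3, 1, seed = 1)
  # the two gene rows are affinely dependent
  cent <- lr - rowMeans(lr)
  expect_lt(abs(abs(cor(cent[1, ], cent[2, ])) - 1), 1e-10)

  ev <- pca_decompose(generate_lowrank_noiseless(10, 8, 3, seed = 5))$eigenvalues
  expect_equal(sum(ev > 1e-10 * ev[1]), 3)
  expect_error(generate_lowrank_noiseless(10, 8, 0), "rank")
  expect_error(generate_lowrank_noiseless(10, 8, 8), "rank")
})

test_that("a synthetic study round-trips through disk", {
  dir <- withr::local_tempdir()
  sim <- small_planted(seed = 2)
  spec <- synthetic_spec(n_tfs = 300, n_samples_major = 45, n_samples_minor = 15,
                         module_layout = default_module_layout(300), seed = 2)
  paths <- write_synthetic_study(sim, spec, dir)
  back <- read_expression(paths[["expression"]])
  expect_equal(unclass(back), unclass(sim$expression), ignore_attr = TRUE,
               tolerance = 1e-12)
  truth <- read.csv(paths[["truth"]])
  expect_equal(sum(truth$kind == "tf"), 300)
  cfg <- jsonlite::read_json(paths[["spec"]])
  expect_equal(cfg$seed, 2)
})
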