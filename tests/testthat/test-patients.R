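test_that("patient_network thresholds Spearman sample correlations", {
  sim <- small_planted(seed = 1)
  x <- sim$expression
  # two identical patients correlate at any cutoff below 1
  x2 <- cbind(x, dup = x[, 1])
  colnames(x2) <- c(colnames(x), "dup")
  a <- patient_network(x2, rownames(x2)[1:50], 0.99)
  expect_equal(a[colnames(x)[1], "dup"], 1)
  expect_equal(diag(a), setNames(rep(0, ncol(x2)), colnames(x2)))
  # absurdly high cutoff: empty graph
  ahi <- patient_network(x, rownames(x)[1:50], 0.9999)
  expect_equal(sum(ahi), 0)
  expect_error(patient_network(x, c("TF_nope_1", rownames(x)[1:3]), 0.8), "absent")
  expect_error(patient_network(x, rownames(x)[1:2], 0.8), "at least 3")
})

test_that("separation_score matches hand enumeration on a 4-patient toy", {
  a <- matrix(0, 4, 4, dimnames = rep(list(paste0("p", 1:4)), 2))
  a["p1", "p2"] <- a["p2", "p1"] <- 1   # group 4 complete
  a["p2", "p3"] <- a["p3", "p2"] <- 1   # one cross edge
  gr <- c(p1 = "4", p2 = "4", p3 = "4S", p4 = "4S")
  expect_equal(separation_score(a, gr), 1 - 1 / 4)

  # disjoint complete groups: 1; complete graph overall: 0
  b <- matrix(0, 4, 4, dimnames = rep(list(paste0("p", 1:4)), 2))
  b[1:2, 1:2] <- 1; b[3:4, 3:4] <- 1; diag(b) <- 0
  expect_equal(separation_score(b, gr), 1)
  k4 <- matrix(1, 4, 4) - diag(4)
  dimnames(k4) <- dimnames(b)
  expect_equal(separation_score(k4, gr), 0)

  # relabeling patients within groups changes nothing
  perm <- c("p2", "p1", "p4", "p3")
  expect_equal(separation_score(a[perm, perm], gr), separation_score(a, gr))
  expect_error(separation_score(a, c(p1 = "4", p2 = "4", p3 = "4", p4 = "4")),
               "two patient groups")
})

test_that("separation curves: differential module dominates, null is flat", {
  cuts <- seq(0.5, 0.95, 0.05)
  res <- vapply(1:6, function(s) {
    sim <- small_planted(seed = s)
    x <- sim$expression
    tr <- sim$truth$tf_module_labels
    gr <- sim$truth$patient_group_labels
    b1 <- names(tr)[tr == "bridge1"]
    set.seed(s)
    nullset <- sample(names(tr)[tr %in% c("core1", "core2")], length(b1))
    cd <- separation_curve(x, b1, gr, cuts, subset_name = "diff")
    cn <- separation_curve(x, nullset, gr, cuts, subset_name = "null")
    c(diff = max(cd$separation, na.rm = TRUE),
      null = max(cn$separation, na.rm = TRUE))
  }, numeric(2))
  expect_gt(mean(res["diff", ]), mean(res["null", ]))
  expect_true(all(res["diff", ] > res["null", ]))

  # single cutoff equals a direct score
  sim <- small_planted(seed = 1)
  tr <- sim$truth$tf_module_labels
  b1 <- names(tr)[tr == "bridge1"]
  gr <- sim$truth$patient_group_labels
  one <- separation_curve(sim$expression, b1, gr, 0.8)
  a <- patient_network(sim$expression, b1, 0.8)
  expect_equal(one$separation, separation_score(a, gr))
  expect_error(separation_curve(sim$expression, b1, gr, c(0.8, 0.7)),
               "increasing")
})

test_that("permuted group labels give separation indistinguishable from zero", {
  sim <- small_planted(seed = 2)
  tr <- sim$truth$tf_module_labels
  b1 <- names(tr)[tr == "bridge1"]
  gr <- sim$truth$patient_group_labels
  a <- patient_network(sim$expression, b1, 0.8)
  set.seed(11)
  perms <- vapply(1:100, function(i) {
    separation_score(a, setNames(sample(gr), names(gr)))
  }, numeric(1))
  se <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms)), 2 * se + 1e-8)
})

test_that("q3_filter retains exactly the top three quarters", {
  # distinct medians 0..7 -> 25th percentile 1.75, keep 6 of 8
  x <- matrix(0:7, 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  keep <- q3_filter(x)
  expect_equal(length(keep), 6)
  expect_setequal(keep, paste0("g", 3:8))

  # all medians tied: keep everything, warn
  xt <- matrix(5, 8, 5, dimnames = dimnames(x))
  expect_warning(kt <- q3_filter(xt), "equal")
  expect_equal(length(kt), 8)

  # constructed low-expression quarter is exactly what gets removed
  sim <- small_planted(seed = 3)
  x2 <- sim$expression
  low <- paste0("low", 1:100)
  xl <- rbind(x2, matrix(0.01 * runif(100 * ncol(x2)), 100, ncol(x2),
                         dimnames = list(low, colnames(x2))))
  kept <- q3_filter(xl)
  expect_true(!any(low %in% kept))
  expect_equal(length(kept), 300)
})

test_that("de_subset is calibrated under the null and finds planted signal", {
  # no differential modules: BH keeps the discovery fraction near alpha
  fdr_ok <- vapply(1:10, function(s) {
    sim <- small_planted(seed = s, differential_modules = character(0))
    hits <- de_subset(sim$expression, sim$truth$patient_group_labels, alpha = 0.05)
    length(hits) / nrow(sim$expression)
  }, numeric(1))
  expect_lte(mean(fdr_ok), 1.5 * 0.05)

  # strongly differential core module: subset covers >= 80% of it
  lay <- data.frame(module_id = c("core1", "isolated"), size = c(60, 140),
                    role = c("core", "isolated"), attached_core = NA)
  cover <- vapply(1:6, function(s) {
    sp <- synthetic_spec(n_tfs = 200, n_samples_major = 100, n_samples_minor = 20,
                         module_layout = lay,
                         differential_modules = "core1", effect_size = 3,
                         seed = s)
    sim <- generate_planted_expression(sp)
    hits <- de_subset(sim$expression, sim$truth$patient_group_labels, alpha = 0.01)
    tr <- sim$truth$tf_module_labels
    mean(names(tr)[tr == "core1"] %in% hits)
  }, numeric(1))
  expect_gte(mean(cover), 0.8)

  # alpha 0: empty; external list passes through verbatim
  sim <- small_planted(seed = 1)
  expect_length(de_subset(sim$expression, sim$truth$patient_group_labels,
                          alpha = 0), 0)
  ext <- rownames(sim$expression)[5:9]
  expect_equal(de_subset(sim$expression, NULL, external = c(ext, "NOPE")), ext)
})
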