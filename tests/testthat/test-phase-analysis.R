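test_that("sample correlations are symmetric with unit diagonal", {
  set.seed(41)
  m <- matrix(rlnorm(200), 20, 10)
  colnames(m) <- paste0("T", 1:10)
  cc <- sample_correlation_matrix(m)
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 10))
  expect_true(all(cc >= -1 & cc <= 1))
  # duplicated columns correlate at 1; rank-reversed at -1
  m2 <- cbind(a = 1:10, b = 1:10, c = 10:1)
  expect_equal(sample_correlation_matrix(m2)["a", "b"], 1)
  expect_equal(sample_correlation_matrix(m2)["a", "c"], -1)
  # constant column flagged
  m3 <- cbind(a = 1:10, b = rep(2, 10))
  expect_warning(cc3 <- sample_correlation_matrix(m3), "constant")
  expect_true(is.na(cc3["a", "b"]))
})

test_that("adjacent timepoints correlate in the expected band", {
  # abundance-structured missingness, as in real filtered proteomes;
  # missing-at-random dropout scrambles low-abundance ranks and lowers
  # the adjacent correlations well below what real data shows
  tc <- simulate_timecourse(sim_config(seed = 19, n_genes = 2000,
                                       dropout_bias = TRUE))
  cc <- sample_correlation_matrix(tc$protein)
  s <- tc$protein$samples
  tpo <- tc$protein$timepoint_order
  adj <- vapply(seq_len(length(tpo) - 1L), function(i) {
    a <- which(s$timepoint == tpo[i])
    b <- which(s$timepoint == tpo[i + 1])
    mean(cc[a, b])
  }, numeric(1))
  expect_true(all(adj > 0.8 & adj < 0.99))
})

test_that("phase partitioning recovers the implanted reference blocks", {
  tc <- simulate_timecourse(sim_config(seed = 23, n_genes = 800,
                                       noise_sd = 1, phase_effect_size = 3))
  pp <- partition_phases(tc$protein, k = 3)
  expect_true(pp$stable)
  expect_identical(unname(pp$assignment[stomach_timepoints()]),
                   unname(reference_phases()[stomach_timepoints()]))
  expect_identical(mclust::adjustedRandIndex(
    pp$assignment[names(tc$truth$phase_assignment)],
    tc$truth$phase_assignment), 1)
  # replicate-averaged mode agrees
  pp2 <- partition_phases(tc$protein, k = 3, collapse = TRUE)
  expect_identical(pp2$assignment, pp$assignment)
  expect_error(partition_phases(tc$protein, k = 20), "exceeds")
})

test_that("a structureless matrix is flagged unstable", {
  set.seed(77)
  tc <- simulate_timecourse(sim_config(seed = 77, n_genes = 300,
                                       de_fraction = 0, temporal_sd = 0,
                                       dropout_rate = 0))
  pp <- partition_phases(tc$protein, k = 3)
  expect_false(pp$stable)
})

test_that("row-wise ANOVA agrees with stats::oneway.test", {
  set.seed(51)
  m <- matrix(rnorm(15 * 9), 15, 9)
  groups <- rep(c("a", "b", "c"), each = 3)
  res <- devomics:::.row_anova(m, groups)
  for (i in c(1, 7, 15)) {
    ref <- oneway.test(m[i, ] ~ groups, var.equal = TRUE)
    expect_equal(res$F[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("BH adjustment and untestable-row handling are correct", {
  tps <- stomach_timepoints()
  cols <- as.vector(outer(tps, 1:3, function(t, r) paste0(t, "_", r)))
  set.seed(52)
  m <- matrix(rlnorm(8 * 45), 8, 45, dimnames = list(sprintf("g%d", 1:8), cols))
  m[8, ] <- 5  # constant row: untestable
  qm <- quant_matrix(m, unit = "iFOT")
  de <- anova_bh(qm, reference_phases())
  expect_true(is.na(de$q[8]) && is.na(de$p[8]))
  testable <- !is.na(de$p)
  # BH step-up recomputed by hand from the reported p-values
  p <- de$p[testable]
  mm <- length(p)
  o <- order(p)
  qhand <- numeric(mm)
  qhand[o] <- rev(cummin(rev(p[o] * mm / seq_len(mm))))
  expect_equal(de$q[testable], pmin(1, qhand), tolerance = 1e-12)
  expect_true(all(de$q >= de$p, na.rm = TRUE))
  # q is monotone nondecreasing in p rank
  expect_true(all(diff(de$q[testable][o]) >= -1e-15))
})

test_that("implanted phase shifts are detected with controlled FDR", {
  tc <- simulate_timecourse(sim_config(seed = 61, n_genes = 600,
                                       de_fraction = 0.2, temporal_sd = 0,
                                       dropout_rate = 0, noise_sd = 1,
                                       phase_effect_size = 3))
  de <- anova_bh(qm_log10(tc$protein), tc$truth$phase_assignment, fdr = 0.01)
  called <- de$gene[de$significant]
  expect_gt(mean(tc$truth$de_genes %in% called), 0.9)
  expect_lt(mean(!(called %in% tc$truth$de_genes)), 0.05)
  # the phase of maximal mean matches the implanted peak
  hit <- intersect(called, tc$truth$de_genes)
  agree <- mean(de$phase[match(hit, de$gene)] == tc$truth$peak_phase[hit])
  expect_gt(agree, 0.95)
})

test_that("anova_bh validates its inputs", {
  qm <- toy_qm(rlnorm(12))
  expect_error(anova_bh(qm, c(E12.5 = "Ph1")), "missing")
  part <- c(E12.5 = "Ph1", W8 = "Ph2")
  expect_silent(anova_bh(qm, part))
  one_rep <- quant_matrix(matrix(rlnorm(4), 2,
                                 dimnames = list(c("a", "b"),
                                                 c("E12.5_1", "W8_1"))))
  expect_error(anova_bh(one_rep, part), ">= 2 samples")
})

test_that("Ward coexpression groups recover profile archetypes", {
  tps <- stomach_timepoints()
  cols <- as.vector(outer(tps, 1:3, function(t, r) paste0(t, "_", r)))
  phase_of <- reference_phases()[sub("_[^_]+$", "", cols)]
  set.seed(71)
  n_per <- 30
  arch <- c("Ph1", "Ph2", "Ph3")
  m <- do.call(rbind, lapply(arch, function(ph) {
    base <- ifelse(phase_of == ph, 6, 2)
    t(replicate(n_per, base + rnorm(length(cols), 0, 0.5)))
  }))
  m <- m - min(m) + 0.01
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  qm <- quant_matrix(m, unit = "iFOT")
  cl <- coexpress_clusters(qm, n_groups = 3)
  truthlab <- rep(1:3, each = n_per)
  expect_gte(mclust::adjustedRandIndex(cl, truthlab), 0.95)
  # groups are ordered by the development position of their peak
  expect_identical(unname(cl[1]), 1L)
  expect_identical(unname(cl[n_per * 2 + 1]), 3L)
  # duplicated rows land in the same group
  qm2 <- quant_matrix(m[c(1, 1, 31, 31, 61, 61), ], unit = "iFOT")
  cl2 <- coexpress_clusters(qm2, n_groups = 3)
  expect_identical(unname(cl2[1]), unname(cl2[2]))
  # degenerate cut: every gene its own group
  qm3 <- quant_matrix(m[1:4, ], unit = "iFOT")
  expect_identical(sort(unname(coexpress_clusters(qm3, 4))), 1:4)
  expect_error(coexpress_clusters(qm3, 10), "exceeds")
})

test_that("PCA scores match a naive eigendecomposition on a toy matrix", {
  set.seed(81)
  m <- matrix(rlnorm(20), 5, 4,
              dimnames = list(paste0("g", 1:5),
                              c("E12.5_1", "E12.5_2", "W8_1", "W8_2")))
  qm <- quant_matrix(m, unit = "iFOT")
  pp <- suppressWarnings(partition_phases(qm, k = 2))
  # oracle: z-score rows, center columns of the transpose, eigendecompose
  # the sample covariance
  zm <- t(apply(m, 1, function(r) (r - mean(r)) / sd(r)))
  x <- scale(t(zm), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(x) / (nrow(x) - 1))
  scores <- x %*% ev$vectors
  for (j in seq_len(ncol(pp$pca)))
    expect_equal(abs(unname(pp$pca[, j])), abs(unname(scores[, j])),
                 tolerance = 1e-8)
})

test_that("GMT over-representation uses the exact hypergeometric tail", {
  gmt <- list(setA = letters[1:5], setB = letters[6:15])
  universe <- letters[1:20]
  res <- enrich_gmt(letters[1:5], gmt, universe)
  # full overlap of query and setA: p = 1 / C(20, 5)
  expect_equal(res$p[res$set == "setA"], 1 / choose(20, 5))
  # zero overlap: over-representation p is ~1
  expect_gt(res$p[res$set == "setB"], 0.99)
  # query = universe = the set: no enrichment possible
  res2 <- enrich_gmt(letters[1:5], list(s = letters[1:5]), letters[1:5])
  expect_equal(res2$p, 1)
  expect_error(enrich_gmt(letters[1:3], gmt, character(0)), "empty")
  expect_error(enrich_gmt(c("zz"), gmt, letters[1:20]), "subset")
})

test_that("GMT files round-trip through the reader", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("pathX\tdesc\tg1\tg2\tg3", "pathY\tdesc\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_identical(sets$pathX, c("g1", "g2", "g3"))
  expect_identical(sets$pathY, c("g2", "g4"))
})
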