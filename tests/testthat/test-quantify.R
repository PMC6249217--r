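test_that("iBAQ divides attributed intensity by theoretical peptide count", {
  # protein with 2 observable peptides: MKAAAAAAKCCCCCCCK -> MK, AAAAAAK,
  # CCCCCCCK: counts AAAAAAK + CCCCCCCK = 2
  proteome <- c(P1 = "MKAAAAAAKCCCCCCCK")
  psms <- rbind(psm_row("AAAAAAK", "P1", 25, intensity = 1000),
                psm_row("CCCCCCCK", "P1", 25, intensity = 3000))
  ib <- compute_ibaq(psms, proteome)
  expect_identical(ib["P1", "E12.5_1"], 2000)
  # no evidence in a sample -> 0 (missing substituted with zero)
  psms2 <- rbind(psms, psm_row("AAAAAAK", "P1", 25, 500, sample = "W8_1"))
  ib2 <- compute_ibaq(psms2, proteome)
  expect_identical(ib2["P1", "W8_1"], 250)
  expect_identical(ncol(ib2), 2L)
  # shared-only evidence is excluded under the default attribution policy
  proteome3 <- c(P1 = "MKAAAAAAKCCCCCCCK", P2 = "AAAAAAKDDDDDDDK")
  psms3 <- psm_row("AAAAAAK", "P1;P2", 25, 1000)
  ib3 <- compute_ibaq(psms3, proteome3)
  expect_identical(unname(ib3[, "E12.5_1"]), c(0, 0))
  ib3b <- compute_ibaq(psms3, proteome3, shared = "all")
  expect_true(all(ib3b[, "E12.5_1"] > 0))
})

test_that("proteins without observable peptides are non-quantifiable", {
  proteome <- c(P1 = "MKAAAAAAK", P0 = "KKKK")
  psms <- rbind(psm_row("AAAAAAK", "P1", 25),
                psm_row("KK", "P0", 25))
  ib <- compute_ibaq(psms, proteome)
  expect_true(all(is.na(ib["P0", ])))
  expect_false(anyNA(ib["P1", ]))
})

test_that("iFOT scales each sample to 1e5 and preserves zeros", {
  expect_equal(compute_ifot(c(A = 3, B = 1)), c(A = 75000, B = 25000))
  expect_equal(unname(compute_ifot(c(X = 7))), 1e5)
  v <- c(A = 5, B = 0, C = 15)
  out <- compute_ifot(v)
  expect_identical(unname(out["B"]), 0)
  expect_equal(sum(out), 1e5)
  expect_error(compute_ifot(c(A = 0, B = 0)), "no positive")
  m <- cbind(s1 = c(1, 3), s2 = c(2, 0))
  rownames(m) <- c("A", "B")
  fm <- compute_ifot(m)
  expect_equal(unname(colSums(fm)), c(1e5, 1e5))
  expect_error(compute_ifot(cbind(s1 = c(1, 1), s2 = c(0, 0))),
               "no positive iBAQ")
})

test_that("high-quality filter requires a unique and two strict peptides", {
  # 1 unique (25) + 1 shared (22): both strict, unique counts -> kept
  psms <- rbind(psm_row("AAAAAAK", "P1", 25),
                psm_row("CCCCCCK", "P1;P2", 22))
  expect_true("P1" %in% filter_high_quality(psms))
  # under the stricter reading the unique peptide does not count
  expect_false("P1" %in% filter_high_quality(
    psms, strict_includes_unique = FALSE))
  # 3 strict peptides but none unique -> dropped
  psms2 <- rbind(psm_row("AAAAAAK", "P1;P2", 25),
                 psm_row("CCCCCCK", "P1;P2", 30),
                 psm_row("DDDDDDK", "P1;P2", 40))
  expect_length(filter_high_quality(psms2), 0L)
  # 1 unique below 20 + only 1 strict -> dropped
  psms3 <- rbind(psm_row("AAAAAAK", "P1", 15),
                 psm_row("CCCCCCK", "P1;P2", 21))
  expect_false("P1" %in% filter_high_quality(psms3))
  # best score per peptide sequence is what counts (repeat observations)
  psms4 <- rbind(psm_row("AAAAAAK", "P1", 15),
                 psm_row("AAAAAAK", "P1", 25, sample = "W8_1"),
                 psm_row("CCCCCCK", "P1", 21))
  expect_true("P1" %in% filter_high_quality(psms4))
})

test_that("adding evidence never removes an accession (monotonicity)", {
  set.seed(31)
  cfg <- sim_config(seed = 31, n_genes = 25, n_novel_junctions = 0)
  sim <- simulate_genome(cfg)
  p <- simulate_psm_table(sim, cfg)
  psms <- p$psms
  half <- psms[seq_len(nrow(psms) %/% 2), ]
  kept_half <- filter_high_quality(half)
  kept_full <- filter_high_quality(psms)
  expect_true(all(kept_half %in% kept_full))
})

test_that("replicate-consistency keeps 2-of-3 detections at one timepoint", {
  # g01 present in 2/3 at E12.5; g02 in 1/3 everywhere; g03 all-zero
  # column order is E12.5_1, W8_1, E12.5_2, W8_2, E12.5_3, W8_3
  qm <- toy_qm(c(5, 0, 5, 0, 0, 0,
                 7, 0, 0, 7, 0, 0,
                 0, 0, 0, 0, 0, 0))
  out <- filter_replicate_consistency(qm)
  expect_identical(rownames(out$values), "g01")
  qm4 <- quant_matrix(matrix(c(1, 1, 2, 2), 1,
                             dimnames = list("g", c("E12.5_1", "E12.5_2",
                                                    "W8_1", "W8_2"))))
  expect_warning(filter_replicate_consistency(qm4), "replicates")
})

test_that("core proteome requires detection at every timepoint", {
  tps <- stomach_timepoints()
  cols <- as.vector(outer(tps, 1:3, function(t, r) paste0(t, "_", r)))
  m <- matrix(1, 3, length(cols), dimnames = list(c("all", "m14", "one"), cols))
  m["m14", c("W8_1", "W8_2", "W8_3")] <- 0          # missing one timepoint
  m["one", ] <- 0; m["one", "E12.5_1"] <- 1         # 1 replicate only
  qm <- quant_matrix(m, unit = "iFOT")
  expect_identical(core_proteome(qm), "all")
})

test_that("simulated core accessions are recovered exactly", {
  cfg <- sim_config(seed = 12, n_genes = 40, n_novel_junctions = 0)
  sim <- simulate_genome(cfg)
  p <- simulate_psm_table(sim, cfg)
  qm <- quantify_psms(p$psms[!p$psms$is_junction, ], sim$proteome)
  core <- core_proteome(qm, min_reps = 3L)
  # every implanted ubiquitous accession that is quantifiable must be core
  quantifiable <- rownames(qm$values)
  expect_true(all(intersect(p$truth$core_accessions, quantifiable) %in% core))
})

test_that("the dataset tiers are nested and sum to 1e5 per sample", {
  cfg <- sim_config(seed = 6, n_genes = 50, n_novel_junctions = 0)
  sim <- simulate_genome(cfg)
  p <- simulate_psm_table(sim, cfg)
  ds <- build_datasets(p$psms, sim$proteome)
  expect_true(all(ds$dataset2 %in% ds$dataset1))
  expect_true(all(ds$dataset3 %in% ds$dataset2))
  expect_true(ds$counts["dataset1"] >= ds$counts["dataset2"])
  expect_true(ds$counts["dataset2"] >= ds$counts["dataset3"])
  qm <- quantify_psms(p$psms, sim$proteome, accessions = ds$dataset2)
  expect_lt(max(abs(colSums(qm$values) - 1e5)) / 1e5, 1e-9)
})
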