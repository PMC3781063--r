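test_that("panel generator is deterministic and respects its record-count contract", {
  cfg <- small_config(seed = 11)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a, b)

  expect_equal(n_variants(a$variants),
               cfg$n_background_snps + cfg$n_reference_only + cfg$n_indels + 2L)
  expect_equal(sum(a$variants$sites$class == "INDEL"), cfg$n_indels)

  # written files are byte-identical across reruns
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_panel(simulate_panel(cfg), d1)
  p2 <- write_panel(simulate_panel(cfg), d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
})

test_that("planted causal pair sits 760 bp apart, conserved/coding on the lower SNP only", {
  sim <- simulate_panel(panel_config(seed = 3))
  expect_equal(diff(sim$truth$causal_positions), 760)
  expect_equal(sim$truth$causal_positions, c(73665304, 73666064))
  conserved <- annotate_conservation(sim$variants, sim$conservation)
  i1 <- match(73665304, sim$variants$sites$pos)
  i2 <- match(73666064, sim$variants$sites$pos)
  expect_true(conserved[i1])
  expect_false(conserved[i2])
  cq <- call_consequence("chr6", 73665304, sim$variants$sites$ref[i1],
                         sim$variants$sites$alt[i1], sim$gene_model, sim$reference)
  expect_equal(cq$category, "missense")
  expect_equal(cq$protein_change, "Arg625Cys")
  cq2 <- call_consequence("chr6", 73666064, sim$variants$sites$ref[i2],
                          sim$variants$sites$alt[i2], sim$gene_model, sim$reference)
  expect_equal(cq2$category, "intronic")
})

test_that("invalid panel configurations are rejected with the violated invariant named", {
  expect_error(small_config(n_background_snps = -1), "counts")
  expect_error(small_config(background_allele_freq = 1), "background_allele_freq")
  expect_error(panel_config(region = genomic_interval("chr6", 1, 10000),
                            flank_exclusion_5prime = 6000,
                            flank_exclusion_3prime = 6000),
               "flank exclusions")
  expect_error(small_config(causal_pair_offsets = c(1000100, 1000200)),
               "core")
})

test_that("background heterozygosity matches 2pq under HWE", {
  p <- 0.5
  cfg <- small_config(seed = 5, n_background_snps = 3000L,
                      background_allele_freq = p)
  sim <- simulate_panel(cfg)
  special <- c(sim$truth$causal_positions, sim$truth$flank_discordant_positions,
               sim$truth$planted_reference_only_positions)
  bg <- sim$variants$sites$class == "SNP" & !(sim$variants$sites$pos %in% special)
  g <- sim$variants$geno[bg, ]
  het <- mean(g == 1L)
  se <- sqrt(2 * p * (1 - p) * (1 - 2 * p * (1 - p)) / length(g))
  expect_lt(abs(het - 2 * p * (1 - p)), 3 * se)
})

test_that("cohort generator reproduces carrier arithmetic and the LD structure", {
  out <- simulate_cohort(cohort_config(seed = 2))
  expect_equal(nrow(out$cohort), 936)
  cs <- carrier_summary(out$cohort$locus1_dosage, out$cohort$coat_label)
  expect_equal(cs$n_carriers, 28)
  expect_equal(cs$n_noncarriers, 908)
  expect_true(complete_ld_check(out$cohort$locus1_dosage, out$cohort$locus2_dosage))
  silver <- out$cohort$coat_label == "Silver"
  expect_true(all(out$cohort$locus1_dosage[silver] >= 1))

  empty <- simulate_cohort(cohort_config(n_total = 0, n_carriers_het = 0,
                                         n_carriers_hom = 0))
  expect_equal(nrow(empty$cohort), 0)

  disc <- simulate_cohort(cohort_config(n_total = 100, n_carriers_het = 10,
                                        n_carriers_hom = 2, n_discordant = 5,
                                        seed = 9))
  expect_false(complete_ld_check(disc$cohort$locus1_dosage,
                                 disc$cohort$locus2_dosage))
  expect_error(cohort_config(n_total = 10, n_carriers_het = 8, n_carriers_hom = 3),
               "exceed")
})

test_that("depth simulation places CNVs and gaps where planted, deterministically", {
  iv <- genomic_interval("chrT", 1000001, 1010000)
  cnv <- list(interval = genomic_interval("chrT", 1002001, 1004000),
              copy_ratio = 0.5)
  tr <- simulate_depth_tracks(iv, c("c1", "c2", "u1"), mean_depths = 100,
                              planted_cnvs = list(cnv), cnv_samples = c("c1", "c2"),
                              noise_sd = 0, seed = 4)
  expect_true(all(tr$depth[, "u1"] == 100))
  in_cnv <- 2001:4000
  expect_true(all(tr$depth[in_cnv, "c1"] == 50))
  expect_true(all(tr$depth[-in_cnv, "c1"] == 100))

  tr2 <- simulate_depth_tracks(iv, "s", mean_depths = 80, noise_sd = 8, seed = 7)
  tr3 <- simulate_depth_tracks(iv, "s", mean_depths = 80, noise_sd = 8, seed = 7)
  expect_identical(tr2, tr3)
  expect_true(all(tr2$depth >= 0))

  gap <- genomic_interval("chrT", 1005001, 1005640)
  trg <- simulate_depth_tracks(iv, c("a", "b"), gaps = list(gap), seed = 1)
  expect_true(all(trg$depth[5001:5640, ] == 0))
  expect_error(simulate_depth_tracks(iv, "s", planted_cnvs = list(
    list(interval = genomic_interval("chrT", 999000, 1001000), copy_ratio = 2))),
    "outside region")
})
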