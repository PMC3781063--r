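panel_matrix <- function(rows) {
  g <- do.call(rbind, rows)
  colnames(g) <- sprintf("horse%d", 1:10)
  g
}

test_that("the worked ten-horse example leaves exactly the two concordant sites", {
  perfect <- c(rep(2L, 5), 1L, rep(0L, 4))
  g <- panel_matrix(list(
    perfect,
    c(rep(2L, 5), 1L, 0L, 1L, 0L, 0L),   # control heterozygous
    c(2L, 2L, 2L, 0L, 0L, 1L, rep(0L, 4)),# case split
    rep(0L, 10),                           # monomorphic
    rep(2L, 10),                           # reference-only pattern
    c(rep(2L, 5), 0L, rep(0L, 4)),         # intermediate not het
    perfect,
    c(rep(1L, 5), 1L, rep(0L, 4))))        # cases het
  vt <- make_vt(c(101, 205, 300, 404, 502, 608, 861, 907), g)
  out <- concordance_filter(vt, manifest_514())
  expect_equal(out$candidates$sites$pos, c(101, 861))
  expect_equal(n_variants(out$candidates) + n_variants(out$excluded), 8)

  # the violating sample is named with observed and required genotype
  aud <- out$audit[out$audit$pos == 205, ]
  expect_equal(aud$sample, "horse8")
  expect_equal(aud$observed, "0/1")
  expect_equal(aud$required, "0/0")
})

test_that("matching is orientation-agnostic", {
  flipped <- c(rep(0L, 5), 1L, rep(2L, 4))
  vt <- make_vt(1, panel_matrix(list(flipped)))
  out <- concordance_filter(vt, manifest_514())
  expect_equal(n_variants(out$candidates), 1)
})

test_that("missing genotypes follow the configured policy", {
  with_na <- c(rep(2L, 4), NA, 1L, rep(0L, 4))
  vt <- make_vt(1, panel_matrix(list(with_na)))
  strict <- concordance_filter(vt, manifest_514(),
                               concordance_policy("fail_variant"))
  expect_equal(n_variants(strict$candidates), 0)
  expect_true("horse5" %in% strict$audit$sample)
  lenient <- concordance_filter(vt, manifest_514(),
                                concordance_policy("ignore_sample"))
  expect_equal(n_variants(lenient$candidates), 1)
})

test_that("the vectorized filter agrees with a naive per-sample oracle", {
  set.seed(77)
  for (rep in 1:6) {
    n <- 300
    g <- matrix(sample(c(0:2, NA), n * 10, TRUE, prob = c(.3, .3, .3, .1)),
                n, 10, dimnames = list(NULL, sprintf("horse%d", 1:10)))
    vt <- make_vt(seq_len(n), g)
    for (pol in list(concordance_policy("fail_variant"),
                     concordance_policy("ignore_sample"),
                     concordance_policy("fail_variant",
                                        require_intermediate_het = FALSE))) {
      expect_equal(concordance_filter(vt, manifest_514(), pol,
                                      audit = FALSE)$is_candidate,
                   oracle_concordance(vt, manifest_514(), pol))
    }
  }
})

test_that("planted causal pair always survives; flank discordants never do", {
  for (seed in c(1:10, 101:115)) {
    sim <- simulate_panel(small_config(seed = seed))
    out <- concordance_filter(sim$variants, sim$manifest, audit = FALSE)
    cand <- sim$variants$sites$pos[out$is_candidate]
    expect_true(all(sim$truth$causal_positions %in% cand), label = paste("seed", seed))
    expect_equal(sort(cand), sim$truth$expected_candidates)
    expect_false(any(sim$truth$flank_discordant_positions %in% cand))
    # every extra candidate genuinely matches the pattern
    extra <- setdiff(cand, sim$truth$causal_positions)
    if (length(extra)) {
      idx <- match(extra, sim$variants$sites$pos)
      expect_true(all(oracle_concordance(sim$variants[idx], sim$manifest)))
    }
  }
})

test_that("closed-form background pass rate matches brute-force enumeration", {
  # full 10-sample panel, p = 0.5: (2pq)^1 * 2 * (1/4)^9 = 0.5^18
  expect_equal(expected_background_pass_rate(0.5, 5, 1, 4), 0.5^18)
  expect_equal(oracle_pass_rate(0.5, 5, 1, 4), 0.5^18, tolerance = 1e-12)
  # two-sample panel without intermediate
  expect_equal(expected_background_pass_rate(0.5, 1, 0, 1), 0.125)
  expect_equal(oracle_pass_rate(0.5, 1, 0, 1), 0.125, tolerance = 1e-12)
  # small asymmetric panel at p = 0.3 against enumeration
  expect_equal(expected_background_pass_rate(0.3, 2, 1, 2),
               oracle_pass_rate(0.3, 2, 1, 2), tolerance = 1e-12)
  # allele-frequency symmetry
  for (p in c(0.1, 0.25, 0.4)) {
    expect_equal(expected_background_pass_rate(p, 5, 1, 4),
                 expected_background_pass_rate(1 - p, 5, 1, 4))
  }
  expect_error(expected_background_pass_rate(0, 5, 1, 4), "inside")
  expect_error(expected_background_pass_rate(1.2, 5, 1, 4), "inside")
})

test_that("empirical pass rate of HWE sites matches the closed form within 3 SE", {
  n_sites <- 100000L
  set.seed(2024)
  run_check <- function(p, n_case, n_int, n_ctrl) {
    n <- n_case + n_int + n_ctrl
    g <- matrix(rbinom(n_sites * n, 2, p), n_sites, n,
                dimnames = list(NULL, paste0("s", seq_len(n))))
    storage.mode(g) <- "integer"
    manifest <- sample_manifest(data.frame(
      sample_id = paste0("s", seq_len(n)),
      phenotype = c(rep("case", n_case), rep("intermediate", n_int),
                    rep("control", n_ctrl)),
      breed = "X", stringsAsFactors = FALSE))
    vt <- make_vt(seq_len(n_sites), g)
    hits <- sum(concordance_filter(vt, manifest, audit = FALSE)$is_candidate)
    pr <- expected_background_pass_rate(p, n_case, n_int, n_ctrl)
    expect_lt(abs(hits - n_sites * pr), 3 * sqrt(n_sites * pr * (1 - pr)) + 1e-9)
  }
  run_check(0.5, 5, 1, 4)   # study-sized panel: expectation ~0.38 sites
  run_check(0.3, 2, 1, 2)   # denser check: expectation ~163 sites
})

test_that("haplotype boundary markers require the class-structured discordance signature", {
  m <- manifest_514()
  g5 <- c(2L, 2L, 2L, 0L, 0L, 1L, rep(0L, 4))  # Rocky Mountain cases switch
  g3 <- c(rep(2L, 5), 0L, rep(0L, 4))           # intermediate lacks the haplotype
  random_violation <- c(2L, 1L, 2L, 2L, 2L, 1L, rep(0L, 4))  # case het: no clean structure
  breed_inconsistent <- c(2L, 2L, 0L, 0L, 2L, 1L, rep(0L, 4)) # split not along breeds
  candidate <- c(rep(2L, 5), 1L, rep(0L, 4))
  vt <- make_vt(1:5, panel_matrix(list(g5, g3, random_violation,
                                       breed_inconsistent, candidate)))
  expect_equal(haplotype_boundary_markers(vt, m),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
})
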