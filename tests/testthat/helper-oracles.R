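# Independent oracles and small fixtures shared across the suite.

# Desk-sized generator settings used where the full-scale interval is not
# itself under test.
small_config <- function(seed = 1L, ...) {
  start <- 1000000L
  args <- list(region = genomic_interval("chrT", start, start + 39999L),
               causal_pair_offsets = c(start + 15000L, start + 15760L),
               flank_exclusion_5prime = 3000L, flank_exclusion_3prime = 3000L,
               n_background_snps = 60L, n_reference_only = 8L, n_indels = 12L,
               seed = seed)
  do.call(panel_config, utils::modifyList(args, list(...)))
}

make_vt <- function(pos, geno, ref = "A", alt = "T", qual = 100, depth = 1000,
                    chrom = "chrT") {
  n <- length(pos)
  variant_table(
    data.frame(chrom = chrom, pos = pos, ref = rep_len(ref, n),
               alt = rep_len(alt, n), qual = rep_len(qual, n),
               depth = rep_len(depth, n), stringsAsFactors = FALSE),
    geno)
}

manifest_514 <- function() {
  sample_manifest(data.frame(
    sample_id = sprintf("horse%d", 1:10),
    phenotype = c(rep("case", 5), "intermediate", rep("control", 4)),
    breed = c("American Miniature", "Icelandic Horse", "Icelandic Horse",
              "Rocky Mountain Horse", "Rocky Mountain Horse",
              "American Miniature", "American Miniature", "American Miniature",
              "Rocky Mountain Horse", "Rocky Mountain Horse"),
    stringsAsFactors = FALSE))
}

# Naive per-variant, per-sample re-check of the concordance pattern,
# written independently of the vectorized filter.
oracle_concordance <- function(vt, manifest, policy = concordance_policy()) {
  ph <- manifest$phenotype[match(vt_samples(vt), manifest$sample_id)]
  vapply(seq_len(n_variants(vt)), function(i) {
    g <- vt$geno[i, ]
    for (orient in list(c(case = 2L, control = 0L), c(case = 0L, control = 2L))) {
      ok <- TRUE
      for (j in seq_along(g)) {
        need <- if (ph[j] == "case") orient[["case"]]
                else if (ph[j] == "control") orient[["control"]]
                else if (policy$require_intermediate_het) 1L
                else NA_integer_
        if (is.na(need)) next
        if (is.na(g[j])) {
          if (policy$missing_genotype_handling == "fail_variant") { ok <- FALSE; break }
        } else if (g[j] != need) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }, logical(1))
}

# Brute-force pass probability: enumerate every genotype configuration of
# the panel under HWE and sum the probability of those the filter keeps.
oracle_pass_rate <- function(p, n_case, n_int, n_ctrl) {
  n <- n_case + n_int + n_ctrl
  ph <- c(rep("case", n_case), rep("intermediate", n_int), rep("control", n_ctrl))
  gp <- c((1 - p)^2, 2 * p * (1 - p), p^2)  # P(dosage = 0, 1, 2)
  configs <- as.matrix(expand.grid(rep(list(0:2), n)))
  manifest <- sample_manifest(data.frame(
    sample_id = paste0("s", seq_len(n)), phenotype = ph, breed = "X",
    stringsAsFactors = FALSE))
  storage.mode(configs) <- "integer"
  colnames(configs) <- paste0("s", seq_len(n))
  vt <- make_vt(seq_len(nrow(configs)), configs)
  keep <- concordance_filter(vt, manifest, audit = FALSE)$is_candidate
  probs <- apply(configs, 1L, function(g) prod(gp[g + 1L]))
  sum(probs[keep])
}

# Exhaustive grid search over the feasible haplotype-frequency ridge (the
# MLE keeps allele frequencies at their observed values, so the likelihood
# is maximized along the 1-D family indexed by p_AB).
grid_ld_oracle <- function(counts, n_grid = 20001L) {
  N <- sum(counts)
  pA <- sum(counts * (0:2)[row(counts)]) / (2 * N)
  pB <- sum(counts * (0:2)[col(counts)]) / (2 * N)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  p11 <- seq(lo, hi, length.out = n_grid)
  p10 <- pA - p11; p01 <- pB - p11; p00 <- 1 - pA - pB + p11
  ll <- numeric(n_grid)
  for (i in 0:2) for (j in 0:2) {
    nij <- counts[i + 1L, j + 1L]
    if (nij == 0) next
    pr <- switch(paste(i, j),
      "0 0" = p00^2, "0 1" = 2 * p00 * p01, "0 2" = p01^2,
      "1 0" = 2 * p00 * p10, "1 1" = 2 * p11 * p00 + 2 * p10 * p01,
      "1 2" = 2 * p01 * p11,
      "2 0" = p10^2, "2 1" = 2 * p10 * p11, "2 2" = p11^2)
    ll <- ll + nij * log(pmax(pr, 1e-300))
  }
  best <- which.max(ll)
  list(loglik = ll[best],
       freqs = c(AB = p11[best], Ab = p10[best], aB = p01[best], ab = p00[best]))
}

# Whole-protein translation oracle for consequence calls: translate the
# full CDS before and after the substitution with Biostrings and diff.
oracle_consequence_call <- function(pos, alt, model, reference) {
  region_start <- reference$start
  chars <- strsplit(reference$seq, "")[[1]]
  tx_seq <- function(ch) {
    cds <- mcoamap:::cds_positions(model)
    b <- ch[cds - region_start + 1L]
    if (model$strand == "-") b <- unname(c(A="T",C="G",G="C",T="A")[b])
    paste(b, collapse = "")
  }
  p_ref <- as.character(Biostrings::translate(Biostrings::DNAString(tx_seq(chars)),
                                              if.fuzzy.codon = "X"))
  chars2 <- chars
  chars2[pos - region_start + 1L] <- alt
  p_alt <- as.character(Biostrings::translate(Biostrings::DNAString(tx_seq(chars2)),
                                              if.fuzzy.codon = "X"))
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  if (!length(d)) return(list(category = "synonymous", residue = NA))
  aa_alt <- substr(p_alt, d[1], d[1])
  list(category = if (aa_alt == "*") "nonsense" else "missense", residue = d[1],
       ref_aa = substr(p_ref, d[1], d[1]), alt_aa = aa_alt)
}

# Per-base membership oracle for interval-track questions.
oracle_covered_bp <- function(track) {
  length(unique(unlist(mapply(seq, track$start, track$end, SIMPLIFY = FALSE))))
}
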