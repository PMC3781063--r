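test_that("track normalization merges overlaps and preserves covered bases", {
  tr <- normalize_track(data.frame(chrom = "c", start = c(10, 15), end = c(20, 30)))
  expect_equal(tr$start, 10)
  expect_equal(tr$end, 30)

  disjoint <- data.frame(chrom = "c", start = c(50, 5), end = c(60, 8))
  tr2 <- normalize_track(disjoint)
  expect_equal(tr2$start, c(5, 50))

  expect_error(normalize_track(data.frame(chrom = "c", start = 10, end = 5)),
               "start > end")

  set.seed(31)
  for (rep in 1:10) {
    s <- sample(1:500, 30, TRUE)
    raw <- data.frame(chrom = "c", start = s, end = s + sample(0:40, 30, TRUE))
    nt <- normalize_track(raw)
    expect_equal(sum(nt$end - nt$start + 1), oracle_covered_bp(raw))
    expect_true(all(diff(nt$start) > 0))
    if (nrow(nt) > 1) expect_true(all(nt$start[-1] > nt$end[-nrow(nt)] + 1))
  }
})

test_that("conservation annotation is point-inclusive and matches a membership oracle", {
  # element spans the coding SNP but not the intronic one
  track <- normalize_track(data.frame(chrom = "chr6",
                                      start = c(73665200, 73600000),
                                      end = c(73665400, 73600100)))
  geno <- matrix(0L, 2, 2, dimnames = list(NULL, c("s1", "s2")))
  vt <- make_vt(c(73665304, 73666064), geno, ref = "C", alt = "T", chrom = "chr6")
  conserved <- annotate_conservation(vt, track)
  expect_equal(as.logical(conserved), c(TRUE, FALSE))
  expect_equal(attr(conserved, "n_conserved"), 1)

  # boundary bases count as inside
  vt2 <- make_vt(c(73665200, 73665400, 73665401), matrix(0L, 3, 1,
                 dimnames = list(NULL, "s")), chrom = "chr6")
  expect_equal(as.logical(annotate_conservation(vt2, track)),
               c(TRUE, TRUE, FALSE))

  empty <- normalize_track(data.frame(chrom = character(), start = numeric(),
                                      end = numeric()))
  expect_false(any(annotate_conservation(vt, empty)))

  set.seed(13)
  for (rep in 1:5) {
    s <- sample(1:2000, 40, TRUE)
    track_r <- normalize_track(data.frame(chrom = "c", start = s,
                                          end = s + sample(0:50, 40, TRUE)))
    pos <- sample(1:2100, 300, TRUE)
    vt_r <- make_vt(pos, matrix(0L, 300, 1, dimnames = list(NULL, "s")), chrom = "c")
    member <- vapply(pos, function(p)
      any(p >= track_r$start & p <= track_r$end), logical(1))
    expect_equal(as.logical(annotate_conservation(vt_r, track_r)), member)
  }
})

test_that("consequence calls on a plus-strand toy gene follow the genetic code", {
  # 5 codons: ATG CGC AAA TAC TGA
  seq <- paste0(strrep("T", 100), "ATGCGCAAATACTGA", strrep("T", 100))
  ref <- reference_slice("c", 1, seq)
  model <- gene_model("toy", "+", data.frame(start = 101, end = 115),
                      cds_start = 101, cds_end = 115)
  # CGC -> TGC at codon 2, position 1: Arg -> Cys
  cq <- call_consequence("c", 104, "C", "T", model, ref)
  expect_equal(cq$category, "missense")
  expect_equal(cq$protein_change, "Arg2Cys")
  expect_equal(cq$codon_change, "CGC>TGC")
  # synonymous: AAA -> AAG (Lys)
  expect_equal(call_consequence("c", 109, "A", "G", model, ref)$category,
               "synonymous")
  # nonsense: TAC -> TAA
  nn <- call_consequence("c", 112, "C", "A", model, ref)
  expect_equal(nn$category, "nonsense")
  expect_equal(nn$protein_change, "Tyr4Ter")
  # outside the gene span
  expect_equal(call_consequence("c", 50, "T", "A", model, ref)$category,
               "intergenic")
  # errors
  expect_error(call_consequence("c", 104, "CA", "C", model, ref), "SNPs only")
  expect_error(call_consequence("c", 104, "G", "T", model, ref), "mismatch")
})

test_that("intronic and UTR classification follow the exon/CDS structure", {
  seq <- paste(rep("ACGT", 100), collapse = "")
  ref <- reference_slice("c", 1, substr(strrep("A", 400), 1, 400))
  model <- gene_model("toy", "+",
                      data.frame(start = c(51, 151), end = c(100, 250)),
                      cds_start = 61, cds_end = 200)
  expect_equal(call_consequence("c", 120, "A", "G", model, ref)$category,
               "intronic")
  expect_equal(call_consequence("c", 55, "A", "G", model, ref)$category, "utr")
  expect_equal(call_consequence("c", 220, "A", "G", model, ref)$category, "utr")
})

test_that("minus-strand consequences agree with a whole-protein translation oracle", {
  sim <- simulate_panel(small_config(seed = 17))
  model <- sim$gene_model
  ref <- sim$reference
  cds <- mcoamap:::cds_positions(model)
  set.seed(99)
  probe <- sample(cds[4:(length(cds) - 3)], 60)  # skip start/stop codons
  for (pos in probe) {
    base <- mcoamap:::ref_base(ref, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), base)) {
      got <- call_consequence(ref$chrom, pos, base, alt, model, ref)
      want <- oracle_consequence_call(pos, alt, model, ref)
      expect_equal(got$category, want$category,
                   label = sprintf("pos %d %s>%s", pos, base, alt))
      if (want$category != "synonymous") {
        idx <- as.numeric(gsub("[A-Za-z]", "", got$protein_change))
        expect_equal(idx, want$residue)
      }
    }
  }
})

test_that("strand symmetry: a minus-strand gene equals its mirrored plus-strand twin", {
  # minus-strand gene over a random 300 bp slice
  set.seed(7)
  chars <- sample(c("A", "C", "G", "T"), 300, TRUE)
  ref_minus <- reference_slice("c", 1, paste(chars, collapse = ""))
  model_minus <- gene_model("g", "-",
                            data.frame(start = c(41, 141), end = c(100, 220)),
                            cds_start = 61, cds_end = 202)
  # mirrored plus-strand twin: position p maps to 301 - p on the
  # reverse-complemented sequence
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- rev(unname(comp[chars]))
  ref_plus <- reference_slice("c", 1, paste(rc, collapse = ""))
  model_plus <- gene_model("g", "+",
                           data.frame(start = 301 - c(220, 100),
                                      end = 301 - c(141, 41)),
                           cds_start = 301 - 202, cds_end = 301 - 61)
  cds <- mcoamap:::cds_positions(model_minus)
  for (pos in cds[seq(1, length(cds), by = 7)]) {
    base <- chars[pos]
    for (alt in setdiff(c("A", "C", "G", "T"), base)) {
      a <- call_consequence("c", pos, base, alt, model_minus, ref_minus)
      b <- call_consequence("c", 301 - pos, comp[[base]], comp[[alt]],
                            model_plus, ref_plus)
      expect_equal(a, b, label = sprintf("pos %d", pos))
    }
  }
})

test_that("reference-only classification tags all-hom-alt sites and recovers planted counts", {
  g <- rbind(rep(2L, 10),
             c(rep(2L, 9), 1L),
             c(rep(2L, 9), NA))
  colnames(g) <- paste0("s", 1:10)
  vt <- make_vt(1:3, g)
  flag <- classify_reference_only(vt)
  expect_equal(as.logical(flag), c(TRUE, FALSE, TRUE))

  sim <- simulate_panel(small_config(seed = 23, n_reference_only = 60L))
  flag2 <- classify_reference_only(sim$variants)
  expect_equal(attr(flag2, "n_reference_only"), 60)
  expect_true(all(sim$truth$planted_reference_only_positions %in%
                    sim$variants$sites$pos[flag2]))
})

test_that("gene model and reference round-trip through their file formats", {
  sim <- simulate_panel(small_config(seed = 29))
  gm_path <- withr::local_tempfile(fileext = ".tsv")
  fa_path <- withr::local_tempfile(fileext = ".fa")
  write_gene_model(sim$gene_model, gm_path)
  write_reference_fasta(sim$reference, fa_path)
  gm <- read_gene_model(gm_path)
  expect_equal(gm$exons, sim$gene_model$exons)
  expect_equal(gm$strand, sim$gene_model$strand)
  expect_equal(gm$cds_start, sim$gene_model$cds_start)
  fa <- read_reference_fasta(fa_path)
  expect_equal(fa$seq, sim$reference$seq)
  expect_equal(fa$start, sim$reference$start)

  bed_path <- withr::local_tempfile(fileext = ".bed")
  write_bed(sim$conservation, bed_path)
  back <- normalize_track(read_bed(bed_path))
  expect_equal(back$start, sim$conservation$start)
  expect_equal(back$end, sim$conservation$end)
})
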