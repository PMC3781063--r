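#' Configuration for the synthetic sequenced panel
#'
#' Defaults emulate the MCOA study panel: a ten-horse panel (5 case /
#' 1 intermediate / 4 control, three breeds) over a ~208 kb interval with a
#' planted causal SNP pair 760 bp apart (only the lower-coordinate SNP being
#' conserved and coding), 547 polymorphic background SNPs plus 60
#' reference-only SNPs (609 SNPs in total) and 129 indels, and
#' haplotype-discordance clusters inside a 7.2 kb + 7.2 kb pair of flank
#' exclusion zones (14.4 kb in total).
#'
#' @param region [genomic_interval()] to simulate over.
#' @param n_case,n_intermediate,n_control Panel class sizes.
#' @param n_background_snps Background SNPs in total; the planted flank
#'   discordance clusters are drawn from this budget and the remainder are
#'   polymorphic sites drawn per sample under Hardy-Weinberg equilibrium,
#'   so the output always holds exactly
#'   `n_background_snps + n_reference_only + n_indels + 2` records.
#' @param n_reference_only SNPs at which every sample is homozygous for the
#'   non-reference allele.
#' @param n_indels Background indels.
#' @param conserved_fraction Fraction of the interval covered by constraint
#'   elements (default 0.038, matching a sparse conserved-element track).
#' @param causal_pair_offsets Positions of the two causal SNPs (default
#'   73665304 and 73666064, 760 bp apart). Both must lie strictly inside the
#'   interval remaining after flank exclusion.
#' @param flank_exclusion_5prime,flank_exclusion_3prime Width in bp of the
#'   zones at each end of the region carrying planted discordance clusters.
#' @param background_allele_freq HWE allele frequency of background sites.
#' @param n_flank_markers Discordant markers planted per flank cluster.
#' @param seed Integer seed; all randomness in [simulate_panel()] flows
#'   from it.
#' @return Object of class `panel_config`.
#' @export
panel_config <- function(region = genomic_interval("chr6", 73640494, 73848154),
                         n_case = 5L, n_intermediate = 1L, n_control = 4L,
                         n_background_snps = 547L, n_reference_only = 60L,
                         n_indels = 129L, conserved_fraction = 0.038,
                         causal_pair_offsets = c(73665304, 73666064),
                         flank_exclusion_5prime = 7200L,
                         flank_exclusion_3prime = 7200L,
                         background_allele_freq = 0.5,
                         n_flank_markers = 5L, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "panel_config")
  validate_panel_config(cfg)
  cfg
}

validate_panel_config <- function(cfg) {
  counts <- c(cfg$n_case, cfg$n_intermediate, cfg$n_control,
              cfg$n_background_snps, cfg$n_reference_only, cfg$n_indels,
              cfg$n_flank_markers)
  if (any(counts < 0)) stop("configuration error: all counts must be >= 0")
  if (cfg$n_case < 1 || cfg$n_control < 1)
    stop("configuration error: at least one case and one control required")
  if (cfg$conserved_fraction < 0 || cfg$conserved_fraction > 1)
    stop("configuration error: conserved_fraction must lie in [0, 1]")
  if (cfg$background_allele_freq <= 0 || cfg$background_allele_freq >= 1)
    stop("configuration error: background_allele_freq must lie in (0, 1)")
  L <- interval_length(cfg$region)
  if (L < cfg$flank_exclusion_5prime + cfg$flank_exclusion_3prime + 1)
    stop("configuration error: region shorter than flank exclusions + 1")
  core_lo <- cfg$region$start + cfg$flank_exclusion_5prime
  core_hi <- cfg$region$end - cfg$flank_exclusion_3prime
  cp <- sort(cfg$causal_pair_offsets)
  if (length(cp) != 2L || cp[1L] == cp[2L])
    stop("configuration error: causal_pair_offsets must be two distinct positions")
  if (any(cp <= core_lo) || any(cp >= core_hi))
    stop("configuration error: causal positions must lie strictly inside the post-exclusion core")
  invisible(cfg)
}

panel_breeds <- function(n_case, n_intermediate, n_control) {
  if (n_case == 5L && n_intermediate == 1L && n_control == 4L) {
    ## the three-breed composition of the modelled ten-horse panel
    list(case = c("American Miniature", "Icelandic Horse", "Icelandic Horse",
                  "Rocky Mountain Horse", "Rocky Mountain Horse"),
         intermediate = "American Miniature",
         control = c("American Miniature", "American Miniature",
                     "Rocky Mountain Horse", "Rocky Mountain Horse"))
  } else {
    pal <- c("BreedA", "BreedB", "BreedC")
    list(case = rep(pal, length.out = n_case),
         intermediate = rep(pal[1L], length.out = n_intermediate),
         control = rep(pal, length.out = n_control))
  }
}

## scalar checks shared by generation-time truth derivation
site_is_candidate <- function(dos, classes) {
  if (anyNA(dos)) return(FALSE)
  ok <- function(a, b) all(dos[classes == "case"] == a) &&
    all(dos[classes == "intermediate"] == 1L) &&
    all(dos[classes == "control"] == b)
  ok(2L, 0L) || ok(0L, 2L)
}

site_is_boundary_marker <- function(dos, classes, breeds) {
  if (anyNA(dos)) return(FALSE)
  if (site_is_candidate(dos, classes)) return(FALSE)
  cse <- dos[classes == "case"]
  int <- dos[classes == "intermediate"]
  ctl <- dos[classes == "control"]
  cb <- breeds[classes == "case"]
  for (ab in list(c(2L, 0L), c(0L, 2L))) {
    a <- ab[1L]; b <- ab[2L]
    if (!all(ctl == b)) next
    unanimous <- all(vapply(split(cse, cb), function(x) length(unique(x)) == 1L,
                            logical(1)))
    split_type <- all(cse %in% c(a, b)) && unanimous &&
      any(cse == a) && any(cse == b) && all(int == 1L)
    carrier_type <- all(cse == a) && length(int) > 0L && all(int == b)
    if (split_type || carrier_type) return(TRUE)
  }
  FALSE
}

draw_hwe_row <- function(n, p) as.integer(stats::rbinom(n, 2L, p))

## HWE draw avoiding the boundary-marker signature (so that the planted
## flank clusters remain the only IBD contradictions); candidate-pattern
## draws are kept.
draw_background_row <- function(n, p, classes, breeds) {
  repeat {
    dos <- draw_hwe_row(n, p)
    if (!site_is_boundary_marker(dos, classes, breeds)) return(dos)
  }
}

build_gene_model <- function(chrom, causal_pos) {
  c0 <- causal_pos
  exons <- data.frame(start = numeric(11), end = numeric(11))
  exons[11, ] <- c(c0 - 203, c0 + 100)
  exons[10, ] <- c(c0 + 301, c0 + 500)
  exons[9, ] <- c(c0 + 1301, c0 + 1500)
  for (k in 8:1) exons[k, ] <- c(c0 + 1801 + (8 - k) * 500,
                                 c0 + 2000 + (8 - k) * 500)
  gene_model("PMEL_toy", "-", exons, cds_start = c0 - 29, cds_end = c0 + 4972)
}

## overwrite the CDS of a random reference so the transcript is an ORF whose
## codon 625 is CGC (Arg); the planted C>T transcript change (genomic G>A on
## the minus strand) then reads Arg625Cys.
fill_cds <- function(ref_chars, model, region) {
  cds <- cds_positions(model)
  n_codon <- length(cds) / 3L
  stops <- c("TAA", "TAG", "TGA")
  codon_pool <- setdiff(names(Biostrings::GENETIC_CODE), stops)
  codons <- sample(codon_pool, n_codon, replace = TRUE)
  codons[1L] <- "ATG"
  codons[625L] <- "CGC"
  codons[n_codon] <- "TGA"
  tx <- strsplit(paste(codons, collapse = ""), "")[[1L]]
  genomic <- if (model$strand == "-") unname(COMPLEMENT[tx]) else tx
  ref_chars[cds - region$start + 1L] <- genomic
  ref_chars
}

build_conservation <- function(region, causal, conserved_fraction) {
  L <- interval_length(region)
  target <- conserved_fraction * L
  starts <- numeric(0); ends <- numeric(0)
  covered <- 0
  while (covered < target) {
    len <- sample(100:600, 1L)
    s <- sample(seq(region$start, region$end - len), 1L)
    starts <- c(starts, s); ends <- c(ends, s + len - 1L)
    covered <- covered + len
  }
  ## force an element over the coding causal SNP, none over the intronic one
  starts <- c(starts, causal[1L] - 75); ends <- c(ends, causal[1L] + 75)
  hit2 <- starts <= causal[2L] & ends >= causal[2L] &
    !(starts <= causal[1L] & ends >= causal[1L])
  starts <- starts[!hit2]; ends <- ends[!hit2]
  tr <- normalize_track(data.frame(chrom = region$chrom, start = starts, end = ends))
  ## trimming may still be needed if the forced causal-1 element was merged
  ## toward causal 2 by a neighbour
  if (any(tr$start <= causal[2L] & tr$end >= causal[2L])) {
    i <- which(tr$start <= causal[2L] & tr$end >= causal[2L])
    tr$end[i] <- causal[2L] - 1L
  }
  tr
}

random_alt <- function(ref) sample(setdiff(c("A", "C", "G", "T"), ref), 1L)

#' Simulate the sequenced panel with planted ground truth
#'
#' Generates, deterministically for a given seed, the full input set for the
#' exclusion pipeline: a variant table (two causal SNPs with the concordant
#' incomplete-dominance pattern, HWE background SNPs, reference-only SNPs,
#' indels, and flank discordance clusters), the sample manifest, a
#' constraint-element track, a minus-strand toy PMEL gene model whose codon
#' 625 sits on the lower-coordinate causal SNP, the reference slice, and a
#' truth ledger for testing recovery.
#'
#' @param config A [panel_config()].
#' @param planted_cnvs Optional list of CNVs recorded in the truth ledger
#'   (each `list(interval = genomic_interval, copy_ratio = )`), for use with
#'   [simulate_depth_tracks()].
#' @return List with elements `variants` ([variant_table()]), `manifest`
#'   ([sample_manifest()]), `conservation` (normalized track),
#'   `gene_model`, `reference` ([reference_slice()]) and `truth` (list:
#'   `causal_positions`, `expected_candidates`, `flank_discordant_positions`,
#'   `planted_cnvs`, `planted_reference_only_positions`,
#'   `expected_narrowed_interval`).
#' @export
simulate_panel <- function(config = panel_config(), planted_cnvs = list()) {
  validate_panel_config(config)
  set.seed(config$seed)
  region <- config$region
  L <- interval_length(region)
  causal <- sort(config$causal_pair_offsets)

  br <- panel_breeds(config$n_case, config$n_intermediate, config$n_control)
  classes <- c(rep("case", config$n_case),
               rep("intermediate", config$n_intermediate),
               rep("control", config$n_control))
  breeds <- c(br$case, br$intermediate, br$control)
  ns <- length(classes)
  ids <- sprintf("horse%d", seq_len(ns))
  manifest <- sample_manifest(data.frame(sample_id = ids, phenotype = classes,
                                         breed = breeds, stringsAsFactors = FALSE))

  ## flank discordance clusters (innermost marker pinned to the zone edge)
  f5 <- config$flank_exclusion_5prime
  f3 <- config$flank_exclusion_3prime
  k <- config$n_flank_markers
  pick_extra <- function(lo, hi, m) {
    if (m <= 0L || hi < lo) numeric(0) else sample(seq(lo, hi), min(m, hi - lo + 1L))
  }
  pos5 <- if (f5 > 0 && k > 0)
    sort(unique(c(region$start + f5 - 1,
                  pick_extra(region$start, region$start + f5 - 2, k - 1L))))
    else numeric(0)
  pos3 <- if (f3 > 0 && k > 0)
    sort(unique(c(region$end - f3 + 1,
                  pick_extra(region$end - f3 + 2, region$end, k - 1L))))
    else numeric(0)

  n_bg_random <- config$n_background_snps - length(pos5) - length(pos3)
  if (n_bg_random < 0)
    stop("configuration error: n_background_snps smaller than the planted flank clusters")
  used <- c(causal, pos5, pos3)
  pool <- setdiff(seq(region$start, region$end - 4L), used)
  n_other <- n_bg_random + config$n_reference_only + config$n_indels
  if (n_other > length(pool)) stop("region too small for requested variant counts")
  other <- sample(pool, n_other)
  bg_pos <- sort(other[seq_len(n_bg_random)])
  ro_pos <- sort(other[n_bg_random + seq_len(config$n_reference_only)])
  indel_pos <- sort(other[n_bg_random + config$n_reference_only +
                            seq_len(config$n_indels)])

  ## reference sequence, gene model, CDS fill
  ref_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  model <- build_gene_model(region$chrom, causal[1L])
  if (min(model$exons$start) < region$start || max(model$exons$end) > region$end)
    stop("configuration error: gene model anchored at the causal SNP exceeds the region")
  ref_chars <- fill_cds(ref_chars, model, region)
  reference <- reference_slice(region$chrom, region$start,
                               paste(ref_chars, collapse = ""))
  base_at <- function(pos) ref_chars[pos - region$start + 1L]

  ## genotype patterns
  case_idx <- which(classes == "case")
  divergent_breed <- breeds[case_idx[length(case_idx)]]
  divergent <- breeds[case_idx] == divergent_breed
  geno_causal <- ifelse(classes == "case", 2L, ifelse(classes == "intermediate", 1L, 0L))
  g5 <- geno_causal
  if (length(unique(breeds[case_idx])) > 1L) {
    g5[case_idx[divergent]] <- 0L
  } else if (config$n_intermediate > 0) {
    g5[classes == "intermediate"] <- 0L
  } else {
    g5[case_idx] <- 0L  # degenerate panel: whole-case haplotype switch
  }
  g3 <- geno_causal
  if (config$n_intermediate > 0) {
    g3[classes == "intermediate"] <- 0L
  } else if (length(unique(breeds[case_idx])) > 1L) {
    g3[case_idx[divergent]] <- 0L
  } else {
    g3[case_idx] <- 0L
  }

  p <- config$background_allele_freq
  rows <- list()
  add_row <- function(pos, ref, alt, dos, class) {
    rows[[length(rows) + 1L]] <<- list(pos = pos, ref = ref, alt = alt,
                                       dos = dos, class = class)
  }
  add_row(causal[1L], "G", "A", geno_causal, "SNP")
  add_row(causal[2L], base_at(causal[2L]), random_alt(base_at(causal[2L])),
          geno_causal, "SNP")
  for (pp in pos5) add_row(pp, base_at(pp), random_alt(base_at(pp)), g5, "SNP")
  for (pp in pos3) add_row(pp, base_at(pp), random_alt(base_at(pp)), g3, "SNP")
  for (pp in bg_pos)
    add_row(pp, base_at(pp), random_alt(base_at(pp)),
            draw_background_row(ns, p, classes, breeds), "SNP")
  for (pp in ro_pos)
    add_row(pp, base_at(pp), random_alt(base_at(pp)), rep(2L, ns), "SNP")
  for (pp in indel_pos) {
    len <- sample(1:3, 1L)
    if (stats::runif(1) < 0.5) {  # deletion
      ref <- paste(ref_chars[(pp - region$start + 1L):(pp - region$start + 1L + len)],
                   collapse = "")
      alt <- base_at(pp)
    } else {                      # insertion
      ref <- base_at(pp)
      alt <- paste(c(ref, sample(c("A", "C", "G", "T"), len, replace = TRUE)),
                   collapse = "")
    }
    add_row(pp, ref, alt, draw_background_row(ns, p, classes, breeds), "INDEL")
  }

  ord <- order(vapply(rows, `[[`, numeric(1), "pos"))
  rows <- rows[ord]
  n <- length(rows)
  sites <- data.frame(
    chrom = region$chrom,
    pos = vapply(rows, `[[`, numeric(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    qual = round(stats::runif(n, 25, 500), 1),
    depth = pmin(pmax(round(stats::rnorm(n, 1000, 60)), 500), 1500),
    class = vapply(rows, `[[`, character(1), "class"),
    stringsAsFactors = FALSE)
  geno <- do.call(rbind, lapply(rows, `[[`, "dos"))
  colnames(geno) <- ids
  variants <- variant_table(sites, geno)

  conservation <- build_conservation(region, causal, config$conserved_fraction)

  ## truth: re-derive candidacy and narrowing from the generated genotypes
  is_cand <- vapply(seq_len(n), function(i)
    site_is_candidate(geno[i, ], classes), logical(1))
  is_marker <- vapply(seq_len(n), function(i)
    site_is_boundary_marker(geno[i, ], classes, breeds), logical(1))
  cand_pos <- sites$pos[is_cand]
  marker_pos <- sites$pos[is_marker]
  nstart <- region$start; nend <- region$end
  if (length(cand_pos)) {
    d5 <- marker_pos[marker_pos < min(cand_pos)]
    if (length(d5)) nstart <- max(d5) + 1
    d3 <- marker_pos[marker_pos > max(cand_pos)]
    if (length(d3)) nend <- min(d3) - 1
  }
  truth <- list(
    causal_positions = causal,
    expected_candidates = sort(cand_pos),
    flank_discordant_positions = sort(c(pos5, pos3)),
    planted_cnvs = planted_cnvs,
    planted_reference_only_positions = ro_pos,
    expected_narrowed_interval = genomic_interval(region$chrom, nstart, nend))

  list(variants = variants, manifest = manifest, conservation = conservation,
       gene_model = model, reference = reference, truth = truth)
}

#' Write all panel-simulation outputs to a directory
#'
#' Emits `variants.vcf`, `manifest.tsv`, `conserved.bed`, `gene_model.tsv`,
#' `reference.fa` and `truth.json`.
#'
#' @param sim Result of [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_panel <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  region <- genomic_interval(sim$reference$chrom, sim$reference$start,
                             sim$reference$start + nchar(sim$reference$seq) - 1)
  paths <- c(vcf = file.path(dir, "variants.vcf"),
             manifest = file.path(dir, "manifest.tsv"),
             bed = file.path(dir, "conserved.bed"),
             gene_model = file.path(dir, "gene_model.tsv"),
             reference = file.path(dir, "reference.fa"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$variants, paths[["vcf"]], contig = region)
  write_manifest(sim$manifest, paths[["manifest"]])
  write_bed(sim$conservation, paths[["bed"]])
  write_gene_model(sim$gene_model, paths[["gene_model"]])
  write_reference_fasta(sim$reference, paths[["reference"]])
  tr <- sim$truth
  tr$expected_narrowed_interval <- unclass(tr$expected_narrowed_interval)
  tr$planted_cnvs <- lapply(tr$planted_cnvs, function(x)
    list(interval = unclass(x$interval), copy_ratio = x$copy_ratio))
  jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
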