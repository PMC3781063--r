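#' Minimal gene model
#'
#' Exon coordinates are genomic, 1-based inclusive, sorted ascending and
#' non-overlapping regardless of strand. `cds_start`/`cds_end` delimit the
#' genomic span of the coding sequence (`cds_start <= cds_end`); the number
#' of exonic bases inside that span must be divisible by 3. For minus-strand
#' genes the transcript reads exons from the highest genomic coordinate
#' downwards, reverse-complemented.
#'
#' @param gene_id Gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end` (genomic).
#' @param cds_start,cds_end Genomic bounds of the CDS.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, strand, exons, cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start > exons$end)) stop("exon with start > end")
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("exons must be non-overlapping")
  if (cds_start > cds_end) stop("cds_start must be <= cds_end")
  if (cds_start < min(exons$start) || cds_end > max(exons$end))
    stop("CDS span outside exon union")
  m <- structure(list(gene_id = gene_id, strand = strand, exons = exons,
                      cds_start = cds_start, cds_end = cds_end),
                 class = "gene_model")
  if (length(cds_positions(m)) %% 3L != 0L)
    stop("CDS length is not divisible by 3")
  m
}

## Genomic positions of the transcript, in transcript (5'->3') order.
transcript_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$exons)), function(i)
    seq(model$exons$start[i], model$exons$end[i])), use.names = FALSE)
  if (model$strand == "-") rev(pos) else pos
}

## Genomic positions of the CDS in transcript order.
cds_positions <- function(model) {
  tp <- transcript_positions(model)
  tp[tp >= model$cds_start & tp <= model$cds_end]
}

#' Write / read a minimal gene-model TSV
#'
#' One row per exon: `gene_id`, `strand`, `exon`, `start`, `end`,
#' `cds_start`, `cds_end` (the CDS bounds are repeated on every row).
#'
#' @param model A [gene_model()].
#' @param path File path.
#' @return `path` invisibly, or the re-read `gene_model`.
#' @export
write_gene_model <- function(model, path) {
  df <- data.frame(gene_id = model$gene_id, strand = model$strand,
                   exon = seq_len(nrow(model$exons)),
                   start = model$exons$start, end = model$exons$end,
                   cds_start = model$cds_start, cds_end = model$cds_end)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_model(df$gene_id[1L], df$strand[1L],
             data.frame(start = df$start, end = df$end),
             df$cds_start[1L], df$cds_end[1L])
}

#' Reference sequence slice
#'
#' A stretch of reference sequence anchored at a genomic offset, so that
#' genomic coordinates can be looked up directly. Written to FASTA with the
#' header `chrom:start-end`.
#'
#' @param chrom Chromosome name.
#' @param start Genomic position of the first base of `seq`.
#' @param seq Character scalar of A/C/G/T.
#' @return An object of class `reference_slice`.
#' @export
reference_slice <- function(chrom, start, seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  structure(list(chrom = chrom, start = start, seq = toupper(seq)),
            class = "reference_slice")
}

ref_base <- function(ref, pos) {
  idx <- pos - ref$start + 1L
  if (any(idx < 1L | idx > nchar(ref$seq)))
    stop("position outside reference slice")
  vapply(idx, function(i) substr(ref$seq, i, i), character(1))
}

#' @rdname reference_slice
#' @param ref A `reference_slice`.
#' @param path FASTA path.
#' @export
write_reference_fasta <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(ref$seq)
  names(ss) <- sprintf("%s:%d-%d", ref$chrom, as.integer(ref$start),
                       as.integer(ref$start + nchar(ref$seq) - 1L))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' @rdname reference_slice
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)[1L]
  m <- regmatches(hdr, regexec("^(\\S+):(\\d+)-(\\d+)", hdr))[[1L]]
  if (length(m) != 4L) stop("FASTA header is not of the form chrom:start-end: ", hdr)
  reference_slice(m[2L], as.numeric(m[3L]), as.character(ss[[1L]]))
}

#' Normalize a constraint-element track
#'
#' Sorts the elements and merges overlapping or bookended ones, so that
#' downstream membership queries see a canonical, non-redundant track.
#'
#' @param elements Data frame with `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. from [read_bed()].
#' @return Data frame of class `conservation_track`, sorted, non-overlapping.
#' @export
normalize_track <- function(elements) {
  if (any(elements$start > elements$end)) stop("element with start > end")
  if (nrow(elements) == 0L) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric())
  } else {
    out <- granges_to_df(GenomicRanges::reduce(as_granges(elements)))
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("conservation_track", "data.frame")
  out
}

#' Flag variants overlapping constraint elements
#'
#' A variant is conserved when its position lies inside any element
#' (endpoints inclusive).
#'
#' @param vt A [variant_table()].
#' @param track A normalized [normalize_track()] data frame.
#' @return Logical vector, one element per variant; the number of conserved
#'   variants is attached as attribute `n_conserved`.
#' @export
annotate_conservation <- function(vt, track) {
  stopifnot(inherits(vt, "variant_table"))
  if (nrow(track) == 0L || n_variants(vt) == 0L) {
    out <- rep(FALSE, n_variants(vt))
  } else {
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(vt$sites$chrom,
                             IRanges::IRanges(vt$sites$pos, vt$sites$pos)),
      as_granges(track))
    out <- seq_len(n_variants(vt)) %in% S4Vectors::queryHits(hits)
  }
  attr(out, "n_conserved") <- sum(out)
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(b) unname(COMPLEMENT[toupper(b)])

aa_three_letter <- function(aa1) {
  if (aa1 == "*") return("Ter")
  code <- Biostrings::AMINO_ACID_CODE
  out <- code[aa1]
  if (is.na(out)) stop("unknown amino acid: ", aa1)
  unname(out)
}

#' Call the molecular consequence of a SNP against a gene model
#'
#' Classifies a single-nucleotide variant as intergenic, intronic, UTR,
#' synonymous, missense or nonsense by translating the affected codon before
#' and after substitution with the standard genetic code. Minus-strand genes
#' are handled by complementing the alleles into transcript orientation.
#' Protein changes are reported as e.g. `Arg625Cys`, numbering residues from
#' the CDS start codon.
#'
#' @param chrom,pos,ref,alt The variant (plus-strand alleles).
#' @param model A [gene_model()].
#' @param reference A [reference_slice()] covering the gene span.
#' @return List of class `consequence` with `category`, `protein_change`
#'   (or `NA`), `codon_change` (or `NA`).
#' @export
call_consequence <- function(chrom, pos, ref, alt, model, reference) {
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("consequence calling supports SNPs only")
  if (ref_base(reference, pos) != toupper(ref))
    stop(sprintf("reference allele mismatch at %s:%d: VCF says %s, reference has %s",
                 chrom, pos, ref, ref_base(reference, pos)))
  span_lo <- min(model$exons$start)
  span_hi <- max(model$exons$end)
  mk <- function(category, protein = NA_character_, codon = NA_character_)
    structure(list(category = category, protein_change = protein,
                   codon_change = codon), class = "consequence")
  if (pos < span_lo || pos > span_hi) return(mk("intergenic"))
  in_exon <- any(pos >= model$exons$start & pos <= model$exons$end)
  if (!in_exon) return(mk("intronic"))
  cds <- cds_positions(model)
  k <- match(pos, cds)
  if (is.na(k)) return(mk("utr"))
  codon_idx <- (k - 1L) %/% 3L + 1L
  codon_pos <- cds[((codon_idx - 1L) * 3L + 1L):(codon_idx * 3L)]
  ref_codon <- ref_base(reference, codon_pos)
  if (model$strand == "-") ref_codon <- comp_base(ref_codon)
  alt_codon <- ref_codon
  within <- match(pos, codon_pos)
  alt_codon[within] <- if (model$strand == "-") comp_base(alt) else toupper(alt)
  ref_aa <- unname(Biostrings::GENETIC_CODE[paste(ref_codon, collapse = "")])
  alt_aa <- unname(Biostrings::GENETIC_CODE[paste(alt_codon, collapse = "")])
  codon_change <- sprintf("%s>%s", paste(ref_codon, collapse = ""),
                          paste(alt_codon, collapse = ""))
  if (identical(ref_aa, alt_aa)) {
    mk("synonymous",
       sprintf("%s%d%s", aa_three_letter(ref_aa), codon_idx, aa_three_letter(alt_aa)),
       codon_change)
  } else if (identical(alt_aa, "*")) {
    mk("nonsense",
       sprintf("%s%dTer", aa_three_letter(ref_aa), codon_idx), codon_change)
  } else {
    mk("missense",
       sprintf("%s%d%s", aa_three_letter(ref_aa), codon_idx, aa_three_letter(alt_aa)),
       codon_change)
  }
}

#' Tag reference-only differences
#'
#' A site where every non-missing genotype is homozygous for the alternate
#' allele differs from the reference genome but carries no information about
#' the trait contrast; such sites are tagged and excluded from candidacy.
#' Sites with no non-missing genotype are not tagged.
#'
#' @param vt A [variant_table()].
#' @return Logical vector (`TRUE` = reference-only difference), with the
#'   count attached as attribute `n_reference_only`.
#' @export
classify_reference_only <- function(vt) {
  stopifnot(inherits(vt, "variant_table"))
  g <- vt$geno
  n_obs <- rowSums(!is.na(g))
  out <- n_obs > 0L & rowSums(g == 2L, na.rm = TRUE) == n_obs
  attr(out, "n_reference_only") <- sum(out)
  out
}

#' Annotate a variant table for the candidate report
#'
#' Convenience wrapper combining conservation, coding status and consequence
#' into a candidate-report data frame (`pos`, `ref`, `alt`, `conserved`,
#' `coding`, `consequence`).
#'
#' @param vt A [variant_table()].
#' @param track Normalized conservation track.
#' @param model A [gene_model()].
#' @param reference A [reference_slice()].
#' @return Data frame, one row per variant.
#' @export
annotate_variants <- function(vt, track, model, reference) {
  conserved <- annotate_conservation(vt, track)
  n <- n_variants(vt)
  cat_ <- character(n)
  prot <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (vt$sites$class[i] != "SNP") {
      cds <- cds_positions(model)
      cat_[i] <- if (vt$sites$pos[i] %in% cds) "coding_indel_unclassified" else "none"
      next
    }
    cq <- call_consequence(vt$sites$chrom[i], vt$sites$pos[i], vt$sites$ref[i],
                           vt$sites$alt[i], model, reference)
    cat_[i] <- cq$category
    prot[i] <- cq$protein_change
  }
  coding <- cat_ %in% c("synonymous", "missense", "nonsense",
                        "coding_indel_unclassified")
  data.frame(pos = vt$sites$pos, ref = vt$sites$ref, alt = vt$sites$alt,
             conserved = as.logical(conserved), coding = coding,
             consequence = ifelse(is.na(prot) | cat_ == "synonymous",
                                  ifelse(cat_ %in% c("intergenic", "intronic", "utr", "none"),
                                         "none", cat_),
                                  prot),
             category = cat_, stringsAsFactors = FALSE)
}
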