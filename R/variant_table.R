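#' Construct a table of biallelic variant calls
#'
#' The central variant container: site-level fields in `sites` and per-sample
#' genotypes as an alt-allele dosage matrix (`0` hom-ref, `1` het, `2` hom-alt,
#' `NA` missing). Multi-allelic records must be decomposed into biallelic rows
#' before construction; [read_vcf()] does this automatically.
#'
#' @param sites Data frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`
#'   (PHRED site quality), `depth` (site total read depth) and optionally
#'   `class` (`"SNP"`/`"INDEL"`; inferred from allele lengths when absent).
#' @param geno Integer matrix, `nrow(sites)` x n_samples, values in
#'   `{0, 1, 2, NA}`, with sample IDs as column names.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, geno) {
  req <- c("chrom", "pos", "ref", "alt", "qual", "depth")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stop("sites is missing columns: ", paste(miss, collapse = ", "))
  if (!is.matrix(geno) || nrow(geno) != nrow(sites))
    stop("geno must be a matrix with one row per site")
  if (is.null(colnames(geno))) stop("geno must have sample IDs as column names")
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  if (is.null(sites$class)) {
    sites$class <- ifelse(nchar(sites$ref) == 1L & nchar(sites$alt) == 1L,
                          "SNP", "INDEL")
  }
  rownames(sites) <- NULL
  storage.mode(geno) <- "integer"
  structure(list(sites = sites, geno = geno), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d variants (%d SNP, %d INDEL) x %d samples\n",
              n_variants(x), sum(x$sites$class == "SNP"),
              sum(x$sites$class == "INDEL"), length(vt_samples(x))))
  if (n_variants(x) > 0) print(utils::head(x$sites, 5))
  invisible(x)
}

#' Number of variant records
#' @param x A [variant_table()].
#' @return Integer count.
#' @export
n_variants <- function(x) nrow(x$sites)

#' Sample identifiers of a variant table
#' @param x A [variant_table()].
#' @return Character vector of sample IDs.
#' @export
vt_samples <- function(x) colnames(x$geno)

#' Subset a variant table by row
#' @param x A [variant_table()].
#' @param i Row index (integer or logical).
#' @param ... Unused.
#' @export
`[.variant_table` <- function(x, i, ...) {
  variant_table(x$sites[i, , drop = FALSE], x$geno[i, , drop = FALSE])
}

dosage_to_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0L] <- "0/0"
  out[!is.na(d) & d == 1L] <- "0/1"
  out[!is.na(d) & d == 2L] <- "1/1"
  out
}

#' Read a VCF file into a variant table
#'
#' Multi-allelic records are decomposed into one biallelic row per ALT allele
#' (genotype alleles other than the focal ALT count as reference). Records
#' outside `region` are dropped. Site depth is taken from `INFO/DP`.
#'
#' @param path Path to a VCF (v4.x) file with genotype columns.
#' @param region Optional [genomic_interval()] restricting the records kept.
#' @return A [variant_table()] with samples in file order.
#' @export
read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF has no sample columns: ", path)
  sample_ids <- colnames(gt)[-1L]
  if (nrow(fix) == 0L) {
    return(variant_table(
      data.frame(chrom = character(), pos = numeric(), ref = character(),
                 alt = character(), qual = numeric(), depth = numeric(),
                 class = character(), stringsAsFactors = FALSE),
      matrix(integer(), 0L, length(sample_ids),
             dimnames = list(NULL, sample_ids))))
  }
  pos <- as.numeric(fix[, "POS"])
  dp <- suppressWarnings(as.numeric(sub(".*DP=([0-9]+).*", "\\1", fix[, "INFO"])))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  gt_field <- sub(":.*", "", gt[, -1L, drop = FALSE])

  rows <- vector("list", nrow(fix))
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1L]]
    gtr <- gt_field[r, ]
    gtr[is.na(gtr)] <- "."
    alleles <- strsplit(gsub("\\|", "/", gtr), "/", fixed = TRUE)
    per_alt <- lapply(seq_along(alts), function(k) {
      dos <- vapply(alleles, function(a) {
        if (length(a) == 0L || any(is.na(a)) || any(a == ".")) return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1))
      list(alt = alts[k], dosage = dos)
    })
    rows[[r]] <- per_alt
  }
  n_out <- sum(lengths(rows))
  sites <- data.frame(chrom = character(n_out), pos = numeric(n_out),
                      ref = character(n_out), alt = character(n_out),
                      qual = numeric(n_out), depth = numeric(n_out),
                      stringsAsFactors = FALSE)
  geno <- matrix(NA_integer_, n_out, length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  i <- 0L
  for (r in seq_len(nrow(fix))) {
    for (pa in rows[[r]]) {
      i <- i + 1L
      sites$chrom[i] <- fix[r, "CHROM"]
      sites$pos[i] <- pos[r]
      sites$ref[i] <- fix[r, "REF"]
      sites$alt[i] <- pa$alt
      sites$qual[i] <- qual[r]
      sites$depth[i] <- dp[r]
      geno[i, ] <- pa$dosage
    }
  }
  vt <- variant_table(sites, geno)
  if (!is.null(region)) {
    keep <- vt$sites$chrom == region$chrom & interval_contains(region, vt$sites$pos)
    vt <- vt[keep]
  }
  vt
}

#' Write a variant table to a plain-text VCF v4.2 file
#'
#' Emits QUAL, `INFO/DP` and a `GT` genotype column per sample, one biallelic
#' record per row, in position order as stored.
#'
#' @param vt A [variant_table()].
#' @param path Output path.
#' @param contig Optional contig length written into the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path, contig = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mcoamap",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth at site">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'), con)
  if (!is.null(contig))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", contig$chrom,
                       as.integer(contig$end)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", vt_samples(vt)), collapse = "\t"), con)
  if (n_variants(vt) > 0L) {
    gts <- apply(vt$geno, 1L, dosage_to_gt)
    gts <- if (is.matrix(gts)) t(gts) else matrix(gts, ncol = 1L)
    lines <- paste(vt$sites$chrom, format(vt$sites$pos, scientific = FALSE, trim = TRUE),
                   ".", vt$sites$ref, vt$sites$alt,
                   formatC(vt$sites$qual, format = "g", digits = 10), ".",
                   paste0("DP=", as.integer(vt$sites$depth)), "GT",
                   apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a sample manifest
#'
#' Tab-separated file with columns `sample_id`, `phenotype`, `breed`.
#' Phenotypes are normalized to `case` / `intermediate` / `control`
#' (accepting the field labels `MCOA`, `Cyst` and `Unaffected`).
#'
#' @param path Path to the manifest TSV.
#' @return Data frame of class `sample_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_manifest(df)
}

#' Construct a sample manifest
#'
#' @param df Data frame with `sample_id`, `phenotype`, `breed`.
#' @return Validated data frame of class `sample_manifest`.
#' @export
sample_manifest <- function(df) {
  req <- c("sample_id", "phenotype", "breed")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  map <- c(mcoa = "case", case = "case", cyst = "intermediate",
           intermediate = "intermediate", unaffected = "control",
           control = "control")
  ph <- map[tolower(df$phenotype)]
  if (anyNA(ph))
    stop("unknown phenotype label(s): ",
         paste(unique(df$phenotype[is.na(ph)]), collapse = ", "))
  df$phenotype <- unname(ph)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in manifest")
  if (!any(df$phenotype == "case") || !any(df$phenotype == "control"))
    stop("manifest must contain at least one case and one control")
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' Write a sample manifest TSV
#' @param manifest A [sample_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
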