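#' Pipeline run configuration
#'
#' Collects input paths and stage parameters for [run_pipeline()]. All
#' thresholds are surfaced; the defaults are the study-standard values used
#' throughout the package ([filter_config()], [concordance_policy()],
#' window 500 bp / |log2| >= 0.58 for the coverage scan).
#'
#' @param vcf,manifest,bed,gene_model,reference Paths to the five required
#'   inputs (VCF variants, sample manifest TSV, constraint-element BED,
#'   gene-model TSV, reference FASTA slice).
#' @param depth Optional per-base depth TSV enabling the coverage scan.
#' @param cohort Optional two-locus cohort genotype TSV enabling LD
#'   validation.
#' @param out_dir Output directory for the report files.
#' @param filter A [filter_config()].
#' @param policy A [concordance_policy()].
#' @param window_bp,min_abs_log2 Coverage-scan parameters.
#' @return Object of class `run_config`.
#' @export
run_config <- function(vcf, manifest, bed, gene_model, reference,
                       depth = NULL, cohort = NULL, out_dir = NULL,
                       filter = filter_config(), policy = concordance_policy(),
                       window_bp = 500L, min_abs_log2 = 0.58) {
  req <- c(vcf = vcf, manifest = manifest, bed = bed,
           gene_model = gene_model, reference = reference)
  missing_files <- req[!file.exists(req)]
  if (length(missing_files))
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  structure(list(vcf = vcf, manifest = manifest, bed = bed,
                 gene_model = gene_model, reference = reference,
                 depth = depth, cohort = cohort, out_dir = out_dir,
                 filter = filter, policy = policy, window_bp = window_bp,
                 min_abs_log2 = min_abs_log2),
            class = "run_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Recognized keys: the path arguments of [run_config()] plus
#' `min_site_quality`, `min_depth`, `max_depth`, `quality_strict`,
#' `missing_genotype_handling`, `require_intermediate_het`, `window_bp`,
#' `min_abs_log2`. Lines starting with `#` are ignored.
#'
#' @param path Path to the configuration file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  names(vals) <- keys
  get_ <- function(k, default = NULL) if (k %in% keys) vals[[k]] else default
  num_ <- function(k, default) as.numeric(get_(k, default))
  lgl_ <- function(k, default) as.logical(get_(k, default))
  run_config(
    vcf = get_("vcf"), manifest = get_("manifest"), bed = get_("bed"),
    gene_model = get_("gene_model"), reference = get_("reference"),
    depth = get_("depth"), cohort = get_("cohort"), out_dir = get_("out_dir"),
    filter = filter_config(
      min_site_quality = num_("min_site_quality", 20),
      min_depth = num_("min_depth", 50),
      max_depth = num_("max_depth", 100000),
      quality_strict = lgl_("quality_strict", TRUE)),
    policy = concordance_policy(
      missing_genotype_handling = get_("missing_genotype_handling", "fail_variant"),
      require_intermediate_het = lgl_("require_intermediate_het", TRUE)),
    window_bp = num_("window_bp", 500),
    min_abs_log2 = num_("min_abs_log2", 0.58))
}

#' Run the full exclusion pipeline
#'
#' Executes the stages in order: read variants over the reference interval,
#' site quality/depth filtering, conservation + consequence annotation,
#' reference-only classification, incomplete-dominance concordance
#' filtering, IBD-interval narrowing from haplotype-boundary markers, then
#' (when the inputs are provided) two-locus LD validation in the cohort and
#' the case-versus-control relative coverage scan. One structured log line
#' is emitted per stage with input/output counts. The run is deterministic
#' for fixed inputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log lines.
#' @return A `candidate_report` list: `status` (`"ok"` or
#'   `"no_candidates"`), `counts`, `candidates` (candidate-table data
#'   frame), `narrowing`, `ld`, `cnv_calls`, `rejected`, `audit`. When
#'   `config$out_dir` is set, the report is also written as
#'   `report.json`, `candidates.tsv`, `exclusion_audit.tsv` and
#'   `rejected_sites.tsv`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  reference <- read_reference_fasta(config$reference)
  region <- genomic_interval(reference$chrom, reference$start,
                             reference$start + nchar(reference$seq) - 1)
  vt <- read_vcf(config$vcf, region)
  manifest <- read_manifest(config$manifest)
  track <- normalize_track(read_bed(config$bed))
  model <- read_gene_model(config$gene_model)
  say("stage=read n_variants=%d n_samples=%d region=%s:%d-%d", n_variants(vt),
      length(vt_samples(vt)), region$chrom, as.integer(region$start),
      as.integer(region$end))

  flt <- apply_site_filters(vt, config$filter)
  kept <- flt$kept
  say("stage=filter in=%d kept=%d rejected=%d", n_variants(vt),
      n_variants(kept), n_variants(flt$rejected))

  conserved <- annotate_conservation(kept, track)
  n_conserved_snps <- sum(conserved & kept$sites$class == "SNP")
  n_conserved_indels <- sum(conserved & kept$sites$class == "INDEL")
  say("stage=annotate conserved_snps=%d conserved_indels=%d",
      n_conserved_snps, n_conserved_indels)

  ref_only <- classify_reference_only(kept)
  informative <- kept[!ref_only]
  say("stage=reference_only tagged=%d informative=%d", sum(ref_only),
      n_variants(informative))

  conc <- concordance_filter(informative, manifest, config$policy)
  say("stage=concordance in=%d candidates=%d excluded=%d",
      n_variants(informative), n_variants(conc$candidates),
      n_variants(conc$excluded))

  markers <- haplotype_boundary_markers(kept, manifest)
  status <- if (n_variants(conc$candidates) > 0) "ok" else "no_candidates"
  if (status == "ok") {
    mdf <- rbind(
      data.frame(pos = conc$candidates$sites$pos, status = "concordant"),
      data.frame(pos = kept$sites$pos[markers], status = "discordant"))
    nr <- narrow_interval(region, mdf)
  } else {
    nr <- narrow_interval(region, data.frame(pos = numeric(), status = character()))
  }
  say("stage=narrow excluded_5prime=%d excluded_3prime=%d narrowed_kb=%.1f",
      as.integer(nr$excluded_5prime_bp), as.integer(nr$excluded_3prime_bp),
      interval_length(nr$narrowed) / 1000)

  cand_table <- annotate_variants(conc$candidates, track, model, reference)

  ld <- NULL
  if (!is.null(config$cohort)) {
    cohort <- read_cohort(config$cohort)
    counts <- two_locus_counts(cohort$locus1_dosage, cohort$locus2_dosage)
    fit <- em_haplotype_frequencies(counts)
    carriers <- carrier_summary(cohort$locus1_dosage, cohort$coat_label)
    ld <- list(result = fit, carriers = carriers,
               complete_ld = complete_ld_check(cohort$locus1_dosage,
                                               cohort$locus2_dosage))
    say("stage=ld n=%d carriers=%d noncarriers=%d r2=%.4f complete_ld=%s",
        sum(counts), carriers$n_carriers, carriers$n_noncarriers,
        fit$r_squared, ld$complete_ld)
  }

  cnv_calls <- NULL
  if (!is.null(config$depth)) {
    tracks <- read_depth_tsv(config$depth)
    ph <- manifest$phenotype[match(colnames(tracks$depth), manifest$sample_id)]
    case_tr <- depth_tracks(tracks$interval,
                            tracks$depth[, ph == "case", drop = FALSE])
    ctrl_tr <- depth_tracks(tracks$interval,
                            tracks$depth[, ph == "control", drop = FALSE])
    cnv_calls <- relative_coverage_scan(case_tr, ctrl_tr, config$window_bp,
                                        config$min_abs_log2)
    say("stage=coverage_scan n_calls=%d", nrow(cnv_calls))
  }

  report <- list(
    status = status,
    counts = list(
      raw = n_variants(vt),
      rejected = n_variants(flt$rejected),
      post_filter = n_variants(kept),
      snps = sum(kept$sites$class == "SNP"),
      indels = sum(kept$sites$class == "INDEL"),
      conserved_snps = n_conserved_snps,
      conserved_indels = n_conserved_indels,
      reference_only = sum(ref_only),
      concordant = n_variants(conc$candidates)),
    candidates = cand_table,
    narrowing = list(
      original = unclass(nr$original), narrowed = unclass(nr$narrowed),
      excluded_5prime_bp = nr$excluded_5prime_bp,
      excluded_3prime_bp = nr$excluded_3prime_bp,
      boundary_markers = as.list(nr$boundary_markers)),
    ld = if (!is.null(ld)) list(
      haplotype_freqs = as.list(ld$result$haplotype_freqs),
      D = ld$result$D, D_prime = ld$result$D_prime,
      r_squared = ld$result$r_squared, converged = ld$result$converged,
      n_carriers = ld$carriers$n_carriers,
      n_noncarriers = ld$carriers$n_noncarriers,
      complete_ld = ld$complete_ld),
    cnv_calls = cnv_calls,
    rejected = flt$reasons,
    audit = conc$audit)
  class(report) <- "candidate_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- report
    out$audit <- NULL; out$rejected <- NULL
    jsonlite::write_json(unclass(out), file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(cand_table, file.path(config$out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(conc$audit))
      utils::write.table(conc$audit, file.path(config$out_dir, "exclusion_audit.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(flt$reasons, file.path(config$out_dir, "rejected_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("<candidate_report> status=%s\n", x$status))
  cat("  counts:", paste(sprintf("%s=%s", names(x$counts), unlist(x$counts)),
                         collapse = " "), "\n")
  cat(sprintf("  narrowed: %s:%d-%d (%.1f kb)\n", x$narrowing$narrowed$chrom,
              as.integer(x$narrowing$narrowed$start),
              as.integer(x$narrowing$narrowed$end),
              (x$narrowing$narrowed$end - x$narrowing$narrowed$start + 1) / 1000))
  if (nrow(x$candidates)) {
    cat("  candidates:\n")
    print(x$candidates[, c("pos", "ref", "alt", "conserved", "coding", "consequence")])
  }
  invisible(x)
}
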