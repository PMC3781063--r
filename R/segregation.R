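#' Concordance-filter policy
#'
#' How missing genotypes are treated and whether intermediate-phenotype
#' samples are required to be heterozygous. With the default
#' `fail_variant` policy a candidate must be positively confirmed in every
#' sample: any missing genotype among the samples a constraint applies to
#' excludes the variant. Under `ignore_sample`, missing genotypes are
#' dropped from their class before checking (a class left empty imposes no
#' constraint).
#'
#' @param missing_genotype_handling `"fail_variant"` (default) or
#'   `"ignore_sample"`.
#' @param require_intermediate_het Logical (default `TRUE`). When `FALSE`,
#'   intermediate-phenotype samples are unconstrained.
#' @return An object of class `concordance_policy`.
#' @export
concordance_policy <- function(missing_genotype_handling = c("fail_variant", "ignore_sample"),
                               require_intermediate_het = TRUE) {
  structure(list(missing_genotype_handling = match.arg(missing_genotype_handling),
                 require_intermediate_het = isTRUE(require_intermediate_het)),
            class = "concordance_policy")
}

class_indices <- function(vt, manifest) {
  ids <- vt_samples(vt)
  unmatched <- setdiff(ids, manifest$sample_id)
  if (length(unmatched))
    stop("samples absent from manifest: ", paste(unmatched, collapse = ", "))
  ph <- manifest$phenotype[match(ids, manifest$sample_id)]
  list(case = which(ph == "case"), intermediate = which(ph == "intermediate"),
       control = which(ph == "control"))
}

## Orientation-specific check matrices. `target` is the dosage every member
## of the class must equal. Returns per-variant logical.
all_equal_rows <- function(g, cols, target, missing_fails) {
  if (length(cols) == 0L) return(rep(TRUE, nrow(g)))
  sub <- g[, cols, drop = FALSE]
  ok <- rowSums(sub == target, na.rm = TRUE)
  n_na <- rowSums(is.na(sub))
  if (missing_fails) ok == length(cols) else ok == length(cols) - n_na
}

#' Incomplete-dominance genotype concordance filter
#'
#' The core exclusion step: a variant is retained as a candidate if and only
#' if, for one of the two allele orientations, every case is homozygous for
#' the putative disease allele, every intermediate-phenotype sample is
#' heterozygous, and every control is homozygous for the opposite allele.
#' Orientation is free because either the reference or the alternate allele
#' may travel with the disease haplotype.
#'
#' @param vt A [variant_table()].
#' @param manifest A [sample_manifest()] covering every genotyped sample.
#' @param policy A [concordance_policy()].
#' @param audit Logical; when `TRUE` (default) an exclusion audit listing,
#'   per excluded variant, the violating samples with observed and required
#'   genotypes (for the closer orientation) is returned. Disable for large
#'   property-style runs.
#' @return List with `candidates` (variant_table), `excluded`
#'   (variant_table), `is_candidate` (logical over the input) and `audit`
#'   (data frame `pos`, `sample`, `observed`, `required`, or `NULL`).
#' @export
concordance_filter <- function(vt, manifest, policy = concordance_policy(),
                               audit = TRUE) {
  stopifnot(inherits(vt, "variant_table"), inherits(manifest, "sample_manifest"),
            inherits(policy, "concordance_policy"))
  idx <- class_indices(vt, manifest)
  g <- vt$geno
  mf <- policy$missing_genotype_handling == "fail_variant"
  use_int <- policy$require_intermediate_het

  ok_alt <- all_equal_rows(g, idx$case, 2L, mf) &
    all_equal_rows(g, idx$control, 0L, mf)
  ok_ref <- all_equal_rows(g, idx$case, 0L, mf) &
    all_equal_rows(g, idx$control, 2L, mf)
  if (use_int) {
    int_ok <- all_equal_rows(g, idx$intermediate, 1L, mf)
    ok_alt <- ok_alt & int_ok
    ok_ref <- ok_ref & int_ok
  }
  is_candidate <- ok_alt | ok_ref

  audit_df <- NULL
  if (audit && any(!is_candidate)) {
    rows <- list()
    ids <- vt_samples(vt)
    ph <- manifest$phenotype[match(ids, manifest$sample_id)]
    req_for <- function(orient) {
      r <- ifelse(ph == "case", if (orient == "alt") 2L else 0L,
                  ifelse(ph == "control", if (orient == "alt") 0L else 2L, 1L))
      if (!use_int) r[ph == "intermediate"] <- NA_integer_
      r
    }
    req_alt <- req_for("alt"); req_ref <- req_for("ref")
    for (i in which(!is_candidate)) {
      gi <- g[i, ]
      viol <- function(req) {
        v <- !is.na(req) & (is.na(gi) & mf | (!is.na(gi) & gi != req))
        if (!mf) v[is.na(gi)] <- FALSE
        v
      }
      v_alt <- viol(req_alt); v_ref <- viol(req_ref)
      use <- if (sum(v_alt) <= sum(v_ref)) list(v = v_alt, r = req_alt)
             else list(v = v_ref, r = req_ref)
      if (any(use$v))
        rows[[length(rows) + 1L]] <- data.frame(
          pos = vt$sites$pos[i], sample = ids[use$v],
          observed = dosage_to_gt(gi[use$v]),
          required = dosage_to_gt(use$r[use$v]), stringsAsFactors = FALSE)
    }
    audit_df <- if (length(rows)) do.call(rbind, rows)
    else data.frame(pos = numeric(), sample = character(),
                    observed = character(), required = character())
  }
  list(candidates = vt[is_candidate], excluded = vt[!is_candidate],
       is_candidate = is_candidate, audit = audit_df)
}

#' Flag haplotype-boundary markers for IBD narrowing
#'
#' A site qualifies as a boundary marker when its genotypes contradict a
#' single shared disease haplotype while retaining a clean class structure,
#' i.e. for one allele orientation (disease allele A, other allele B):
#' every control is homozygous B, and either (a) the cases are each
#' homozygous, unanimous within breed, with at least one breed homozygous A
#' and one homozygous B while intermediates are heterozygous (a breed subset
#' of cases carries a different haplotype), or (b) every case is homozygous
#' A but an intermediate is homozygous B (the obligate-carrier sample does
#' not carry the disease haplotype). Concordance candidates are never
#' markers. Sites with any missing genotype are not markers.
#'
#' @param vt A [variant_table()].
#' @param manifest A [sample_manifest()] (breeds are used for the
#'   within-breed unanimity requirement on cases).
#' @return Logical vector, one element per variant.
#' @export
haplotype_boundary_markers <- function(vt, manifest) {
  stopifnot(inherits(vt, "variant_table"), inherits(manifest, "sample_manifest"))
  idx <- class_indices(vt, manifest)
  ids <- vt_samples(vt)
  g <- vt$geno
  n <- n_variants(vt)
  if (n == 0L) return(logical(0))
  breeds <- manifest$breed[match(ids, manifest$sample_id)]
  case_breeds <- split(idx$case, breeds[idx$case])

  marker_for <- function(a_dos, b_dos) {
    ctrl_ok <- all_equal_rows(g, idx$control, b_dos, missing_fails = TRUE)
    int <- g[, idx$intermediate, drop = FALSE]
    cse <- g[, idx$case, drop = FALSE]
    no_na <- rowSums(is.na(cse)) == 0L &
      (ncol(int) == 0L | rowSums(is.na(int)) == 0L)
    cases_hom <- rowSums(cse == 1L, na.rm = TRUE) == 0L
    breed_unanimous <- Reduce(`&`, lapply(case_breeds, function(cols) {
      sub <- g[, cols, drop = FALSE]
      apply(sub, 1L, function(r) length(unique(r)) == 1L)
    }), rep(TRUE, n))
    any_a <- rowSums(cse == a_dos, na.rm = TRUE) > 0L
    any_b <- rowSums(cse == b_dos, na.rm = TRUE) > 0L
    int_het <- if (ncol(int) == 0L) rep(TRUE, n) else rowSums(int != 1L, na.rm = TRUE) == 0L
    int_homb <- if (ncol(int) == 0L) rep(FALSE, n) else rowSums(int != b_dos, na.rm = TRUE) == 0L
    all_a <- rowSums(cse != a_dos, na.rm = TRUE) == 0L
    type_split <- cases_hom & breed_unanimous & any_a & any_b & int_het
    type_carrier <- all_a & int_homb
    no_na & ctrl_ok & (type_split | type_carrier)
  }
  cand <- concordance_filter(vt, manifest, audit = FALSE)$is_candidate
  (marker_for(2L, 0L) | marker_for(0L, 2L)) & !cand
}

#' Probability that a neutral HWE site passes the concordance filter
#'
#' Closed form for genotypes drawn independently per sample under
#' Hardy-Weinberg equilibrium at allele frequency `p`:
#' `(2pq)^n_intermediate * (p^(2 n_case) q^(2 n_control) + q^(2 n_case) p^(2 n_control))`.
#' Used by property tests comparing the empirical pass rate of simulated
#' background sites against expectation.
#'
#' @param p Allele frequency, strictly inside (0, 1).
#' @param n_case,n_intermediate,n_control Panel class sizes
#'   (`n_case >= 1`, `n_control >= 1`).
#' @return Probability.
#' @export
expected_background_pass_rate <- function(p, n_case, n_intermediate, n_control) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("p must lie strictly inside (0, 1)")
  if (n_case < 1L || n_control < 1L)
    stop("at least one case and one control are required")
  q <- 1 - p
  (2 * p * q)^n_intermediate *
    (p^(2 * n_case) * q^(2 * n_control) + q^(2 * n_case) * p^(2 * n_control))
}
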