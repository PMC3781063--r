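#' Configuration for the genotyped validation cohort
#'
#' Defaults emulate the 936-horse validation panel: 24 heterozygous carriers
#' (the Silver horses) and 4 homozygous carriers (chestnut carriers) of the
#' focal allele at both loci, no discordant individuals, hence 908
#' non-carriers. The heterozygous/homozygous split among the 28 carriers is
#' a free parameter (the modelled study does not report it).
#'
#' @param n_total Cohort size (default 936).
#' @param n_carriers_het Individuals heterozygous at both loci (default 24).
#' @param n_carriers_hom Individuals homozygous for the focal allele at both
#'   loci (default 4).
#' @param n_discordant Individuals carrying the focal allele at locus 1 but
#'   not at locus 2 (default 0; any positive value breaks complete LD).
#' @param seed Integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_total = 936L, n_carriers_het = 24L,
                          n_carriers_hom = 4L, n_discordant = 0L, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  if (any(unlist(cfg[1:4]) < 0)) stop("configuration error: counts must be >= 0")
  if (cfg$n_carriers_het + cfg$n_carriers_hom + cfg$n_discordant > cfg$n_total)
    stop("configuration error: carrier + discordant counts exceed n_total")
  cfg
}

#' Simulate the two-locus validation cohort
#'
#' Carriers receive identical dosages at both loci (complete LD) unless
#' `n_discordant > 0`, in which case that many individuals carry the focal
#' allele at locus 1 only. Row order is shuffled deterministically.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (data frame `horse_id`, `locus1_dosage`,
#'   `locus2_dosage`, `coat_label`) and `truth` (list `n_carriers`,
#'   `n_noncarriers`, `complete_ld`).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_total
  het <- config$n_carriers_het; hom <- config$n_carriers_hom
  disc <- config$n_discordant
  d1 <- c(rep(1L, het), rep(2L, hom), rep(1L, disc),
          rep(0L, n - het - hom - disc))
  d2 <- c(rep(1L, het), rep(2L, hom), rep(0L, disc),
          rep(0L, n - het - hom - disc))
  label <- c(rep("Silver", het), rep("chestnut", hom),
             rep("other", n - het - hom))
  ord <- if (n > 0) sample.int(n) else integer(0)
  cohort <- data.frame(horse_id = sprintf("H%04d", seq_len(n)),
                       locus1_dosage = d1[ord], locus2_dosage = d2[ord],
                       coat_label = label[ord], stringsAsFactors = FALSE)
  list(cohort = cohort,
       truth = list(n_carriers = het + hom + disc,
                    n_noncarriers = n - het - hom - disc,
                    complete_ld = disc == 0L))
}

#' Write a cohort genotype TSV
#' @param cohort Data frame from [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
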