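#' Tabulate two-locus genotype counts
#'
#' Builds the 3x3 table `n[i+1, j+1]` = number of individuals with `i`
#' copies of the focal allele at locus 1 and `j` copies at locus 2.
#'
#' @param dosage1,dosage2 Integer vectors in `{0, 1, 2}`, same length.
#' @return 3x3 integer matrix with dimnames `0:2`.
#' @export
two_locus_counts <- function(dosage1, dosage2) {
  stopifnot(length(dosage1) == length(dosage2))
  if (length(dosage1) && (!all(dosage1 %in% 0:2) || !all(dosage2 %in% 0:2)))
    stop("dosages must be 0, 1 or 2")
  tab <- table(factor(dosage1, levels = 0:2), factor(dosage2, levels = 0:2))
  m <- matrix(as.integer(tab), 3L, 3L, dimnames = list(0:2, 0:2))
  m
}

## Unambiguous haplotype contributions of each genotype class except the
## double heterozygote; row order AB, Ab, aB, ab.
fixed_hap_counts <- function(n) {
  AB <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
  Ab <- 2 * n[3, 1] + n[3, 2] + n[2, 1]
  aB <- 2 * n[1, 3] + n[1, 2] + n[2, 3]
  ab <- 2 * n[1, 1] + n[1, 2] + n[2, 1]
  c(AB = AB, Ab = Ab, aB = aB, ab = ab)
}

genotype_class_probs <- function(f) {
  p11 <- f[1]; p10 <- f[2]; p01 <- f[3]; p00 <- f[4]
  m <- matrix(0, 3, 3)
  m[1, 1] <- p00^2;        m[1, 2] <- 2 * p00 * p01; m[1, 3] <- p01^2
  m[2, 1] <- 2 * p00 * p10; m[2, 2] <- 2 * p11 * p00 + 2 * p10 * p01
  m[2, 3] <- 2 * p01 * p11
  m[3, 1] <- p10^2;        m[3, 2] <- 2 * p10 * p11; m[3, 3] <- p11^2
  m
}

ld_loglik <- function(counts, f) {
  pm <- genotype_class_probs(f)
  sum(counts[counts > 0] * log(pm[counts > 0]))
}

run_em <- function(f, fixed, n11, N, tol, max_iter) {
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    denom <- f[1] * f[4] + f[2] * f[3]
    w <- if (denom > 0) f[1] * f[4] / denom else 0.5
    new_f <- (fixed + n11 * c(w, 1 - w, 1 - w, w)) / (2 * N)
    if (max(abs(new_f - f)) < tol) { f <- new_f; converged <- TRUE; break }
    f <- new_f
    if (it >= max_iter) break
  }
  list(f = f, iterations = it, converged = converged)
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies from unphased genotype counts,
#' treating the phase of double heterozygotes as missing data. The EM runs
#' from linkage-equilibrium and from both phase-boundary initializations,
#' returning the best-likelihood solution (the two-locus likelihood can be
#' multimodal and the equilibrium start sits on a symmetry point when the
#' double-heterozygote split is exactly even).
#'
#' @param counts 3x3 matrix from [two_locus_counts()].
#' @param tol Convergence tolerance on the maximum absolute haplotype
#'   frequency change (default `1e-10`).
#' @param max_iter Iteration cap per start (default 1000).
#' @return List of class `ld_result`: `haplotype_freqs` (named `AB`, `Ab`,
#'   `aB`, `ab`), `D`, `D_prime`, `r_squared`, `log_likelihood`,
#'   `iterations`, `converged`, `degenerate`.
#' @export
em_haplotype_frequencies <- function(counts, tol = 1e-10, max_iter = 1000L) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3L, 3L)), all(counts >= 0))
  N <- sum(counts)
  if (N < 1) stop("counts must contain at least one individual")
  if (tol <= 0) stop("tol must be > 0")
  pA <- sum(counts * (0:2)[row(counts)]) / (2 * N)
  pB <- sum(counts * (0:2)[col(counts)]) / (2 * N)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    warning("monomorphic locus: LD statistics reported as 0")
    f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
           ab = (1 - pA) * (1 - pB))
    return(structure(list(haplotype_freqs = f, D = 0, D_prime = 0,
                          r_squared = 0, log_likelihood = ld_loglik(counts, f),
                          iterations = 0L, converged = TRUE, degenerate = TRUE),
                     class = "ld_result"))
  }
  fixed <- fixed_hap_counts(counts)
  n11 <- counts[2, 2]
  le <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  hi <- min(pA, pB); lo <- max(0, pA + pB - 1)
  starts <- list(le,
                 c(hi, pA - hi, pB - hi, 1 - pA - pB + hi),
                 c(lo, pA - lo, pB - lo, 1 - pA - pB + lo))
  ## nudge boundary starts into the interior so every haplotype class has mass
  starts <- lapply(starts, function(s) { s <- pmax(s, 1e-8); s / sum(s) })
  fits <- lapply(starts, run_em, fixed = fixed, n11 = n11,
                 N = N, tol = tol, max_iter = max_iter)
  lls <- vapply(fits, function(x) ld_loglik(counts, x$f), numeric(1))
  best <- fits[[which.max(lls)]]
  f <- best$f
  names(f) <- c("AB", "Ab", "aB", "ab")
  stats <- ld_statistics(f)
  structure(list(haplotype_freqs = f, D = stats$D, D_prime = stats$D_prime,
                 r_squared = stats$r_squared, log_likelihood = max(lls),
                 iterations = best$iterations, converged = best$converged,
                 degenerate = isTRUE(stats$degenerate)),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("<ld_result> D = %.4g, D' = %.4g, r^2 = %.4g%s (logLik %.4f, %d iter%s)\n",
              x$D, x$D_prime, x$r_squared,
              if (x$degenerate) " [degenerate]" else "",
              x$log_likelihood, x$iterations,
              if (x$converged) "" else ", not converged"))
  cat("  haplotype freqs:",
      paste(sprintf("%s=%.5f", names(x$haplotype_freqs), x$haplotype_freqs),
            collapse = " "), "\n")
  invisible(x)
}

#' Pairwise LD statistics from haplotype frequencies
#'
#' `D = p_AB - p_A p_B`; `D' = |D| / D_max` with the usual allele-frequency
#' bound on `D_max` (defined as 0 when `D = 0`); `r^2 = D^2 / (p_A q_A p_B q_B)`.
#' A locus with allele frequency 0 or 1 yields a degenerate flag and zero
#' statistics.
#'
#' @param freqs Numeric vector `(p_AB, p_Ab, p_aB, p_ab)`, non-negative,
#'   summing to 1.
#' @return List `D`, `D_prime`, `r_squared`, `degenerate`.
#' @export
ld_statistics <- function(freqs) {
  stopifnot(length(freqs) == 4L, all(freqs >= -1e-12))
  if (abs(sum(freqs) - 1) > 1e-6) stop("haplotype frequencies must sum to 1")
  pA <- freqs[1] + freqs[2]
  pB <- freqs[1] + freqs[3]
  qA <- 1 - pA; qB <- 1 - pB
  if (min(pA, qA, pB, qB) <= 1e-12) {
    warning("allele frequency at 0 or 1: LD statistics reported as 0")
    return(list(D = 0, D_prime = 0, r_squared = 0, degenerate = TRUE))
  }
  D <- unname(freqs[1] - pA * pB)
  d_max <- if (D > 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  d_prime <- if (D == 0) 0 else abs(D) / d_max
  list(D = D, D_prime = unname(d_prime),
       r_squared = unname(D^2 / (pA * qA * pB * qB)), degenerate = FALSE)
}

#' Carrier summary for one locus
#'
#' A carrier has dosage >= 1 of the focal allele. When labels are supplied
#' (e.g. coat colours), a per-label carrier breakdown is included.
#'
#' @param dosages Integer vector in `{0, 1, 2}`.
#' @param labels Optional character vector of individual labels.
#' @return List `n_carriers`, `n_noncarriers`, `n_total`, `by_label`
#'   (data frame or `NULL`).
#' @export
carrier_summary <- function(dosages, labels = NULL) {
  if (length(dosages) && !all(dosages %in% 0:2)) stop("dosages must be 0, 1 or 2")
  carrier <- dosages >= 1L
  by_label <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(dosages))
    agg <- stats::aggregate(carrier, by = list(label = labels),
                            FUN = function(x) c(sum(x), length(x)))
    by_label <- data.frame(label = agg$label, n_carriers = agg$x[, 1],
                           n_total = agg$x[, 2], stringsAsFactors = FALSE)
  }
  list(n_carriers = sum(carrier), n_noncarriers = sum(!carrier),
       n_total = length(dosages), by_label = by_label)
}

#' Check for complete two-locus LD at the individual level
#'
#' `TRUE` iff every individual carries identical dosages at both loci
#' (vacuously `TRUE` for an empty cohort) — the observable signature of
#' complete LD between two variants in a genotyped cohort.
#'
#' @param dosage1,dosage2 Integer vectors in `{0, 1, 2}`, same length.
#' @return Logical scalar.
#' @export
complete_ld_check <- function(dosage1, dosage2) {
  stopifnot(length(dosage1) == length(dosage2))
  if (length(dosage1) == 0L) return(TRUE)
  all(dosage1 == dosage2)
}

#' Read a two-locus cohort genotype TSV
#'
#' Columns: `horse_id`, `locus1_dosage`, `locus2_dosage` and optionally
#' `coat_label`.
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("horse_id", "locus1_dosage", "locus2_dosage")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort file missing columns: ", paste(miss, collapse = ", "))
  df
}
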