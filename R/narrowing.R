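#' Narrow an IBD interval using flanking discordant markers
#'
#' Clusters of haplotype-discordant markers at the ends of a candidate
#' interval contradict the shared ancestral haplotype there and allow the
#' interval to be trimmed. Scanning inward from each end, the new 5' edge is
#' placed one base past the largest-coordinate discordant marker that lies
#' before the first concordant marker (the discordant site itself cannot be
#' on the disease haplotype, so its base is excluded); the 3' edge is
#' symmetric. A flank with no discordant markers leaves that edge unchanged.
#' Discordant markers between the outermost concordant markers are interior
#' contradictions: they are counted but do not move an edge.
#'
#' @param region A [genomic_interval()].
#' @param markers Data frame with columns `pos` and `status`
#'   (`"concordant"` / `"discordant"`; any other value is ignored). All
#'   positions must lie within `region`.
#' @return List of class `narrowing_result`: `original`, `narrowed`
#'   (both [genomic_interval()]), `excluded_5prime_bp`, `excluded_3prime_bp`,
#'   `boundary_markers` (positions defining each new edge, `NA` when an edge
#'   is unchanged) and `n_interior_discordant`.
#' @export
narrow_interval <- function(region, markers) {
  stopifnot(inherits(region, "genomic_interval"), is.data.frame(markers),
            all(c("pos", "status") %in% names(markers)))
  if (nrow(markers) && !all(interval_contains(region, markers$pos)))
    stop("marker positions outside region")
  conc <- sort(markers$pos[markers$status == "concordant"])
  disc <- sort(markers$pos[markers$status == "discordant"])
  if (length(disc) && !length(conc))
    stop("no IBD core remains: discordant markers but no concordant marker in region")

  new_start <- region$start
  new_end <- region$end
  b5 <- NA_real_; b3 <- NA_real_
  if (length(conc)) {
    d5 <- disc[disc < conc[1L]]
    if (length(d5)) { b5 <- max(d5); new_start <- b5 + 1 }
    d3 <- disc[disc > conc[length(conc)]]
    if (length(d3)) { b3 <- min(d3); new_end <- b3 - 1 }
  }
  narrowed <- genomic_interval(region$chrom, new_start, new_end)
  interior <- sum(disc > new_start & disc < new_end)
  structure(list(original = region, narrowed = narrowed,
                 excluded_5prime_bp = new_start - region$start,
                 excluded_3prime_bp = region$end - new_end,
                 boundary_markers = c(`5prime` = b5, `3prime` = b3),
                 n_interior_discordant = interior),
            class = "narrowing_result")
}

#' @export
print.narrowing_result <- function(x, ...) {
  cat(sprintf("<narrowing_result> %s:%d-%d -> %d-%d (excluded %d + %d bp, %0.1f kb remain)\n",
              x$original$chrom, as.integer(x$original$start), as.integer(x$original$end),
              as.integer(x$narrowed$start), as.integer(x$narrowed$end),
              as.integer(x$excluded_5prime_bp), as.integer(x$excluded_3prime_bp),
              interval_length(x$narrowed) / 1000))
  invisible(x)
}
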