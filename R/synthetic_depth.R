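#' Simulate per-base depth tracks
#'
#' Produces one integer depth track per sample over the interval. Inside a
#' planted CNV, samples listed in `cnv_samples` have expected depth
#' `mean_depth * copy_ratio`; everywhere else expected depth equals the
#' sample mean. Gaussian noise of standard deviation `noise_sd` is added,
#' rounded and floored at zero. Optional `gaps` (emulating unalignable
#' reference-genome gaps) zero the depth of every sample.
#'
#' @param region A [genomic_interval()].
#' @param samples Character vector of sample IDs.
#' @param mean_depths Per-sample mean depth, recycled (default 100; the
#'   depth scale is a knob because nothing downstream depends on absolute
#'   depth).
#' @param planted_cnvs List of `list(interval = genomic_interval,
#'   copy_ratio = )`, each interval within `region`.
#' @param cnv_samples Samples the CNVs apply to (e.g. the case samples).
#' @param noise_sd Depth noise standard deviation (default 0).
#' @param gaps List of [genomic_interval()] zeroed in all samples.
#' @param seed Integer seed.
#' @return A [depth_tracks()] object.
#' @export
simulate_depth_tracks <- function(region, samples, mean_depths = 100,
                                  planted_cnvs = list(), cnv_samples = character(),
                                  noise_sd = 0, gaps = list(), seed = 1L) {
  stopifnot(inherits(region, "genomic_interval"), length(samples) >= 1L)
  mean_depths <- rep(mean_depths, length.out = length(samples))
  if (any(mean_depths <= 0)) stop("mean_depths must be > 0")
  for (cnv in planted_cnvs) {
    iv <- cnv$interval
    if (iv$start < region$start || iv$end > region$end)
      stop("planted CNV outside region: ", iv$chrom, ":", iv$start, "-", iv$end)
  }
  set.seed(seed)
  L <- interval_length(region)
  offset <- function(iv) (iv$start - region$start + 1L):(iv$end - region$start + 1L)
  d <- matrix(0L, L, length(samples), dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    mu <- rep(mean_depths[j], L)
    if (samples[j] %in% cnv_samples)
      for (cnv in planted_cnvs) mu[offset(cnv$interval)] <- mean_depths[j] * cnv$copy_ratio
    x <- if (noise_sd > 0) stats::rnorm(L, mu, noise_sd) else mu
    d[, j] <- pmax(0L, as.integer(round(x)))
  }
  for (gap in gaps) d[offset(gap), ] <- 0L
  depth_tracks(region, d)
}
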