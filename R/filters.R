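#' Site-level filter configuration
#'
#' Defaults follow the sequencing study this pipeline models: PHRED site
#' quality strictly above 20, and site total depth between 50 and 100,000
#' reads (a varfilter-style band set relative to very deep amplicon
#' coverage). `quality_strict = FALSE` switches the quality comparison to
#' `>=` for callers whose convention is inclusive. An optional separate
#' (typically laxer) quality threshold can be given for indels.
#'
#' @param min_site_quality PHRED site-quality threshold (default 20).
#' @param min_depth,max_depth Inclusive site total-depth band (default
#'   50 to 100,000 reads).
#' @param quality_strict Logical; `TRUE` (default) keeps only qualities
#'   strictly greater than the threshold.
#' @param indel_min_quality Optional PHRED threshold applied to INDEL
#'   records instead of `min_site_quality`; `NULL` (default) applies the
#'   same threshold to both classes.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_site_quality = 20, min_depth = 50,
                          max_depth = 100000, quality_strict = TRUE,
                          indel_min_quality = NULL) {
  if (min_depth > max_depth) stop("min_depth must be <= max_depth")
  if (min_site_quality < 0 || min_depth < 0) stop("thresholds must be >= 0")
  structure(list(min_site_quality = min_site_quality, min_depth = min_depth,
                 max_depth = max_depth, quality_strict = isTRUE(quality_strict),
                 indel_min_quality = indel_min_quality),
            class = "filter_config")
}

#' Apply site quality and depth filters
#'
#' Partitions a variant table into records passing both the quality and the
#' depth criterion, and rejected records annotated with the reason(s)
#' (`quality`, `depth_low`, `depth_high`). Records with missing quality or
#' depth fail the corresponding criterion.
#'
#' @param vt A [variant_table()].
#' @param config A [filter_config()].
#' @return List with elements `kept` (a `variant_table`), `rejected` (a
#'   `variant_table`) and `reasons` (data frame `pos`, `reason`, one row per
#'   rejected record).
#' @export
apply_site_filters <- function(vt, config = filter_config()) {
  stopifnot(inherits(vt, "variant_table"), inherits(config, "filter_config"))
  qual <- vt$sites$qual
  thr <- rep(config$min_site_quality, n_variants(vt))
  if (!is.null(config$indel_min_quality))
    thr[vt$sites$class == "INDEL"] <- config$indel_min_quality
  q_ok <- if (config$quality_strict) qual > thr else qual >= thr
  q_ok[is.na(q_ok)] <- FALSE
  d_low <- is.na(vt$sites$depth) | vt$sites$depth < config$min_depth
  d_high <- !is.na(vt$sites$depth) & vt$sites$depth > config$max_depth
  keep <- q_ok & !d_low & !d_high

  reason <- character(0)
  pos <- numeric(0)
  if (any(!keep)) {
    idx <- which(!keep)
    tags <- lapply(idx, function(i) {
      r <- character(0)
      if (!q_ok[i]) r <- c(r, "quality")
      if (d_low[i]) r <- c(r, "depth_low")
      if (d_high[i]) r <- c(r, "depth_high")
      r
    })
    pos <- rep(vt$sites$pos[idx], lengths(tags))
    reason <- unlist(tags)
  }
  list(kept = vt[keep], rejected = vt[!keep],
       reasons = data.frame(pos = pos, reason = reason,
                            stringsAsFactors = FALSE))
}
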