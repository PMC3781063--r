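#' Per-base depth tracks for a set of samples
#'
#' @param interval A [genomic_interval()].
#' @param depth Integer matrix, `interval_length(interval)` rows, one column
#'   per sample (column names = sample IDs), all values >= 0.
#' @return Object of class `depth_tracks`.
#' @export
depth_tracks <- function(interval, depth) {
  stopifnot(inherits(interval, "genomic_interval"), is.matrix(depth))
  if (nrow(depth) != interval_length(interval))
    stop("depth matrix must have one row per base of the interval")
  if (is.null(colnames(depth))) stop("depth matrix needs sample IDs as column names")
  if (any(depth < 0)) stop("depths must be >= 0")
  structure(list(interval = interval, depth = depth), class = "depth_tracks")
}

#' @export
print.depth_tracks <- function(x, ...) {
  cat(sprintf("<depth_tracks> %s:%d-%d, %d samples, mean depth %.1f\n",
              x$interval$chrom, as.integer(x$interval$start),
              as.integer(x$interval$end), ncol(x$depth), mean(x$depth)))
  invisible(x)
}

#' Normalize depth tracks to mean 1
#'
#' Divides each sample's per-base depth by that sample's mean, removing
#' library-size differences so that case and control depths are comparable.
#' Bases that are zero in every sample (emulated reference-genome gaps) are
#' excluded from the mean and flagged in the `masked` attribute.
#'
#' @param tracks A [depth_tracks()] object.
#' @return Numeric matrix of normalized depths (same shape), with logical
#'   attribute `masked` marking all-zero gap bases. Each column's mean over
#'   unmasked bases is 1.
#' @export
normalize_depth <- function(tracks) {
  stopifnot(inherits(tracks, "depth_tracks"))
  d <- tracks$depth
  masked <- rowSums(d) == 0
  means <- colMeans(d[!masked, , drop = FALSE])
  if (all(masked) || any(!is.finite(means)) || any(means <= 0))
    stop("track with zero mean depth cannot be normalized")
  out <- sweep(d, 2L, means, `/`)
  attr(out, "masked") <- masked
  out
}

#' Case-versus-control relative coverage scan
#'
#' Tiles the interval with non-overlapping windows and computes, per window,
#' `log2(mean normalized case depth / mean normalized control depth)`.
#' Windows whose absolute statistic reaches `min_abs_log2` are reported as
#' copy-number calls, merged when adjacent with the same direction. Gap
#' bases (zero depth in all samples) are masked from window statistics and
#' windows with more than half their bases masked are skipped.
#'
#' @param case_tracks,control_tracks [depth_tracks()] over the same interval.
#' @param window_bp Window size in bp (default 500).
#' @param min_abs_log2 Call threshold on `|log2 ratio|` (default 0.58,
#'   i.e. about 1.5-fold, sized to catch a single-copy loss or gain).
#' @return Data frame of calls: `chrom`, `start`, `end`, `log2_ratio`
#'   (depth-weighted mean over merged windows), `direction` (`loss`/`gain`).
#' @export
relative_coverage_scan <- function(case_tracks, control_tracks,
                                   window_bp = 500L, min_abs_log2 = 0.58) {
  stopifnot(inherits(case_tracks, "depth_tracks"),
            inherits(control_tracks, "depth_tracks"), window_bp >= 1L)
  iv <- case_tracks$interval
  if (!identical(unclass(iv), unclass(control_tracks$interval)))
    stop("case and control tracks must share the same interval")
  L <- interval_length(iv)
  both <- cbind(case_tracks$depth, control_tracks$depth)
  masked <- rowSums(both) == 0
  case_n <- sweep(case_tracks$depth, 2L,
                  colMeans(case_tracks$depth[!masked, , drop = FALSE]), `/`)
  ctrl_n <- sweep(control_tracks$depth, 2L,
                  colMeans(control_tracks$depth[!masked, , drop = FALSE]), `/`)
  case_mean <- rowMeans(case_n)
  ctrl_mean <- rowMeans(ctrl_n)

  n_win <- ceiling(L / window_bp)
  win_id <- rep(seq_len(n_win), each = window_bp, length.out = L)
  keep <- !masked
  frac_masked <- tapply(masked, win_id, mean)
  w_case <- tapply(ifelse(keep, case_mean, NA), win_id, mean, na.rm = TRUE)
  w_ctrl <- tapply(ifelse(keep, ctrl_mean, NA), win_id, mean, na.rm = TRUE)
  stat <- log2(w_case / w_ctrl)
  usable <- frac_masked <= 0.5 & is.finite(stat)
  hit <- usable & abs(stat) >= min_abs_log2

  if (!any(hit)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      log2_ratio = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- which(hit)
  dir_ <- ifelse(stat[idx] > 0, "gain", "loss")
  grp <- cumsum(c(TRUE, diff(idx) != 1L | dir_[-1L] != dir_[-length(dir_)]))
  out <- do.call(rbind, lapply(split(seq_along(idx), grp), function(g) {
    w <- idx[g]
    data.frame(chrom = iv$chrom,
               start = iv$start + (min(w) - 1L) * window_bp,
               end = min(iv$start + max(w) * window_bp - 1L, iv$end),
               log2_ratio = mean(stat[w]), direction = dir_[g[1L]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate per-sample sequencing statistics
#'
#' Sums the yield column and averages the mapping and coverage columns of a
#' per-sample sequencing summary (total yield in Gb, percent reads mapped,
#' percent mapped to the target interval, mean target coverage).
#'
#' @param stats Data frame with columns `yield_gb`, `mapped_pct`,
#'   `ibd_mapped_pct`, `mean_coverage_x` (e.g. from [read_panel_stats()]).
#' @return List `n_samples`, `total_yield_gb`, `mean_coverage_x`,
#'   `mean_mapped_pct`, `mean_ibd_mapped_pct`.
#' @export
summarize_panel_stats <- function(stats) {
  req <- c("yield_gb", "mapped_pct", "ibd_mapped_pct", "mean_coverage_x")
  miss <- setdiff(req, names(stats))
  if (length(miss)) stop("stats table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(stats) == 0L) stop("stats table is empty")
  list(n_samples = nrow(stats),
       total_yield_gb = sum(stats$yield_gb),
       mean_coverage_x = mean(stats$mean_coverage_x),
       mean_mapped_pct = mean(stats$mapped_pct),
       mean_ibd_mapped_pct = mean(stats$ibd_mapped_pct))
}

#' Read a per-sample sequencing summary CSV
#'
#' @param path CSV with columns `id`, `phenotype`, `breed`, `yield_gb`,
#'   `mapped_pct`, `ibd_mapped_pct`, `mean_coverage_x`. The copy shipped
#'   with the package (`system.file("extdata", "panel_sequencing_summary.csv",
#'   package = "mcoamap")`) holds the ten-horse MCOA sequencing panel summary.
#' @return Data frame.
#' @export
read_panel_stats <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write per-base depth tables
#'
#' Tab-separated per-base depth: columns `chrom`, `pos`, then one depth
#' column per sample (pileup-style).
#'
#' @param tracks A [depth_tracks()] object.
#' @param path File path.
#' @return `path` invisibly, or a `depth_tracks` object.
#' @export
write_depth_tsv <- function(tracks, path) {
  stopifnot(inherits(tracks, "depth_tracks"))
  df <- data.table::data.table(chrom = tracks$interval$chrom,
                               pos = seq(tracks$interval$start, tracks$interval$end))
  df <- cbind(df, data.table::as.data.table(tracks$depth))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_depth_tsv
#' @export
read_depth_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  iv <- genomic_interval(df$chrom[1L], min(df$pos), max(df$pos))
  d <- as.matrix(df[, setdiff(names(df), c("chrom", "pos")), drop = FALSE])
  depth_tracks(iv, d[order(df$pos), , drop = FALSE])
}
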