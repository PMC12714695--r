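#' Call enriched regions from a fold-change track
#'
#' Maximal runs of bins at or above the threshold become candidate regions;
#' regions separated by at most `merge_gap` bins are merged, and regions
#' narrower than `min_width` bins are dropped. No significance testing is
#' performed, so no multiple-testing correction is needed.
#'
#' @param s_hat fold-change track (per bin).
#' @param bins matching `GRanges` bin map.
#' @param threshold fold-change threshold (default 2).
#' @param merge_gap maximum gap, in bins, across which adjacent regions are
#'   merged (default 2).
#' @param min_width minimum region width in bins (default 2; use ~5 for
#'   broad marks).
#' @param name region name (e.g. the mark), recorded in the output.
#' @return A `region_set`: `GRanges` with metadata columns `name`,
#'   `mean_fc`, `max_fc` and attributes `threshold`, `merge_gap`,
#'   `min_width`.
#' @export
call_regions <- function(s_hat, bins, threshold = 2, merge_gap = 2L,
                         min_width = 2L, name = "region") {
  stopifnot(length(s_hat) == length(bins), threshold > 0)
  binw <- max(width(bins))
  hit <- bins[s_hat >= threshold]
  merged <- GenomicRanges::reduce(hit, min.gapwidth = merge_gap * binw + 1L)
  ov <- GenomicRanges::findOverlaps(merged, bins)
  q <- S4Vectors::queryHits(ov)
  n_bins <- tabulate(q, nbins = length(merged))
  vals <- s_hat[S4Vectors::subjectHits(ov)]
  mcols(merged)$name <- rep(name, length(merged))
  mcols(merged)$mean_fc <- as.numeric(tapply(vals, factor(q, seq_along(merged)), mean))
  mcols(merged)$max_fc <- as.numeric(tapply(vals, factor(q, seq_along(merged)), max))
  merged <- merged[n_bins >= min_width]
  S4Vectors::metadata(merged) <- list(threshold = threshold,
                                      merge_gap = merge_gap,
                                      min_width = min_width)
  merged
}

#' Bin-level precision, recall and F1 of called regions against truth
#'
#' @param called `GRanges` of called regions.
#' @param truth `GRanges` of true regions.
#' @param bins `GRanges` bin map defining the evaluation units.
#' @return list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
evaluate_regions <- function(called, truth, bins) {
  in_called <- IRanges::overlapsAny(bins, called)
  in_truth <- IRanges::overlapsAny(bins, truth)
  tp <- sum(in_called & in_truth)
  fp <- sum(in_called & !in_truth)
  fn <- sum(!in_called & in_truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Sweep the fold-change threshold and report the best bin-level F1
#'
#' @param s_hat fold-change track.
#' @param bins `GRanges` bin map.
#' @param truth `GRanges` of true regions.
#' @param thresholds thresholds to try.
#' @param ... further arguments to [call_regions()].
#' @return list with `sweep` (data.frame of threshold/precision/recall/F1)
#'   and `best` (row with maximal F1).
#' @export
sweep_threshold <- function(s_hat, bins, truth,
                            thresholds = seq(1.2, 8, by = 0.2), ...) {
  rows <- lapply(thresholds, function(thr) {
    called <- call_regions(s_hat, bins, threshold = thr, ...)
    ev <- evaluate_regions(called, truth, bins)
    data.frame(threshold = thr, precision = ev$precision,
               recall = ev$recall, f1 = ev$f1)
  })
  sweep <- do.call(rbind, rows)
  list(sweep = sweep, best = sweep[which.max(sweep$f1), ])
}

#' Write regions as BED6 plus a statistics TSV
#'
#' The BED score is the mean fold-change scaled by 100 and capped at 1000;
#' the accompanying `.tsv` keeps the unscaled statistics. Files round-trip
#' byte-identically through [read_regions()].
#'
#' @param regions a [call_regions()] result.
#' @param path output BED path (the TSV gets the same path with `.tsv`).
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L, end = end(regions),
                   name = mcols(regions)$name,
                   score = pmin(round(100 * mcols(regions)$mean_fc), 1000L),
                   strand = ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  stats <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                      name = df$name,
                      mean_fc = sprintf("%.10g", mcols(regions)$mean_fc),
                      max_fc = sprintf("%.10g", mcols(regions)$max_fc))
  write.table(stats, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read regions written by [write_regions()]
#'
#' @param path BED path (its `.tsv` sidecar must sit next to it).
#' @return `GRanges` with `name`, `mean_fc`, `max_fc` metadata columns.
#' @export
read_regions <- function(path) {
  stats <- read.csv(paste0(path, ".tsv"), sep = "\t",
                    colClasses = c(mean_fc = "character",
                                   max_fc = "character"))
  GRanges(stats$chrom, IRanges(stats$start + 1L, stats$end),
          name = stats$name,
          mean_fc = as.numeric(stats$mean_fc),
          max_fc = as.numeric(stats$max_fc))
}
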