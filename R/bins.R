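#' Tile a genome into contiguous fixed-width bins
#'
#' Bins are contiguous, non-overlapping and cover each chromosome completely;
#' the last bin of a chromosome may be shorter than `bin_width`.
#'
#' @param seqlengths named integer vector of chromosome lengths (bp).
#' @param bin_width bin width in bp (default 200).
#' @return A `GRanges` of bins carrying the genome's `seqinfo`.
#' @examples
#' genome_bins(c(chr1 = 1000), bin_width = 200)
#' @export
genome_bins <- function(seqlengths, bin_width = 200) {
  stopifnot(length(seqlengths) > 0, !is.null(names(seqlengths)), bin_width >= 1)
  tiles <- GenomicRanges::tileGenome(seqlengths, tilewidth = bin_width,
                                     cut.last.tile.in.chrom = TRUE)
  tiles
}

#' Average per-bin coverage of weighted intervals
#'
#' Computes, for each bin, the base-pair pileup of the (weighted) intervals
#' averaged over the bin's true width: `sum(overlap_bp * weight) / width(bin)`.
#' Intervals on chromosomes absent from `bins` are skipped; their count is
#' attached as attribute `n_skipped`.
#'
#' @param intervals `GRanges` of (extended) read intervals; an optional
#'   numeric metadata column `weight` gives the per-read weight (default 1).
#' @param bins bins from [genome_bins()].
#' @return Numeric vector of length `length(bins)`.
#' @export
bin_coverage <- function(intervals, bins) {
  weight <- mcols(intervals)$weight %||% rep(1, length(intervals))
  known <- as.character(seqnames(intervals)) %in% seqlevels(bins)
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    intervals <- intervals[known]
    weight <- weight[known]
  }
  gr <- GRanges(seqnames(intervals), ranges(intervals),
                seqinfo = seqinfo(bins))
  gr <- GenomicRanges::trim(gr)
  cov <- GenomicRanges::coverage(gr, weight = weight)
  avg <- GenomicRanges::binnedAverage(bins, cov, "cvg")
  structure(mcols(avg)$cvg, n_skipped = n_skipped)
}

#' Construct a set of binned coverage tracks
#'
#' Container for the G x N matrix of per-bin average coverage, one column per
#' sample, with its bin map and sample metadata. Columns are ordered with all
#' control samples first, then treatments grouped by condition.
#'
#' @param bins `GRanges` bin map.
#' @param values non-negative numeric matrix, `length(bins)` rows and one
#'   column per sample.
#' @param samples a [parse_sample_sheet()] result (or equivalent data.frame)
#'   describing the columns, in column order.
#' @param fragment_lengths optional named vector of fragment lengths (bp) per
#'   condition.
#' @return A `binned_tracks` object.
#' @export
binned_tracks <- function(bins, values, samples, fragment_lengths = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(bins), ncol(values) == nrow(samples))
  if (any(values < 0)) stop("coverage values must be non-negative")
  if (is.unsorted(!samples$is_control))  # controls must come first
    stop("sample columns must be ordered controls first")
  colnames(values) <- paste0(samples$condition, "_rep", samples$replicate)
  structure(list(bins = bins, values = values,
                 samples = as.data.frame(samples),
                 fragment_lengths = fragment_lengths,
                 conditions = attr(samples, "conditions") %||%
                   c(unique(samples$condition[samples$is_control]),
                     unique(samples$condition[!samples$is_control]))),
            class = "binned_tracks")
}

#' @export
print.binned_tracks <- function(x, ...) {
  cat(sprintf("binned_tracks: %d bins x %d samples (%d condition(s))\n",
              nrow(x$values), ncol(x$values), length(x$conditions)))
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  bin width :", max(width(x$bins)), "bp\n")
  invisible(x)
}

#' Remove blacklisted bins from binned tracks
#'
#' Every bin overlapping any blacklist interval (by at least 1 bp) is removed
#' from all columns. The removed bin indices are retained in attribute
#' `removed_bins` for coordinate round-trips. An empty blacklist is the
#' identity.
#'
#' @param tracks a [binned_tracks()] object.
#' @param blacklist `GRanges` of regions to exclude (e.g. an ENCODE-style
#'   blacklist read with [rtracklayer::import.bed()]), or `NULL`.
#' @return A filtered `binned_tracks` object.
#' @export
apply_blacklist <- function(tracks, blacklist) {
  stopifnot(inherits(tracks, "binned_tracks"))
  if (is.null(blacklist) || length(blacklist) == 0L) {
    attr(tracks, "removed_bins") <- integer(0)
    return(tracks)
  }
  hit <- IRanges::overlapsAny(tracks$bins, blacklist, minoverlap = 1L)
  out <- tracks
  out$bins <- tracks$bins[!hit]
  out$values <- tracks$values[!hit, , drop = FALSE]
  attr(out, "removed_bins") <- which(hit)
  out
}

#' Write a per-bin signal track as bedGraph
#'
#' @param bins `GRanges` bin map.
#' @param values numeric vector, one value per bin.
#' @param path output file path (0-based half-open bedGraph).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, values, path) {
  stopifnot(length(bins) == length(values))
  gr <- bins
  mcols(gr) <- NULL
  gr$score <- as.numeric(values)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path path to a 4-column bedGraph.
#' @return `GRanges` with a numeric `score` column.
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import.bedGraph(path)
}
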