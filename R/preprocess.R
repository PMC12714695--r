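#' Preprocess samples into a binned, normalized coverage matrix
#'
#' Runs the full preprocessing chain for every sample in the sheet: read the
#' alignments (BAM) or pre-computed coverage (bedGraph), estimate one fragment
#' length per treatment condition (control = median of those), extend reads,
#' weight each library to a 25-million-read total, average the weighted pileup
#' over fixed-width bins, and remove blacklisted bins.
#'
#' bedGraph inputs are taken as already-extended coverage; their
#' reads-equivalent library size is `sum(score * width) / fragment_length`,
#' and the fragment length must then be supplied via `fragment_lengths`
#' (default 200 bp otherwise).
#'
#' @param sheet a [parse_sample_sheet()] result.
#' @param seqlengths named chromosome lengths (bp); when `NULL`, taken from
#'   the first BAM header.
#' @param bin_width bin width in bp (default 200).
#' @param blacklist optional `GRanges` of regions to exclude.
#' @param target library-size normalization target (reads; default 25e6).
#' @param fragment_lengths optional named per-condition fragment lengths (bp)
#'   overriding estimation.
#' @param shift_range fragment-length search range in bp.
#' @return A [binned_tracks()] object.
#' @export
preprocess_samples <- function(sheet, seqlengths = NULL, bin_width = 200,
                               blacklist = NULL, target = 25e6,
                               fragment_lengths = NULL,
                               shift_range = c(50L, 500L)) {
  stopifnot(inherits(sheet, "sample_sheet"))
  is_bam <- grepl("\\.bam$", sheet$filepath, ignore.case = TRUE)
  reads <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet)))
    reads[[i]] <- if (is_bam[i]) read_alignments(sheet$filepath[i])
                  else read_bedgraph(sheet$filepath[i])

  if (is.null(seqlengths)) {
    withlen <- Filter(function(g) !all(is.na(seqlengths(g))), reads)
    if (!length(withlen))
      stop("seqlengths must be given when no input carries chromosome lengths")
    seqlengths <- seqlengths(withlen[[1]])
  }
  bins <- genome_bins(seqlengths, bin_width)

  if (is.null(fragment_lengths)) {
    if (any(is_bam[!sheet$is_control])) {
      idx <- which(is_bam)
      fragment_lengths <- estimate_fragment_lengths(reads[idx], sheet[idx, ],
                                                    shift_range)
    }
    # conditions not covered (e.g. bedGraph-only) fall back to the default
    missing <- setdiff(attr(sheet, "conditions"), names(fragment_lengths))
    fragment_lengths <- c(fragment_lengths,
                          stats::setNames(rep(200, length(missing)), missing))
  }

  values <- matrix(0, length(bins), nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    cond <- sheet$condition[i]
    fl <- fragment_lengths[[cond]]
    if (is_bam[i]) {
      role <- if (sheet$is_control[i]) "control" else "treatment"
      ext <- extend_reads(reads[[i]], fl, role)
      ext <- normalize_library(ext, target)
      values[, i] <- bin_coverage(ext, bins)
    } else {
      gr <- reads[[i]]
      mcols(gr)$weight <- gr$score
      raw <- bin_coverage(gr, bins)
      n_equiv <- sum(as.numeric(gr$score) * width(gr)) / fl
      if (n_equiv <= 0) stop("empty coverage in ", sheet$filepath[i])
      values[, i] <- raw * (target / n_equiv)
    }
  }
  tracks <- binned_tracks(bins, values, sheet, fragment_lengths)
  apply_blacklist(tracks, blacklist)
}
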