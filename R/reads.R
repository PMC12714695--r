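#' Read aligned reads from a BAM file
#'
#' Loads mapped, QC-passing, non-duplicate primary alignments as genomic
#' intervals. Alignment, duplicate marking and quality filtering are assumed
#' done upstream; reads failing vendor QC, PCR duplicates and unmapped reads
#' are excluded here.
#'
#' @param path path to a BAM file.
#' @return `GRanges` with strand set from the alignment.
#' @export
read_alignments <- function(path) {
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE,
                                  isNotPassingQualityControls = FALSE,
                                  isSecondaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("rname", "pos", "strand", "qwidth"))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(res$pos)
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  GRanges(res$rname[keep],
          IRanges(start = res$pos[keep], width = res$qwidth[keep]),
          strand = res$strand[keep],
          seqlengths = hdr)
}

#' Estimate fragment length by strand cross-correlation
#'
#' Counts 5' read ends per base on each strand and scans shifts of the
#' minus-strand profile against the plus-strand profile; the shift maximizing
#' the cross-correlation is the fragment-length estimate.
#'
#' @param reads `GRanges` of aligned reads with strand.
#' @param shift_range integer vector `c(min, max)` of candidate shifts in bp
#'   (default 50--500).
#' @return Estimated fragment length in bp.
#' @export
estimate_fragment_length <- function(reads, shift_range = c(50L, 500L)) {
  shifts <- seq.int(shift_range[1], shift_range[2])
  plus <- reads[strand(reads) == "+"]
  minus <- reads[strand(reads) == "-"]
  if (length(plus) == 0L || length(minus) == 0L)
    stop("fragment-length estimation needs reads on both strands (",
         length(plus), " plus / ", length(minus), " minus reads found)")
  score <- numeric(length(shifts))
  for (chr in unique(as.character(seqnames(reads)))) {
    p5 <- start(plus[seqnames(plus) == chr])
    m5 <- end(minus[seqnames(minus) == chr])
    if (!length(p5) || !length(m5)) next
    L <- max(p5, m5) + 1L
    pc <- tabulate(p5, nbins = L)
    mc <- tabulate(m5, nbins = L)
    for (i in seq_along(shifts)) {
      s <- shifts[i]
      score[i] <- score[i] + sum(pc[seq_len(L - s)] * mc[seq_len(L - s) + s])
    }
  }
  if (all(score == 0))
    stop("strand cross-correlation is flat; cannot estimate fragment length")
  shifts[which.max(score)]
}

#' Estimate fragment lengths for all conditions
#'
#' One fragment length is estimated per treatment condition (pooling its
#' replicates); the control condition's length is the median of the treatment
#' estimates.
#'
#' @param reads_by_sample list of `GRanges`, one per sample, in sample-sheet
#'   order.
#' @param sheet the matching [parse_sample_sheet()] result.
#' @param shift_range passed to [estimate_fragment_length()].
#' @return Named numeric vector of fragment lengths (bp), one per condition.
#' @export
estimate_fragment_lengths <- function(reads_by_sample, sheet,
                                      shift_range = c(50L, 500L)) {
  stopifnot(length(reads_by_sample) == nrow(sheet))
  treat_conds <- unique(sheet$condition[!sheet$is_control])
  if (length(treat_conds) == 0L)
    stop("no treatment condition to estimate fragment lengths from")
  est <- vapply(treat_conds, function(cond) {
    pooled <- do.call(c, unname(reads_by_sample[sheet$condition == cond]))
    estimate_fragment_length(pooled, shift_range)
  }, numeric(1))
  ctrl_conds <- unique(sheet$condition[sheet$is_control])
  out <- c(stats::setNames(rep(stats::median(est), length(ctrl_conds)), ctrl_conds), est)
  out
}

#' Extend reads to fragment length
#'
#' Treatment reads are extended in the 5' to 3' direction to the fragment
#' length; control reads are extended equally in both directions about their
#' midpoint. Extensions past chromosome ends are clipped.
#'
#' @param reads `GRanges` of aligned reads.
#' @param fragment_length target length in bp.
#' @param role `"treatment"` or `"control"`.
#' @return `GRanges` of extended intervals.
#' @export
extend_reads <- function(reads, fragment_length, role = c("treatment", "control")) {
  role <- match.arg(role)
  stopifnot(fragment_length > 0)
  fix <- if (role == "treatment") "start" else "center"
  # resizing may step past chromosome bounds before the clip; that is expected
  out <- suppressWarnings(GenomicRanges::resize(reads, width = fragment_length,
                                                fix = fix))
  suppressWarnings(GenomicRanges::trim(out))
}

#' Normalize a library to a fixed total of 25 million reads
#'
#' Assigns each read the weight `target / n_reads`, so the weighted read
#' total equals `target` exactly. Weighting (rather than subsampling) keeps
#' the result deterministic.
#'
#' @param reads `GRanges` of read intervals.
#' @param target target library size (default 25 million reads).
#' @return `reads` with a numeric metadata column `weight`.
#' @export
normalize_library <- function(reads, target = 25e6) {
  n <- length(reads)
  if (n == 0L) stop("cannot normalize an empty library")
  mcols(reads)$weight <- rep(target / n, n)
  reads
}
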