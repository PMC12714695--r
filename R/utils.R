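#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- Rle runValue
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths seqlengths<- seqnames keepSeqlevels Seqinfo seqinfo
#' @importFrom stats rpois rnbinom rnorm rbeta runif setNames
#' @importFrom utils read.csv write.csv write.table head tail
#' @importFrom tools md5sum
#' @importFrom grDevices hcl.colors
#' @importFrom graphics image lines legend par axis
NULL

# machine guard for divisions/logs inside the factorization
.EPS <- 1e-12

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb the
#' caller's random number stream. With `seed = NULL` the expression runs on the
#' current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed derivation; kept well below .Machine$integer.max
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147480000L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
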