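#' @importFrom stats plogis qlogis pnorm rbinom rnorm rpois runif sd
#'   wilcox.test phyper quantile median setNames predict coef simulate
#'   residuals
#' @importFrom graphics plot abline
#' @importFrom utils combn read.table write.table head
#' @importFrom Rcpp evalCpp
#' @useDynLib ernapred, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert 0-based half-open intervals to a GRanges
#'
#' All coordinates inside the package are 0-based half-open (BED convention);
#' GenomicRanges is 1-based closed, so conversion happens only at call sites
#' that delegate interval arithmetic.
#'
#' @param x data.frame with columns chrom, start, end (0-based half-open).
#' @return A \code{GRanges} object.
#' @keywords internal
#' @noRd
as_granges0 <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

## GRanges of width-1 positions from 0-based base coordinates
as_granges_pos <- function(chrom, pos0) {
  GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = pos0 + 1L, width = 1L)
  )
}

## edge-to-edge gap (0 if overlapping/adjacent) from each range in x to the
## nearest range in y; Inf when y has no range on x's chromosome
gap_to_nearest <- function(x_gr, y_gr) {
  out <- rep(Inf, length(x_gr))
  if (length(y_gr) == 0L || length(x_gr) == 0L) return(out)
  hits <- GenomicRanges::distanceToNearest(x_gr, y_gr, ignore.strand = TRUE)
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

validate_intervals <- function(x, what = "interval") {
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: start=%s end=%s (need 0 <= start < end)",
                 what, bad[1], x$start[bad[1]], x$end[bad[1]]), call. = FALSE)
  }
  invisible(x)
}

#' Derive a reproducible stage seed from a global seed and a stage name
#'
#' Stages of the pipeline each consume their own RNG stream so they can be
#' re-run independently yet reproducibly. The stage seed is the global seed
#' offset by a small hash of the stage name, kept below 2^31.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 977L + h * 131L) %% 2147483647)
}
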