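#' Define the intergenic enhancer catalog
#'
#' Candidate enhancer peaks (P300-bound, or H3K4me1-enriched for the broader
#' catalog) are retained when they lie outside every gene body and their
#' signal window -- \code{window_half_bp} either side of the peak midpoint --
#' is at least \code{exclusion_bp} from every TSS and from every
#' H3K4me3-enriched region. Distances are edge-to-edge gaps (0 when
#' overlapping), so a window overlapping an H3K4me3 region is removed.
#'
#' @param peaks data.frame of candidate peaks (chrom, start, end, optional
#'   name), 0-based half-open.
#' @param genes gene table from [read_gene_table()].
#' @param k4me3_regions data.frame of H3K4me3-enriched regions.
#' @param exclusion_bp minimum gap to any TSS or H3K4me3 region (default
#'   3000).
#' @param window_half_bp half-width of the signal window around the peak
#'   midpoint (default 1000).
#' @param provenance catalog source label, \code{"P300"} or
#'   \code{"H3K4me1+me3-"}.
#' @return data.frame of class \code{enhancer_catalog}: \code{id},
#'   \code{chrom}, \code{start}, \code{end} (the signal window),
#'   \code{peak_start}, \code{peak_end}, \code{provenance},
#'   \code{mean_mappability} (NA until the mappability filter runs).
#' @export
define_intergenic_enhancers <- function(peaks, genes, k4me3_regions,
                                        exclusion_bp = 3000,
                                        window_half_bp = 1000,
                                        provenance = c("P300", "H3K4me1+me3-")) {
  provenance <- match.arg(provenance)
  if (nrow(peaks) == 0L) {
    warning("empty peak set: catalog is empty")
    return(empty_catalog(provenance))
  }
  validate_intervals(peaks, "peak")
  mid <- (peaks$start + peaks$end) %/% 2L
  win <- data.frame(chrom = peaks$chrom,
                    start = pmax(mid - window_half_bp, 0L),
                    end = mid + window_half_bp)
  peak_gr <- as_granges0(peaks)
  win_gr <- as_granges0(win)

  body_gr <- as_granges0(data.frame(chrom = genes$chrom, start = genes$body_start,
                                    end = genes$body_end))
  in_body <- GenomicRanges::countOverlaps(peak_gr, body_gr) > 0L
  tss_gr <- as_granges_pos(genes$chrom, genes$tss)
  tss_gap <- gap_to_nearest(win_gr, tss_gr)
  k4_gap <- if (nrow(k4me3_regions)) {
    gap_to_nearest(win_gr, as_granges0(k4me3_regions))
  } else rep(Inf, nrow(peaks))

  keep <- !in_body & tss_gap >= exclusion_bp & k4_gap >= exclusion_bp
  ids <- if (!is.null(peaks$name) && !anyNA(peaks$name)) {
    as.character(peaks$name)
  } else sprintf("enh_%05d", seq_len(nrow(peaks)))
  nk <- sum(keep)
  out <- data.frame(id = ids[keep], chrom = peaks$chrom[keep],
                    start = win$start[keep], end = win$end[keep],
                    peak_start = peaks$start[keep], peak_end = peaks$end[keep],
                    provenance = rep(provenance, nk),
                    mean_mappability = rep(NA_real_, nk), stringsAsFactors = FALSE)
  class(out) <- c("enhancer_catalog", "data.frame")
  out
}

empty_catalog <- function(provenance) {
  out <- data.frame(id = character(), chrom = character(), start = integer(),
                    end = integer(), peak_start = integer(), peak_end = integer(),
                    provenance = character(), mean_mappability = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("enhancer_catalog", "data.frame")
  out
}

#' Filter enhancers by mean mappability
#'
#' The length-weighted mean mappability of each enhancer window is computed
#' from the mappability track; bases not covered by any segment count as 0
#' (conservative). Enhancers with mean below \code{min_mean} are dropped --
#' the threshold is a strict less-than, so a mean exactly at the boundary is
#' kept.
#'
#' @param enhancers an \code{enhancer_catalog}.
#' @param mappability data.frame from [read_mappability()].
#' @param min_mean drop threshold (default 0.85).
#' @return The filtered catalog with \code{mean_mappability} filled in.
#' @export
apply_mappability_filter <- function(enhancers, mappability, min_mean = 0.85) {
  if (nrow(enhancers) == 0L) return(enhancers)
  win_gr <- as_granges0(enhancers)
  map_gr <- as_granges0(mappability)
  hits <- GenomicRanges::findOverlaps(win_gr, map_gr)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::pintersect(IRanges::ranges(win_gr)[q], IRanges::ranges(map_gr)[s])
  wsum <- rowsum(IRanges::width(ov) * mappability$value[s], q)
  mean_map <- rep(0, nrow(enhancers))
  mean_map[as.integer(rownames(wsum))] <- wsum[, 1] / (enhancers$end - enhancers$start)[as.integer(rownames(wsum))]
  enhancers$mean_mappability <- mean_map
  out <- enhancers[!(mean_map < min_mean), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_erna_signal <- function(x, y_plus = NULL, y_minus = NULL) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (any(!is.finite(x))) stop("signal matrix contains non-finite values", call. = FALSE)
  structure(list(x = x, y_plus = y_plus, y_minus = y_minus),
            class = "erna_signal")
}

#' @export
print.erna_signal <- function(x, ...) {
  cat(sprintf("signal matrix: %d enhancers x %d mark tracks%s\n",
              nrow(x$x), ncol(x$x),
              if (!is.null(x$y_plus)) " (+ stranded GRO-seq)" else ""))
  cat("  marks:", paste(colnames(x$x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.erna_signal <- function(x) dim(x$x)

#' Compute the log-density signal matrix
#'
#' For each track and enhancer window, the average read density is the
#' number of reads whose midpoint falls in the window, per kb of window, per
#' million total reads in the track; the stored value is
#' \code{log_base(density + pseudocount)}. GRO-seq densities are computed
#' separately for the sense and antisense strands. Midpoint assignment
#' avoids double-counting reads at window edges; the value is invariant to
#' uniform sequencing-depth changes.
#'
#' @param enhancers an \code{enhancer_catalog}.
#' @param tracks named list of unstranded read data.frames (one per mark).
#' @param gro_reads stranded read data.frame (strand \code{+}/\code{-}), or
#'   \code{NULL} when GRO-seq is unavailable (prediction-only use).
#' @param pseudocount added before the log (default 1).
#' @param log_base logarithm base (default 2).
#' @return An \code{erna_signal}: list with matrix \code{x} (enhancers x
#'   marks) and numeric \code{y_plus}, \code{y_minus}.
#' @export
compute_signal_matrix <- function(enhancers, tracks, gro_reads = NULL,
                                  pseudocount = 1, log_base = 2) {
  stopifnot(nrow(enhancers) > 0L, length(tracks) > 0L)
  win_gr <- as_granges0(enhancers)
  kb <- (enhancers$end - enhancers$start) / 1000
  one_track <- function(reads, label) {
    tot <- nrow(reads)
    if (tot == 0L) stop("track with zero total reads: ", label, call. = FALSE)
    mids <- (reads$start + reads$end) %/% 2L
    cnt <- GenomicRanges::countOverlaps(win_gr, as_granges_pos(reads$chrom, mids))
    dens <- (cnt / kb) / (tot / 1e6)
    log(dens + pseudocount, base = log_base)
  }
  x <- vapply(names(tracks), function(mk) one_track(tracks[[mk]], mk),
              numeric(nrow(enhancers)))
  x <- matrix(x, nrow = nrow(enhancers),
              dimnames = list(enhancers$id, names(tracks)))
  y_plus <- y_minus <- NULL
  if (!is.null(gro_reads)) {
    if (!all(gro_reads$strand %in% c("+", "-"))) {
      stop("GRO-seq reads must all be stranded (+/-)", call. = FALSE)
    }
    y_plus <- one_track(gro_reads[gro_reads$strand == "+", , drop = FALSE], "GRO+")
    y_minus <- one_track(gro_reads[gro_reads$strand == "-", , drop = FALSE], "GRO-")
  }
  new_erna_signal(x, y_plus, y_minus)
}

#' Subset an erna_signal by enhancer ids
#' @param signal an \code{erna_signal}.
#' @param ids enhancer ids to keep, in order.
#' @return An \code{erna_signal} restricted to \code{ids}.
#' @export
signal_subset <- function(signal, ids) {
  idx <- match(ids, rownames(signal$x))
  if (anyNA(idx)) stop("unknown enhancer id(s) in subset", call. = FALSE)
  new_erna_signal(signal$x[idx, , drop = FALSE],
                  signal$y_plus[idx], signal$y_minus[idx])
}
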