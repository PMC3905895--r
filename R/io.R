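#' Read a BED file of intervals or mapped reads
#'
#' Parses BED3/BED6: the first three columns (chrom, start, end) are
#' mandatory; columns 4-6 (name, score, strand) are used when present.
#' Coordinates are kept 0-based half-open throughout the package. Lines
#' beginning with \code{track}, \code{browser} or \code{#} are skipped.
#'
#' @param path path to a BED file.
#' @param stranded if \code{TRUE}, require a strand column (field 6) and fail
#'   when it is absent or not \code{+}/\code{-}.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{score}, \code{strand} (\code{"*"} when unstranded),
#'   one row per input line, input order preserved.
#' @export
read_bed <- function(path, stranded = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1]
    stop(sprintf("BED parse error at line %d of %s: fewer than 3 fields",
                 lineno[i], path), call. = FALSE)
  }
  if (stranded && any(nf < 6L)) {
    i <- which(nf < 6L)[1]
    stop(sprintf("BED parse error at line %d of %s: strand column required but absent",
                 lineno[i], path), call. = FALSE)
  }
  grab <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_, "")
  start <- suppressWarnings(as.integer(grab(2)))
  end <- suppressWarnings(as.integer(grab(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d of %s: bad coordinates '%s'",
                 lineno[bad[1]], path, lines[bad[1]]), call. = FALSE)
  }
  strand <- grab(6)
  strand[is.na(strand)] <- "*"
  if (stranded) {
    badstr <- which(!strand %in% c("+", "-"))
    if (length(badstr)) {
      stop(sprintf("BED parse error at line %d of %s: strand must be + or -, got '%s'",
                   lineno[badstr[1]], path, strand[badstr[1]]), call. = FALSE)
    }
  } else {
    strand[!strand %in% c("+", "-")] <- "*"
  }
  score <- suppressWarnings(as.numeric(grab(5)))
  data.frame(chrom = grab(1), start = start, end = end,
             name = grab(4), score = score, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' Inverse of [read_bed()]: writes as many of the BED3..BED6 columns as the
#' input carries, so that \code{read_bed} then \code{write_bed} round-trips.
#'
#' @param x data.frame as returned by [read_bed()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, as.integer(x$start), as.integer(x$end))
  has_name <- !is.null(x$name) && any(!is.na(x$name))
  has_score <- !is.null(x$score) && any(!is.na(x$score))
  has_strand <- !is.null(x$strand) && any(x$strand %in% c("+", "-"))
  if (has_name || has_score || has_strand) cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
  if (has_score || has_strand) {
    sc <- x$score %||% rep(NA_real_, nrow(x))
    cols <- c(cols, list(ifelse(is.na(sc), 0, sc)))
  }
  if (has_strand) cols <- c(cols, list(x$strand))
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read a minimal gene annotation table
#'
#' Expects a tab-separated table with columns \code{gene_id}, \code{chrom},
#' \code{strand}, \code{txStart}, \code{txEnd} (refFlat-like; header lines
#' start with \code{#}). The TSS is computed strand-aware: for \code{+} genes
#' it is \code{txStart}; for \code{-} genes the last base, \code{txEnd - 1}
#' (0-based), since the TSS is the 5' end on the gene's own strand.
#'
#' @param path path to the gene table.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{tss}, \code{body_start}, \code{body_end}.
#' @export
read_gene_table <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  col.names = c("gene_id", "chrom", "strand", "txStart", "txEnd"),
                  colClasses = c("character", "character", "character", "integer", "integer"))
  bad <- which(!x$strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("gene table: unknown strand '%s' for gene %s",
                 x$strand[bad[1]], x$gene_id[bad[1]]), call. = FALSE)
  }
  validate_intervals(data.frame(start = x$txStart, end = x$txEnd), "gene body")
  data.frame(gene_id = x$gene_id, chrom = x$chrom, strand = x$strand,
             tss = ifelse(x$strand == "+", x$txStart, x$txEnd - 1L),
             body_start = x$txStart, body_end = x$txEnd,
             stringsAsFactors = FALSE)
}

#' Read a mappability track
#'
#' BED4-with-value: chrom, start, end, value in [0, 1]. Segments on one
#' chromosome must not overlap.
#'
#' @param path path to the mappability file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{value}.
#' @export
read_mappability <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  col.names = c("chrom", "start", "end", "value"),
                  colClasses = c("character", "integer", "integer", "numeric"))
  validate_intervals(x, "mappability segment")
  bad <- which(x$value < 0 | x$value > 1 | is.na(x$value))
  if (length(bad)) {
    stop(sprintf("mappability value out of [0,1] at row %d: %s",
                 bad[1], x$value[bad[1]]), call. = FALSE)
  }
  for (chr in unique(x$chrom)) {
    xi <- x[x$chrom == chr, ]
    xi <- xi[order(xi$start), ]
    if (nrow(xi) > 1L && any(xi$start[-1] < xi$end[-nrow(xi)])) {
      stop("overlapping mappability segments on ", chr, call. = FALSE)
    }
  }
  x
}

#' Read a gene expression table
#'
#' Tab-separated \code{gene_id}, \code{fpkm}; FPKM must be non-negative.
#'
#' @param path path to the expression table.
#' @return data.frame with columns \code{gene_id}, \code{fpkm}.
#' @export
read_expression <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  col.names = c("gene_id", "fpkm"),
                  colClasses = c("character", "numeric"))
  if (any(x$fpkm < 0 | is.na(x$fpkm))) stop("negative or missing FPKM", call. = FALSE)
  x
}

#' Write a table with a '#'-prefixed header line
#' @param x data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv_commented <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(x), collapse = "\t")), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path, colClasses = NA) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  x <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  col.names = cols, colClasses = colClasses)
  x
}

#' Write / read a signal matrix
#'
#' The signal matrix holds the log-transformed average read density of every
#' mark (columns) at every enhancer (rows) plus the stranded GRO-seq log
#' densities \code{y_plus}, \code{y_minus}. Serialized as TSV with a
#' \code{#} header naming tracks.
#'
#' @param signal an \code{erna_signal} object from [compute_signal_matrix()].
#' @param path file path.
#' @return \code{path} (write) or an \code{erna_signal} (read).
#' @export
write_signal_matrix <- function(signal, path) {
  stopifnot(inherits(signal, "erna_signal"))
  df <- data.frame(enhancer_id = rownames(signal$x), signal$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(signal$y_plus)) {
    df$y_plus <- signal$y_plus
    df$y_minus <- signal$y_minus
  }
  write_tsv_commented(df, path)
}

#' @rdname write_signal_matrix
#' @export
read_signal_matrix <- function(path) {
  df <- read_tsv_commented(path)
  ids <- as.character(df$enhancer_id)
  yp <- df$y_plus
  ym <- df$y_minus
  marks <- setdiff(names(df), c("enhancer_id", "y_plus", "y_minus"))
  x <- as.matrix(df[, marks, drop = FALSE])
  rownames(x) <- ids
  new_erna_signal(x, yp, ym)
}
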