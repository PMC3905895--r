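#' Assign each enhancer to its closest gene TSS
#'
#' Distance is measured from the enhancer window center to the TSS; the
#' minimizing gene is linked when within \code{max_dist}, otherwise the
#' enhancer stays unassigned. Exact distance ties break to the gene with the
#' smaller TSS coordinate, so assignment is deterministic.
#'
#' @param enhancers an \code{enhancer_catalog} (or data.frame with id,
#'   chrom, start, end).
#' @param genes gene table from [read_gene_table()].
#' @param max_dist maximum linking distance in bp (default 100000).
#' @return data.frame: \code{id}, \code{gene_id} (NA when unassigned),
#'   \code{distance}.
#' @export
assign_genes <- function(enhancers, genes, max_dist = 100000) {
  center <- (enhancers$start + enhancers$end) %/% 2L
  gene_id <- rep(NA_character_, nrow(enhancers))
  distance <- rep(NA_real_, nrow(enhancers))
  for (chr in unique(enhancers$chrom)) {
    gi <- which(genes$chrom == chr)
    if (!length(gi)) next
    ei <- which(enhancers$chrom == chr)
    tss <- genes$tss[gi]
    ord <- order(tss, gi)
    tss <- tss[ord]; gid <- genes$gene_id[gi][ord]
    d <- abs(outer(center[ei], tss, "-"))
    best <- apply(d, 1, function(r) which(r == min(r))[1])  # smallest TSS on ties
    dmin <- d[cbind(seq_along(ei), best)]
    ok <- dmin <= max_dist
    gene_id[ei[ok]] <- gid[best[ok]]
    distance[ei[ok]] <- dmin[ok]
  }
  data.frame(id = enhancers$id, gene_id = gene_id, distance = distance,
             stringsAsFactors = FALSE)
}

#' Classify enhancers by proximity to H3K27ac-enriched regions
#'
#' An enhancer is H3K27ac-positive when the edge-to-edge distance from its
#' window to any H3K27ac peak is at most \code{dist} (overlap counts as 0).
#'
#' @param enhancers an \code{enhancer_catalog}.
#' @param k27ac_peaks data.frame of H3K27ac peak intervals.
#' @param dist distance threshold in bp (default 2000).
#' @return Character vector \code{"+"} / \code{"-"} per enhancer, named by id.
#' @export
classify_h3k27ac <- function(enhancers, k27ac_peaks, dist = 2000) {
  if (nrow(enhancers) == 0L) return(setNames(character(), character()))
  if (is.null(k27ac_peaks) || nrow(k27ac_peaks) == 0L) {
    return(setNames(rep("-", nrow(enhancers)), enhancers$id))
  }
  gap <- gap_to_nearest(as_granges0(enhancers), as_granges0(k27ac_peaks))
  setNames(ifelse(gap <= dist, "+", "-"), enhancers$id)
}

#' Cross enhancers into the four eRNA x H3K27ac subgroups
#'
#' @param erna_status named vector over enhancers: \code{"positive"} /
#'   \code{"negative"} (measured labels or thresholded predictions);
#'   ambiguous entries are excluded.
#' @param k27ac_status named \code{"+"}/\code{"-"} vector from
#'   [classify_h3k27ac()].
#' @return data.frame: \code{id}, \code{erna}, \code{k27ac},
#'   \code{subgroup} in \code{eRNA+K27ac+}, \code{eRNA+K27ac-},
#'   \code{eRNA-K27ac+}, \code{eRNA-K27ac-}.
#' @export
subgroup_enhancers <- function(erna_status, k27ac_status) {
  ids <- intersect(names(erna_status), names(k27ac_status))
  er <- erna_status[ids]
  keep <- er %in% c("positive", "negative")
  ids <- ids[keep]; er <- er[keep]
  k2 <- k27ac_status[ids]
  subgroup <- paste0(ifelse(er == "positive", "eRNA+", "eRNA-"),
                     ifelse(k2 == "+", "K27ac+", "K27ac-"))
  data.frame(id = ids, erna = unname(er), k27ac = unname(k2),
             subgroup = subgroup, stringsAsFactors = FALSE)
}

#' Compare associated-gene expression between enhancer groups
#'
#' For every requested pair of groups, a two-sided Mann-Whitney rank-sum
#' test on the FPKM of the genes linked to each group's enhancers. A gene
#' linked by several enhancers of the same group counts once in that group
#' (deduplication avoids pseudo-replication). Exact p-values for small
#' untied samples, normal approximation with continuity correction
#' otherwise (the \code{stats::wilcox.test} convention).
#'
#' @param groups data.frame from [subgroup_enhancers()], or any data.frame
#'   with \code{id} and \code{subgroup}.
#' @param links data.frame from [assign_genes()].
#' @param expression data.frame \code{gene_id}, \code{fpkm}.
#' @param pairs list of 2-vectors of group names; default: all pairs.
#' @return A list with \code{summary} (per-group n and median FPKM) and
#'   \code{tests} (group pair, n1, n2, W, p).
#' @export
compare_expression <- function(groups, links, expression, pairs = NULL) {
  merged <- merge(groups, links, by = "id")
  merged <- merged[!is.na(merged$gene_id), , drop = FALSE]
  merged <- merge(merged, expression, by = "gene_id")
  fpkm_by_group <- lapply(split(merged, merged$subgroup), function(d) {
    d <- d[!duplicated(d$gene_id), , drop = FALSE]
    d$fpkm
  })
  gnames <- names(fpkm_by_group)
  if (length(gnames) < 2L) stop("need at least two non-empty groups", call. = FALSE)
  if (is.null(pairs)) {
    pairs <- combn(gnames, 2, simplify = FALSE)
  }
  tests <- lapply(pairs, function(pr) {
    a <- fpkm_by_group[[pr[1]]]; b <- fpkm_by_group[[pr[2]]]
    if (is.null(a) || is.null(b) || !length(a) || !length(b)) {
      warning("group pair skipped (no assigned genes): ",
              pr[1], " vs ", pr[2])
      return(NULL)
    }
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(a), n2 = length(b),
               W = unname(wt$statistic), p = wt$p.value,
               median1 = median(a), median2 = median(b),
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  summary <- data.frame(
    subgroup = gnames,
    n_genes = vapply(fpkm_by_group, length, 0L),
    median_fpkm = vapply(fpkm_by_group, median, 0),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(summary = summary, tests = tests)
}

#' Apply a trained model to another cell type
#'
#' Predicts eRNA probabilities for a target cell-type signal matrix using a
#' model trained elsewhere. By default the standardization is recomputed on
#' the target cell's own means and sds so the model sees comparably scaled
#' inputs; \code{standardize = "training"} keeps the fit-time parameters.
#' When labels for the target cells are supplied, AUC and MCC are reported.
#'
#' @param model an \code{erna_logit} fit.
#' @param signal_other the target cell-type \code{erna_signal}; must contain
#'   every mark of the model.
#' @param labels optional \code{erna_labels} for the target enhancers.
#' @param standardize \code{"target"} (default) or \code{"training"}.
#' @return A list with \code{probability} (named vector), \code{call}
#'   (\code{positive}/\code{negative} at 0.5) and, when labels are given,
#'   \code{evaluation} (auc, mcc, mcc_max).
#' @export
cross_celltype_predict <- function(model, signal_other, labels = NULL,
                                   standardize = c("target", "training")) {
  standardize <- match.arg(standardize)
  x <- if (inherits(signal_other, "erna_signal")) signal_other$x else signal_other
  missing_marks <- setdiff(model$marks, colnames(x))
  if (length(missing_marks)) {
    stop("target cell type lacks mark(s): ", paste(missing_marks, collapse = ", "),
         call. = FALSE)
  }
  if (standardize == "target") {
    ctr <- colMeans(x[, model$marks, drop = FALSE])
    sc <- apply(x[, model$marks, drop = FALSE], 2, sd)
    sc[sc <= 0] <- 1
    p <- predict(model, x, center = ctr, scale = sc)
  } else {
    p <- predict(model, x)
  }
  out <- list(probability = p,
              call = ifelse(p >= 0.5, "positive", "negative"),
              standardize = standardize)
  if (!is.null(labels)) {
    tr <- training_response(labels, names(p))
    out$evaluation <- evaluate_predictions(tr$y, p[tr$ids])
  }
  out
}
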