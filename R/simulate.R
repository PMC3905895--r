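#' Configuration for the synthetic enhancer experiment
#'
#' The generator emulates the statistical structure the analysis assumes:
#' enhancers carry a latent active/inactive state; log read densities of
#' chromatin marks shift with that state (activating acetylations correlated
#' with each other, a repressive mark anti-correlated, elongation-associated
#' marks mildly elevated); stranded GRO-seq density is strongly bimodal on
#' the log scale, elevated on both strands at active enhancers; mappability
#' is 1 almost everywhere with planted low-mappability windows; and genes
#' linked to active enhancers have elevated expression.
#'
#' Counts are Poisson on an exponentiated Gaussian, so per-state log
#' densities are approximately Gaussian and the two-component structure of
#' the log GRO-seq histogram holds by construction. Acetylation marks share a
#' latent factor with correlation \code{rho}, giving the subset-selection
#' stage real redundancy to break.
#'
#' @param ... named overrides of any field. Key fields: \code{n_enhancers}
#'   (2000), \code{n_genes} (500), \code{marks} (data.frame with columns
#'   \code{mark}, \code{group}, \code{effect} in log-density units),
#'   \code{rho} acetylation-group correlation (0.6), \code{noise_sd}
#'   mark log-density noise (1.2, so single-mark discrimination stays below
#'   the AUC ceiling), \code{gro_noise_sd} GRO-seq log-density noise (0.5 --
#'   nascent-transcription bimodality is far sharper than mark densities),
#'   \code{fraction_active} (0.5), \code{depth} expected reads at baseline
#'   density (20), \code{gro_effect} GRO-seq log shift for active enhancers
#'   (3, i.e. 6 GRO noise sd), \code{window_bp} enhancer window (2000),
#'   \code{fraction_low_mappability} (0.05), \code{n_genebody_violations} and
#'   \code{n_tss_violations} planted filter violations (0),
#'   \code{expression_shift} natural-log FPKM shift for genes linked to
#'   active enhancers (2), \code{seed}.
#' @return A validated list of class \code{synth_config}.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_enhancers = 2000,
    n_genes = 500,
    marks = default_marks(),
    rho = 0.6,
    noise_sd = 1.2,
    gro_noise_sd = 0.5,
    fraction_active = 0.5,
    depth = 20,
    gro_effect = 3,
    window_bp = 2000,
    read_length = 36,
    fraction_low_mappability = 0.05,
    n_genebody_violations = 0,
    n_tss_violations = 0,
    expression_shift = 2,
    baseline_log_fpkm = 1.5,
    baseline_sdlog = 1,
    background_per_kb = 0.02,
    gene_block_bp = 150000,
    desert_spacing_bp = 10000,
    k27ac_peak_factor = 3,
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("synth_config: unknown field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(cfg$n_enhancers >= 1, cfg$n_genes >= 1,
            cfg$fraction_active >= 0, cfg$fraction_active <= 1,
            cfg$rho >= 0, cfg$rho < 1,
            cfg$depth >= 0, cfg$noise_sd >= 0,
            all(is.finite(cfg$marks$effect)),
            cfg$window_bp >= 200,
            cfg$fraction_low_mappability >= 0, cfg$fraction_low_mappability <= 1)
  if (!all(c("mark", "group", "effect") %in% names(cfg$marks))) {
    stop("synth_config: marks needs columns mark, group, effect", call. = FALSE)
  }
  if (cfg$desert_spacing_bp < cfg$window_bp + 1000) {
    stop("synth_config: genome too small -- desert spacing below window size", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Default mark panel of the generator
#'
#' Ten chromatin marks in four groups: three correlated activating
#' acetylations, one repressive mark with a negative shift, two
#' elongation-associated marks with moderate positive shifts, and four
#' neutral marks carrying no state information. Effects are shifts of the
#' log read density (natural-log units) between active and inactive states.
#'
#' @return data.frame with columns \code{mark}, \code{group}, \code{effect}.
#' @export
default_marks <- function() {
  data.frame(
    mark = c("H3K27ac", "H3K9ac", "H4K8ac",
             "H3K27me3",
             "H3K79me1", "H3K36me3",
             "H3K4me1", "H3K4me3", "H3K9me3", "H2A.Z"),
    group = c(rep("acetyl", 3), "repressive", rep("elongation", 2), rep("neutral", 4)),
    effect = c(2.0, 1.8, 1.6, -2.0, 1.5, 1.2, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Generate the synthetic annotation: genes, enhancer sites, mappability, truth
#'
#' Genes are laid out in fixed blocks on chr1, each with a 10 kb body, a
#' promoter H3K4me3 region (TSS +/- 1 kb) and, for the first
#' \code{n_genes} enhancers, one linked enhancer 20 kb downstream of the
#' gene body (so its nearest TSS within 100 kb is its own gene). Surplus
#' enhancers sit on a gene-free chr2 so they stay unassigned. Enhancer sites
#' are placed so the intergenic filter retains all of them unless violations
#' are deliberately planted: \code{n_genebody_violations} sites inside gene
#' bodies and \code{n_tss_violations} sites whose window lies under 3 kb
#' from a TSS. A seeded fraction of ordinary enhancers gets a mappability
#' 0.5 window to exercise the mappability filter deterministically.
#'
#' @param cfg a [synth_config()].
#' @return A list of class \code{synth_annotation} with elements
#'   \code{genes}, \code{enhancer_sites} (peak intervals, BED-like),
#'   \code{k4me3_peaks}, \code{mappability}, \code{genome} (chrom lengths)
#'   and \code{truth} (per-site latent state, violation class, low
#'   mappability flag, linked gene).
#' @export
synth_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_genebody_violations > cfg$n_genes || cfg$n_tss_violations > cfg$n_genes) {
    stop("genome too small to place requested violation counts", call. = FALSE)
  }
  set.seed(derive_seed(cfg$seed, "annotation"))
  nG <- cfg$n_genes
  nE <- cfg$n_enhancers
  blk <- cfg$gene_block_bp
  half <- cfg$window_bp %/% 2L

  gi <- seq_len(nG) - 1L
  strand <- ifelse(gi %% 2L == 0L, "+", "-")
  body_start <- as.integer(gi * blk + 50000)
  body_end <- body_start + 10000L
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(nG)),
    chrom = "chr1", strand = strand,
    tss = ifelse(strand == "+", body_start, body_end - 1L),
    body_start = body_start, body_end = body_end,
    stringsAsFactors = FALSE
  )

  n_linked <- min(nG, nE)
  centers1 <- as.integer(body_end[seq_len(n_linked)] + 20000)
  chrom1 <- rep("chr1", n_linked)
  linked_gene <- genes$gene_id[seq_len(n_linked)]
  n_desert <- nE - n_linked
  if (n_desert > 0L) {
    centers2 <- as.integer(5000 + (seq_len(n_desert) - 1) * cfg$desert_spacing_bp)
    centers <- c(centers1, centers2)
    chrom <- c(chrom1, rep("chr2", n_desert))
    linked_gene <- c(linked_gene, rep(NA_character_, n_desert))
  } else {
    centers <- centers1
    chrom <- chrom1
  }
  violation <- rep("none", nE)

  # planted violations, appended after the ordinary sites
  if (cfg$n_genebody_violations > 0L) {
    idx <- seq_len(cfg$n_genebody_violations)
    centers <- c(centers, genes$body_start[idx] + 5000L)
    chrom <- c(chrom, rep("chr1", length(idx)))
    linked_gene <- c(linked_gene, rep(NA_character_, length(idx)))
    violation <- c(violation, rep("gene_body", length(idx)))
  }
  if (cfg$n_tss_violations > 0L) {
    idx <- seq_len(cfg$n_tss_violations)
    vtss <- genes$tss[idx]
    vcen <- as.integer(ifelse(genes$strand[idx] == "+", vtss - 2000L, vtss + 2000L))
    centers <- c(centers, vcen)
    chrom <- c(chrom, rep("chr1", length(idx)))
    linked_gene <- c(linked_gene, rep(NA_character_, length(idx)))
    violation <- c(violation, rep("tss_proximal", length(idx)))
  }
  n_tot <- length(centers)
  ids <- sprintf("enh_%05d", seq_len(n_tot))
  state <- ifelse(rbinom(n_tot, 1L, cfg$fraction_active) == 1L, "active", "inactive")

  n_low <- round(cfg$fraction_low_mappability * nE)
  low <- rep(FALSE, n_tot)
  if (n_low > 0L) low[sample(seq_len(nE), n_low)] <- TRUE

  enhancer_sites <- data.frame(
    chrom = chrom, start = centers - 250L, end = centers + 250L,
    name = ids, score = NA_real_, strand = "*", stringsAsFactors = FALSE
  )
  k4me3_peaks <- data.frame(
    chrom = genes$chrom, start = pmax(genes$tss - 1000L, 0L),
    end = genes$tss + 1000L, name = paste0("k4me3_", genes$gene_id),
    score = NA_real_, strand = "*", stringsAsFactors = FALSE
  )
  genome <- data.frame(
    chrom = c("chr1", if (n_desert > 0L) "chr2"),
    length = as.integer(c(nG * blk,
               if (n_desert > 0L) n_desert * cfg$desert_spacing_bp + 10000)),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    id = ids, chrom = chrom, center = centers, state = state,
    violation = violation, low_mappability = low,
    linked_gene = linked_gene, stringsAsFactors = FALSE
  )
  mappability <- build_mappability(genome, truth[truth$low_mappability, ], half)
  structure(list(genes = genes, enhancer_sites = enhancer_sites,
                 k4me3_peaks = k4me3_peaks, mappability = mappability,
                 genome = genome, truth = truth, cfg = cfg),
            class = "synth_annotation")
}

## partition the genome into mappability segments: value 1 everywhere except
## planted 0.5 windows over low-mappability enhancers
build_mappability <- function(genome, low_truth, half) {
  out <- list()
  for (i in seq_len(nrow(genome))) {
    chr <- genome$chrom[i]
    len <- genome$length[i]
    lows <- low_truth[low_truth$chrom == chr, ]
    lows <- lows[order(lows$center), ]
    starts <- pmax(lows$center - half, 0L)
    ends <- pmin(lows$center + half, len)
    cuts <- as.integer(c(0L, rbind(starts, ends), len))
    seg_start <- cuts[-length(cuts)]
    seg_end <- cuts[-1]
    value <- rep(1, length(seg_start))
    if (nrow(lows)) value[seq(2, by = 2, length.out = nrow(lows))] <- 0.5
    keep <- seg_end > seg_start
    out[[i]] <- data.frame(chrom = chr, start = seg_start[keep],
                           end = seg_end[keep], value = value[keep],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## Poisson counts per (enhancer, track) under the latent-state model.
## Acetylation marks share a per-enhancer latent factor (correlation rho).
draw_counts <- function(cfg, truth) {
  set.seed(derive_seed(cfg$seed, "counts"))
  n <- nrow(truth)
  act <- as.numeric(truth$state == "active")
  marks <- cfg$marks
  z_acetyl <- rnorm(n)
  eps <- matrix(0, n, nrow(marks), dimnames = list(truth$id, marks$mark))
  for (i in seq_len(nrow(marks))) {
    e <- rnorm(n)
    if (marks$group[i] == "acetyl" && cfg$rho > 0) {
      eps[, i] <- cfg$noise_sd * (sqrt(cfg$rho) * z_acetyl + sqrt(1 - cfg$rho) * e)
    } else {
      eps[, i] <- cfg$noise_sd * e
    }
  }
  counts <- matrix(0L, n, nrow(marks), dimnames = dimnames(eps))
  for (i in seq_len(nrow(marks))) {
    lam <- cfg$depth * exp(marks$effect[i] * act + eps[, i])
    counts[, i] <- rpois(n, lam)
  }
  gro_plus <- rpois(n, cfg$depth * exp(cfg$gro_effect * act + cfg$gro_noise_sd * rnorm(n)))
  gro_minus <- rpois(n, cfg$depth * exp(cfg$gro_effect * act + cfg$gro_noise_sd * rnorm(n)))
  list(counts = counts, gro_plus = gro_plus, gro_minus = gro_minus)
}

#' Generate read-level tracks from the synthetic annotation
#'
#' For enhancer j and track i the read count is Poisson with mean
#' \code{depth * exp(effect_i * active_j + eps_ij)}; reads are placed
#' uniformly within the enhancer window. GRO-seq sense and antisense reads
#' are both elevated at active enhancers (bidirectional transcription).
#' Background reads are scattered uniformly over the genome at
#' \code{background_per_kb} per track. H3K27ac peak calls are derived by
#' thresholding the simulated H3K27ac counts, so H3K27ac status is
#' correlated with, but not identical to, the latent state.
#'
#' @param cfg a [synth_config()].
#' @param ann a [synth_annotation()] built from the same configuration.
#' @return A list with \code{tracks} (named list of unstranded read
#'   data.frames), \code{gro} (stranded read data.frame), \code{k27ac_peaks},
#'   and the underlying \code{counts}.
#' @export
synth_reads <- function(cfg, ann) {
  stopifnot(inherits(ann, "synth_annotation"))
  cnt <- draw_counts(cfg, ann$truth)
  set.seed(derive_seed(cfg$seed, "reads"))
  half <- cfg$window_bp %/% 2L
  rl <- cfg$read_length
  win_start <- ann$truth$center - half
  place <- function(counts) {
    idx <- rep.int(seq_along(counts), counts)
    lo <- win_start[idx]
    s <- lo + floor(runif(length(idx)) * (cfg$window_bp - rl))
    data.frame(chrom = ann$truth$chrom[idx], start = as.integer(s),
               end = as.integer(s + rl), stringsAsFactors = FALSE)
  }
  background <- function() {
    kb <- sum(ann$genome$length) / 1000
    nbg <- rpois(1L, cfg$background_per_kb * kb)
    if (nbg == 0L) {
      return(data.frame(chrom = character(), start = integer(), end = integer(),
                        stringsAsFactors = FALSE))
    }
    ci <- sample.int(nrow(ann$genome), nbg, replace = TRUE,
                     prob = ann$genome$length / sum(ann$genome$length))
    s <- floor(runif(nbg) * (ann$genome$length[ci] - rl))
    data.frame(chrom = ann$genome$chrom[ci], start = as.integer(s),
               end = as.integer(s + rl), stringsAsFactors = FALSE)
  }
  tracks <- list()
  for (i in seq_len(ncol(cnt$counts))) {
    df <- rbind(place(cnt$counts[, i]), background())
    df$name <- rep(NA_character_, nrow(df))
    df$score <- rep(NA_real_, nrow(df))
    df$strand <- rep("*", nrow(df))
    tracks[[colnames(cnt$counts)[i]]] <- df
  }
  gp <- place(cnt$gro_plus); gp$strand <- rep("+", nrow(gp))
  gm <- place(cnt$gro_minus); gm$strand <- rep("-", nrow(gm))
  bg <- background()
  bg$strand <- if (nrow(bg)) sample(c("+", "-"), nrow(bg), replace = TRUE) else character()
  gro <- rbind(gp, gm, bg)
  gro$name <- rep(NA_character_, nrow(gro))
  gro$score <- rep(NA_real_, nrow(gro))
  gro <- gro[, c("chrom", "start", "end", "name", "score", "strand")]

  thr <- cfg$k27ac_peak_factor * cfg$depth
  hit <- cnt$counts[, "H3K27ac"] >= thr
  k27 <- data.frame(chrom = ann$truth$chrom[hit],
                    start = ann$truth$center[hit] - half,
                    end = ann$truth$center[hit] + half,
                    name = paste0("k27ac_", ann$truth$id[hit]),
                    score = NA_real_, strand = "*", stringsAsFactors = FALSE)
  list(tracks = tracks, gro = gro, k27ac_peaks = k27, counts = cnt)
}

#' Build the signal matrix directly from simulated counts
#'
#' Fast path that skips read placement: identical count draws to
#' [synth_reads()] under the same seed, converted to log densities with the
#' same formula the catalog stage uses (reads per kb per million track
#' reads, then \code{log2(density + pseudocount)}). Used where only the
#' matrix is needed, e.g. replicated model-selection experiments.
#'
#' @param cfg a [synth_config()].
#' @param ann a [synth_annotation()].
#' @param pseudocount,log_base as in [compute_signal_matrix()].
#' @return An \code{erna_signal} over the non-violating, well-mappable
#'   enhancers (the set the catalog stage would retain).
#' @export
synth_signal <- function(cfg, ann, pseudocount = 1, log_base = 2) {
  cnt <- draw_counts(cfg, ann$truth)
  keep <- ann$truth$violation == "none" & !ann$truth$low_mappability
  kb <- cfg$window_bp / 1000
  bg <- cfg$background_per_kb * sum(ann$genome$length) / 1000
  dens <- function(counts) {
    tot <- sum(counts) + bg
    (counts[keep] / kb) / (tot / 1e6)
  }
  x <- apply(cnt$counts, 2, dens)
  rownames(x) <- ann$truth$id[keep]
  logb <- function(v) log(v + pseudocount, base = log_base)
  new_erna_signal(logb(x), logb(dens(cnt$gro_plus)), logb(dens(cnt$gro_minus)))
}

#' Generate per-gene expression tied to linked enhancer activity
#'
#' Genes linked to an active enhancer draw log FPKM from
#' \code{baseline + expression_shift}; all other genes from the baseline;
#' log-normal noise with sd \code{baseline_sdlog}.
#'
#' @param cfg a [synth_config()].
#' @param ann a [synth_annotation()].
#' @return data.frame with columns \code{gene_id}, \code{fpkm}, one row per
#'   annotated gene.
#' @export
synth_expression <- function(cfg, ann) {
  set.seed(derive_seed(cfg$seed, "expression"))
  genes <- ann$genes
  tr <- ann$truth[ann$truth$violation == "none", ]
  active_genes <- tr$linked_gene[tr$state == "active" & !is.na(tr$linked_gene)]
  shift <- ifelse(genes$gene_id %in% active_genes, cfg$expression_shift, 0)
  logf <- cfg$baseline_log_fpkm + shift + cfg$baseline_sdlog * rnorm(nrow(genes))
  data.frame(gene_id = genes$gene_id, fpkm = exp(logf), stringsAsFactors = FALSE)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits every file the pipeline reads -- per-mark read BEDs, a stranded
#' GRO-seq BED, P300 / H3K4me3 / H3K27ac peak BEDs, the gene table, the
#' mappability track and the expression table -- plus a manifest TSV listing
#' each file and its role, and the ground truth as TSV for test consumption.
#' Byte-identical under a fixed seed.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the manifest data.frame and the in-memory
#'   annotation.
#' @export
synth_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- synth_annotation(cfg)
  rd <- synth_reads(cfg, ann)
  expr <- synth_expression(cfg, ann)
  p <- function(f) file.path(dir, f)
  manifest <- list()
  add <- function(file, role) manifest[[length(manifest) + 1L]] <<- data.frame(
    file = file, role = role, stringsAsFactors = FALSE)

  for (mk in names(rd$tracks)) {
    f <- paste0("reads_", gsub("[^A-Za-z0-9]", "", mk), ".bed")
    write_bed(rd$tracks[[mk]][, c("chrom", "start", "end")], p(f))
    add(f, paste0("mark_reads:", mk))
  }
  write_bed(rd$gro, p("reads_GROseq.bed")); add("reads_GROseq.bed", "gro_reads")
  write_bed(ann$enhancer_sites, p("peaks_P300.bed")); add("peaks_P300.bed", "p300_peaks")
  write_bed(ann$enhancer_sites, p("peaks_H3K4me1.bed")); add("peaks_H3K4me1.bed", "h3k4me1_peaks")
  write_bed(ann$k4me3_peaks, p("peaks_H3K4me3.bed")); add("peaks_H3K4me3.bed", "h3k4me3_peaks")
  write_bed(rd$k27ac_peaks, p("peaks_H3K27ac.bed")); add("peaks_H3K27ac.bed", "h3k27ac_peaks")
  genes_out <- data.frame(ann$genes$gene_id, ann$genes$chrom, ann$genes$strand,
                          ann$genes$body_start, ann$genes$body_end)
  write.table(genes_out, p("genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  add("genes.tsv", "gene_table")
  write.table(ann$mappability, p("mappability.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  add("mappability.bed", "mappability")
  write.table(expr, p("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  add("expression.tsv", "expression")
  write_tsv_commented(ann$truth, p("truth.tsv")); add("truth.tsv", "truth")
  manifest <- do.call(rbind, manifest)
  write_tsv_commented(manifest, p("manifest.tsv"))
  invisible(list(manifest = manifest, annotation = ann, dir = dir))
}
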