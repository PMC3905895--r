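test_that("intergenic filter enforces gene-body and 3 kb proximity rules", {
  genes <- tiny_genes()  # TSSs at 100000 (+) and 259999 (-)
  k4 <- data.frame(chrom = "chr1", start = c(99000L, 259000L),
                   end = c(101000L, 261000L))
  peaks <- data.frame(
    chrom = "chr1",
    # centers: far (ok), 2999 bp from TSS (drop), inside gene body (drop),
    # exactly 3000 bp gap from TSS window edge (keep)
    start = c(150000L - 250L, 100000L - 2999L - 1000L - 250L, 105000L - 250L,
              200000L - 250L),
    end = c(150000L + 250L, 100000L - 2999L - 1000L + 250L, 105000L + 250L,
            200000L + 250L),
    name = c("far", "near_tss", "in_body", "mid"), stringsAsFactors = FALSE)
  cat1 <- define_intergenic_enhancers(peaks, genes, k4)
  expect_true(all(c("far", "mid") %in% cat1$id))
  expect_false("in_body" %in% cat1$id)
  expect_false("near_tss" %in% cat1$id)
  # windows are centered on peak midpoints with the requested half-width
  expect_equal(cat1$end - cat1$start, rep(2000L, nrow(cat1)))
  expect_equal((cat1$start + cat1$end) %/% 2L,
               (cat1$peak_start + cat1$peak_end) %/% 2L)
})

test_that("boundary case: a TSS exactly 3 kb away is retained, 2999 bp is not", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      tss = 500000L, body_start = 500000L, body_end = 510000L,
                      stringsAsFactors = FALSE)
  k4 <- data.frame(chrom = character(), start = integer(), end = integer())
  mk_peak <- function(center, nm) data.frame(chrom = "chr1", start = center - 250L,
                                             end = center + 250L, name = nm,
                                             stringsAsFactors = FALSE)
  # window edge at center+1000; gap to TSS point = tss - (center+1000)
  keep <- mk_peak(500000L - 1000L - 3000L, "at3000")   # gap exactly 3000
  drop <- mk_peak(500000L - 1000L - 2999L, "at2999")   # gap 2999
  cat_keep <- define_intergenic_enhancers(keep, genes, k4)
  cat_drop <- define_intergenic_enhancers(drop, genes, k4)
  expect_equal(cat_keep$id, "at3000")
  expect_equal(nrow(cat_drop), 0L)
})

test_that("empty peak set warns and yields an empty catalog", {
  expect_warning(
    cat0 <- define_intergenic_enhancers(
      data.frame(chrom = character(), start = integer(), end = integer()),
      tiny_genes(), data.frame(chrom = character(), start = integer(), end = integer())),
    "empty")
  expect_equal(nrow(cat0), 0L)
})

test_that("mappability filter drops strictly below the threshold", {
  enh <- data.frame(id = c("a", "b", "c"), chrom = "chr1",
                    start = c(0L, 10000L, 20000L),
                    end = c(2000L, 12000L, 22000L),
                    peak_start = c(0L, 10000L, 20000L),
                    peak_end = c(2000L, 12000L, 22000L),
                    provenance = "P300", mean_mappability = NA_real_,
                    stringsAsFactors = FALSE)
  class(enh) <- c("enhancer_catalog", "data.frame")
  mapp <- data.frame(chrom = "chr1",
                     start = c(0L, 2000L, 10000L, 12000L, 20000L),
                     end = c(2000L, 10000L, 12000L, 20000L, 22000L),
                     value = c(0.84, 1, 0.85, 1, 1))
  out <- apply_mappability_filter(enh, mapp, 0.85)
  expect_equal(out$id, c("b", "c"))          # 0.84 dropped, 0.85 kept
  expect_equal(out$mean_mappability, c(0.85, 1))
  # uncovered bases count as zero
  enh2 <- enh[enh$id == "a", ]
  half_cov <- data.frame(chrom = "chr1", start = 0L, end = 1000L, value = 1)
  out2 <- apply_mappability_filter(enh2, half_cov, 0.4)
  expect_equal(out2$mean_mappability, 0.5)
})

test_that("filter order does not matter and the catalog is idempotent", {
  cfg <- synth_config(n_enhancers = 120, n_genes = 50, seed = 5,
                      n_genebody_violations = 4, n_tss_violations = 2,
                      fraction_low_mappability = 0.1)
  ann <- synth_annotation(cfg)
  c1 <- define_intergenic_enhancers(ann$enhancer_sites, ann$genes, ann$k4me3_peaks)
  a_then_b <- apply_mappability_filter(c1, ann$mappability)
  # reverse order: mappability filter on all raw windows first, then intergenic
  raw <- ann$enhancer_sites
  raw_cat <- data.frame(id = raw$name, chrom = raw$chrom,
                        start = (raw$start + raw$end) %/% 2L - 1000L,
                        end = (raw$start + raw$end) %/% 2L + 1000L,
                        peak_start = raw$start, peak_end = raw$end,
                        provenance = "P300", mean_mappability = NA_real_,
                        stringsAsFactors = FALSE)
  class(raw_cat) <- c("enhancer_catalog", "data.frame")
  mapp_first <- apply_mappability_filter(raw_cat, ann$mappability)
  b_then_a <- define_intergenic_enhancers(
    data.frame(chrom = mapp_first$chrom, start = mapp_first$peak_start,
               end = mapp_first$peak_end, name = mapp_first$id),
    ann$genes, ann$k4me3_peaks)
  expect_setequal(a_then_b$id, b_then_a$id)
  # idempotence: re-filtering the filtered catalog changes nothing
  again <- apply_mappability_filter(a_then_b, ann$mappability)
  expect_identical(again$id, a_then_b$id)
  c_again <- define_intergenic_enhancers(
    data.frame(chrom = a_then_b$chrom, start = a_then_b$peak_start,
               end = a_then_b$peak_end, name = a_then_b$id),
    ann$genes, ann$k4me3_peaks)
  expect_identical(c_again$id, a_then_b$id)
})

test_that("planted violations are removed in exactly the planted numbers", {
  cfg <- synth_config(n_enhancers = 200, n_genes = 80, seed = 23,
                      n_genebody_violations = 7, n_tss_violations = 4,
                      fraction_low_mappability = 0.05)
  ann <- synth_annotation(cfg)
  c1 <- define_intergenic_enhancers(ann$enhancer_sites, ann$genes, ann$k4me3_peaks)
  removed <- setdiff(ann$truth$id, c1$id)
  expect_setequal(removed, ann$truth$id[ann$truth$violation != "none"])
  c2 <- apply_mappability_filter(c1, ann$mappability)
  removed2 <- setdiff(c1$id, c2$id)
  expect_setequal(removed2, ann$truth$id[ann$truth$low_mappability])
})

test_that("signal matrix implements the density and log transform exactly", {
  enh <- data.frame(id = "e1", chrom = "chr1", start = 1000L, end = 2000L,
                    peak_start = 1400L, peak_end = 1600L, provenance = "P300",
                    mean_mappability = 1, stringsAsFactors = FALSE)
  class(enh) <- c("enhancer_catalog", "data.frame")
  # 10 reads with midpoints inside the window + filler elsewhere for a total
  # of 1e6 reads is impractical; use 100 total reads and scale by hand
  inwin <- data.frame(chrom = "chr1", start = 1500L + 0:9, end = 1540L + 0:9)
  outwin <- data.frame(chrom = "chr1", start = rep(50000L, 90), end = rep(50040L, 90))
  reads <- rbind(inwin, outwin)
  sig <- compute_signal_matrix(enh, list(mk = reads), NULL,
                               pseudocount = 1, log_base = 2)
  # density = (10 reads / 1 kb) / (100/1e6 M reads) = 1e5; value = log2(1e5+1)
  expect_equal(sig$x[1, "mk"], log2(1e5 + 1))
  # zero reads in window, pseudocount 1 -> 0
  far <- data.frame(chrom = "chr1", start = rep(90000L, 50), end = rep(90040L, 50))
  sig0 <- compute_signal_matrix(enh, list(mk = far), NULL)
  expect_equal(sig0$x[1, "mk"], 0)
  # depth-doubling invariance
  sig2 <- compute_signal_matrix(enh, list(mk = rbind(reads, reads)), NULL)
  expect_equal(sig2$x[1, "mk"], sig$x[1, "mk"])
  # zero-total track errors
  none <- data.frame(chrom = character(), start = integer(), end = integer())
  expect_error(compute_signal_matrix(enh, list(mk = none), NULL), "zero total")
})

test_that("worked example: 10 reads in 1 kb at 1e6 track total gives log2(11)", {
  enh <- data.frame(id = "e1", chrom = "chr1", start = 0L, end = 1000L,
                    peak_start = 400L, peak_end = 600L, provenance = "P300",
                    mean_mappability = 1, stringsAsFactors = FALSE)
  class(enh) <- c("enhancer_catalog", "data.frame")
  # synthesize totals via a mock: 10 in-window plus 999,990 outside
  inwin <- data.frame(chrom = "chr1", start = 100L + 0:9, end = 140L + 0:9)
  outwin <- data.frame(chrom = "chr1",
                       start = rep(5000L, 999990L), end = rep(5040L, 999990L))
  reads <- rbind(inwin, outwin)
  sig <- compute_signal_matrix(enh, list(mk = reads), NULL)
  expect_equal(sig$x[1, "mk"], log2(10 + 1), tolerance = 1e-9)
})

test_that("GRO-seq strands are computed separately", {
  enh <- data.frame(id = c("e1", "e2"), chrom = "chr1",
                    start = c(0L, 5000L), end = c(1000L, 6000L),
                    peak_start = c(0L, 5000L), peak_end = c(1000L, 6000L),
                    provenance = "P300", mean_mappability = 1,
                    stringsAsFactors = FALSE)
  class(enh) <- c("enhancer_catalog", "data.frame")
  gro <- data.frame(chrom = "chr1",
                    start = c(rep(100L, 8), rep(5100L, 2)),
                    end = c(rep(140L, 8), rep(5140L, 2)),
                    strand = c(rep("+", 8), rep("-", 2)))
  tracks <- list(mk = data.frame(chrom = "chr1", start = 1L, end = 40L))
  sig <- compute_signal_matrix(enh, tracks, gro)
  # all + reads in e1, all - reads in e2
  expect_gt(sig$y_plus[1], sig$y_plus[2])
  expect_lt(sig$y_minus[1], sig$y_minus[2])
  bad <- gro; bad$strand[1] <- "*"
  expect_error(compute_signal_matrix(enh, tracks, bad), "stranded")
})
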