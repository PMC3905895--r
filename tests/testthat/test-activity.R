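mk_enh <- function(ids, chrom, centers, half = 1000L) {
  out <- data.frame(id = ids, chrom = chrom, start = centers - half,
                    end = centers + half, peak_start = centers - 250L,
                    peak_end = centers + 250L, provenance = "P300",
                    mean_mappability = 1, stringsAsFactors = FALSE)
  class(out) <- c("enhancer_catalog", "data.frame")
  out
}

test_that("gene assignment picks the nearest TSS within 100 kb", {
  genes <- data.frame(gene_id = c("near", "far", "other"), chrom = "chr1",
                      strand = "+", tss = c(150000L, 180000L, 900000L),
                      body_start = c(150000L, 180000L, 900000L),
                      body_end = c(151000L, 181000L, 901000L),
                      stringsAsFactors = FALSE)
  enh <- mk_enh(c("e1", "e2"), "chr1", c(100000L, 700000L))
  links <- assign_genes(enh, genes, max_dist = 100000)
  expect_equal(links$gene_id[links$id == "e1"], "near")   # 50 kb beats 80 kb
  expect_equal(links$distance[links$id == "e1"], 50000)
  # nearest TSS 200 kb away -> unassigned
  expect_true(is.na(links$gene_id[links$id == "e2"]))
  # one bp over the limit is unassigned (single-gene annotation)
  one <- genes[genes$gene_id == "near", ]
  enh3 <- mk_enh("e3", "chr1", 150000L + 100001L)
  expect_true(is.na(assign_genes(enh3, one, 100000)$gene_id))
  enh4 <- mk_enh("e4", "chr1", 150000L + 100000L)
  expect_equal(assign_genes(enh4, one, 100000)$gene_id, "near")
})

test_that("equidistant TSS ties break to the lower coordinate", {
  genes <- data.frame(gene_id = c("right", "left"), chrom = "chr1", strand = "+",
                      tss = c(210000L, 190000L),
                      body_start = c(210000L, 190000L),
                      body_end = c(211000L, 191000L), stringsAsFactors = FALSE)
  enh <- mk_enh("mid", "chr1", 200000L)
  expect_equal(assign_genes(enh, genes)$gene_id, "left")
})

test_that("assignment is invariant under genome-wide translation", {
  set.seed(61)
  centers <- sort(sample(1e5:1e6, 20))
  genes <- data.frame(gene_id = paste0("g", 1:8), chrom = "chr1", strand = "+",
                      tss = sort(sample(1e5:1e6, 8)), stringsAsFactors = FALSE)
  genes$body_start <- genes$tss; genes$body_end <- genes$tss + 1000L
  enh <- mk_enh(paste0("e", 1:20), "chr1", centers)
  shift <- 12345L
  genes2 <- genes
  genes2$tss <- genes2$tss + shift
  genes2$body_start <- genes2$body_start + shift
  genes2$body_end <- genes2$body_end + shift
  enh2 <- mk_enh(paste0("e", 1:20), "chr1", centers + shift)
  l1 <- assign_genes(enh, genes)
  l2 <- assign_genes(enh2, genes2)
  expect_identical(l1$gene_id, l2$gene_id)
  expect_identical(l1$distance, l2$distance)
})

test_that("H3K27ac status uses the 2 kb edge-to-edge rule", {
  peaks <- data.frame(chrom = "chr1", start = 50000L, end = 51000L)
  overlapping <- mk_enh("ov", "chr1", 50500L)
  at2000 <- mk_enh("at2000", "chr1", 51000L + 2000L + 1000L)  # gap exactly 2000
  at2001 <- mk_enh("at2001", "chr1", 51000L + 2001L + 1000L)  # gap 2001
  expect_equal(unname(classify_h3k27ac(overlapping, peaks)), "+")
  expect_equal(unname(classify_h3k27ac(at2000, peaks)), "+")
  expect_equal(unname(classify_h3k27ac(at2001, peaks)), "-")
  none <- data.frame(chrom = character(), start = integer(), end = integer())
  expect_equal(unname(classify_h3k27ac(overlapping, none)), "-")
})

test_that("subgroups cross the two statuses and exclude ambiguous", {
  er <- c(e1 = "positive", e2 = "negative", e3 = "ambiguous", e4 = "positive")
  k27 <- c(e1 = "+", e2 = "+", e3 = "-", e4 = "-")
  g <- subgroup_enhancers(er, k27)
  expect_equal(nrow(g), 3L)
  expect_equal(g$subgroup[g$id == "e1"], "eRNA+K27ac+")
  expect_equal(g$subgroup[g$id == "e2"], "eRNA-K27ac+")
  expect_equal(g$subgroup[g$id == "e4"], "eRNA+K27ac-")
  # sizes sum to the number of unambiguous enhancers
  expect_equal(sum(table(g$subgroup)), sum(er != "ambiguous"))
})

test_that("expression comparison dedups genes and detects planted shifts", {
  # identical multisets -> p = 1
  groups <- data.frame(id = paste0("e", 1:6),
                       subgroup = rep(c("A", "B"), each = 3),
                       stringsAsFactors = FALSE)
  links <- data.frame(id = paste0("e", 1:6),
                      gene_id = paste0("g", c(1, 2, 3, 4, 5, 6)),
                      distance = 1000)
  expr <- data.frame(gene_id = paste0("g", 1:6), fpkm = rep(c(1, 2, 3), 2))
  res <- compare_expression(groups, links, expr)
  expect_equal(res$tests$p, 1)
  # duplicate links to one gene count once
  links2 <- links
  links2$gene_id[2] <- "g1"
  res2 <- compare_expression(groups, links2, expr)
  expect_equal(res2$tests$n1, 2L)
  # minimal 1 vs 1 case
  g1 <- data.frame(id = c("e1", "e2"), subgroup = c("A", "B"))
  l1 <- data.frame(id = c("e1", "e2"), gene_id = c("g1", "g2"), distance = 1)
  x1 <- data.frame(gene_id = c("g1", "g2"), fpkm = c(1, 2))
  expect_equal(compare_expression(g1, l1, x1)$tests$p, 1)
  # planted shift in the synthetic generator
  cfg <- synth_config(n_enhancers = 500, n_genes = 500, seed = 3,
                      expression_shift = 2, fraction_low_mappability = 0)
  ann <- synth_annotation(cfg)
  expr_s <- synth_expression(cfg, ann)
  tr <- ann$truth
  groups_s <- data.frame(id = tr$id,
                         subgroup = ifelse(tr$state == "active", "eRNA+", "eRNA-"))
  links_s <- data.frame(id = tr$id, gene_id = tr$linked_gene, distance = 0)
  res_s <- compare_expression(groups_s, links_s, expr_s,
                              pairs = list(c("eRNA+", "eRNA-")))
  expect_lt(res_s$tests$p, 1e-6)
  expect_gt(res_s$summary$median_fpkm[res_s$summary$subgroup == "eRNA+"],
            res_s$summary$median_fpkm[res_s$summary$subgroup == "eRNA-"])
})

test_that("cross-cell-type transfer reproduces in-sample predictions on identity", {
  sig <- toy_signal(n = 400, seed = 31)
  lab <- label_enhancers(sig)
  fit <- erna_logit(sig, lab, marks = c("actA", "rep1"))
  same <- cross_celltype_predict(fit, sig, labels = lab,
                                 standardize = "training")
  insample <- predict(fit, sig)
  expect_equal(same$probability, insample, tolerance = 1e-12)
  expect_gt(same$evaluation$auc, 0.95)
  # target-moment standardization changes scaling, not discrimination
  tgt <- cross_celltype_predict(fit, sig, labels = lab)
  expect_equal(tgt$evaluation$auc, same$evaluation$auc, tolerance = 0.02)
  # missing mark errors by name
  sig2 <- ernapred:::new_erna_signal(sig$x[, c("actB", "neut")],
                                     sig$y_plus, sig$y_minus)
  expect_error(cross_celltype_predict(fit, sig2), "actA")
})

test_that("transfer to an independently generated cell type keeps accuracy", {
  sigA <- toy_signal(n = 800, seed = 41, effect = 2, noise = 0.8)
  sigB <- toy_signal(n = 800, seed = 42, effect = 2, noise = 0.8)
  labA <- label_enhancers(sigA)
  labB <- label_enhancers(sigB)
  fit <- erna_logit(sigA, labA)
  inA <- evaluate_predictions(ernapred:::training_response(labA, rownames(sigA$x))$y,
                              predict(fit, sigA)[ernapred:::training_response(labA, rownames(sigA$x))$ids])
  toB <- cross_celltype_predict(fit, sigB, labels = labB)
  expect_lt(abs(toB$evaluation$auc - inA$auc), 0.03)
})
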