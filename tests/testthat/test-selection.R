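test_that("subset enumeration is complete, ordered and validated", {
  marks <- c("d", "b", "a", "c")
  s2 <- enumerate_subsets(marks, 2)
  expect_length(s2, choose(4, 2))
  expect_identical(s2[[1]], c("a", "b"))
  expect_length(enumerate_subsets(marks, 4), 1L)
  expect_error(enumerate_subsets(marks, 0), "out of range")
  expect_error(enumerate_subsets(marks, 5), "out of range")
  # no duplicates
  expect_equal(anyDuplicated(vapply(s2, paste, "", collapse = "+")), 0L)
})

test_that("cv plan stratifies and is deterministic under the seed", {
  y <- setNames(rep(c(1L, 0L), c(80, 20)), paste0("e", 1:100))
  p1 <- make_cv_plan(y, k = 10, seed = 3)
  p2 <- make_cv_plan(y, k = 10, seed = 3)
  expect_identical(p1$fold, p2$fold)
  expect_equal(as.vector(table(p1$fold)), rep(10L, 10))
  for (f in 1:10) {
    expect_equal(sum(p1$y[p1$fold == f] == 1L), 8L)
    expect_equal(sum(p1$y[p1$fold == f] == 0L), 2L)
  }
  expect_error(make_cv_plan(y, k = 1), "folds")
  expect_false(identical(make_cv_plan(y, k = 10, seed = 4)$fold, p1$fold))
})

test_that("nested CV with a single candidate reduces to plain K-fold CV", {
  sig <- toy_signal(n = 300, seed = 14)
  state <- attr(sig, "state")
  labs <- setNames(state, rownames(sig$x))
  plan <- make_cv_plan(labs, k = 5, inner_k = 3, seed = 2)
  res <- nested_cv_evaluate(sig, labs, list(c("actA", "neut")), plan)
  # plain K-fold of the same subset with the same folds
  x <- sig$x[match(plan$ids, rownames(sig$x)), c("actA", "neut")]
  plain <- vapply(1:5, function(ko) {
    ernapred:::fit_score(x, plan$y, which(plan$fold != ko),
                         which(plan$fold == ko))[["auc"]]
  }, 0)
  expect_equal(unlist(res[1, paste0("auc_fold", 1:5)]), plain,
               ignore_attr = TRUE)
  expect_equal(res$mean_auc, mean(plain))
  expect_equal(res$n_folds_scored, 5L)
})

test_that("nested CV is bit-identical under a fixed seed and hides test data", {
  sig <- toy_signal(n = 200, seed = 15)
  labs <- setNames(attr(sig, "state"), rownames(sig$x))
  plan <- make_cv_plan(labs, k = 4, inner_k = 3, seed = 9)
  subs <- enumerate_subsets(colnames(sig$x), 2)
  r1 <- nested_cv_evaluate(sig, labs, subs, plan, top_n_inner = 3)
  r2 <- nested_cv_evaluate(sig, labs, subs, plan, top_n_inner = 3)
  expect_identical(r1, r2)
  # with top_n_inner < number of candidates some subsets go unscored
  expect_true(all(r1$n_folds_scored >= 1))
  expect_lte(nrow(r1), length(subs))
  expect_error(nested_cv_evaluate(sig, labs, subs, plan, top_n_inner = 0),
               "top_n_inner")
})

test_that("select_top_models applies both published rules", {
  res <- data.frame(subset = sprintf("s%02d", 1:100), m = 4,
                    mean_auc = seq(0.99, 0.01, length.out = 100),
                    mean_mcc = seq(0.9, 0.0, length.out = 100))
  class(res) <- c("subset_results", "data.frame")
  # identical rankings: exactly 5 selected at 5%
  sel <- select_top_models(res, "top_fraction", fraction = 0.05)
  expect_equal(nrow(sel$selected), 5L)
  expect_equal(sel$selected$subset, sprintf("s%02d", 1:5))
  # disjoint rankings: empty intersection
  res2 <- res
  res2$mean_mcc <- rev(res2$mean_mcc)
  expect_warning(sel2 <- select_top_models(res2, "top_fraction", fraction = 0.05),
                 "empty")
  expect_equal(nrow(sel2$selected), 0L)
  # relative rule arithmetic: 0.86 >= 0.95*0.90 and 0.58 >= 0.95*0.60
  res3 <- data.frame(subset = c("good", "bad"), m = 4,
                     mean_auc = c(0.86, 0.80), mean_mcc = c(0.58, 0.50))
  class(res3) <- c("subset_results", "data.frame")
  sel3 <- select_top_models(res3, "relative", full_auc = 0.90, full_mcc = 0.60)
  expect_equal(sel3$selected$subset, "good")
})

test_that("mark enrichment equals exact combinatorial enumeration", {
  mk_report <- function(universe, selected) {
    res <- data.frame(subset = universe, m = 2,
                      mean_auc = seq(1, 0.5, length.out = length(universe)),
                      mean_mcc = seq(1, 0.5, length.out = length(universe)))
    class(res) <- c("subset_results", "data.frame")
    structure(list(selected = res[match(selected, universe), ],
                   rule = "top_fraction", params = list(), results = res),
              class = "selection_report")
  }
  # worked example: N=10, K_pop=5, n=4, k=4
  uni <- c(paste0("A+x", 1:5), paste0("y", 1:5, "+z", 1:5))
  rep1 <- mk_report(uni, uni[1:4])
  e <- mark_enrichment(rep1, "A")
  expect_equal(e$p, 5 / 210)
  expect_equal(c(e$k, e$K_pop, e$n, e$N), c(4, 5, 4, 10))
  # mark in every subset -> p = 1; absent from selection -> p = 1
  uni2 <- paste0("A+m", 1:6)
  expect_equal(mark_enrichment(mk_report(uni2, uni2[1:3]), "A")$p, 1)
  expect_equal(mark_enrichment(rep1, "z4")$p, 1)
  expect_error(mark_enrichment(rep1, "absent"), "absent")
  # randomized oracle equivalence for N <= 12
  set.seed(33)
  for (r in 1:100) {
    N <- sample(4:12, 1)
    K_pop <- sample(1:N, 1)
    uni <- c(paste0("T+f", seq_len(K_pop)),
             if (K_pop < N) paste0("g", seq_len(N - K_pop), "+h", seq_len(N - K_pop)))
    n <- sample(1:N, 1)
    sel <- sample(uni, n)
    k <- sum(grepl("(^|\\+)T(\\+|$)", sel))
    got <- mark_enrichment(mk_report(uni, sel), "T")$p
    expect_equal(got, hyper_upper_enum(k, K_pop, N, n), tolerance = 1e-12)
  }
})

test_that("m-vs-m+1 comparison is an exact paired signed-rank test", {
  mk_res <- function(auc) {
    k <- length(auc)
    df <- data.frame(subset = "s", m = 1)
    df[paste0("auc_fold", 1:k)] <- as.list(auc)
    df[paste0("mcc_fold", 1:k)] <- as.list(auc)
    df$mean_auc <- mean(auc); df$mean_mcc <- mean(auc); df$n_folds_scored <- k
    attr(df, "k") <- k
    class(df) <- c("subset_results", "data.frame")
    df
  }
  a <- seq(0.80, 0.89, by = 0.01)
  # identical vectors -> p = 1
  expect_equal(compare_m_performance(mk_res(a), mk_res(a))$p.value, 1)
  # uniformly better in all 10 folds -> exact two-sided tail 2/2^10
  b <- a + seq(0.011, 0.02, by = 0.001)
  expect_equal(compare_m_performance(mk_res(a), mk_res(b))$p.value,
               2 / 2^10)
  # K = 1 is insufficient
  expect_error(compare_m_performance(mk_res(0.8), mk_res(0.9)), "insufficient")
})

test_that("true informative subset wins nested CV on planted data", {
  # 2 informative of 6 marks at m=2: quick single-replicate check
  set.seed(55)
  n <- 600
  state <- rbinom(n, 1, 0.5)
  x <- matrix(rnorm(n * 6, sd = 1), n, 6,
              dimnames = list(paste0("e", 1:n),
                              c("inf1", "inf2", "n1", "n2", "n3", "n4")))
  x[, "inf1"] <- x[, "inf1"] + 2.5 * state
  x[, "inf2"] <- x[, "inf2"] - 2.5 * state
  labs <- setNames(state, rownames(x))
  plan <- make_cv_plan(labs, k = 5, inner_k = 5, seed = 6)
  res <- nested_cv_evaluate(x, labs, enumerate_subsets(colnames(x), 2), plan,
                            top_n_inner = 5)
  expect_equal(res$subset[1], "inf1+inf2")
})

test_that("nested-CV outer AUC does not beat full-data refit (optimism check)", {
  sig <- toy_signal(n = 400, seed = 44, effect = 1.2, noise = 1)
  labs <- setNames(attr(sig, "state"), rownames(sig$x))
  plan <- make_cv_plan(labs, k = 5, inner_k = 4, seed = 11)
  res <- nested_cv_evaluate(sig, labs, list(colnames(sig$x)), plan)
  fit <- erna_logit(sig$x, labs[rownames(sig$x)])
  full_auc <- roc_auc(labs, predict(fit, sig$x))$auc
  expect_lte(res$mean_auc[1], full_auc + 0.02)
})
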