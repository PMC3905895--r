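#' Enumerate all size-m mark subsets
#'
#' @param marks character vector of mark names.
#' @param m subset size, \code{1 <= m <= length(marks)}.
#' @return A list of character vectors, all \code{choose(length(marks), m)}
#'   subsets in deterministic lexicographic order.
#' @export
enumerate_subsets <- function(marks, m) {
  if (m < 1L || m > length(marks)) {
    stop("subset size m out of range [1, ", length(marks), "]", call. = FALSE)
  }
  marks <- sort(marks)
  cmb <- combn(marks, m, simplify = FALSE)
  cmb[order(vapply(cmb, paste, "", collapse = "\r"))]
}

#' Build a stratified cross-validation plan
#'
#' Outer folds partition the unambiguous (positive/negative) enhancers,
#' stratified by label so each fold carries the class balance of the whole
#' set; deterministic under the seed. Inner folds used inside
#' [nested_cv_evaluate()] are derived from the same seed.
#'
#' @param labels an \code{erna_labels} object (ambiguous excluded), or a 0/1
#'   vector named by enhancer id.
#' @param k number of outer folds (default 10).
#' @param inner_k number of inner folds (default 10).
#' @param seed RNG seed.
#' @return A list of class \code{cv_plan}: \code{ids}, \code{y}, a
#'   \code{fold} assignment per id, \code{k}, \code{inner_k}, \code{seed}.
#' @export
make_cv_plan <- function(labels, k = 10L, inner_k = 10L, seed = 1L) {
  if (inherits(labels, "erna_labels") || is.data.frame(labels)) {
    keep <- labels$label != "ambiguous"
    ids <- labels$id[keep]
    y <- as.integer(labels$label[keep] == "positive")
  } else {
    y <- as.integer(labels)
    ids <- names(labels) %||% as.character(seq_along(y))
  }
  if (k < 2L) stop("need at least 2 folds", call. = FALSE)
  if (min(table(y)) < k) {
    stop("too few members of one class for ", k, " stratified folds", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(ids = ids, y = y, fold = fold, k = as.integer(k),
                 inner_k = as.integer(inner_k), seed = as.integer(seed)),
            class = "cv_plan")
}

## stratified fold assignment for an index subset, seeded
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## fit on train rows, AUC (and optionally MCC) on test rows; X standardized
## inside erna_logit would repeat work, so this lean path standardizes once
## per call on the training rows only.
fit_score <- function(X, y, train, test, lambda = 1e-6, want_mcc = FALSE) {
  Xtr <- X[train, , drop = FALSE]
  ctr <- colMeans(Xtr)
  sc <- sqrt(colSums(sweep(Xtr, 2, ctr)^2) / (nrow(Xtr) - 1))
  sc[sc <= 0] <- 1
  Xs <- sweep(sweep(Xtr, 2, ctr), 2, sc, "/")
  fit <- logit_newton(cbind(1, Xs), y[train], lambda = lambda, tol = 1e-8,
                      max_iter = 50L, diagnostics = FALSE)
  Xte <- sweep(sweep(X[test, , drop = FALSE], 2, ctr), 2, sc, "/")
  p <- plogis(drop(fit$beta[1] + Xte %*% fit$beta[-1]))
  auc <- auc_rank(y[test], p)
  if (want_mcc) {
    c(auc = auc, mcc = mcc(confusion_at_threshold(y[test], p, 0.5)))
  } else c(auc = auc)
}

## AUC without the ROC-point bookkeeping (hot path)
auc_rank <- function(y, s) {
  P <- sum(y == 1L); N <- length(y) - P
  (sum(rank(s)[y == 1L]) - P * (P + 1) / 2) / (P * N)
}

#' Evaluate mark subsets under nested cross-validation
#'
#' For each outer fold, an inner K-fold cross-validation on the outer
#' training data ranks every candidate subset by mean inner AUC; the
#' \code{top_n_inner} best are refit on the full outer training data and
#' scored (AUC and MCC at 0.5) on the held-out fold. Subsets selected in the
#' inner loop are therefore never exposed to outer test data. Subsets that
#' never reach any fold's inner top list carry no outer score and are
#' dropped from the ranking; outer scores are averaged across the folds
#' where the subset was scored.
#'
#' @param signal an \code{erna_signal} or numeric matrix.
#' @param labels labels accepted by [make_cv_plan()] (used only to align
#'   rows; the plan carries the response).
#' @param subsets list of mark-name vectors, e.g. from [enumerate_subsets()].
#' @param plan a \code{cv_plan}.
#' @param top_n_inner how many inner-ranked subsets advance to outer scoring
#'   per fold (default 10).
#' @param lambda ridge penalty passed to the fits.
#' @return data.frame of class \code{subset_results}: one row per evaluated
#'   subset with \code{subset} (collapsed by \code{+}), \code{m}, per-fold
#'   AUC/MCC columns (NA where not scored), \code{mean_auc}, \code{mean_mcc},
#'   \code{n_folds_scored}, ranked by mean AUC (ties: mean MCC, then subset
#'   order).
#' @export
nested_cv_evaluate <- function(signal, labels, subsets, plan,
                               top_n_inner = 10L, lambda = 1e-6) {
  stopifnot(inherits(plan, "cv_plan"), length(subsets) > 0L)
  if (top_n_inner < 1L) stop("top_n_inner must be >= 1", call. = FALSE)
  x <- if (inherits(signal, "erna_signal")) signal$x else signal
  idx <- match(plan$ids, rownames(x))
  if (anyNA(idx)) stop("plan ids missing from signal matrix", call. = FALSE)
  x <- x[idx, , drop = FALSE]
  y <- plan$y
  sub_names <- vapply(subsets, paste, "", collapse = "+")
  nS <- length(subsets)
  K <- plan$k
  auc_f <- matrix(NA_real_, nS, K, dimnames = list(sub_names, NULL))
  mcc_f <- matrix(NA_real_, nS, K, dimnames = list(sub_names, NULL))
  sub_cols <- lapply(subsets, function(s) match(s, colnames(x)))
  if (anyNA(unlist(sub_cols))) stop("subset mark absent from signal matrix", call. = FALSE)

  sub_cols0 <- lapply(sub_cols, function(ci) as.integer(ci - 1L))
  for (ko in seq_len(K)) {
    outer_train <- which(plan$fold != ko)
    outer_test <- which(plan$fold == ko)
    inner_fold <- stratified_folds(y[outer_train], plan$inner_k,
                                   seed = plan$seed * 131L + ko)
    inner_auc <- .inner_cv_auc_cpp(x[outer_train, , drop = FALSE],
                                   as.integer(y[outer_train]), sub_cols0,
                                   as.integer(inner_fold), plan$inner_k,
                                   lambda, 1e-8, 50L)
    mean_inner <- rowMeans(inner_auc)
    top <- order(-mean_inner, seq_len(nS))[seq_len(min(top_n_inner, nS))]
    for (s in top) {
      sc <- fit_score(x[, sub_cols[[s]], drop = FALSE], y, outer_train,
                      outer_test, lambda, want_mcc = TRUE)
      auc_f[s, ko] <- sc[["auc"]]
      mcc_f[s, ko] <- sc[["mcc"]]
    }
  }
  scored <- rowSums(!is.na(auc_f)) > 0L
  out <- data.frame(subset = sub_names, m = lengths(subsets),
                    stringsAsFactors = FALSE)
  colnames(auc_f) <- paste0("auc_fold", seq_len(K))
  colnames(mcc_f) <- paste0("mcc_fold", seq_len(K))
  out <- cbind(out, auc_f, mcc_f)
  out$mean_auc <- rowMeans(auc_f, na.rm = TRUE)
  out$mean_mcc <- rowMeans(mcc_f, na.rm = TRUE)
  out$n_folds_scored <- rowSums(!is.na(auc_f))
  out <- out[scored, , drop = FALSE]
  out$mean_auc[is.nan(out$mean_auc)] <- NA_real_
  out <- out[order(-out$mean_auc, -out$mean_mcc, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- K
  attr(out, "n_candidates") <- nS
  attr(out, "all_subsets") <- sub_names
  class(out) <- c("subset_results", "data.frame")
  out
}

#' Select top models from subset results
#'
#' Two selection rules: \code{"top_fraction"} takes the intersection of the
#' top fraction by mean AUC and the top fraction by mean MCC (default 5\%,
#' measured against the number of constructed candidate models);
#' \code{"relative"} keeps subsets reaching at least \code{ratio} of the
#' full model's AUC and MCC (default 0.95).
#'
#' @param results a \code{subset_results} data.frame.
#' @param rule \code{"top_fraction"} or \code{"relative"}.
#' @param fraction top fraction for the first rule (default 0.05).
#' @param full_auc,full_mcc full-model reference performance (required for
#'   the relative rule).
#' @param ratio relative-rule ratio (default 0.95).
#' @return A list of class \code{selection_report}: \code{selected}
#'   (data.frame of selected rows), \code{rule}, parameters, and the
#'   evaluated results.
#' @export
select_top_models <- function(results, rule = c("top_fraction", "relative"),
                              fraction = 0.05, full_auc = NULL, full_mcc = NULL,
                              ratio = 0.95) {
  rule <- match.arg(rule)
  stopifnot(nrow(results) > 0L)
  if (rule == "top_fraction") {
    # the fraction is of all constructed candidate models; subsets that never
    # reached an inner top list simply cannot be among the winners
    n_universe <- attr(results, "n_candidates") %||% nrow(results)
    n_top <- min(max(1L, floor(fraction * n_universe)), nrow(results))
    by_auc <- results$subset[order(-results$mean_auc, results$subset)][seq_len(n_top)]
    by_mcc <- results$subset[order(-results$mean_mcc, results$subset)][seq_len(n_top)]
    chosen <- intersect(by_auc, by_mcc)
    params <- list(fraction = fraction, n_top = n_top)
  } else {
    if (is.null(full_auc) || is.null(full_mcc)) {
      stop("relative rule needs full-model AUC and MCC", call. = FALSE)
    }
    chosen <- results$subset[results$mean_auc >= ratio * full_auc &
                             results$mean_mcc >= ratio * full_mcc]
    params <- list(ratio = ratio, full_auc = full_auc, full_mcc = full_mcc)
  }
  if (length(chosen) == 0L) warning("selection is empty under rule '", rule, "'")
  sel <- results[match(chosen, results$subset), , drop = FALSE]
  sel <- sel[order(-sel$mean_auc, -sel$mean_mcc, sel$subset), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(selected = sel, rule = rule, params = params,
                 results = results),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("model selection: %d of %d evaluated subsets selected (rule: %s)\n",
              nrow(x$selected), nrow(x$results), x$rule))
  if (nrow(x$selected)) {
    top <- head(x$selected[, c("subset", "mean_auc", "mean_mcc")], 5)
    top$mean_auc <- round(top$mean_auc, 4)
    top$mean_mcc <- round(top$mean_mcc, 4)
    print(top)
  }
  cat("note: enrichment p-values are raw hypergeometric, no multiplicity correction\n")
  invisible(x)
}

#' Hypergeometric over-representation of a mark among selected models
#'
#' One-sided upper-tail hypergeometric test: from a population of N
#' evaluated subsets of which K contain the mark, n were selected and k of
#' those contain the mark; p = P(X >= k).
#'
#' @param report a \code{selection_report}.
#' @param mark mark name.
#' @return A one-row data.frame: \code{mark}, \code{k}, \code{K_pop},
#'   \code{n}, \code{N}, \code{p}.
#' @export
mark_enrichment <- function(report, mark) {
  stopifnot(inherits(report, "selection_report"))
  if (nrow(report$selected) == 0L) stop("selection is empty", call. = FALSE)
  universe <- strsplit(report$results$subset, "+", fixed = TRUE)
  if (!mark %in% unique(unlist(universe))) {
    stop("mark '", mark, "' absent from the evaluated subset universe", call. = FALSE)
  }
  sel <- strsplit(report$selected$subset, "+", fixed = TRUE)
  N <- length(universe)
  K_pop <- sum(vapply(universe, function(s) mark %in% s, logical(1)))
  n <- length(sel)
  k <- sum(vapply(sel, function(s) mark %in% s, logical(1)))
  p <- phyper(k - 1, K_pop, N - K_pop, n, lower.tail = FALSE)
  data.frame(mark = mark, k = k, K_pop = K_pop, n = n, N = N, p = p,
             stringsAsFactors = FALSE)
}

#' Compare best-model performance between subset sizes m and m+1
#'
#' Paired two-sided Wilcoxon signed-rank test on the per-outer-fold AUCs of
#' the best subset at each size; the AUCs share folds, hence the pairing.
#' Exact distribution when the fold count permits.
#'
#' @param results_m,results_m_plus_1 \code{subset_results} for the two sizes
#'   (their top rows are compared).
#' @return A list with the fold-wise AUC vectors, the best subset names and
#'   \code{p.value}.
#' @export
compare_m_performance <- function(results_m, results_m_plus_1) {
  k1 <- attr(results_m, "k"); k2 <- attr(results_m_plus_1, "k")
  if (is.null(k1) || is.null(k2) || k1 != k2) {
    stop("mismatched outer fold sets", call. = FALSE)
  }
  if (k1 < 2L) stop("insufficient fold pairs for a paired test", call. = FALSE)
  get_best <- function(res) {
    # prefer the top-ranked subset that was scored on every outer fold
    i <- which(res$n_folds_scored == attr(res, "k"))[1]
    if (is.na(i)) i <- 1L
    v <- unlist(res[i, paste0("auc_fold", seq_len(attr(res, "k")))])
    list(subset = res$subset[i], auc = as.numeric(v))
  }
  a <- get_best(results_m); b <- get_best(results_m_plus_1)
  both <- !is.na(a$auc) & !is.na(b$auc)
  if (sum(both) < 2L) {
    stop("insufficient fold pairs with scores for both subset sizes", call. = FALSE)
  }
  a$auc <- a$auc[both]; b$auc <- b$auc[both]
  if (all(a$auc == b$auc)) {
    p <- 1
  } else {
    p <- suppressWarnings(
      wilcox.test(a$auc, b$auc, paired = TRUE,
                  exact = (k1 <= 25))$p.value)
  }
  list(best_m = a$subset, best_m_plus_1 = b$subset,
       auc_m = a$auc, auc_m_plus_1 = b$auc, p.value = p)
}
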