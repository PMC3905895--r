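# Small in-code fixtures shared across test files.

# brute-force AUC: pairwise positive-negative comparisons, ties half credit
auc_bruteforce <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# brute-force optimal 2-partition by within-cluster sum of squares over all
# 2^n - 2 assignments (n <= 12 in tests)
kmeans2_bruteforce <- function(v) {
  n <- length(v)
  best <- Inf
  best_assign <- NULL
  for (mask in 1:(2^n - 2)) {
    a <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    wss <- sum((v[a] - mean(v[a]))^2) + sum((v[!a] - mean(v[!a]))^2)
    if (wss < best - 1e-12) {
      best <- wss
      best_assign <- a
    }
  }
  # orient: TRUE = high cluster
  if (mean(v[best_assign]) < mean(v[!best_assign])) best_assign <- !best_assign
  list(high = best_assign, wss = best)
}

# exact upper-tail hypergeometric by enumerating the support
hyper_upper_enum <- function(k, K_pop, N, n) {
  sum(vapply(k:min(K_pop, n), function(i) {
    choose(K_pop, i) * choose(N - K_pop, n - i)
  }, 0)) / choose(N, n)
}

# a tiny deterministic gene table: two genes on chr1
tiny_genes <- function() {
  data.frame(gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
             tss = c(100000L, 259999L), body_start = c(100000L, 250000L),
             body_end = c(110000L, 260000L), stringsAsFactors = FALSE)
}

# uniform mappability covering chr1/chr2
flat_mappability <- function(value = 1, len = 10000000L) {
  data.frame(chrom = c("chr1", "chr2"), start = 0L, end = len, value = value,
             stringsAsFactors = FALSE)
}

# signal matrix with marks drawn around a planted binary state
toy_signal <- function(n = 200, seed = 1, effect = 3, noise = 0.5,
                       gro_effect = 4) {
  set.seed(seed)
  state <- rbinom(n, 1, 0.5)
  x <- cbind(actA = effect * state + rnorm(n, sd = noise),
             actB = 0.8 * effect * state + rnorm(n, sd = noise),
             rep1 = -effect * state + rnorm(n, sd = noise),
             neut = rnorm(n, sd = noise))
  rownames(x) <- sprintf("e%04d", seq_len(n))
  sig <- ernapred:::new_erna_signal(
    x,
    y_plus = gro_effect * state + rnorm(n, sd = noise),
    y_minus = gro_effect * state + rnorm(n, sd = noise))
  attr(sig, "state") <- state
  sig
}
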