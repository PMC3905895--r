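#' Exact 1-D 2-means clustering
#'
#' Finds the global optimum of two-cluster K-means in one dimension by
#' scanning the n-1 split points of the sorted values: the optimal 2-means
#' partition of points on a line is always an interval split, so the scan is
#' exact and removes initialization randomness entirely. The cluster with
#' the larger mean is labeled high; ties at the threshold go to the low
#' cluster (conservative).
#'
#' @param values numeric vector with at least two distinct values.
#' @return A list with \code{assignment} (\code{"low"}/\code{"high"} per
#'   input value), \code{means} (named low/high cluster means), and
#'   \code{threshold}, the midpoint between the boundary members.
#' @export
kmeans_1d_two <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  if (length(unique(values)) < 2L) {
    stop("degenerate input: all values identical", call. = FALSE)
  }
  s <- sort(values)
  n <- length(s)
  cs <- cumsum(s)
  tot <- cs[n]
  k <- seq_len(n - 1L)
  # within-cluster SS = total SS - sum of per-cluster n*mean^2 (+const)
  obj <- cs[k]^2 / k + (tot - cs[k])^2 / (n - k)
  split <- which.max(obj)  # maximizing between-cluster term minimizes WSS
  thr <- (s[split] + s[split + 1L]) / 2
  lo_mean <- cs[split] / split
  hi_mean <- (tot - cs[split]) / (n - split)
  assignment <- ifelse(values <= thr, "low", "high")
  list(assignment = assignment,
       means = c(low = lo_mean, high = hi_mean),
       threshold = thr)
}

#' Label enhancers eRNA-positive / negative / ambiguous from GRO-seq
#'
#' Two independent exact 2-means clusterings partition the log GRO-seq
#' densities on the sense and the antisense strand into high and low groups.
#' Because eRNAs are bidirectionally transcribed, an enhancer is
#' eRNA-positive only when it falls in the high cluster on both strands, and
#' eRNA-negative only when low on both; mixed-strand enhancers are labeled
#' ambiguous and flagged for exclusion from supervised training, though a
#' trained model can still score them.
#'
#' @param signal an \code{erna_signal} carrying \code{y_plus} and
#'   \code{y_minus}.
#' @return data.frame of class \code{erna_labels}: \code{id}, \code{label}
#'   (\code{positive}/\code{negative}/\code{ambiguous}), \code{y_plus},
#'   \code{y_minus}, \code{sense_call}, \code{antisense_call}; per-strand
#'   thresholds and cluster means as attributes.
#' @export
label_enhancers <- function(signal) {
  stopifnot(inherits(signal, "erna_signal"))
  if (is.null(signal$y_plus) || is.null(signal$y_minus)) {
    stop("signal matrix has no stranded GRO-seq densities", call. = FALSE)
  }
  km_p <- kmeans_1d_two(signal$y_plus)
  km_m <- kmeans_1d_two(signal$y_minus)
  label <- ifelse(km_p$assignment == "high" & km_m$assignment == "high", "positive",
           ifelse(km_p$assignment == "low" & km_m$assignment == "low", "negative",
                  "ambiguous"))
  out <- data.frame(id = rownames(signal$x), label = label,
                    y_plus = signal$y_plus, y_minus = signal$y_minus,
                    sense_call = km_p$assignment,
                    antisense_call = km_m$assignment,
                    stringsAsFactors = FALSE)
  attr(out, "sense_threshold") <- km_p$threshold
  attr(out, "antisense_threshold") <- km_m$threshold
  attr(out, "sense_means") <- km_p$means
  attr(out, "antisense_means") <- km_m$means
  class(out) <- c("erna_labels", "data.frame")
  out
}

#' @export
print.erna_labels <- function(x, ...) {
  tab <- table(factor(x$label, levels = c("positive", "negative", "ambiguous")))
  cat("eRNA labels from bidirectional GRO-seq clustering\n")
  cat(sprintf("  positive: %d   negative: %d   ambiguous (excluded from training): %d\n",
              tab["positive"], tab["negative"], tab["ambiguous"]))
  cat(sprintf("  sense threshold %.3f, antisense threshold %.3f\n",
              attr(x, "sense_threshold"), attr(x, "antisense_threshold")))
  invisible(x)
}

## binary 0/1 response over the unambiguous enhancers, in signal order
training_response <- function(labels, ids) {
  lab <- labels$label[match(ids, labels$id)]
  keep <- !is.na(lab) & lab != "ambiguous"
  list(ids = ids[keep], y = as.integer(lab[keep] == "positive"))
}
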