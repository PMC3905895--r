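#' Logistic regression linking chromatin marks to eRNA production
#'
#' Fits the model \eqn{\mathrm{logit}\, p_j = \beta_0 + \sum_i \beta_i
#' x_{ij}} where \eqn{p_j} is the probability that enhancer \eqn{j} is
#' eRNA-positive and \eqn{x_{ij}} is the log read density of mark \eqn{i} at
#' that enhancer. Features are standardized (mean 0, sd 1) before fitting so
#' coefficients are comparable across marks; the fit is maximum likelihood
#' by Newton-Raphson with a small L2 (ridge) penalty for numerical
#' stability, with step-halving whenever a Newton step would decrease the
#' penalized log-likelihood. Coefficients on the raw density scale are
#' recoverable via \code{coef(fit, scale = "raw")}.
#'
#' @param signal an \code{erna_signal}, or a plain numeric matrix with
#'   rownames.
#' @param labels an \code{erna_labels} object (ambiguous enhancers are
#'   excluded), or a 0/1 vector aligned with the matrix rows.
#' @param marks character vector of mark names to use (default: all columns).
#' @param lambda ridge penalty on standardized coefficients, default
#'   \code{1e-6}; set 0 for plain maximum likelihood.
#' @param tol convergence: maximum absolute score below \code{tol}
#'   (default \code{1e-8}).
#' @param max_iter Newton iteration cap (default 100).
#' @return An object of class \code{erna_logit}.
#' @export
erna_logit <- function(signal, labels, marks = NULL, lambda = 1e-6,
                       tol = 1e-8, max_iter = 100L) {
  x <- if (inherits(signal, "erna_signal")) signal$x else signal
  stopifnot(is.matrix(x))
  if (inherits(labels, "erna_labels") || is.data.frame(labels)) {
    tr <- training_response(labels, rownames(x))
    x <- x[match(tr$ids, rownames(x)), , drop = FALSE]
    y <- tr$y
  } else {
    y <- as.integer(labels)
    stopifnot(length(y) == nrow(x), all(y %in% c(0L, 1L)))
  }
  if (is.null(marks)) marks <- colnames(x)
  missing_marks <- setdiff(marks, colnames(x))
  if (length(missing_marks)) {
    stop("mark(s) not in signal matrix: ", paste(missing_marks, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, marks, drop = FALSE]
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  if (any(scale_ <= 0)) {
    stop("constant feature column(s): ", paste(marks[scale_ <= 0], collapse = ", "),
         call. = FALSE)
  }
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  fit <- logit_newton(cbind(1, xs), y, lambda = lambda, tol = tol,
                      max_iter = max_iter)
  beta <- fit$beta
  names(beta) <- c("(Intercept)", marks)
  # back-transform to raw-density scale
  raw_slopes <- beta[-1] / scale_
  raw <- c(beta[1] - sum(raw_slopes * center), raw_slopes)
  names(raw) <- names(beta)
  structure(list(marks = marks, coefficients = beta, coefficients_raw = raw,
                 center = center, scale = scale_, lambda = lambda,
                 converged = fit$converged, iterations = fit$iterations,
                 loglik = fit$loglik, vcov = fit$vcov,
                 n = length(y), n_pos = sum(y), fitted = fit$fitted,
                 y_train = y),
            class = "erna_logit")
}

## Newton-Raphson with ridge penalty and step-halving on X including the
## intercept column (compiled core). Penalty applies to all coefficients
## (negligible at the default lambda; exact ML at lambda = 0).
logit_newton <- function(X, y, lambda = 1e-6, tol = 1e-8, max_iter = 100L,
                         diagnostics = TRUE) {
  fit <- .logit_newton_cpp(X, as.numeric(y), lambda, tol, as.integer(max_iter),
                           diagnostics)
  fit$beta <- drop(fit$beta)
  fit$fitted <- drop(fit$fitted)
  fit
}

#' @export
print.erna_logit <- function(x, ...) {
  cat(sprintf("eRNA logistic regression: %d marks, n = %d (%d positive)\n",
              length(x$marks), x$n, x$n_pos))
  cat(sprintf("  %s in %d Newton iterations, log-likelihood %.2f, ridge %.1e\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$loglik, x$lambda))
  cat("  standardized coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.erna_logit <- function(object, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  if (scale == "standardized") object$coefficients else object$coefficients_raw
}

#' @export
summary.erna_logit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  out <- list(coefficients = tab, loglik = object$loglik,
              converged = object$converged, iterations = object$iterations,
              n = object$n, n_pos = object$n_pos, lambda = object$lambda)
  class(out) <- "summary.erna_logit"
  out
}

#' @export
print.summary.erna_logit <- function(x, ...) {
  cat(sprintf("eRNA logistic regression (n = %d, %d positive; ridge %.1e)\n",
              x$n, x$n_pos, x$lambda))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("log-likelihood %.2f; %s in %d iterations\n", x$loglik,
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' Predict eRNA probabilities for enhancers
#'
#' @param object an \code{erna_logit} fit.
#' @param newdata an \code{erna_signal} or numeric matrix containing all the
#'   model's marks; standardization parameters stored at fit time are
#'   applied unless \code{center}/\code{scale} overrides are given.
#' @param type \code{"response"} for probabilities in (0,1), \code{"link"}
#'   for the linear predictor.
#' @param center,scale optional per-mark standardization overrides (used for
#'   cross-cell-type transfer, where the target cell's own moments are
#'   preferred).
#' @param ... unused.
#' @return Named numeric vector, one value per enhancer row.
#' @export
predict.erna_logit <- function(object, newdata, type = c("response", "link"),
                               center = NULL, scale = NULL, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "erna_signal")) newdata$x else newdata
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list("1", names(x)))
  missing_marks <- setdiff(object$marks, colnames(x))
  if (length(missing_marks)) {
    stop("mark(s) missing from prediction input: ",
         paste(missing_marks, collapse = ", "), call. = FALSE)
  }
  x <- x[, object$marks, drop = FALSE]
  center <- center %||% object$center
  scale <- scale %||% object$scale
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  eta <- drop(object$coefficients[1] + xs %*% object$coefficients[-1])
  names(eta) <- rownames(x)
  if (type == "link") eta else plogis(eta)
}

#' @export
residuals.erna_logit <- function(object, type = c("deviance", "pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- object$fitted
  y <- object$y_train
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu * (1 - mu)),
         deviance = sign(y - mu) * sqrt(-2 * (y * log(pmax(mu, 1e-300)) +
                                              (1 - y) * log(pmax(1 - mu, 1e-300)))))
}

#' Simulate responses from a fitted eRNA model
#' @param object an \code{erna_logit} fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame of 0/1 draws, one column per simulation.
#' @export
simulate.erna_logit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  out <- as.data.frame(replicate(nsim, rbinom(length(mu), 1L, mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
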