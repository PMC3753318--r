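#' Estimate the null proportion pi0
#'
#' Storey's estimator \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} /
#' (m(1-\lambda))} evaluated over a grid of tuning values and smoothed with
#' a cubic smoothing spline (3 df), read off at the largest \eqn{\lambda}
#' and clamped to (0, 1]. With fewer than 10 p-values the smoother is
#' unreliable, so the fixed-\eqn{\lambda = 0.5} estimate is used instead
#' (with a warning).
#'
#' @param p Vector of p-values in [0, 1].
#' @param lambda Tuning grid (default 0.05 to 0.90 in steps of 0.05).
#' @return Estimated null proportion in (0, 1].
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.90, by = 0.05)) {
  check_pvalues(p)
  m <- length(p)
  if (m < 10L) {
    warning("fewer than 10 p-values; using the fixed lambda = 0.5 estimator")
    pi0 <- mean(p > 0.5) / 0.5
  } else {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
  }
  if (pi0 <= 0) {
    warning("pi0 estimate non-positive; clamping to 1/m")
    pi0 <- 1 / m
  }
  min(pi0, 1)
}

check_pvalues <- function(p) {
  if (anyNA(p)) stop("p-values must not contain NA")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  invisible(p)
}

#' Storey q-values
#'
#' Computes q-values by the step-up minimum
#' \deqn{q_{(i)} = \min_{j \ge i} \hat\pi_0 \, m \, p_{(j)} / j}
#' on the sorted p-values, mapped back to input order. With
#' \eqn{\hat\pi_0 = 1} this reduces exactly to Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param p Vector of p-values in [0, 1].
#' @param lambda Tuning grid passed to \code{\link{estimate_pi0}}.
#' @param pi0 Optional fixed null proportion; estimated when \code{NULL}.
#' @return Object of class \code{"qvalue_result"}: list with \code{p},
#'   \code{q}, \code{pi0}, \code{lambda}.
#' @examples
#' res <- storey_qvalues(c(0.001, 0.01, 0.2, 0.8, 0.9, 1, 0.5, 0.4, 0.6, 0.3))
#' res$q
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.90, by = 0.05), pi0 = NULL) {
  check_pvalues(p)
  m <- length(p)
  if (is.null(pi0)) pi0 <- estimate_pi0(p, lambda)
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(p = p, q = q, pi0 = pi0, lambda = lambda),
            class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat("Storey q-values: m = ", length(x$p), ", pi0-hat = ",
      format(x$pi0, digits = 4L), ", ", sum(x$q < 0.05),
      " test(s) at q < 0.05\n", sep = "")
  invisible(x)
}

#' Write p/q-values as TSV
#'
#' @param x A \code{\link{storey_qvalues}} result.
#' @param path Output file; the pi0 estimate is recorded in a header comment.
#' @return \code{path}, invisibly.
#' @export
write_qvalues <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pi0 = %.6g", x$pi0), con)
  utils::write.table(data.frame(p = x$p, q = x$q), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
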