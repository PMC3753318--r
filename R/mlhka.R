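#' Multilocus ML-HKA Poisson log-likelihood
#'
#' The multilocus HKA model treats the segregating-site count and the
#' outgroup divergence count of each locus as independent Poisson draws,
#' \deqn{S_i \sim Pois(k_i \theta_i a_{n_i}), \quad
#'       D_i \sim Pois(\theta_i (T + (1 + k_i)/2)),}
#' where \eqn{\theta_i} is the locus population mutation parameter on the
#' whole-locus scale, \eqn{T} the species divergence time shared across loci
#' (units of 2N generations), \eqn{a_{n_i}} the harmonic number for the
#' locus sample size, and \eqn{k_i} a selection parameter scaling the focal
#' species' coalescent depth: \eqn{k < 1} signals a sweep, \eqn{k > 1}
#' balancing selection. The \eqn{(1 + k_i)/2} term carries the
#' ancestral-polymorphism contribution to divergence.
#'
#' @param counts Data frame with columns \code{locus}, \code{S}, \code{D},
#'   \code{L}, \code{n}.
#' @param theta Per-locus theta values (whole-locus scale), in row order.
#' @param T_div Shared divergence time.
#' @param k Per-locus selection parameters (1 = neutral), in row order.
#' @return The log-likelihood (sum over loci of the two Poisson log-pmfs).
#' @export
hka_loglik <- function(counts, theta, T_div, k = rep(1, nrow(counts))) {
  counts <- validate_hka_counts(counts)
  if (length(theta) != nrow(counts) || length(k) != nrow(counts)) {
    stop("theta and k must have one value per locus")
  }
  a <- harmonic_number(counts$n)
  lam_S <- k * theta * a
  lam_D <- theta * (T_div + (1 + k) / 2)
  if (any(lam_S <= 0) || any(lam_D <= 0)) {
    stop("non-positive expected count; theta, T and k must be positive")
  }
  sum(stats::dpois(counts$S, lam_S, log = TRUE) +
        stats::dpois(counts$D, lam_D, log = TRUE))
}

# Evaluate `expr` under a seeded RNG without disturbing the caller's stream
# (the convention stats::simulate uses).
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

validate_hka_counts <- function(counts) {
  need <- c("locus", "S", "D", "L", "n")
  if (!all(need %in% names(counts))) {
    stop("HKA counts need columns ", paste(need, collapse = ", "))
  }
  if (any(duplicated(counts$locus))) stop("duplicate locus ids in count data")
  if (any(counts$S < 0) || any(counts$D < 0)) stop("S and D must be >= 0")
  if (any(counts$n < 2)) stop("all loci need n >= 2")
  if (any(counts$L < 1)) stop("all loci need L >= 1")
  if (any(counts$S != round(counts$S)) || any(counts$D != round(counts$D))) {
    stop("S and D must be integer counts (round the divergence mean first)")
  }
  counts
}

# Profile log-likelihood: given (T, k) the per-locus theta maximizing the
# two Poisson terms has closed form theta = (S + D) / (k a + T + (1 + k)/2).
profile_theta <- function(counts, a, T_div, k, eps = 1e-9) {
  pmax((counts$S + counts$D) / (k * a + T_div + (1 + k) / 2), eps)
}

profile_loglik <- function(counts, a, T_div, k) {
  theta <- profile_theta(counts, a, T_div, k)
  lam_S <- k * theta * a
  lam_D <- theta * (T_div + (1 + k) / 2)
  sum(stats::dpois(counts$S, lam_S, log = TRUE) +
        stats::dpois(counts$D, lam_D, log = TRUE))
}

#' Fit the ML-HKA model
#'
#' Maximizes the \code{\link{hka_loglik}} likelihood. Under the neutral
#' model (\code{focal = NULL}) all \eqn{k_i = 1} and the free parameters are
#' the per-locus \eqn{\theta_i} plus the shared divergence time \eqn{T}.
#' Under the selection model one focal locus gets a free selection parameter
#' \eqn{k} within \code{k_bounds}. The per-locus thetas are profiled out in
#' closed form, so the optimization is one-dimensional in \eqn{\log T}
#' (neutral) or two-dimensional in \eqn{(\log T, \log k)} (selection); a
#' deterministic coarse grid plus seeded multi-start quasi-Newton refinement
#' (Nelder-Mead fallback) guards against the \eqn{S = 0} boundary.
#'
#' @param counts Data frame with columns \code{locus}, \code{S}, \code{D},
#'   \code{L}, \code{n} (one row per locus; a single pool).
#' @param focal Locus id to test for selection, or \code{NULL} for the
#'   strictly neutral model.
#' @param k_bounds Admissible range for the selection parameter.
#' @param n_starts Number of optimizer starts for the selection fit.
#' @param seed Integer seed for the jittered starts (fit is deterministic
#'   given the seed).
#' @return Object of class \code{"mlhka"}: list with \code{theta} (named,
#'   whole-locus scale), \code{T} , \code{k} (named), \code{lnL},
#'   \code{converged}, \code{n_free}, \code{focal}, \code{counts}.
#' @examples
#' cts <- data.frame(locus = c("a", "b"), S = c(5, 7), D = c(10, 12),
#'                   L = c(500, 500), n = c(8, 8))
#' fit0 <- mlhka(cts)
#' fit1 <- mlhka(cts, focal = "a")
#' anova(fit0, fit1)
#' @export
mlhka <- function(counts, focal = NULL, k_bounds = c(1e-4, 100),
                  n_starts = 8L, seed = 1L) {
  counts <- validate_hka_counts(counts)
  if (nrow(counts) < 1L) stop("the ML-HKA fit needs >= 1 locus")
  a <- harmonic_number(counts$n)
  logT_box <- log(c(1e-5, 1e5))

  if (is.null(focal)) {
    k <- rep(1, nrow(counts))
    obj <- function(logT) -profile_loglik(counts, a, exp(logT), k)
    grid <- seq(logT_box[1L], logT_box[2L], length.out = 101L)
    vals <- vapply(grid, obj, 0)
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optim(grid[i], obj, method = "Brent", lower = lo, upper = hi)
    T_hat <- exp(opt$par)
    theta <- profile_theta(counts, a, T_hat, k)
    fit <- list(theta = stats::setNames(theta, counts$locus), T = T_hat,
                k = stats::setNames(k, counts$locus), lnL = -opt$value,
                converged = opt$convergence == 0L,
                n_free = nrow(counts) + 1L, focal = NULL, counts = counts,
                k_bounds = k_bounds)
    class(fit) <- "mlhka"
    return(fit)
  }

  fi <- match(focal, counts$locus)
  if (is.na(fi)) stop("focal locus '", focal, "' not present in the count data")
  if (nrow(counts) < 2L) stop("the selection model needs at least one non-focal locus")
  logk_box <- log(k_bounds)

  obj2 <- function(par) {
    k <- rep(1, nrow(counts))
    k[fi] <- exp(par[2L])
    -profile_loglik(counts, a, exp(par[1L]), k)
  }

  # deterministic starts around the neutral T-hat plus seeded jitter
  fit0 <- mlhka(counts, focal = NULL, k_bounds = k_bounds)
  logT0 <- log(fit0$T)
  k_starts <- log(pmin(pmax(c(k_bounds[1L], 0.01, 0.1, 1, 10, k_bounds[2L]),
                            k_bounds[1L]), k_bounds[2L]))
  starts <- cbind(logT0, unique(k_starts))
  n_extra <- max(0L, n_starts - nrow(starts))
  if (n_extra > 0L) {
    starts <- rbind(starts, with_preserved_rng(seed, {
      cbind(stats::runif(n_extra, logT_box[1L] / 2, logT_box[2L] / 2),
            stats::runif(n_extra, logk_box[1L], logk_box[2L]))
    }))
  }

  best <- NULL
  conv <- FALSE
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[s, ], obj2, method = "L-BFGS-B",
                   lower = c(logT_box[1L], logk_box[1L]),
                   upper = c(logT_box[2L], logk_box[2L]),
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) {
      res <- stats::optim(starts[s, ], function(p) {
        p <- pmin(pmax(p, c(logT_box[1L], logk_box[1L])),
                  c(logT_box[2L], logk_box[2L]))
        obj2(p)
      }, method = "Nelder-Mead", control = list(reltol = 1e-12))
      res$par <- pmin(pmax(res$par, c(logT_box[1L], logk_box[1L])),
                      c(logT_box[2L], logk_box[2L]))
    }
    if (is.null(best) || res$value < best$value) best <- res
    if (res$convergence == 0L) conv <- TRUE
  }
  if (is.null(best)) stop("ML-HKA selection fit failed to converge from any start")

  T_hat <- unname(exp(best$par[1L]))
  k_hat <- unname(exp(best$par[2L]))
  k <- rep(1, nrow(counts)); k[fi] <- k_hat
  theta <- profile_theta(counts, a, T_hat, k)
  fit <- list(theta = stats::setNames(theta, counts$locus), T = T_hat,
              k = stats::setNames(k, counts$locus), lnL = -best$value,
              converged = conv, n_free = nrow(counts) + 2L, focal = focal,
              counts = counts, k_bounds = k_bounds)
  class(fit) <- "mlhka"
  fit
}

#' @export
print.mlhka <- function(x, digits = 4L, ...) {
  cat("ML-HKA ", if (is.null(x$focal)) "neutral" else
    paste0("selection (focal: ", x$focal, ")"), " model, ",
    nrow(x$counts), " loci\n", sep = "")
  cat("  lnL = ", format(x$lnL, digits = digits + 2L),
      ",  T-hat = ", format(x$T, digits = digits), sep = "")
  if (!is.null(x$focal)) {
    cat(",  k-hat = ", format(x$k[[x$focal]], digits = digits), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.mlhka <- function(object, ...) {
  cts <- object$counts
  a <- harmonic_number(cts$n)
  tab <- data.frame(
    locus = cts$locus, S = cts$S, D = cts$D, n = cts$n, L = cts$L,
    theta_hat = unname(object$theta), k = unname(object$k),
    E_S = unname(object$k * object$theta * a),
    E_D = unname(object$theta * (object$T + (1 + object$k) / 2))
  )
  out <- list(fit = object, table = tab)
  class(out) <- "summary.mlhka"
  out
}

#' @export
print.summary.mlhka <- function(x, digits = 4L, ...) {
  print(x$fit, digits = digits)
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mlhka <- function(object, ...) {
  cf <- c(object$theta, T = object$T)
  names(cf)[seq_along(object$theta)] <- paste0("theta.", names(object$theta))
  if (!is.null(object$focal)) cf <- c(cf, k = unname(object$k[[object$focal]]))
  cf
}

#' @export
logLik.mlhka <- function(object, ...) {
  structure(object$lnL, df = object$n_free, class = "logLik")
}

#' @export
fitted.mlhka <- function(object, ...) {
  a <- harmonic_number(object$counts$n)
  data.frame(locus = object$counts$locus,
             E_S = unname(object$k * object$theta * a),
             E_D = unname(object$theta * (object$T + (1 + object$k) / 2)))
}

#' @export
residuals.mlhka <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  f <- fitted(object)
  rs <- object$counts$S - f$E_S
  rd <- object$counts$D - f$E_D
  if (type == "pearson") {
    rs <- rs / sqrt(f$E_S); rd <- rd / sqrt(f$E_D)
  }
  cbind(S = stats::setNames(rs, object$counts$locus), D = rd)
}

#' Simulate count data from a fitted ML-HKA model
#'
#' Parametric-bootstrap draws of (S, D) from the fitted Poisson means.
#'
#' @param object An \code{\link{mlhka}} fit.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of \code{nsim} count data frames.
#' @export
simulate.mlhka <- function(object, nsim = 1L, seed = NULL, ...) {
  a <- harmonic_number(object$counts$n)
  lam_S <- unname(object$k * object$theta * a)
  lam_D <- unname(object$theta * (object$T + (1 + object$k) / 2))
  m <- nrow(object$counts)
  draw <- function() {
    lapply(seq_len(nsim), function(i) {
      out <- object$counts[, c("locus", "L", "n")]
      out$S <- stats::rpois(m, lam_S)
      out$D <- stats::rpois(m, lam_D)
      out[, c("locus", "S", "D", "L", "n")]
    })
  }
  if (is.null(seed)) draw() else with_preserved_rng(seed, draw())
}

#' Likelihood-ratio test between nested ML-HKA fits
#'
#' Twice the log-likelihood difference between the selection and neutral
#' fits is referred to a chi-square distribution (default 2 degrees of
#' freedom, the convention used in sequence-based domestication scans; set
#' \code{df = 1} to count only the selection parameter).
#'
#' @param fit0 Neutral-model fit (\code{\link{mlhka}} with \code{focal = NULL}).
#' @param fit1 Selection-model fit on the same count data.
#' @param df Chi-square degrees of freedom.
#' @return Object of class \code{"hka_lrt"}: \code{locus}, \code{lnL0},
#'   \code{lnL1}, \code{statistic}, \code{df}, \code{p_value}, \code{k_hat}.
#' @export
hka_lrt <- function(fit0, fit1, df = 2L) {
  if (!inherits(fit0, "mlhka") || !inherits(fit1, "mlhka")) {
    stop("fit0 and fit1 must be mlhka fits")
  }
  if (!identical(sort(fit0$counts$locus), sort(fit1$counts$locus))) {
    stop("fits are not nested: different locus sets")
  }
  if (is.null(fit1$focal)) stop("fit1 must be a selection fit (focal locus set)")
  if (!all(fit0$k == 1)) {
    stop("fit0 must be the neutral fit (all k constrained to 1)")
  }
  lrt <- 2 * (fit1$lnL - fit0$lnL)
  if (lrt < -1e-6) {
    warning("selection fit has lower lnL than neutral fit (", format(lrt),
            "); clamping LRT to 0 (optimizer noise)")
  }
  lrt <- max(0, lrt)
  out <- list(locus = fit1$focal, lnL0 = fit0$lnL, lnL1 = fit1$lnL,
              statistic = lrt, df = df,
              p_value = stats::pchisq(lrt, df = df, lower.tail = FALSE),
              k_hat = unname(fit1$k[[fit1$focal]]))
  class(out) <- "hka_lrt"
  out
}

#' @export
print.hka_lrt <- function(x, digits = 4L, ...) {
  cat("ML-HKA likelihood-ratio test, focal locus '", x$locus, "'\n", sep = "")
  cat("  LRT = ", format(x$statistic, digits = digits), " (df = ", x$df,
      "),  P = ", format(x$p_value, digits = digits),
      ",  k-hat = ", format(x$k_hat, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
anova.mlhka <- function(object, object2, df = 2L, ...) {
  fits <- list(object, object2)
  is_sel <- !vapply(fits, function(f) is.null(f$focal), TRUE)
  if (sum(is_sel) != 1L) stop("anova needs one neutral and one selection fit")
  res <- hka_lrt(fits[[which(!is_sel)]], fits[[which(is_sel)]], df = df)
  out <- data.frame(n_free = c(fits[[which(!is_sel)]]$n_free,
                               fits[[which(is_sel)]]$n_free),
                    lnL = c(res$lnL0, res$lnL1),
                    LRT = c(NA, res$statistic), df = c(NA, res$df),
                    p_value = c(NA, res$p_value),
                    row.names = c("neutral",
                                  paste0("selection(", res$locus, ")")))
  structure(out, heading = "ML-HKA likelihood-ratio test",
            class = c("anova", "data.frame"))
}

#' One-shot ML-HKA test of a focal locus
#'
#' Convenience wrapper: fits the neutral and selection models on the same
#' counts and returns the likelihood-ratio test.
#'
#' @inheritParams mlhka
#' @param df Chi-square degrees of freedom for the test.
#' @return An \code{\link{hka_lrt}} result.
#' @export
hka_test <- function(counts, focal, df = 2L, k_bounds = c(1e-4, 100),
                     n_starts = 8L, seed = 1L) {
  fit0 <- mlhka(counts, focal = NULL, k_bounds = k_bounds, seed = seed)
  fit1 <- mlhka(counts, focal = focal, k_bounds = k_bounds,
                n_starts = n_starts, seed = seed)
  hka_lrt(fit0, fit1, df = df)
}
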