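test_that("the Poisson log-likelihood matches a textbook re-implementation", {
  one <- data.frame(locus = "x", S = 5L, D = 10L, L = 500L, n = 2L)
  # direct Poisson pmf evaluation: logPois(5;5) + logPois(10;10)
  expect_equal(hka_loglik(one, theta = 5, T_div = 1, k = 1),
               dpois(5, 5, log = TRUE) + dpois(10, 10, log = TRUE))
  expect_equal(hka_loglik(one, theta = 5, T_div = 1, k = 1), -3.818864,
               tolerance = 1e-6)

  # random small instances vs an independent textbook Poisson formula
  set.seed(14)
  for (rep in 1:20) {
    cts <- data.frame(locus = c("a", "b", "c"),
                      S = rpois(3, 8), D = rpois(3, 20),
                      L = c(500L, 600L, 700L), n = c(8L, 6L, 4L))
    theta <- runif(3, 2, 12); T_div <- runif(1, 1, 10); k <- runif(3, 0.1, 2)
    a <- vapply(cts$n, function(n) sum(1 / seq_len(n - 1)), 0)
    lam_S <- k * theta * a
    lam_D <- theta * (T_div + (1 + k) / 2)
    ref <- sum(cts$S * log(lam_S) - lam_S - lgamma(cts$S + 1) +
                 cts$D * log(lam_D) - lam_D - lgamma(cts$D + 1))
    expect_equal(hka_loglik(cts, theta, T_div, k), ref, tolerance = 1e-12)
  }

  # k = 1 everywhere is the neutral evaluation
  cts <- data.frame(locus = c("a", "b"), S = c(5L, 7L), D = c(10L, 12L),
                    L = c(500L, 500L), n = c(8L, 8L))
  expect_equal(hka_loglik(cts, c(4, 5), 2, k = c(1, 1)),
               hka_loglik(cts, c(4, 5), 2))
  expect_error(hka_loglik(cts, c(0, 5), 2), "positive")
})

test_that("the neutral fit solves the moment equations", {
  # single locus: S = theta, D = theta (T + 1) exactly
  one <- data.frame(locus = "x", S = 5L, D = 10L, L = 500L, n = 2L)
  f <- mlhka(one)
  expect_equal(unname(f$theta), 5, tolerance = 1e-5)
  expect_equal(f$T, 1, tolerance = 1e-4)
  expect_true(f$converged)
  expect_equal(f$n_free, 2L)

  # duplicated loci leave T-hat unchanged
  two <- rbind(one, transform(one, locus = "y"))
  f2 <- mlhka(two)
  expect_equal(f2$T, f$T, tolerance = 1e-4)
  expect_equal(f2$n_free, 3L)
})

test_that("neutral parameters are recovered from simulated counts", {
  set.seed(2024)
  theta_true <- 8; T_true <- 5; n_loci <- 20L
  a8 <- sum(1 / 1:7)
  T_hats <- theta_meds <- numeric(100)
  for (r in 1:100) {
    cts <- data.frame(locus = sprintf("l%02d", 1:n_loci),
                      S = rpois(n_loci, theta_true * a8),
                      D = rpois(n_loci, theta_true * (T_true + 1)),
                      L = 700L, n = 8L)
    f <- mlhka(cts)
    T_hats[r] <- f$T
    theta_meds[r] <- median(f$theta)
  }
  expect_lt(abs(median(T_hats) / T_true - 1), 0.25)
  expect_lt(abs(median(theta_meds) / theta_true - 1), 0.25)
})

test_that("the selection fit behaves at the boundary and under the null", {
  # zero polymorphism with large divergence drives k to the lower bound
  cts <- data.frame(locus = c("f", "a", "b"), S = c(0L, 9L, 11L),
                    D = c(30L, 25L, 28L), L = 700L, n = c(8L, 8L, 8L))
  f0 <- mlhka(cts); f1 <- mlhka(cts, focal = "f")
  expect_lt(f1$k[["f"]], 0.01)
  expect_gt(f1$lnL, f0$lnL)

  # k_true = 1: median k-hat near 1 over simulated datasets
  set.seed(77)
  a8 <- sum(1 / 1:7)
  k_hats <- vapply(1:200, function(r) {
    cts <- data.frame(locus = sprintf("l%d", 1:8),
                      S = rpois(8, 7 * a8), D = rpois(8, 7 * 9),
                      L = 700L, n = 8L)
    mlhka(cts, focal = "l1")$k[["l1"]]
  }, 0)
  expect_gt(median(k_hats), 0.7)
  expect_lt(median(k_hats), 1.4)
})

test_that("the optimizer attains the exhaustive grid-search likelihood", {
  fx <- hka_fixtures()[[1]]
  expect_equal(mlhka(fx)$lnL, oracle_grid_lnL(fx), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(mlhka(fx, focal = "a")$lnL, oracle_grid_lnL(fx, focal = "a"),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("k-hat responds monotonically to the focal polymorphism count", {
  base <- data.frame(locus = c("f", "a", "b"), S = c(12L, 9L, 11L),
                     D = c(26L, 25L, 28L), L = 700L, n = 8L)
  k_hats <- vapply(c(12L, 8L, 4L, 1L, 0L), function(S_f) {
    cts <- base; cts$S[1] <- S_f
    mlhka(cts, focal = "f")$k[["f"]]
  }, 0)
  expect_true(all(diff(k_hats) <= 1e-6))
})

test_that("the likelihood-ratio test follows the chi-square convention", {
  cts <- data.frame(locus = c("f", "a", "b"), S = c(0L, 9L, 11L),
                    D = c(30L, 25L, 28L), L = 700L, n = 8L)
  f0 <- mlhka(cts); f1 <- mlhka(cts, focal = "f")
  res <- hka_lrt(f0, f1)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value,
               pchisq(res$statistic, df = 2, lower.tail = FALSE))
  expect_equal(res$statistic, 2 * (f1$lnL - f0$lnL))

  # chi-square quantile identity at the 5% point
  expect_equal(pchisq(5.991, df = 2, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)

  # constraining k to 1 recovers the neutral model: LRT ~ 0
  f1_null <- mlhka(cts, focal = "f", k_bounds = c(1, 1))
  expect_lt(hka_lrt(f0, f1_null)$statistic, 1e-4)
  expect_equal(hka_lrt(f0, f1_null)$p_value, 1, tolerance = 1e-4)

  # df is a knob
  expect_equal(hka_lrt(f0, f1, df = 1)$p_value,
               pchisq(res$statistic, df = 1, lower.tail = FALSE))

  expect_error(hka_lrt(f1, f1), "neutral fit")
})

test_that("mlhka methods expose the fit in the standard modelling idiom", {
  cts <- data.frame(locus = c("a", "b"), S = c(5L, 7L), D = c(10L, 12L),
                    L = 500L, n = 8L)
  f <- mlhka(cts, focal = "a")
  expect_named(coef(f), c("theta.a", "theta.b", "T", "k"))
  expect_equal(as.numeric(logLik(f)), f$lnL)
  expect_equal(attr(logLik(f), "df"), 4L)
  ft <- fitted(f)
  expect_equal(nrow(ft), 2L)
  r <- residuals(f, type = "raw")
  expect_equal(unname(r[, "S"]), cts$S - ft$E_S)
  av <- anova(mlhka(cts), f)
  expect_equal(av$LRT[2], hka_lrt(mlhka(cts), f)$statistic)
  sims <- simulate(f, nsim = 3, seed = 9)
  expect_length(sims, 3L)
  expect_named(sims[[1]], c("locus", "S", "D", "L", "n"))

  out <- capture.output(print(summary(f)))
  expect_true(any(grepl("selection", out)))
})
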