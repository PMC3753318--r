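# Independent brute-force oracles: deliberately naive re-implementations
# used only to check the package's vectorised code paths.

oracle_complete_deletion <- function(mat) {
  keep <- integer()
  for (cc in seq_len(ncol(mat))) {
    ok <- TRUE
    for (rr in seq_len(nrow(mat))) {
      if (mat[rr, cc] %in% c("-", "N")) ok <- FALSE
    }
    if (ok) keep <- c(keep, cc)
  }
  keep
}

oracle_pi <- function(mat, retained) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      tot <- tot + sum(mat[i, retained] != mat[j, retained])
    }
  }
  tot / (n * (n - 1) / 2) / length(retained)
}

oracle_seg_sites <- function(mat, retained) {
  s <- 0L
  for (cc in retained) {
    if (length(unique(mat[, cc])) > 1L) s <- s + 1L
  }
  s
}

# Step-up q-value minimum computed per element from the definition:
# q_i = min over thresholds t >= p_i of pi0 * m * t / #{p <= t}.
oracle_qvalues <- function(p, pi0 = 1) {
  m <- length(p)
  vapply(p, function(pi_) {
    ts <- p[p >= pi_]
    min(pmin(1, pi0 * m * ts / vapply(ts, function(t) sum(p <= t), 0)))
  }, 0)
}

# Exhaustive nested grid search over (theta_i, T[, k]) of the ML-HKA
# likelihood, refined in stages; independent of the package's profile
# closed form (theta is grid-searched per locus, never solved).
oracle_theta_max <- function(S, D, a, T_div, k) {
  lo <- log(1e-8)
  hi <- log((S + D + 5) * 10)
  v <- NULL
  for (stage in 1:5) {
    g <- seq(lo, hi, length.out = 41L)
    th <- exp(g)
    v <- dpois(S, k * th * a, log = TRUE) +
      dpois(D, th * (T_div + (1 + k) / 2), log = TRUE)
    i <- which.max(v)
    lo <- g[max(1L, i - 1L)]
    hi <- g[min(41L, i + 1L)]
  }
  max(v)
}

oracle_grid_lnL <- function(counts, focal = NULL,
                            k_bounds = c(1e-4, 100)) {
  a <- vapply(counts$n, function(n) sum(1 / seq_len(n - 1L)), 0)
  fi <- if (is.null(focal)) 0L else match(focal, counts$locus)
  lnL_at <- function(T_div, k_focal) {
    sum(vapply(seq_len(nrow(counts)), function(i) {
      oracle_theta_max(counts$S[i], counts$D[i], a[i], T_div,
                       if (i == fi) k_focal else 1)
    }, 0))
  }
  Tlo <- log(1e-5); Thi <- log(1e5)
  klo <- log(k_bounds[1L]); khi <- log(k_bounds[2L])
  best <- -Inf
  for (stage in 1:4) {
    Tg <- seq(Tlo, Thi, length.out = 31L)
    if (is.null(focal)) {
      v <- vapply(Tg, function(lt) lnL_at(exp(lt), 1), 0)
      i <- which.max(v)
      Tlo <- Tg[max(1L, i - 1L)]; Thi <- Tg[min(31L, i + 1L)]
      best <- max(v)
    } else {
      kg <- seq(klo, khi, length.out = 31L)
      M <- matrix(NA_real_, 31L, 31L)
      for (i in 1:31) for (j in 1:31) M[i, j] <- lnL_at(exp(Tg[i]), exp(kg[j]))
      ij <- arrayInd(which.max(M), dim(M))
      Tlo <- Tg[max(1L, ij[1L] - 1L)]; Thi <- Tg[min(31L, ij[1L] + 1L)]
      klo <- kg[max(1L, ij[2L] - 1L)]; khi <- kg[min(31L, ij[2L] + 1L)]
      best <- max(M)
    }
  }
  best
}

# Small fixture set of 2-3 locus HKA count instances
hka_fixtures <- function() {
  list(
    data.frame(locus = c("a", "b"), S = c(5L, 7L), D = c(10L, 12L),
               L = c(500L, 500L), n = c(8L, 8L)),
    data.frame(locus = c("a", "b"), S = c(0L, 9L), D = c(25L, 14L),
               L = c(700L, 700L), n = c(6L, 6L)),
    data.frame(locus = c("a", "b", "c"), S = c(12L, 3L, 8L),
               D = c(30L, 22L, 18L), L = c(800L, 400L, 600L),
               n = c(8L, 6L, 8L)),
    data.frame(locus = c("a", "b", "c"), S = c(2L, 15L, 6L),
               D = c(40L, 35L, 28L), L = c(500L, 900L, 700L),
               n = c(6L, 8L, 6L))
  )
}

# 21-sequence panel sample sheet matching the study design
panel_sheet <- function() {
  as_sample_sheet(data.frame(
    sample_id = c(sprintf("wild%02d", 1:8), sprintf("land%02d", 1:6),
                  sprintf("impr%02d", 1:6), "outg01"),
    pool = rep(c("wild", "landrace", "improved", "outgroup"),
               c(8L, 6L, 6L, 1L))))
}

# tiny alignment builder from residue strings
mk_aln <- function(strings, pools, locus = "loc", cds = NULL, frame = 0L) {
  if (is.null(names(strings))) {
    names(strings) <- sprintf("s%02d", seq_along(strings))
  }
  if (is.null(names(pools))) names(pools) <- names(strings)
  locus_alignment(locus, strings, pools, cds = cds, frame = frame)
}
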