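test_that("sim_config validates the study description", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, bottleneck = c(wild = 1, landrace = 1.2,
                                                   improved = 0.5)),
               "\\(0, 1\\]")
  expect_error(sim_config(seed = 1, sweep_k = 0), "\\(0, 1\\]")
  expect_error(sim_config(seed = 1,
                          pool_sizes = c(wild = 8, landrace = 6,
                                         improved = 6, outgroup = 2)),
               "outgroup")
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$n_neutral + cfg$n_dom + cfg$n_imp, 34L)
  expect_equal((cfg$cds[["end"]] - cfg$cds[["start"]]) %% 3L, 0L)
})

test_that("count simulation is the generative twin of the likelihood", {
  cfg <- sim_config(seed = 8)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1, s2)                       # determinism under a seed

  # Poisson expectations: neutral wild S averages theta * a_n
  a8 <- sum(1 / 1:7)
  theta_w <- cfg$theta_site * cfg$L
  S_draws <- vapply(1:500, function(r) {
    sim <- simulate_counts(sim_config(seed = 10000 + r, n_neutral = 1L,
                                      n_dom = 0L, n_imp = 0L))
    sim$counts$S[sim$counts$pool == "wild"]
  }, 0)
  mu <- theta_w * a8
  se <- sd(S_draws) / sqrt(length(S_draws))
  expect_lt(abs(mean(S_draws) - mu), 3 * se)

  # sweep scaling: swept mean S is ~5% of the neutral twin's
  big <- simulate_counts(sim_config(seed = 9, n_neutral = 200L,
                                    n_dom = 200L, n_imp = 0L))
  imp <- big$counts[big$counts$pool == "improved", ]
  ratio <- mean(imp$S[imp$role == "domestication"]) /
    mean(imp$S[imp$role == "neutral"])
  expect_lt(abs(ratio - 0.05), 0.05)

  # truth table carries the planted k values
  expect_true(all(big$truth$k_true[big$truth$role == "domestication" &
                                     big$truth$pool == "wild"] == 1))
  expect_true(all(big$truth$k_true[big$truth$role == "domestication" &
                                     big$truth$pool == "improved"] == 0.05))
})

test_that("alignment simulation honours the infinite-sites bookkeeping", {
  cfg <- sim_config(seed = 21, L = 500)
  set.seed(21)
  sim <- simulate_alignment(cfg, "locA", role = "domestication")
  aln <- sim$aln
  expect_equal(nrow(aln$seqs), 21L)
  expect_equal(aln$alignment_length, 500L)

  for (pool in c("wild", "landrace", "improved")) {
    sub <- pool_slice(aln, pool)
    expect_equal(segregating_sites(sub),
                 length(sim$truth$mutation_columns[[pool]]))
  }
  # every segregating column is bi-allelic (infinite sites)
  seg <- which(apply(aln$seqs, 2L, function(col) length(unique(col)) > 1L))
  expect_true(all(vapply(seg, function(cc)
    length(unique(aln$seqs[, cc])), 0L) == 2L))
})

test_that("coalescent expectations match their targets", {
  # wild pi averages theta_site across loci
  pis <- vapply(1:300, function(r) {
    cfg <- sim_config(seed = 20000 + r, L = 300)
    set.seed(20000 + r)
    sim <- simulate_alignment(cfg, "l", role = "neutral")
    nucleotide_diversity(pool_slice(sim$aln, "wild"))
  }, 0)
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 0.01), 3 * se)

  # wild divergence averages theta (T + 1) L
  cfg <- sim_config(seed = 1, L = 300)
  Ds <- vapply(1:400, function(r) {
    set.seed(30000 + r)
    sim <- simulate_alignment(cfg, "l", role = "neutral")
    outgroup_divergence(sim$aln, "wild")$D
  }, 0)
  mu <- cfg$theta_site * cfg$L * (cfg$T_div + 1)
  se <- sd(Ds) / sqrt(length(Ds))
  expect_lt(abs(mean(Ds) - mu), 3 * se)
})

test_that("bottleneck-only studies recover the configured diversity ratios", {
  cfg <- sim_config(seed = 31, n_neutral = 200L, n_dom = 0L, n_imp = 0L,
                    L = 300)
  set.seed(31)
  th <- list(wild = numeric(), landrace = numeric(), improved = numeric())
  for (r in 1:200) {
    sim <- simulate_alignment(cfg, paste0("l", r), role = "neutral")
    for (pool in names(th)) {
      d <- diversity_stats(sim$aln, pool)
      th[[pool]] <- c(th[[pool]], d$theta_w)
    }
  }
  expect_lt(abs(mean(th$landrace) / mean(th$wild) - 0.6), 0.1)
  expect_lt(abs(mean(th$improved) / mean(th$wild) - 0.5), 0.1)
})

test_that("study simulation writes a complete runnable input set", {
  dir <- tempfile("study")
  cfg <- sim_config(seed = 77, n_neutral = 3L, n_dom = 2L, n_imp = 2L,
                    L = 300)
  st <- simulate_study(cfg, dir = dir)
  expect_length(list.files(dir, pattern = "\\.fasta$"), 7L)
  expect_equal(nrow(st$sheet), 21L)
  expect_s3_class(st$sheet, "sample_sheet")
  expect_true(file.exists(file.path(dir, "samples.tsv")))
  expect_true(file.exists(file.path(dir, "roles.tsv")))
  expect_true(file.exists(file.path(dir, "cds.tsv")))
  expect_equal(nrow(st$truth), 7L * 3L)

  # default study shape: 34 FASTA files
  dir2 <- tempfile("study34")
  st2 <- simulate_study(sim_config(seed = 78, L = 200), dir = dir2)
  expect_length(list.files(dir2, pattern = "\\.fasta$"), 34L)

  # deterministic: same seed, byte-identical FASTA output
  dir3 <- tempfile("studyrep")
  simulate_study(cfg, dir = dir3)
  f <- paste0(st$roles$locus[1], ".fasta")
  expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir3, f)))
})

test_that("mutation demand beyond the locus length is a hard error", {
  cfg <- sim_config(seed = 2, L = 9, theta_site = 50, cds = c(start = 0L,
                                                              end = 9L))
  set.seed(2)
  expect_error(simulate_alignment(cfg, "tiny"), "increase L")
})
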