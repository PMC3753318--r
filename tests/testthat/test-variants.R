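panel_pools <- function(nw = 8L, nl = 6L, ni = 6L, og = TRUE) {
  ids <- c(sprintf("w%d", seq_len(nw)), sprintf("l%d", seq_len(nl)),
           sprintf("i%d", seq_len(ni)), if (og) "og")
  stats::setNames(rep(c("wild", "landrace", "improved",
                        if (og) "outgroup"), c(nw, nl, ni, if (og) 1L)), ids)
}

test_that("identical pools yield no variant calls", {
  pools <- panel_pools(3L, 3L, 3L, og = FALSE)
  s <- stats::setNames(rep("ACGTACGTA", 9), names(pools))
  expect_equal(nrow(call_pool_variants(mk_aln(s, pools))), 0L)
})

test_that("pool-differentiating columns carry counts, fixation and wild frequency", {
  pools <- panel_pools()
  s <- rep("AAAAA", 21)
  names(s) <- names(pools)
  # column 3 (1-based): wild A x7 G x1, improved fixed G, landrace fixed A
  s[names(pools)[pools == "improved"]] <- "AAGAA"
  s["w8"] <- "AAGAA"
  calls <- call_pool_variants(mk_aln(s, pools))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$column, 2L)              # 0-based
  expect_equal(calls$counts_wild, "A:7,G:1")
  expect_equal(calls$counts_improved, "G:6")
  expect_equal(calls$wild_freq_derived, 0.125)
  expect_match(calls$fixed_between, "landrace-improved")
  # wild is polymorphic at the column, so it never appears as a fixed side
  expect_false(grepl("wild", calls$fixed_between))
})

test_that("missing residues are excluded from per-column counts", {
  pools <- panel_pools(4L, 0L, 4L, og = FALSE)
  pools <- pools[!grepl("^l", names(pools))]
  s <- c(w1 = "ANT", w2 = "ANT", w3 = "NNT", w4 = "NNT",
         i1 = "GNT", i2 = "GNT", i3 = "GNT", i4 = "GNT")
  calls <- call_pool_variants(mk_aln(s, pools))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$counts_wild, "A:2")
  expect_equal(calls$counts_improved, "G:4")
  # wild has only 2 called samples: below min_called, so not "fixed"
  expect_false(grepl("wild", calls$fixed_between))
  # allele counts conserve the non-missing sample count at the column
  n_called <- sum(substr(s, 1L, 1L) != "N")
  expect_equal(2L + 4L, n_called)
})

test_that("coding effects follow the standard genetic code", {
  pools <- panel_pools(2L, 0L, 2L, og = FALSE)
  pools <- pools[!grepl("^l", names(pools))]
  cds <- data.frame(start = 0L, end = 6L)
  aln <- mk_aln(c(w1 = "AAAAAA", w2 = "AAAAAA", i1 = "AAGAAA",
                  i2 = "AAGAAA"), pools, cds = cds)
  # AAA -> AAG is Lys -> Lys
  expect_equal(classify_coding_effect(aln, 2L, "A", "G"), "synonymous")
  # AAA -> AGA is Lys -> Arg
  expect_equal(classify_coding_effect(aln, 1L, "A", "G"), "nonsynonymous")
  # effect is symmetric in allele order
  expect_equal(classify_coding_effect(aln, 1L, "G", "A"), "nonsynonymous")
  # outside the CDS
  aln2 <- mk_aln(c(w1 = "AAAAAAT", w2 = "AAAAAAT", i1 = "AAGAAAT",
                   i2 = "AAGAAAT"), pools,
                 cds = data.frame(start = 0L, end = 6L))
  expect_equal(classify_coding_effect(aln2, 6L, "T", "C"), "noncoding")
  # gaps are structural
  expect_equal(classify_coding_effect(aln, 2L, "A", "-"), "indel")
  # frame inconsistency is a hard error
  aln3 <- mk_aln(c(w1 = "AAAAA", w2 = "AAAAA", i1 = "AAGAA",
                   i2 = "AAGAA"), pools,
                 cds = data.frame(start = 0L, end = 5L))
  expect_error(classify_coding_effect(aln3, 2L, "A", "G"),
               "multiple of 3")
})

test_that("variant calling classifies a planted non-synonymous sweep", {
  cfg <- sim_config(seed = 404, L = 600)
  set.seed(404)
  sim <- simulate_alignment(cfg, "locP", role = "improvement",
                            plant_nonsyn = TRUE)
  calls <- call_pool_variants(sim$aln)
  planted0 <- sim$truth$planted_nonsyn_column - 1L
  row <- calls[calls$column == planted0, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$coding_effect, "nonsynonymous")
  expect_equal(row$wild_freq_derived, 1 / 8)
})

test_that("the fixed-difference screen applies both published filters", {
  cfg <- sim_config(seed = 505, L = 600)
  set.seed(505)
  sim <- simulate_alignment(cfg, "locQ", role = "improvement",
                            plant_nonsyn = TRUE)
  calls <- call_pool_variants(sim$aln)
  planted0 <- sim$truth$planted_nonsyn_column - 1L

  scan <- data.frame(locus = "locQ", q_value = 0.001)
  rep1 <- screen_selected_loci(scan, calls)
  expect_true(planted0 %in% rep1$column)
  # every reported row satisfies the two filters
  expect_true(all(rep1$coding_effect == "nonsynonymous"))
  expect_true(all(rep1$wild_freq_derived < 0.20))

  # cutoff = 1.0 reports every fixed non-synonymous difference
  rep_all <- screen_selected_loci(scan, calls, wild_freq_cutoff = 1.0)
  expect_true(nrow(rep_all) >= nrow(rep1))

  # no significant loci -> empty report
  none <- screen_selected_loci(data.frame(locus = "locQ", q_value = 0.9),
                               calls)
  expect_equal(nrow(none), 0L)
})
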