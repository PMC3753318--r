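#' Configuration of a synthetic domestication-scan study
#'
#' Describes the generative model for a study-shaped synthetic dataset: a
#' stratified panel (wild, landrace, improved plus one outgroup), a
#' genome-wide domestication bottleneck expressed as per-pool diversity
#' scalings, and locus-specific selective sweeps expressed as an additional
#' diversity-scaling factor \code{sweep_k} (< 1) applied to selected loci
#' in the pools where selection acted: domestication candidates are swept
#' in landrace and improved, improvement candidates in improved only.
#'
#' Conventions (used consistently throughout the generator): theta is per
#' site and equals 4Nu; coalescent time is measured in units of 2N
#' generations; a branch of length t carries Poisson(theta_locus/2 * t)
#' mutations; the outgroup lineage has length 2T + 2/n so that the expected
#' ingroup-outgroup divergence at a neutral locus is theta_locus * (T + 1).
#'
#' @param seed Integer seed (mandatory; all randomness derives from it).
#' @param n_neutral,n_dom,n_imp Numbers of neutral, domestication-candidate
#'   and improvement-candidate loci.
#' @param pool_sizes Named sample sizes; the outgroup must be 1.
#' @param L Alignment length per locus (bp).
#' @param theta_site Per-site theta in the wild pool.
#' @param T_div Outgroup divergence time (units of 2N generations).
#' @param bottleneck Named per-pool genome-wide diversity scalings in (0, 1].
#' @param sweep_k Additional per-locus scaling at swept loci, in (0, 1].
#' @param cds \code{c(start, end)} of the CDS interval planted in every
#'   locus (0-based half-open); length must be a multiple of 3.
#' @param frame Reading-frame offset of that CDS.
#' @param n_plant_nonsyn Number of improvement-swept loci that receive a
#'   planted fixed non-synonymous difference (improved pool fixed, one wild
#'   carrier).
#' @return Validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed, n_neutral = 7L, n_dom = 13L, n_imp = 14L,
                       pool_sizes = c(wild = 8L, landrace = 6L,
                                      improved = 6L, outgroup = 1L),
                       L = 700L, theta_site = 0.01, T_div = 8,
                       bottleneck = c(wild = 1, landrace = 0.6,
                                      improved = 0.5),
                       sweep_k = 0.05, cds = NULL,
                       frame = 0L, n_plant_nonsyn = 2L) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  if (is.null(cds)) {
    # default CDS: middle ~40% of the locus, trimmed to whole codons
    start <- floor(L / 4)
    len <- (floor(0.4 * L) %/% 3L) * 3L
    cds <- c(start = start, end = start + len)
  }
  if (cds[["end"]] > L || cds[["start"]] < 0) {
    stop("CDS interval must lie within [0, L)")
  }
  if (!all(ingroup_pools() %in% names(pool_sizes)) ||
      !"outgroup" %in% names(pool_sizes)) {
    stop("pool_sizes must name wild, landrace, improved and outgroup")
  }
  if (pool_sizes[["outgroup"]] != 1L) stop("exactly one outgroup sequence")
  if (any(pool_sizes < 1L)) stop("pool sizes must be >= 1")
  if (any(bottleneck <= 0) || any(bottleneck > 1)) {
    stop("bottleneck scalings must lie in (0, 1]")
  }
  if (sweep_k <= 0 || sweep_k > 1) stop("sweep_k must lie in (0, 1]")
  if ((cds[["end"]] - cds[["start"]]) %% 3L != 0L) {
    stop("CDS interval length must be a multiple of 3")
  }
  structure(list(seed = as.integer(seed), n_neutral = n_neutral,
                 n_dom = n_dom, n_imp = n_imp, pool_sizes = pool_sizes,
                 L = as.integer(L), theta_site = theta_site, T_div = T_div,
                 bottleneck = bottleneck, sweep_k = sweep_k,
                 cds = cds, frame = as.integer(frame),
                 n_plant_nonsyn = as.integer(n_plant_nonsyn)),
            class = "sim_config")
}

sim_locus_table <- function(cfg) {
  data.frame(
    locus = c(sprintf("neut%02d", seq_len(cfg$n_neutral)),
              sprintf("dom%02d", seq_len(cfg$n_dom)),
              sprintf("imp%02d", seq_len(cfg$n_imp))),
    role = rep(c("neutral", "domestication", "improvement"),
               c(cfg$n_neutral, cfg$n_dom, cfg$n_imp)))
}

sweep_factor <- function(role, pool, sweep_k) {
  swept <- (role == "domestication" && pool %in% c("landrace", "improved")) ||
    (role == "improvement" && pool == "improved")
  if (swept) sweep_k else 1
}

#' Simulate HKA count data under the generative twin of the likelihood
#'
#' Draws (S, D) for every locus and ingroup pool directly from the ML-HKA
#' Poisson model: \eqn{S \sim Pois(k \theta a_n)}, \eqn{D \sim
#' Pois(\theta (T + (1+k)/2))} with \eqn{\theta} the pool-scaled
#' whole-locus mutation parameter. This is the exact generative
#' counterpart of \code{\link{hka_loglik}}, which is what parameter-recovery
#' and error-rate testing of the fit requires.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{counts} (columns \code{locus}, \code{pool},
#'   \code{role}, \code{S}, \code{D}, \code{L}, \code{n}) and \code{truth}
#'   (adds \code{k_true}, \code{theta_true}).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed %% .Machine$integer.max)
  loci <- sim_locus_table(cfg)
  rows <- list(); tru <- list()
  for (i in seq_len(nrow(loci))) {
    for (pool in ingroup_pools()) {
      n <- cfg$pool_sizes[[pool]]
      a <- harmonic_number(n)
      k <- sweep_factor(loci$role[i], pool, cfg$sweep_k)
      theta <- cfg$theta_site * cfg$L * cfg$bottleneck[[pool]]
      S <- stats::rpois(1L, k * theta * a)
      D <- stats::rpois(1L, theta * (cfg$T_div + (1 + k) / 2))
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loci$locus[i], pool = pool, role = loci$role[i],
        S = S, D = D, L = cfg$L, n = n)
      tru[[length(tru) + 1L]] <- data.frame(
        locus = loci$locus[i], pool = pool, role = loci$role[i],
        k_true = k, theta_true = theta)
    }
  }
  list(counts = do.call(rbind, rows), truth = do.call(rbind, tru))
}

# Standard n-coalescent branch segments with total size scaled by `scale`.
# Returns list of (tips, len): while j lineages are active, each open
# lineage accrues a segment of the level's exponential waiting time.
coalescent_branches <- function(n, scale = 1) {
  if (n < 2L) return(list())
  lineages <- as.list(seq_len(n))
  branches <- list()
  j <- n
  while (j >= 2L) {
    t <- stats::rexp(1L, rate = j * (j - 1) / 2) * scale
    for (ln in lineages) {
      branches[[length(branches) + 1L]] <- list(tips = ln, len = t)
    }
    pair <- sample.int(j, 2L)
    merged <- c(lineages[[pair[1L]]], lineages[[pair[2L]]])
    lineages <- c(lineages[-pair], list(merged))
    j <- j - 1L
  }
  branches
}

#' Simulate one locus alignment under the coalescent with infinite sites
#'
#' Each ingroup pool receives an independent coalescent genealogy with
#' branch lengths scaled by its bottleneck factor times any sweep factor;
#' mutations are placed on branches at rate theta/2 per unit time onto
#' distinct uniformly-chosen columns (infinite sites, so every segregating
#' column is bi-allelic), and the single outgroup sequence descends from
#' the shared ancestral sequence along a lineage of length 2T + 2/n_wild.
#' Pools are independent coalescents because the fitted ML-HKA likelihood
#' makes exactly that approximation: the generator is its generative twin.
#'
#' @param cfg A \code{\link{sim_config}} (the caller controls the RNG
#'   stream; \code{\link{simulate_study}} seeds it once).
#' @param locus_id Locus name.
#' @param role \code{"neutral"}, \code{"domestication"} or
#'   \code{"improvement"}.
#' @param plant_nonsyn Plant a fixed non-synonymous difference (improved
#'   pool fixed for a derived allele carried by exactly one wild sequence)
#'   at a CDS codon.
#' @return List with the \code{\link{locus_alignment}} (\code{aln}) and a
#'   \code{truth} record (per-pool mutation columns, true k, planted
#'   column).
#' @export
simulate_alignment <- function(cfg, locus_id, role = "neutral",
                               plant_nonsyn = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$L
  bases <- c("A", "C", "G", "T")
  ancestral <- sample(bases, L, replace = TRUE)
  free <- seq_len(L)
  theta_locus <- cfg$theta_site * L
  n_wild <- cfg$pool_sizes[["wild"]]

  ids <- list(); seqs <- list(); pools <- character()
  truth_cols <- list(); k_true <- numeric()
  take_columns <- function(nmut) {
    if (nmut > length(free)) {
      stop("locus ", locus_id, ": mutation demand (", nmut,
           ") exceeds free columns; increase L")
    }
    cols <- if (length(free) == 1L) free[seq_len(nmut)] else
      sample(free, nmut)
    free <<- setdiff(free, cols)
    cols
  }

  for (pool in ingroup_pools()) {
    n <- cfg$pool_sizes[[pool]]
    k <- sweep_factor(role, pool, cfg$sweep_k)
    sc <- cfg$bottleneck[[pool]] * k
    mat <- matrix(rep(ancestral, each = n), nrow = n)
    cols_used <- integer()
    for (br in coalescent_branches(n, scale = sc)) {
      nmut <- stats::rpois(1L, theta_locus / 2 * br$len)
      if (nmut == 0L) next
      cols <- take_columns(nmut)
      for (cc in cols) {
        derived <- sample(setdiff(bases, ancestral[cc]), 1L)
        mat[br$tips, cc] <- derived
      }
      cols_used <- c(cols_used, cols)
    }
    pid <- sprintf("%s%02d", substr(pool, 1L, 4L), seq_len(n))
    rownames(mat) <- pid
    ids[[pool]] <- pid; seqs[[pool]] <- mat
    pools <- c(pools, rep(pool, n))
    truth_cols[[pool]] <- sort(cols_used)
    k_true <- c(k_true, stats::setNames(k, pool))
  }

  # outgroup lineage: length 2T + 2/n_wild in 2N units, wild-scale theta
  og <- ancestral
  nmut_og <- stats::rpois(1L, theta_locus / 2 * (2 * cfg$T_div + 2 / n_wild))
  if (nmut_og > 0L) {
    cols <- take_columns(nmut_og)
    for (cc in cols) og[cc] <- sample(setdiff(bases, og[cc]), 1L)
  }

  planted_col <- NA_integer_
  if (plant_nonsyn) {
    cds_free <- intersect(free, seq.int(cfg$cds[["start"]] + 1L, cfg$cds[["end"]]))
    planted_col <- plant_nonsyn_column(ancestral, cds_free, cfg, locus_id)
    free <- setdiff(free, planted_col$column)
    seqs[["improved"]][, planted_col$column] <- planted_col$derived
    seqs[["wild"]][1L, planted_col$column] <- planted_col$derived
    # the planted column is a polymorphic site in wild; keep the
    # bookkeeping identity S == #distinct mutated columns per pool
    truth_cols[["wild"]] <- sort(c(truth_cols[["wild"]], planted_col$column))
    planted_col <- planted_col$column
  }

  m <- rbind(do.call(rbind, seqs), outg01 = og)
  pool_map <- stats::setNames(c(pools, "outgroup"), rownames(m))
  aln <- locus_alignment(locus_id, m, pool_map,
                         cds = data.frame(start = cfg$cds[["start"]],
                                          end = cfg$cds[["end"]]),
                         frame = cfg$frame)
  truth <- list(locus = locus_id, role = role, k_true = k_true,
                mutation_columns = truth_cols,
                planted_nonsyn_column = planted_col)
  list(aln = aln, truth = truth)
}

# Find a CDS column and derived allele whose substitution (against the
# ancestral codon context) changes the encoded amino acid.
plant_nonsyn_column <- function(ancestral, cds_free, cfg, locus_id) {
  code <- Biostrings::GENETIC_CODE
  start <- cfg$cds[["start"]]; frame <- cfg$frame
  for (col in cds_free) {                  # 1-based column
    cpos <- (col - 1L) - start             # 0-based coding position
    if (cpos < frame) next
    codon_start0 <- start + frame + 3L * ((cpos - frame) %/% 3L)
    codon_cols <- codon_start0 + 1:3
    if (any(codon_cols > cfg$cds[["end"]])) next
    ctx <- ancestral[codon_cols]
    off <- which(codon_cols == col)
    aa0 <- code[[paste0(ctx, collapse = "")]]
    for (derived in setdiff(c("A", "C", "G", "T"), ancestral[col])) {
      alt <- ctx; alt[off] <- derived
      if (!identical(code[[paste0(alt, collapse = "")]], aa0)) {
        return(list(column = col, derived = derived))
      }
    }
  }
  stop("locus ", locus_id, ": no free CDS column admits a non-synonymous ",
       "substitution; increase L or the CDS interval")
}

#' Simulate a complete study directory
#'
#' Writes an immediately runnable pipeline input emulating the stratified
#' study design: one FASTA per locus (neutral panel plus domestication and
#' improvement candidates, with sweeps planted per role), the sample sheet,
#' a locus-role table, the CDS interval table and the simulation truth.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param dir Output directory (created if needed).
#' @return List with \code{dir}, \code{sheet}, \code{roles}, \code{truth}
#'   (data frame of per locus x pool true k and mutation counts) and
#'   \code{files}.
#' @export
simulate_study <- function(cfg, dir = tempfile("simstudy")) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed %% .Machine$integer.max)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci <- sim_locus_table(cfg)
  imp_idx <- which(loci$role == "improvement")
  plant <- rep(FALSE, nrow(loci))
  if (cfg$n_plant_nonsyn > 0L && length(imp_idx)) {
    plant[imp_idx[seq_len(min(cfg$n_plant_nonsyn, length(imp_idx)))]] <- TRUE
  }

  sheet <- NULL; truth_rows <- list(); files <- character()
  for (i in seq_len(nrow(loci))) {
    sim <- simulate_alignment(cfg, loci$locus[i], loci$role[i],
                              plant_nonsyn = plant[i])
    f <- file.path(dir, paste0(loci$locus[i], ".fasta"))
    write_locus_fasta(sim$aln, f)
    files <- c(files, f)
    if (is.null(sheet)) {
      sheet <- data.frame(sample_id = rownames(sim$aln$seqs),
                          pool = unname(sim$aln$pools))
    }
    for (pool in ingroup_pools()) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        locus = loci$locus[i], role = loci$role[i], pool = pool,
        k_true = sim$truth$k_true[[pool]],
        n_mutations = length(sim$truth$mutation_columns[[pool]]),
        planted_nonsyn_column = sim$truth$planted_nonsyn_column)
    }
  }
  truth <- do.call(rbind, truth_rows)

  sheet_path <- file.path(dir, "samples.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  roles_path <- file.path(dir, "roles.tsv")
  utils::write.table(loci, roles_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cds_path <- file.path(dir, "cds.tsv")
  utils::write.table(
    data.frame(locus_id = loci$locus, start = cfg$cds[["start"]],
               end = cfg$cds[["end"]], frame = cfg$frame),
    cds_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(dir = dir, sheet = as_sample_sheet(sheet), roles = loci,
       truth = truth,
       files = c(files, sheet = sheet_path, roles = roles_path,
                 cds = cds_path, truth = truth_path))
}
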