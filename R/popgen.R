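#' Harmonic number used by Watterson's estimator
#'
#' \eqn{a_n = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param n Number of sequences (>= 1).
#' @return The harmonic number; 0 for n = 1.
#' @export
harmonic_number <- function(n) {
  if (any(n < 1L)) stop("n must be >= 1")
  vapply(n, function(ni) if (ni < 2L) 0 else sum(1 / seq_len(ni - 1L)), 0)
}

#' Columns retained under complete deletion
#'
#' Complete deletion drops every alignment column in which any sequence of
#' the analysis set carries a gap (\code{-}) or missing base (\code{N});
#' all remaining statistics are computed on the retained columns only.
#'
#' @param aln A \code{\link{locus_alignment}} (or a character matrix).
#' @return Integer vector of retained column indices (1-based).
#' @export
complete_deletion <- function(aln) {
  m <- if (inherits(aln, "locus_alignment")) aln$seqs else aln
  keep <- colSums(m == "-" | m == "N") == 0L
  which(keep)
}

seq_matrix <- function(aln) {
  if (inherits(aln, "locus_alignment")) aln$seqs else aln
}

#' Number of segregating sites
#'
#' Counts retained columns with two or more distinct residues among the
#' ingroup sequences. Multi-allelic columns count once.
#'
#' @param aln Ingroup alignment (n >= 2 sequences).
#' @param retained Retained column indices; defaults to
#'   \code{\link{complete_deletion}} of \code{aln}.
#' @return Integer count S.
#' @export
segregating_sites <- function(aln, retained = complete_deletion(aln)) {
  m <- seq_matrix(aln)
  if (nrow(m) < 2L) stop("segregating sites require n >= 2 sequences")
  if (!length(retained)) return(0L)
  sub <- m[, retained, drop = FALSE]
  sum(apply(sub, 2L, function(col) length(unique(col)) > 1L))
}

#' Watterson's theta per site
#'
#' \eqn{\theta_W = S / (a_n L)} with \eqn{a_n} the (n-1)-th harmonic number
#' and L the number of retained sites.
#'
#' @param S Segregating-site count.
#' @param n Number of sequences (>= 2).
#' @param L_net Retained sites; 0 gives \code{NA}.
#' @return Per-site theta, or \code{NA_real_} when undefined.
#' @export
watterson_theta <- function(S, n, L_net) {
  if (n < 2L) stop("Watterson's theta requires n >= 2")
  if (L_net == 0L) return(NA_real_)
  S / (harmonic_number(n) * L_net)
}

#' Nucleotide diversity per site
#'
#' Mean pairwise difference over all n(n-1)/2 unordered sequence pairs on
#' retained columns, divided by the number of retained sites.
#'
#' @inheritParams segregating_sites
#' @return Per-site pi, or \code{NA_real_} if no columns are retained.
#' @export
nucleotide_diversity <- function(aln, retained = complete_deletion(aln)) {
  m <- seq_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("nucleotide diversity requires n >= 2")
  if (!length(retained)) return(NA_real_)
  sub <- m[, retained, drop = FALSE]
  npairs <- n * (n - 1) / 2
  # column-wise allele counts: pairwise differences at a column with allele
  # counts c_a sum to C(n,2) - sum_a C(c_a,2)
  diff_total <- sum(apply(sub, 2L, function(col) {
    cnt <- table(col)
    npairs - sum(cnt * (cnt - 1) / 2)
  }))
  diff_total / npairs / length(retained)
}

#' Haplotype count
#'
#' Number of distinct residue strings restricted to retained columns.
#'
#' @inheritParams segregating_sites
#' @return Integer count in [1, n].
#' @export
haplotype_count <- function(aln, retained = complete_deletion(aln)) {
  m <- seq_matrix(aln)
  if (!length(retained)) return(1L)
  length(unique(apply(m[, retained, drop = FALSE], 1L, paste0, collapse = "")))
}

#' Mean divergence to the outgroup
#'
#' Average Hamming distance between each ingroup sequence and the single
#' outgroup sequence, on columns retained under complete deletion of the
#' joint (ingroup + outgroup) set. No multiple-hit correction is applied:
#' the ML-HKA framework consumes raw counts.
#'
#' @param aln A \code{\link{locus_alignment}} containing the outgroup.
#' @param pool Ingroup pool to compare against the outgroup.
#' @return Data frame with \code{locus_id}, \code{pool}, \code{D} (exact
#'   mean), \code{D_round}, \code{d_per_site}, \code{L_net}.
#' @export
outgroup_divergence <- function(aln, pool) {
  og <- which(aln$pools == "outgroup")
  if (length(og) != 1L) {
    stop("locus ", aln$locus_id, ": exactly one outgroup sequence required, found ",
         length(og))
  }
  ing <- pool_slice(aln, pool)
  joint <- rbind(ing$seqs, aln$seqs[og, , drop = FALSE])
  retained <- complete_deletion(joint)
  if (!length(retained)) {
    return(data.frame(locus_id = aln$locus_id, pool = pool, D = NA_real_,
                      D_round = NA_integer_, d_per_site = NA_real_, L_net = 0L))
  }
  out_res <- joint[nrow(joint), retained]
  in_res <- joint[seq_len(nrow(joint) - 1L), retained, drop = FALSE]
  per_seq <- rowSums(in_res != rep(out_res, each = nrow(in_res)))
  D <- mean(per_seq)
  data.frame(locus_id = aln$locus_id, pool = pool, D = D,
             D_round = as.integer(round(D)), d_per_site = D / length(retained),
             L_net = length(retained))
}

#' Per-pool diversity statistics for one locus
#'
#' The DnaSP-style summary: S, pi, Watterson's theta and the haplotype
#' count, computed on the pool's sequences after complete deletion within
#' the pool.
#'
#' @param aln A \code{\link{locus_alignment}}.
#' @param pool Ingroup pool label.
#' @return One-row data frame: \code{locus_id}, \code{pool}, \code{n},
#'   \code{L_net}, \code{S}, \code{pi}, \code{theta_w}, \code{n_hap},
#'   \code{a_n}.
#' @export
diversity_stats <- function(aln, pool) {
  ing <- pool_slice(aln, pool)
  n <- nrow(ing$seqs)
  if (n < 2L) stop("locus ", aln$locus_id, ", pool ", pool,
                   ": diversity statistics require n >= 2")
  retained <- complete_deletion(ing)
  L <- length(retained)
  S <- if (L) segregating_sites(ing, retained) else 0L
  data.frame(
    locus_id = aln$locus_id, pool = pool, n = n, L_net = L, S = S,
    pi = if (L) nucleotide_diversity(ing, retained) else NA_real_,
    theta_w = if (L) watterson_theta(S, n, L) else NA_real_,
    n_hap = haplotype_count(ing, retained),
    a_n = harmonic_number(n)
  )
}

#' HKA count data for one locus and pool
#'
#' Extracts the (S, D, L, n) quadruple the ML-HKA likelihood consumes.
#' Complete deletion is applied to the joint set (pool sequences plus the
#' outgroup) so that polymorphism and divergence are counted on the same
#' site set.
#'
#' @param aln A \code{\link{locus_alignment}} with outgroup.
#' @param pool Ingroup pool label.
#' @param role Locus role annotation (\code{"neutral"} or a candidate class).
#' @return One-row data frame: \code{locus}, \code{pool}, \code{role},
#'   \code{S}, \code{D} (rounded), \code{D_exact}, \code{L}, \code{n}.
#' @export
hka_counts <- function(aln, pool, role = NA_character_) {
  og <- which(aln$pools == "outgroup")
  if (length(og) != 1L) {
    stop("locus ", aln$locus_id, ": exactly one outgroup sequence required")
  }
  ing <- pool_slice(aln, pool)
  n <- nrow(ing$seqs)
  if (n < 2L) stop("locus ", aln$locus_id, ", pool ", pool, ": n >= 2 required")
  joint <- rbind(ing$seqs, aln$seqs[og, , drop = FALSE])
  retained <- complete_deletion(joint)
  L <- length(retained)
  S <- if (L) segregating_sites(ing$seqs, retained) else 0L
  out_res <- joint[nrow(joint), retained]
  per_seq <- if (L) rowSums(ing$seqs[, retained, drop = FALSE] !=
                              rep(out_res, each = n)) else numeric()
  D <- if (L) mean(per_seq) else NA_real_
  data.frame(locus = aln$locus_id, pool = pool, role = role, S = S,
             D = as.integer(round(D)), D_exact = D, L = L, n = n)
}

#' Write a per-locus, per-pool diversity table
#'
#' @param df Data frame of stacked \code{\link{diversity_stats}} rows
#'   (optionally with a divergence column).
#' @param path Output TSV.
#' @return \code{path}, invisibly.
#' @export
write_diversity_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write HKA count tables
#'
#' TSV with columns \code{locus}, \code{pool}, \code{role}, \code{S},
#' \code{D}, \code{L}, \code{n} so the likelihood machinery can run without
#' alignments.
#'
#' @param path TSV file.
#' @return Data frame of counts.
#' @export
read_hka_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "pool", "role", "S", "D", "L", "n")
  if (!all(need %in% names(df))) {
    stop("count table must have columns ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_hka_counts
#' @param df Count data frame.
#' @export
write_hka_counts <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
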