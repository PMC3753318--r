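#' Call pool-differentiating variants in a locus alignment
#'
#' Scans every alignment column and emits those with more than one allele
#' among the non-missing ingroup calls (missing \code{N} residues are
#' excluded per column; gaps are reported as the structural allele
#' \code{"-"}). For each emitted column, per-pool allele counts are
#' recorded, pool pairs that are each monomorphic for different alleles are
#' flagged as fixed differences, the coding effect is classified when CDS
#' intervals are annotated, and the frequency in the wild pool of any
#' allele fixed in the improved pool is reported (the ancestral-frequency
#' filter of the fixed-difference screen).
#'
#' Columns in the output are 0-based, matching the CDS interval convention.
#'
#' @param aln A \code{\link{locus_alignment}}.
#' @param min_called Minimum non-missing calls for a pool to be declared
#'   monomorphic/fixed (guards against fixation inferred from 1-2 samples).
#' @return Data frame of class \code{"variant_table"}: \code{locus},
#'   \code{column} (0-based), \code{alleles}, one \code{counts_<pool>}
#'   column per pool (format \code{"A:7,G:1"}), \code{fixed_between},
#'   \code{coding_effect}, \code{wild_freq_derived}.
#' @export
call_pool_variants <- function(aln, min_called = 4L) {
  pools_here <- intersect(pool_levels(), unique(aln$pools))
  ing <- intersect(ingroup_pools(), pools_here)
  if (length(ing) < 2L) stop("variant calling needs >= 2 ingroup pools")
  idx_by_pool <- lapply(pools_here, function(pl) which(aln$pools == pl))
  names(idx_by_pool) <- pools_here

  rows <- list()
  for (col in seq_len(aln$alignment_length)) {
    res <- aln$seqs[, col]
    called_ing <- res[aln$pools %in% ing & res != "N"]
    alleles <- sort(unique(called_ing))
    if (length(alleles) < 2L) next

    cnt_by_pool <- lapply(idx_by_pool, function(idx) {
      v <- res[idx]
      table(v[v != "N"])
    })
    cnt_str <- vapply(cnt_by_pool, function(ct) {
      if (!length(ct)) return("")
      paste(sprintf("%s:%d", names(ct), as.integer(ct)), collapse = ",")
    }, "")

    # fixed allele per ingroup pool (monomorphic over >= min_called calls)
    fixed_allele <- vapply(ing, function(pl) {
      ct <- cnt_by_pool[[pl]]
      if (length(ct) == 1L && sum(ct) >= min_called) names(ct) else NA_character_
    }, "")
    fixed_pairs <- character()
    if (length(ing) >= 2L) {
      prs <- utils::combn(ing, 2L)
      for (j in seq_len(ncol(prs))) {
        f1 <- fixed_allele[[prs[1L, j]]]; f2 <- fixed_allele[[prs[2L, j]]]
        if (!is.na(f1) && !is.na(f2) && f1 != f2) {
          fixed_pairs <- c(fixed_pairs, paste(prs[, j], collapse = "-"))
        }
      }
    }

    wild_freq <- NA_real_
    if (all(c("wild", "improved") %in% ing) && !is.na(fixed_allele[["improved"]])) {
      wct <- cnt_by_pool[["wild"]]
      if (sum(wct) > 0L) {
        fa <- fixed_allele[["improved"]]
        nfa <- if (fa %in% names(wct)) as.numeric(wct[[fa]]) else 0
        wild_freq <- nfa / sum(wct)
      }
    }

    effect <- if ("-" %in% alleles) {
      "indel"
    } else if (is.null(aln$cds)) {
      "noncoding"
    } else {
      classify_coding_effect(aln, col - 1L, alleles[1L], alleles[2L])
    }

    row <- data.frame(locus = aln$locus_id, column = col - 1L,
                      alleles = paste(alleles, collapse = "/"),
                      stringsAsFactors = FALSE)
    for (pl in pools_here) row[[paste0("counts_", pl)]] <- cnt_str[[pl]]
    row$fixed_between <- paste(fixed_pairs, collapse = ";")
    row$coding_effect <- effect
    row$wild_freq_derived <- wild_freq
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    df <- data.frame(locus = character(), column = integer(),
                     alleles = character(), fixed_between = character(),
                     coding_effect = character(),
                     wild_freq_derived = numeric())
    df
  }
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Classify a substitution as synonymous or non-synonymous
#'
#' Translates the codon containing the alignment column under each allele
#' using the standard genetic code; identical amino acids give
#' \code{"synonymous"}, different ones \code{"nonsynonymous"}. Columns
#' outside the CDS intervals (or in an incomplete leading codon) are
#' \code{"noncoding"}; gap alleles are \code{"indel"}. The codon context at
#' the two non-focal positions is the column-majority consensus.
#'
#' @param aln A \code{\link{locus_alignment}} with \code{cds} intervals and
#'   \code{frame} set.
#' @param column 0-based alignment column.
#' @param allele_a,allele_b The two alleles at the column.
#' @return \code{"synonymous"}, \code{"nonsynonymous"}, \code{"noncoding"}
#'   or \code{"indel"}.
#' @export
classify_coding_effect <- function(aln, column, allele_a, allele_b) {
  if (allele_a == "-" || allele_b == "-") return("indel")
  if (is.null(aln$cds)) return("noncoding")
  cds_cols <- cds_column_map(aln)           # 0-based, in coding order
  total <- length(cds_cols)
  frame <- aln$frame
  if ((total - frame) %% 3L != 0L) {
    stop("locus ", aln$locus_id, ": CDS length ", total,
         " minus frame offset ", frame, " is not a multiple of 3")
  }
  cpos <- match(column, cds_cols) - 1L      # 0-based coding position
  if (is.na(cpos) || cpos < frame) return("noncoding")
  codon_start <- frame + 3L * ((cpos - frame) %/% 3L)
  codon_cols <- cds_cols[codon_start + 1:3]  # back to 0-based aln columns
  ctx <- vapply(codon_cols, function(cc) column_consensus(aln$seqs[, cc + 1L]), "")
  off <- which(codon_cols == column)
  ca <- ctx; ca[off] <- allele_a
  cb <- ctx; cb[off] <- allele_b
  if (any(!ca %in% c("A", "C", "G", "T")) || any(!cb %in% c("A", "C", "G", "T"))) {
    return("noncoding")
  }
  code <- Biostrings::GENETIC_CODE
  aa_a <- code[[paste0(ca, collapse = "")]]
  aa_b <- code[[paste0(cb, collapse = "")]]
  if (identical(aa_a, aa_b)) "synonymous" else "nonsynonymous"
}

cds_column_map <- function(aln) {
  unlist(lapply(seq_len(nrow(aln$cds)), function(i) {
    seq.int(aln$cds$start[i], aln$cds$end[i] - 1L)
  }))
}

column_consensus <- function(res) {
  res <- res[res != "N" & res != "-"]
  if (!length(res)) return("N")
  ct <- table(res)
  names(ct)[which.max(ct)]  # ties resolved alphabetically (table is sorted)
}

#' Screen FDR-significant loci for fixed non-synonymous differences
#'
#' For every locus significant after FDR correction, lists alignment
#' columns at which the improved gene pool is fixed for a non-synonymous
#' variant whose frequency among wild sequences is below
#' \code{wild_freq_cutoff} -- the pattern expected of a new or rare variant
#' driven to fixation by selection during improvement.
#'
#' @param scan A \code{\link{scan_candidates}} table (needs \code{locus},
#'   \code{q_value}).
#' @param calls A \code{\link{call_pool_variants}} table (one or more loci).
#' @param wild_freq_cutoff Report only variants with wild frequency below
#'   this (1.0 reports every fixed non-synonymous difference).
#' @param fdr_alpha FDR threshold selecting loci to screen.
#' @return Data frame: \code{locus}, \code{column}, \code{allele},
#'   \code{coding_effect}, \code{wild_freq_derived}, \code{q_min}.
#' @export
screen_selected_loci <- function(scan, calls, wild_freq_cutoff = 0.20,
                                 fdr_alpha = 0.05) {
  qmin <- tapply(scan$q_value, scan$locus, function(q) {
    if (all(is.na(q))) NA_real_ else min(q, na.rm = TRUE)
  })
  sig_loci <- names(qmin)[!is.na(qmin) & qmin < fdr_alpha]
  out <- list()
  for (loc in sig_loci) {
    v <- calls[calls$locus == loc & calls$coding_effect == "nonsynonymous" &
                 !is.na(calls$wild_freq_derived) &
                 calls$wild_freq_derived < wild_freq_cutoff, , drop = FALSE]
    if (!nrow(v)) next
    imp_allele <- vapply(strsplit(v$counts_improved, ":", fixed = TRUE),
                         `[`, "", 1L)
    out[[length(out) + 1L]] <- data.frame(
      locus = loc, column = v$column, allele = imp_allele,
      coding_effect = v$coding_effect,
      wild_freq_derived = v$wild_freq_derived,
      q_min = unname(qmin[[loc]]))
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(locus = character(), column = integer(), allele = character(),
               coding_effect = character(), wild_freq_derived = numeric(),
               q_min = numeric())
  }
  rownames(res) <- NULL
  res
}

#' Write a variant table as TSV
#'
#' VCF-like plain-text output; positions are written 1-based in the
#' \code{pos} column (the in-memory \code{column} field is 0-based).
#'
#' @param calls A \code{\link{call_pool_variants}} table.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  out <- calls
  out$pos <- out$column + 1L
  out <- out[, c("locus", "pos", setdiff(names(out), c("locus", "pos")))]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
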