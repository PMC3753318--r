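#' Read a sample sheet assigning sequences to gene pools
#'
#' The sample sheet is a TSV with header columns \code{sample_id} and
#' \code{pool}, one row per sequenced accession. Pools follow the stratified
#' domestication-study design: \code{wild}, \code{landrace}, \code{improved}
#' and a single \code{outgroup} accession. Pool tokens are case-insensitive
#' and stored lower-case.
#'
#' @param path Path to a tab-separated file with columns \code{sample_id}
#'   and \code{pool}.
#' @return A data frame of class \code{"sample_sheet"} with columns
#'   \code{sample_id} and \code{pool}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tpool", "w1\twild", "o1\toutgroup"), tf)
#' read_sample_sheet(tf)
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "pool")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns 'sample_id' and 'pool'; found: ",
         paste(names(df), collapse = ", "))
  }
  as_sample_sheet(df[, need])
}

#' Validate a sample-sheet data frame
#'
#' @param df Data frame with columns \code{sample_id}, \code{pool}.
#' @return The validated sheet, pools normalised to lower case, with class
#'   \code{"sample_sheet"}.
#' @export
as_sample_sheet <- function(df) {
  df$sample_id <- as.character(df$sample_id)
  df$pool <- tolower(as.character(df$pool))
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) {
    stop("duplicate sample_id in sample sheet: ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(df$pool), pool_levels())
  if (length(bad)) {
    stop("unknown pool token(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(pool_levels(), collapse = "/"), ")")
  }
  n_out <- sum(df$pool == "outgroup")
  if (n_out == 0L) stop("sample sheet must contain exactly one outgroup row; found none")
  if (n_out > 1L) stop("sample sheet must contain exactly one outgroup row; found ", n_out)
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

pool_levels <- function() c("wild", "landrace", "improved", "outgroup")
ingroup_pools <- function() c("wild", "landrace", "improved")

#' Construct a locus alignment
#'
#' A locus alignment is the raw analysis unit: one multiple-sequence
#' alignment per locus, each sequence labelled with its gene pool. Residues
#' are upper-case over the alphabet \code{A,C,G,T,-,N}; \code{-} is an
#' alignment gap and \code{N} missing data. Coordinates in CDS interval
#' annotations are 0-based half-open on the forward strand.
#'
#' @param locus_id Locus identifier.
#' @param seqs Character matrix, one row per sequence (rownames are sample
#'   ids), one column per alignment position; or a named character vector of
#'   equal-length residue strings.
#' @param pools Named character vector mapping sample id to pool.
#' @param cds Optional data frame of CDS intervals with columns \code{start},
#'   \code{end} (0-based half-open).
#' @param frame Reading-frame offset of the concatenated CDS (0, 1 or 2).
#' @return An object of class \code{"locus_alignment"}.
#' @export
locus_alignment <- function(locus_id, seqs, pools, cds = NULL, frame = 0L) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop("locus ", locus_id, ": sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    }
    ids <- names(seqs)
    seqs <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(seqs) <- ids
  }
  if (is.null(rownames(seqs))) stop("sequence matrix must have sample ids as rownames")
  seqs[] <- toupper(seqs)
  bad <- !(seqs %in% c("A", "C", "G", "T", "-", "N"))
  n_amb <- sum(bad)
  if (n_amb > 0L) {
    warning("locus ", locus_id, ": ", n_amb,
            " ambiguous residue(s) converted to N")
    seqs[bad] <- "N"
  }
  ids <- rownames(seqs)
  missing_pool <- setdiff(ids, names(pools))
  if (length(missing_pool)) {
    stop("locus ", locus_id, ": sample id(s) not in sample sheet: ",
         paste(missing_pool, collapse = ", "))
  }
  pools <- tolower(pools[ids])
  L <- ncol(seqs)
  if (L < 1L) stop("alignment_length must be >= 1")
  if (!is.null(cds)) {
    cds <- as.data.frame(cds)[, c("start", "end")]
    cds <- cds[order(cds$start), , drop = FALSE]
    ok <- all(cds$start >= 0) && all(cds$end <= L) && all(cds$start < cds$end)
    if (!ok) stop("locus ", locus_id, ": CDS intervals must lie within [0, ",
                  L, ") with start < end")
    if (nrow(cds) > 1L && any(cds$start[-1L] < cds$end[-nrow(cds)])) {
      stop("locus ", locus_id, ": CDS intervals overlap")
    }
    rownames(cds) <- NULL
  }
  structure(
    list(locus_id = locus_id, seqs = seqs, pools = pools,
         alignment_length = L, cds = cds, frame = as.integer(frame)),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("Locus alignment '", x$locus_id, "': ", nrow(x$seqs), " sequence(s) x ",
      x$alignment_length, " bp\n", sep = "")
  cat("  pools:", paste(sprintf("%s=%d", names(table(x$pools)),
                                table(x$pools)), collapse = ", "), "\n")
  if (!is.null(x$cds)) {
    cat("  CDS: ", nrow(x$cds), " interval(s), frame ", x$frame, "\n", sep = "")
  }
  invisible(x)
}

#' Read a per-locus FASTA alignment
#'
#' FASTA headers must be sample ids present in the sheet; sequences must be
#' pre-aligned (equal lengths). Residues are upper-cased and IUPAC ambiguity
#' codes other than \code{N} are converted to \code{N} with a warning.
#'
#' @param path FASTA file (one aligned locus).
#' @param sheet A \code{\link{read_sample_sheet}} result.
#' @param cds Optional CDS interval data frame (\code{start}, \code{end},
#'   0-based half-open).
#' @param frame Reading-frame offset for the CDS.
#' @param locus_id Locus name; defaults to the file name without extension.
#' @return A \code{\link{locus_alignment}}.
#' @export
read_locus_alignment <- function(path, sheet, cds = NULL, frame = 0L,
                                 locus_id = NULL) {
  if (is.null(locus_id)) {
    locus_id <- sub("\\.(fa|fasta|fas)$", "", basename(path), ignore.case = TRUE)
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  lens <- Biostrings::width(ss)
  if (length(unique(lens)) > 1L) {
    stop("locus ", locus_id, ": FASTA records have unequal lengths (",
         paste(unique(lens), collapse = ", "), "); input must be aligned")
  }
  unknown <- setdiff(ids, sheet$sample_id)
  if (length(unknown)) {
    stop("locus ", locus_id, ": FASTA header(s) absent from sample sheet: ",
         paste(unknown, collapse = ", "))
  }
  seqs <- as.character(ss)
  names(seqs) <- ids
  pools <- stats::setNames(sheet$pool, sheet$sample_id)
  locus_alignment(locus_id, seqs, pools, cds = cds, frame = frame)
}

#' Write a locus alignment as canonical FASTA
#'
#' Canonical form: upper-case residues wrapped at 60 columns, so that
#' write-then-read is the identity.
#'
#' @param aln A \code{\link{locus_alignment}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_locus_fasta <- function(aln, path) {
  s <- apply(aln$seqs, 1L, paste0, collapse = "")
  ss <- Biostrings::BStringSet(s)
  names(ss) <- rownames(aln$seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Restrict an alignment to one gene pool
#'
#' Subsets sequences to the requested pool, preserving order of appearance
#' and alignment length. An empty result is an error: downstream statistics
#' need at least the pool's sampled sequences.
#'
#' @param aln A \code{\link{locus_alignment}}.
#' @param pool One of \code{"wild"}, \code{"landrace"}, \code{"improved"},
#'   \code{"outgroup"}.
#' @return A \code{\link{locus_alignment}} containing only that pool.
#' @export
pool_slice <- function(aln, pool) {
  pool <- match.arg(tolower(pool), pool_levels())
  keep <- which(aln$pools == pool)
  if (!length(keep)) {
    stop("locus ", aln$locus_id, ": no sequences in pool '", pool, "'")
  }
  out <- aln
  out$seqs <- aln$seqs[keep, , drop = FALSE]
  out$pools <- aln$pools[keep]
  out
}

#' Read CDS interval annotations
#'
#' BED-like TSV with columns \code{locus_id}, \code{start}, \code{end},
#' \code{frame}; coordinates 0-based half-open, forward strand.
#'
#' @param path TSV file.
#' @return Named list per locus: \code{list(cds = data.frame(start, end),
#'   frame)}.
#' @export
read_cds_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "start", "end", "frame")
  if (!all(need %in% names(df))) {
    stop("CDS table must have columns ", paste(need, collapse = ", "))
  }
  split_df <- split(df, df$locus_id)
  lapply(split_df, function(d) {
    fr <- unique(d$frame)
    if (length(fr) > 1L) {
      stop("locus ", d$locus_id[1L], ": inconsistent frame values in CDS table")
    }
    list(cds = data.frame(start = d$start, end = d$end), frame = as.integer(fr))
  })
}
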