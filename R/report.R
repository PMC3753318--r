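#' Group diversity means and loss relative to wild
#'
#' The Table-1-style group arithmetic: unweighted means of per-locus
#' Watterson's theta by locus role and gene pool, and the percent loss of
#' diversity of each derived pool relative to the same role's wild mean,
#' \eqn{100 (1 - \bar\theta_{pool} / \bar\theta_{wild})}. Percentages are
#' also reported rounded to the nearest 5 for prose-style comparison
#' ("ca. 60\% loss").
#'
#' @param tab Data frame with columns \code{locus}, \code{role},
#'   \code{pool} and the value column.
#' @param value Name of the per-locus diversity column (default
#'   \code{"theta_w"}).
#' @return Data frame of class \code{"group_summary"}: \code{role},
#'   \code{pool}, \code{n_loci}, \code{mean_theta}, \code{loss_vs_wild_pct},
#'   \code{loss_pct_nearest5}.
#' @export
summarize_diversity <- function(tab, value = "theta_w") {
  need <- c("locus", "role", "pool", value)
  if (!all(need %in% names(tab))) {
    stop("need columns ", paste(need, collapse = ", "))
  }
  rows <- list()
  for (role in unique(tab$role)) {
    sub <- tab[tab$role == role, ]
    wild_mean <- mean(sub[[value]][sub$pool == "wild"], na.rm = TRUE)
    for (pool in intersect(c("wild", "landrace", "improved"),
                           unique(sub$pool))) {
      v <- sub[[value]][sub$pool == pool]
      m <- mean(v, na.rm = TRUE)
      loss <- if (is.finite(wild_mean) && wild_mean > 0) {
        100 * (1 - m / wild_mean)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        role = role, pool = pool, n_loci = sum(!is.na(v)), mean_theta = m,
        loss_vs_wild_pct = loss,
        loss_pct_nearest5 = if (is.na(loss)) NA_real_ else 5 * round(loss / 5))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

#' @export
print.group_summary <- function(x, digits = 4L, ...) {
  cat("Group diversity summary (loss relative to same-role wild mean):\n")
  NextMethod()
}

#' Bar chart of group mean diversity
#'
#' @param x A \code{\link{summarize_diversity}} result.
#' @param ... Passed to \code{\link[graphics]{barplot}}.
#' @export
plot.group_summary <- function(x, ...) {
  m <- tapply(x$mean_theta, list(x$pool, x$role), identity)
  m <- m[intersect(c("wild", "landrace", "improved"), rownames(m)), ,
         drop = FALSE]
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = expression("mean " * theta[W]), ...)
  invisible(x)
}

#' Run the full selection-scan pipeline from a configuration file
#'
#' End-to-end orchestration: read inputs, compute per-locus diversity and
#' HKA counts (FASTA mode) or load a count table (counts mode), validate
#' the neutral panel leave-one-out, test every candidate in every pool,
#' attach Storey q-values, classify timing, screen significant loci for
#' fixed non-synonymous differences (FASTA mode), and write the scan table,
#' diversity table, group summary, variant screen and a markdown report.
#' All report numbers are rendered from the written tables.
#'
#' Configuration (YAML file or list): \code{mode} ("fasta" or "counts");
#' FASTA mode needs \code{sample_sheet}, \code{fasta_dir}, \code{roles}
#' (TSV: locus, role) and optionally \code{cds}; counts mode needs
#' \code{count_table}. Optional: \code{alpha} (0.05), \code{lrt_df} (2),
#' \code{fdr_scope} ("joint"), \code{wild_freq_cutoff} (0.2), \code{seed}
#' (1), \code{out_dir}.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory (overrides the config entry).
#' @return Invisible list: \code{scan}, \code{diversity}, \code{summary},
#'   \code{screen}, \code{panel_checks}, \code{files}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML file path or a named list")
  mode <- cfg$mode
  if (is.null(mode) || !mode %in% c("fasta", "counts")) {
    stop("config field 'mode' must be \"fasta\" or \"counts\"")
  }
  req <- if (mode == "fasta") c("sample_sheet", "fasta_dir", "roles")
         else "count_table"
  for (f in req) {
    if (is.null(cfg[[f]])) stop("config field '", f, "' is required in ",
                                mode, " mode")
    if (!file.exists(cfg[[f]])) stop("config field '", f, "': path '",
                                     cfg[[f]], "' does not exist")
  }
  alpha <- cfg$alpha %||% 0.05
  df <- cfg$lrt_df %||% 2L
  fdr_scope <- cfg$fdr_scope %||% "joint"
  cutoff <- cfg$wild_freq_cutoff %||% 0.20
  seed <- cfg$seed %||% 1L
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("sunhka_out")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  diversity <- NULL; screen <- NULL; calls <- NULL
  if (mode == "fasta") {
    sheet <- read_sample_sheet(cfg$sample_sheet)
    roles <- utils::read.delim(cfg$roles, stringsAsFactors = FALSE)
    cds_map <- if (!is.null(cfg$cds)) read_cds_table(cfg$cds) else list()
    div_rows <- list(); cnt_rows <- list(); call_rows <- list()
    for (i in seq_len(nrow(roles))) {
      loc <- roles$locus[i]
      fa <- file.path(cfg$fasta_dir, paste0(loc, ".fasta"))
      if (!file.exists(fa)) fa <- file.path(cfg$fasta_dir, paste0(loc, ".fa"))
      if (!file.exists(fa)) stop("no FASTA for locus '", loc, "' in ",
                                 cfg$fasta_dir)
      ann <- cds_map[[loc]]
      aln <- read_locus_alignment(fa, sheet, cds = ann$cds,
                                  frame = ann$frame %||% 0L, locus_id = loc)
      for (pool in intersect(ingroup_pools(), unique(aln$pools))) {
        d <- diversity_stats(aln, pool)
        d$role <- roles$role[i]
        div_rows[[length(div_rows) + 1L]] <- d
        cnt_rows[[length(cnt_rows) + 1L]] <-
          hka_counts(aln, pool, role = roles$role[i])
      }
      call_rows[[length(call_rows) + 1L]] <- call_pool_variants(aln)
    }
    diversity <- do.call(rbind, div_rows)
    counts <- do.call(rbind, cnt_rows)
    calls <- do.call(rbind, call_rows)
  } else {
    counts <- read_hka_counts(cfg$count_table)
  }

  panel <- counts[counts$role == "neutral", ]
  cand <- counts[counts$role != "neutral", ]
  scan <- scan_candidates(cand, panel, alpha = alpha, df = df,
                          fdr_scope = fdr_scope, seed = seed)
  if (!is.null(diversity)) {
    names(diversity)[names(diversity) == "locus_id"] <- "locus"
  }
  summ <- summarize_diversity(if (is.null(diversity)) scan else diversity)
  if (!is.null(calls)) {
    screen <- screen_selected_loci(scan, calls, wild_freq_cutoff = cutoff)
  }

  files <- c(scan = file.path(out_dir, "scan.tsv"),
             summary = file.path(out_dir, "group_summary.tsv"),
             report = file.path(out_dir, "report.md"))
  write_scan_table(scan, files[["scan"]])
  utils::write.table(summ, files[["summary"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(diversity)) {
    files[["diversity"]] <- file.path(out_dir, "diversity.tsv")
    write_diversity_table(diversity, files[["diversity"]])
  }
  if (!is.null(screen)) {
    files[["screen"]] <- file.path(out_dir, "variant_screen.tsv")
    utils::write.table(screen, files[["screen"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(calls)) {
    files[["variants"]] <- file.path(out_dir, "variants.tsv")
    write_variant_table(calls, files[["variants"]])
  }
  write_report_md(files, out_dir)

  invisible(list(scan = scan, diversity = diversity, summary = summ,
                 screen = screen, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Render report.md strictly from the written TSVs (single source of truth).
write_report_md <- function(files, out_dir) {
  scan <- utils::read.delim(files[["scan"]], stringsAsFactors = FALSE)
  summ <- utils::read.delim(files[["summary"]], stringsAsFactors = FALSE)
  qmin <- tapply(scan$q_value[scan$role != "neutral"],
                 scan$locus[scan$role != "neutral"],
                 function(q) if (all(is.na(q))) NA_real_ else min(q, na.rm = TRUE))
  sig <- names(qmin)[!is.na(qmin) & qmin < 0.05]
  lines <- c(
    "# ML-HKA selection scan report", "",
    sprintf("- loci tested: %d candidates, %d neutral",
            length(unique(scan$locus[scan$role != "neutral"])),
            length(unique(scan$locus[scan$role == "neutral"]))),
    sprintf("- pools: %s", paste(unique(scan$pool), collapse = ", ")),
    sprintf("- loci at FDR < 0.05: %d (%s)", length(sig),
            paste(sig, collapse = ", ")), "",
    "## Group diversity", "",
    paste(utils::capture.output(print.data.frame(summ, digits = 4)),
          collapse = "\n"), "",
    "## Timing classes", "",
    paste(utils::capture.output(print(table(
      unique(scan[scan$role != "neutral", c("locus", "timing_class")])$timing_class))),
      collapse = "\n"))
  if ("screen" %in% names(files)) {
    scr <- utils::read.delim(files[["screen"]], stringsAsFactors = FALSE)
    lines <- c(lines, "", "## Fixed non-synonymous differences (screen)", "",
               if (nrow(scr)) paste(utils::capture.output(
                 print.data.frame(scr, digits = 3)), collapse = "\n")
               else "none")
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(files)
}

#' Published per-locus scan values for cultivated sunflower
#'
#' The bundled table of published per-locus Watterson's theta and ML-HKA
#' P-values for a 34-locus sunflower panel (7 neutral loci, 13 putative
#' domestication genes, 14 putative improvement genes) sampled from wild,
#' landrace and improved gene pools. Used by desk-scale re-analyses: group
#' diversity-loss arithmetic and the FDR reproduction.
#'
#' @param long Return long format (one row per locus x pool) instead of the
#'   published wide layout.
#' @return Data frame; wide: \code{locus}, \code{role}, \code{annotation},
#'   \code{theta_*}, \code{p_*}; long: \code{locus}, \code{role},
#'   \code{pool}, \code{theta_w}, \code{p_value}.
#' @export
sunflower_scan_published <- function(long = FALSE) {
  path <- system.file("extdata", "sunflower_scan_published.tsv",
                      package = "sunhka", mustWork = TRUE)
  wide <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!long) return(wide)
  do.call(rbind, lapply(c("wild", "landrace", "improved"), function(pool) {
    suf <- c(wild = "wild", landrace = "landrace", improved = "improved")[[pool]]
    data.frame(locus = wide$locus, role = wide$role, pool = pool,
               theta_w = wide[[paste0("theta_", suf)]],
               p_value = wide[[paste0("p_", suf)]])
  }))
}
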