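#' Leave-one-out validation of the neutral-locus panel
#'
#' Before candidates are tested, each putatively neutral locus is tested
#' against the remaining panel loci with the ML-HKA selection model. The
#' panel passes when no locus rejects neutrality at \code{alpha}: only then
#' is it a valid yardstick for the candidate scan.
#'
#' @param panel Count data frame (one pool): columns \code{locus}, \code{S},
#'   \code{D}, \code{L}, \code{n}; at least 3 loci.
#' @param alpha Significance threshold for the verdict.
#' @param df Chi-square degrees of freedom of the LRT.
#' @param ... Passed to \code{\link{hka_test}}.
#' @return Object of class \code{"hka_panel_check"}: list with
#'   \code{results} (per-locus data frame of LRT, k-hat, p) and \code{pass}.
#' @export
validate_neutral_panel <- function(panel, alpha = 0.05, df = 2L, ...) {
  panel <- validate_hka_counts(panel)
  if (nrow(panel) < 3L) stop("neutral panel needs >= 3 loci")
  rows <- lapply(panel$locus, function(loc) {
    res <- tryCatch(hka_test(panel, focal = loc, df = df, ...),
                    error = function(e) {
                      warning("panel locus ", loc, ": ", conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) {
      data.frame(locus = loc, k_hat = NA_real_, LRT = NA_real_,
                 p_value = NA_real_)
    } else {
      data.frame(locus = loc, k_hat = res$k_hat, LRT = res$statistic,
                 p_value = res$p_value)
    }
  })
  results <- do.call(rbind, rows)
  out <- list(results = results, alpha = alpha,
              pass = all(results$p_value >= alpha, na.rm = TRUE))
  class(out) <- "hka_panel_check"
  out
}

#' @export
print.hka_panel_check <- function(x, digits = 4L, ...) {
  cat("Neutral-panel leave-one-out check (", nrow(x$results), " loci): ",
      if (x$pass) "PASS" else "FAIL", " at alpha = ", x$alpha, "\n", sep = "")
  print(x$results, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Classify the timing of selection from per-pool P-values
#'
#' Selection at a locus is dated by which derived pools reject neutrality,
#' applied in order: significant in both landrace and improved implies
#' selection during domestication; significant in improved but not landrace
#' implies selection during improvement; otherwise a significant wild-pool
#' test is surfaced as \code{"wild-flagged"} (an anomaly -- selection is
#' inferred relative to wild ancestry, so wild-only significance dates
#' nothing) rather than suppressed.
#'
#' @param p Named vector (or list) of P-values with names among
#'   \code{wild}, \code{landrace}, \code{improved}; missing entries are
#'   treated as non-significant.
#' @param alpha Significance threshold.
#' @return One of \code{"none"}, \code{"domestication"},
#'   \code{"improvement"}, \code{"wild-flagged"}.
#' @export
classify_timing <- function(p, alpha = 0.05) {
  p <- unlist(p)
  sig <- function(pool) {
    pool %in% names(p) && !is.na(p[[pool]]) && p[[pool]] <= alpha
  }
  land <- sig("landrace")
  imp <- sig("improved")
  if (land && imp) return("domestication")
  if (imp) return("improvement")
  if (sig("wild")) return("wild-flagged")
  "none"
}

#' Scan candidate loci against the neutral panel in each gene pool
#'
#' The staged design of a sequence-based domestication scan: each candidate
#' locus is tested with the ML-HKA likelihood-ratio test against the
#' neutral panel, separately within the wild, landrace and improved pools
#' (each pool's test re-estimates T: the pools are separate datasets).
#' Storey q-values are attached jointly across all candidate tests, and a
#' per-locus timing class is derived from the per-pool P-values.
#'
#' @param candidates Count data frame with columns \code{locus},
#'   \code{pool}, \code{role}, \code{S}, \code{D}, \code{L}, \code{n}.
#' @param panel Neutral-panel counts in the same format (role
#'   \code{"neutral"}).
#' @param pools Pools to scan (default: those present in both inputs).
#' @param alpha Significance threshold for flags and timing.
#' @param df LRT degrees of freedom.
#' @param fdr_scope \code{"joint"} computes q-values across all candidate
#'   tests together (all pools); \code{"per-pool"} stratifies by pool.
#' @param timing_on Classify timing from raw P-values (\code{"p"}, the
#'   default) or q-values (\code{"q"}).
#' @param include_panel Also report leave-one-out results for panel loci.
#' @param validate_panel Run \code{\link{validate_neutral_panel}} per pool
#'   first and warn on failure.
#' @param ... Passed to \code{\link{hka_test}}.
#' @return Data frame of class \code{"scan_table"}: one row per locus x
#'   pool with \code{theta_w}, \code{k_hat}, \code{p_value}, \code{q_value},
#'   \code{significant_05}, \code{marginal_10}, \code{timing_class}.
#' @export
scan_candidates <- function(candidates, panel, pools = NULL, alpha = 0.05,
                            df = 2L, fdr_scope = c("joint", "per-pool"),
                            timing_on = c("p", "q"), include_panel = TRUE,
                            validate_panel = TRUE, ...) {
  fdr_scope <- match.arg(fdr_scope)
  timing_on <- match.arg(timing_on)
  need <- c("locus", "pool", "role", "S", "D", "L", "n")
  for (nm in need) {
    if (!nm %in% names(candidates) || !nm %in% names(panel)) {
      stop("candidates and panel need columns ", paste(need, collapse = ", "))
    }
  }
  if (is.null(pools)) {
    pools <- intersect(intersect(unique(candidates$pool), unique(panel$pool)),
                       ingroup_pools())
  }

  rows <- list()
  for (pl in pools) {
    pp <- drop_inadmissible(panel[panel$pool == pl, , drop = FALSE])
    loo <- NULL
    if (validate_panel || include_panel) {
      loo <- validate_neutral_panel(pp[, c("locus", "S", "D", "L", "n")],
                                    alpha = alpha, df = df, ...)
    }
    if (validate_panel && !loo$pass) {
      warning("neutral panel fails leave-one-out validation in pool '", pl,
              "'; candidate tests in this pool may be unreliable")
    }
    cc <- drop_inadmissible(candidates[candidates$pool == pl, , drop = FALSE])
    for (i in seq_len(nrow(cc))) {
      dat <- rbind(pp[, c("locus", "S", "D", "L", "n")],
                   cc[i, c("locus", "S", "D", "L", "n")])
      res <- tryCatch(hka_test(dat, focal = cc$locus[i], df = df, ...),
                      error = function(e) {
                        warning("locus ", cc$locus[i], ", pool ", pl, ": ",
                                conditionMessage(e))
                        NULL
                      })
      rows[[length(rows) + 1L]] <- data.frame(
        locus = cc$locus[i], role = cc$role[i], pool = pl,
        n = cc$n[i], S = cc$S[i], D = cc$D[i], L = cc$L[i],
        theta_w = watterson_theta(cc$S[i], cc$n[i], cc$L[i]),
        k_hat = if (is.null(res)) NA_real_ else res$k_hat,
        p_value = if (is.null(res)) NA_real_ else res$p_value)
    }
    if (include_panel) {
      for (i in seq_len(nrow(pp))) {
        r <- loo$results[loo$results$locus == pp$locus[i], ]
        rows[[length(rows) + 1L]] <- data.frame(
          locus = pp$locus[i], role = "neutral", pool = pl,
          n = pp$n[i], S = pp$S[i], D = pp$D[i], L = pp$L[i],
          theta_w = watterson_theta(pp$S[i], pp$n[i], pp$L[i]),
          k_hat = r$k_hat, p_value = r$p_value)
      }
    }
  }
  tab <- do.call(rbind, rows)

  # q-values across candidate tests only (the neutral rows are diagnostics)
  tab$q_value <- NA_real_
  cand_idx <- which(tab$role != "neutral" & !is.na(tab$p_value))
  if (length(cand_idx)) {
    if (fdr_scope == "joint") {
      tab$q_value[cand_idx] <- storey_qvalues(tab$p_value[cand_idx])$q
    } else {
      for (pl in unique(tab$pool[cand_idx])) {
        idx <- cand_idx[tab$pool[cand_idx] == pl]
        tab$q_value[idx] <- storey_qvalues(tab$p_value[idx])$q
      }
    }
  }
  tab$significant_05 <- !is.na(tab$p_value) & tab$p_value <= alpha
  tab$marginal_10 <- !is.na(tab$p_value) & tab$p_value > alpha &
    tab$p_value <= 0.1

  tab$timing_class <- NA_character_
  for (loc in unique(tab$locus[tab$role != "neutral"])) {
    sel <- tab$locus == loc & tab$role != "neutral"
    use <- if (timing_on == "p") tab$p_value[sel] else tab$q_value[sel]
    tab$timing_class[sel] <- classify_timing(
      stats::setNames(use, tab$pool[sel]), alpha = alpha)
  }
  rownames(tab) <- NULL
  class(tab) <- c("scan_table", "data.frame")
  tab
}

# Exclude loci a pool cannot test (mirrors dropping unsequencable genes at
# the data level), with a message naming them.
drop_inadmissible <- function(counts) {
  bad <- counts$L < 1 | counts$n < 2 | is.na(counts$S) | is.na(counts$D)
  if (any(bad)) {
    message("excluding ", sum(bad), " locus/pool combination(s) with L = 0, ",
            "n < 2 or missing counts: ",
            paste(counts$locus[bad], collapse = ", "))
  }
  counts[!bad, , drop = FALSE]
}

#' @export
print.scan_table <- function(x, digits = 4L, ...) {
  cat("ML-HKA scan table: ", length(unique(x$locus)), " loci x ",
      length(unique(x$pool)), " pool(s)\n", sep = "")
  nsig <- length(unique(x$locus[!is.na(x$q_value) & x$q_value < 0.05]))
  cat("  loci at FDR < 0.05: ", nsig, "\n", sep = "")
  NextMethod()
}

#' Write a scan table as TSV
#'
#' @param tab A \code{\link{scan_candidates}} result.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_scan_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
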