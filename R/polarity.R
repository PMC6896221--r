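# Polarized synonymous substitution counting on ancestor -> descendant
# branches: does codon usage move toward or away from the preferred set, and
# how does third-position GC change at substituted sites?

#' Polarize synonymous substitutions on one branch
#'
#' A codon column counts as one synonymous substitution when the ancestral
#' and descendant codons differ only at the third position and encode the
#' same amino acid. It is classified "to preferred" when the descendant codon
#' is in the species' preferred set and "to unpreferred" otherwise (binary
#' rule, so the two classes always sum to the total). Columns with an amino
#' acid change or a multi-position change are excluded (single-event
#' parsimony). GC tallies cover the third positions of substituted sites
#' only. Opportunity counts (ancestral codons currently unpreferred, i.e.
#' able to gain a preferred codon, vs currently preferred) are recorded over
#' all analysable columns of amino acids possessing a preferred codon, for
#' use by [gc_shift_test()].
#'
#' @param pair An [aligned_codon_pair] with `a` = ancestor, `b` = descendant.
#' @param ocs The species' [optimal_codon_set].
#' @param branch_label Label for reports.
#' @param gc_fallback When TRUE, columns whose amino acid has no flagged
#'   codon are classified by a GC proxy (GC-ending descendant counts as "to
#'   preferred" in a GC-rich species, and conversely in an AT-rich one);
#'   off by default, which keeps the pure binary rule.
#' @return Object of class `branch_substitution_summary`: `to_preferred`,
#'   `to_unpreferred`, `total_synonymous`, `gc_ancestral` and `gc_current`
#'   (percent GC at substituted third positions; NA when no substitution),
#'   `opportunity` (named vector `gain`/`loss`), `excluded` column count and
#'   `chi2_p` (NA until [gc_shift_test()] is run).
#' @export
polarize_branch <- function(pair, ocs, branch_label = NULL,
                            gc_fallback = FALSE) {
  stopifnot(inherits(pair, "aligned_codon_pair"))
  if (!length(ocs$preferred)) stop("optimal codon set is empty")
  code <- .code(pair$genetic_code)
  if (is.null(branch_label))
    branch_label <- paste(pair$label_a, pair$label_b, sep = "->")
  anc <- pair$a
  dec <- pair$b
  aa_anc <- code$code[anc]
  aa_dec <- code$code[dec]
  pref_codons <- unlist(ocs$preferred, use.names = FALSE)
  has_pref_aa <- names(ocs$preferred)

  diff3 <- substr(anc, 3, 3) != substr(dec, 3, 3)
  diff12 <- substr(anc, 1, 2) != substr(dec, 1, 2)
  synsub <- diff3 & !diff12 & aa_anc == aa_dec
  excluded <- sum((diff3 & diff12) | (diff12 & !diff3) |
                  (diff3 & !diff12 & aa_anc != aa_dec))

  idx <- which(synsub)
  dec_s <- dec[idx]
  anc_s <- anc[idx]
  aa_s <- aa_anc[idx]
  to_pref_flag <- dec_s %in% pref_codons
  if (gc_fallback && !is.na(ocs$gc_class)) {
    nofl <- !aa_s %in% has_pref_aa
    if (ocs$gc_class == "GC-rich") {
      to_pref_flag[nofl] <- is_gc_ending(dec_s[nofl])
    } else if (ocs$gc_class == "AT-rich") {
      to_pref_flag[nofl] <- !is_gc_ending(dec_s[nofl])
    }
  }
  to_pref <- sum(to_pref_flag)
  total <- length(idx)
  gc_anc <- if (total) 100 * mean(is_gc_ending(anc_s)) else NA_real_
  gc_cur <- if (total) 100 * mean(is_gc_ending(dec_s)) else NA_real_

  opp_cols <- aa_anc %in% has_pref_aa
  opp_loss <- sum(opp_cols & anc %in% pref_codons)
  opp_gain <- sum(opp_cols & !anc %in% pref_codons)

  structure(
    list(branch_label = branch_label,
         to_preferred = to_pref,
         to_unpreferred = total - to_pref,
         total_synonymous = total,
         gc_ancestral = gc_anc, gc_current = gc_cur,
         opportunity = c(gain = opp_gain, loss = opp_loss),
         excluded = excluded, n_columns = length(anc),
         gc3_preferred = ocs$gc3_preferred,
         chi2_p = NA_real_),
    class = "branch_substitution_summary"
  )
}

#' @export
print.branch_substitution_summary <- function(x, ...) {
  cat("branch:", x$branch_label, "\n")
  cat(sprintf("  to preferred %d + to unpreferred %d = %d synonymous substitutions\n",
              x$to_preferred, x$to_unpreferred, x$total_synonymous))
  if (!is.na(x$gc_ancestral))
    cat(sprintf("  GC3 at substituted sites: %.2f%% (ancestral) -> %.2f%% (current)\n",
                x$gc_ancestral, x$gc_current))
  if (!is.na(x$chi2_p)) cat(sprintf("  chi-squared p = %.4g\n", x$chi2_p))
  invisible(x)
}

#' Test substitution polarity against mutational opportunity
#'
#' Pearson chi-squared (no continuity correction) on the 2x2 table contrasting
#' the observed (to-preferred, to-unpreferred) substitution counts with the
#' opportunity counts: ancestral codons currently unpreferred (able to gain a
#' preferred codon) vs currently preferred (able to lose one). Under no
#' directional excess the observed counts are proportional to opportunity and
#' the statistic is 0. `method = "equal"` instead tests the observed counts
#' against a 50:50 goodness-of-fit split.
#'
#' @param s A `branch_substitution_summary` from [polarize_branch()].
#' @param method `"opportunity"` (default) or `"equal"`.
#' @return The summary with `chi2_p` filled (NA when the test is undefined:
#'   zero substitutions or a zero margin).
#' @export
gc_shift_test <- function(s, method = c("opportunity", "equal")) {
  method <- match.arg(method)
  stopifnot(inherits(s, "branch_substitution_summary"))
  if (s$total_synonymous == 0) {
    s$chi2_p <- NA_real_
    return(s)
  }
  if (method == "equal") {
    s$chi2_p <- suppressWarnings(
      stats::chisq.test(c(s$to_preferred, s$to_unpreferred),
                        p = c(0.5, 0.5))$p.value)
    return(s)
  }
  tab <- cbind(observed = c(s$to_preferred, s$to_unpreferred),
               opportunity = c(s$opportunity[["gain"]],
                               s$opportunity[["loss"]]))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    s$chi2_p <- NA_real_
    return(s)
  }
  s$chi2_p <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$p.value)
  s
}

#' Branch polarity report
#'
#' One row per species branch: GC3 of the preferred codon set, to-preferred,
#' to-unpreferred and total synonymous substitution counts, ancestral and
#' current GC at substituted third positions, and the chi-squared p-value.
#'
#' @param branches List of `branch_substitution_summary` objects (the
#'   chi-squared test is run where still missing).
#' @param path Optional TSV output path.
#' @return A data.frame.
#' @export
branch_report <- function(branches, path = NULL) {
  if (inherits(branches, "branch_substitution_summary"))
    branches <- list(branches)
  rows <- lapply(branches, function(b) {
    if (is.na(b$chi2_p) && b$total_synonymous > 0) b <- gc_shift_test(b)
    data.frame(branch = b$branch_label,
               gc3_preferred = b$gc3_preferred,
               to_preferred = b$to_preferred,
               to_unpreferred = b$to_unpreferred,
               total_substitutions = b$total_synonymous,
               gc_ancestral = b$gc_ancestral,
               gc_current = b$gc_current,
               chi2_p = b$chi2_p,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(branch = character(), gc3_preferred = numeric(),
               to_preferred = integer(), to_unpreferred = integer(),
               total_substitutions = integer(), gc_ancestral = numeric(),
               gc_current = numeric(), chi2_p = numeric())
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
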