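# Per-gene and pooled codon-usage statistics: codon counts, RSCU, Wright's
# effective number of codons (ENC), GC and GC3s content, and the frequency of
# optimal codons (FOP).

#' Count sense codons in one gene
#'
#' Codons containing ambiguity characters and stop codons are skipped, so the
#' counts sum to the number of clean, non-stop codons.
#'
#' @param codons Character vector of codons (one gene), or a [gene_set]
#'   element.
#' @param genetic_code NCBI translation table id.
#' @return Named integer vector over the sense codons of the code.
#' @export
count_codons <- function(codons, genetic_code = "1") {
  code <- .code(genetic_code)
  codons <- codons[is_clean_codon(codons)]
  codons <- codons[!codons %in% code$stops]
  tab <- table(factor(codons, levels = code$sense))
  stats::setNames(as.integer(tab), code$sense)
}

#' Codon count matrix for a gene set
#'
#' @param gs A [gene_set].
#' @return Integer matrix, genes x sense codons.
#' @export
codon_count_matrix <- function(gs) {
  code <- .code(gs$genetic_code)
  m <- t(vapply(gs$genes, count_codons, integer(length(code$sense)),
                genetic_code = gs$genetic_code))
  colnames(m) <- code$sense
  m
}

#' Relative synonymous codon usage
#'
#' RSCU of codon i in a family of k synonyms is its count divided by the mean
#' count over the family. Families with zero total are masked (NA), not zero.
#'
#' @param counts Named count vector over sense codons (from [count_codons()]).
#' @param genetic_code NCBI translation table id.
#' @return Named numeric vector of RSCU values for codons of synonymously
#'   variable amino acids; NA where the family is unobserved.
#' @export
rscu <- function(counts, genetic_code = "1") {
  code <- .code(genetic_code)
  out <- rep(NA_real_, length(code$variable))
  names(out) <- code$variable
  for (aa in names(code$families)[code$degeneracy >= 2]) {
    fam <- code$families[[aa]]
    tot <- sum(counts[fam])
    if (tot > 0) out[fam] <- counts[fam] / (tot / length(fam))
  }
  out
}

#' Wright's effective number of codons (ENC)
#'
#' For each amino acid family with at least two counted codons,
#' `F = (n * sum(p^2) - 1) / (n - 1)` where n is the family total and p the
#' within-family frequencies. F is averaged within each fold class and
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, capped at 61. A missing 3-fold
#' class average is interpolated as `(F2 + F4)/2`; any class average <= 0 is
#' treated as missing; a missing 2-, 4- or 6-fold class leaves ENC undefined
#' (NA). The three six-codon amino acids are treated as single 6-fold
#' families (CodonW-compatible).
#'
#' @param counts Named count vector over sense codons.
#' @param genetic_code NCBI translation table id.
#' @return ENC in `[20, 61]`, or NA when undefined.
#' @export
enc <- function(counts, genetic_code = "1") {
  code <- .code(genetic_code)
  fam_aa <- names(code$families)[code$degeneracy >= 2]
  F_hat <- rep(NA_real_, length(fam_aa))
  names(F_hat) <- fam_aa
  for (aa in fam_aa) {
    fam <- code$families[[aa]]
    n <- sum(counts[fam])
    if (n < 2) next
    p <- counts[fam] / n
    F_hat[aa] <- (n * sum(p^2) - 1) / (n - 1)
  }
  class_mean <- function(k) {
    v <- F_hat[code$fold[fam_aa] == k]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    m <- mean(v)
    if (m <= 0) NA_real_ else m
  }
  F2 <- class_mean(2)
  F3 <- class_mean(3)
  F4 <- class_mean(4)
  F6 <- class_mean(6)
  if (is.na(F3) && !is.na(F2) && !is.na(F4)) F3 <- (F2 + F4) / 2
  if (anyNA(c(F2, F3, F4, F6))) return(NA_real_)
  min(61, 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6)
}

#' GC content at synonymously variable third positions (GC3s)
#'
#' Fraction of G or C third-position bases among codons of amino acids with
#' two or more synonymous codons (Met, Trp and stops excluded).
#'
#' @inheritParams rscu
#' @return GC3s in `[0, 1]`, or NA when no synonymous site was counted.
#' @export
gc3s <- function(counts, genetic_code = "1") {
  code <- .code(genetic_code)
  v <- counts[code$variable]
  tot <- sum(v)
  if (tot == 0) return(NA_real_)
  sum(v[is_gc_ending(code$variable)]) / tot
}

#' Overall GC content of counted codons
#'
#' @inheritParams rscu
#' @return Fraction of G/C bases over all three positions of the counted
#'   (sense, unambiguous) codons; NA on empty input.
#' @export
gc_content <- function(counts, genetic_code = "1") {
  code <- .code(genetic_code)
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  gc_per <- vapply(strsplit(code$sense, ""), function(b)
    sum(b %in% c("G", "C")), numeric(1))
  sum(counts[code$sense] * gc_per) / (3 * tot)
}

#' Frequency of optimal codons (FOP)
#'
#' The count of optimal codons divided by the count of all codons belonging
#' to amino acids that have at least one optimal codon (the Ikemura
#' convention, which makes FOP = 1 attainable).
#'
#' @param counts Named count vector over sense codons.
#' @param ocs An [optimal_codon_set].
#' @param genetic_code NCBI translation table id.
#' @return FOP in `[0, 1]`; NA if the optimal set is empty or no eligible
#'   codon was counted.
#' @export
fop <- function(counts, ocs, genetic_code = "1") {
  code <- .code(genetic_code)
  pref <- unlist(ocs$preferred, use.names = FALSE)
  if (!length(pref)) return(NA_real_)
  eligible_aa <- names(ocs$preferred)[lengths(ocs$preferred) > 0]
  eligible <- unlist(code$families[eligible_aa], use.names = FALSE)
  denom <- sum(counts[eligible])
  if (denom == 0) return(NA_real_)
  sum(counts[pref]) / denom
}

#' Per-gene and pooled codon-usage indices
#'
#' One row per gene (ENC, FOP, GC3s, GC, codon count, expression) plus a
#' pooled row computed on the summed counts of the whole set; per-gene means
#' are also reported since it is ambiguous whether "total transcriptome"
#' statistics should be pooled-count or mean-of-genes — both are emitted.
#'
#' @param gs A filtered [gene_set].
#' @param ocs Optional [optimal_codon_set]; FOP is NA without it.
#' @return An object of class `usage_indices`: list with `per_gene`
#'   (data.frame), `pooled` (one-row data.frame on summed counts) and `means`
#'   (named numeric of per-gene column means).
#' @export
aggregate_indices <- function(gs, ocs = NULL) {
  m <- codon_count_matrix(gs)
  tcode <- gs$genetic_code
  one <- function(v) {
    c(n_codons = sum(v),
      enc = enc(v, tcode),
      fop = if (is.null(ocs)) NA_real_ else fop(v, ocs, tcode),
      gc3s = gc3s(v, tcode),
      gc = gc_content(v, tcode))
  }
  per <- t(apply(m, 1, one))
  per_gene <- data.frame(gene_id = rownames(m), per,
                         expression = as.numeric(gs$expression),
                         row.names = NULL, stringsAsFactors = FALSE)
  pooled <- data.frame(species = gs$species, n_genes = nrow(m),
                       t(one(colSums(m))), row.names = NULL)
  means <- colMeans(per_gene[, c("enc", "fop", "gc3s", "gc")], na.rm = TRUE)
  structure(list(per_gene = per_gene, pooled = pooled, means = means),
            class = "usage_indices")
}

#' @export
print.usage_indices <- function(x, ...) {
  cat("usage_indices:", x$pooled$species, "-", x$pooled$n_genes, "genes\n")
  cat(sprintf("  mean ENC %.2f | mean FOP %s | pooled GC3s %.3f | pooled GC %.3f\n",
              x$means["enc"],
              if (is.na(x$means["fop"])) "NA" else sprintf("%.3f", x$means["fop"]),
              x$pooled$gc3s, x$pooled$gc))
  invisible(x)
}

#' Write usage indices as TSV
#'
#' Emits the per-gene table and a one-row species summary table mirroring an
#' appendix-style layout (species, n_genes, mean ENC, mean FOP, GC, GC3s).
#'
#' @param x A `usage_indices` object.
#' @param per_gene_path,summary_path Output paths (NULL to skip either).
#' @return Invisibly, the summary data.frame.
#' @export
write_indices <- function(x, per_gene_path = NULL, summary_path = NULL) {
  if (!is.null(per_gene_path))
    utils::write.table(x$per_gene, per_gene_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  summ <- data.frame(species = x$pooled$species, n_genes = x$pooled$n_genes,
                     mean_enc = x$means[["enc"]], mean_fop = x$means[["fop"]],
                     gc = x$pooled$gc, gc3s = x$pooled$gc3s)
  if (!is.null(summary_path))
    utils::write.table(summ, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(summ)
}
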