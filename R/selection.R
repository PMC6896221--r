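# Population-scaled selection on codon usage under mutation-selection-drift
# equilibrium. With preferred codon C1 and unpreferred codon C2, mutation
# rates u (C1->C2) and v (C2->C1), and fitness difference s, the stationary
# frequency of the preferred codon is P = e^S / (e^S + k) with S = 2*Ne*s and
# k = u/v. Only the ratio k ever enters a computation; s and Ne are never
# separated.

#' Equilibrium frequency of the preferred codon
#'
#' @param S Population-scaled selection coefficient (2*Ne*s).
#' @param k Mutation bias ratio u/v (preferred->unpreferred over reverse).
#' @return P = exp(S) / (exp(S) + k), in (0, 1).
#' @export
equilibrium_P <- function(S, k) {
  stopifnot(all(k > 0))
  exp(S) / (exp(S) + k)
}

#' Estimate S from an observed preferred-codon frequency
#'
#' Exact inverse of [equilibrium_P()]: `S = log(P * k / (1 - P))`. Negative
#' when P is below the neutral expectation 1/(1+k).
#'
#' @param P Observed frequency of preferred codons, strictly in (0, 1).
#' @param k Mutation bias ratio u/v.
#' @return The population-scaled selection coefficient S.
#' @export
estimate_S <- function(P, k) {
  stopifnot(all(k > 0))
  if (any(P <= 0) || any(P >= 1))
    stop("P must be strictly between 0 and 1 (S is infinite at the bounds)")
  log(P * k / (1 - P))
}

#' Construct a mutation spectrum from measured rates
#'
#' @param u Mutation rate preferred -> unpreferred (relative units).
#' @param v Mutation rate unpreferred -> preferred.
#' @param source Provenance label.
#' @return An object of class `mutation_spectrum` with `k = u/v`.
#' @export
mutation_spectrum <- function(u, v, source = "measured") {
  stopifnot(u > 0, v > 0)
  structure(list(u = u, v = v, k = u / v, source = source),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat(sprintf("mutation_spectrum: u = %g, v = %g, k = %.4f (%s)\n",
              x$u, x$v, x$k, x$source))
  invisible(x)
}

# per-gene optimal and total synonymous codon counts over an amino-acid subset
optimal_count_matrix <- function(gs, ocs, aa_subset) {
  code <- .code(gs$genetic_code)
  counts <- codon_count_matrix(gs)
  aa_subset <- intersect(aa_subset, names(ocs$preferred))
  if (!length(aa_subset)) stop("empty amino-acid subset")
  pref <- unlist(ocs$preferred[aa_subset], use.names = FALSE)
  all_syn <- unlist(code$families[aa_subset], use.names = FALSE)
  cbind(opt = rowSums(counts[, pref, drop = FALSE]),
        tot = rowSums(counts[, all_syn, drop = FALSE]))
}

#' Pooled frequency of optimal codons for the S estimator
#'
#' P is pooled across amino acids (total optimal counts over total synonymous
#' counts), the variance-minimizing treatment.
#'
#' @param gs A [gene_set].
#' @param ocs An [optimal_codon_set].
#' @param aa_subset Amino acids to include (default: all with a preferred
#'   codon).
#' @return List with `P`, per-amino-acid counts and totals.
#' @export
pooled_P <- function(gs, ocs, aa_subset = names(ocs$preferred)) {
  oc <- optimal_count_matrix(gs, ocs, aa_subset)
  tot <- sum(oc[, "tot"])
  if (tot == 0) stop("no synonymous codons counted in the amino-acid subset")
  list(P = sum(oc[, "opt"]) / tot, n_optimal = sum(oc[, "opt"]),
       n_total = tot, aa_subset = aa_subset)
}

#' Infer the mutation bias ratio k from weakly expressed genes
#'
#' Assuming selection on codon usage is negligible in weakly expressed genes,
#' the neutral equilibrium reduces to P = v/(v+u), so `k = (1 - P)/P` with P
#' the pooled optimal-codon frequency in the low-expression set.
#'
#' @param low [gene_set] of weakly expressed genes.
#' @param ocs An [optimal_codon_set].
#' @param aa_subset Amino acids to pool over.
#' @return A [mutation_spectrum] with `source = "inferred-from-low-expression"`.
#' @export
estimate_k_from_low_expression <- function(low, ocs,
                                           aa_subset = names(ocs$preferred)) {
  P <- pooled_P(low, ocs, aa_subset)$P
  if (P <= 0 || P >= 1)
    stop("pooled P in low-expression genes is ", P,
         "; k is undefined at the bounds")
  mutation_spectrum(u = (1 - P) / P, v = 1,
                    source = "inferred-from-low-expression")
}

#' Default amino-acid subset for the two-state S model
#'
#' Two-fold degenerate amino acids with exactly one preferred codon: the
#' model contrasts one preferred with one unpreferred codon, so two-codon
#' families fit it exactly.
#'
#' @param ocs An [optimal_codon_set].
#' @return Character vector of amino acids.
#' @export
twofold_subset <- function(ocs) {
  code <- .code(ocs$genetic_code)
  aa <- names(ocs$preferred)[lengths(ocs$preferred) == 1]
  aa[code$degeneracy[aa] == 2]
}

#' Estimate the strength of selection for optimal codons
#'
#' Computes the population-scaled selection coefficient S for the `n` most
#' highly expressed genes from the pooled optimal-codon frequency P and the
#' mutation bias k, and tests its significance by comparing against S
#' computed on `reps` random sets of `n` genes drawn without replacement from
#' the whole filtered set. k comes from a measured [mutation_spectrum] when
#' supplied, otherwise it is inferred from the `n` least expressed genes.
#'
#' @param gs A filtered [gene_set] carrying expression values, with at least
#'   `2 * n` genes.
#' @param ocs An [optimal_codon_set].
#' @param spectrum Optional measured [mutation_spectrum]; when NULL, k is
#'   inferred from the low-expression genes.
#' @param n Size of the high/low expression sets (default 500).
#' @param reps Number of random gene sets for the null distribution (default
#'   1000; 0 skips the resampling test).
#' @param seed Optional integer seed for the resampling draws.
#' @param aa_subset Amino acids to pool over; default [twofold_subset()].
#' @param exclude_extremes Drop the top-n genes from the null-resampling pool
#'   (default FALSE: the null samples from all filtered genes).
#' @return An object of class `cub_selection`: S, P, k, the resampling
#'   p-value (upper tail, `(1 + #{null >= S}) / (1 + reps)`), a significance
#'   mark (`***` p < 0.01, `*` p < 0.05, `ns` otherwise), the null S values
#'   and bookkeeping fields.
#' @export
selection_analysis <- function(gs, ocs, spectrum = NULL, n = 500,
                               reps = 1000, seed = NULL, aa_subset = NULL,
                               exclude_extremes = FALSE) {
  if (anyNA(gs$expression)) stop("all genes must carry expression values")
  if (length(gs) < 2 * n)
    stop("need at least 2*n = ", 2 * n, " genes; have ", length(gs))
  if (is.null(aa_subset)) aa_subset <- twofold_subset(ocs)
  if (!length(aa_subset)) stop("amino-acid subset is empty")
  ext <- expression_extremes(gs, n = n)
  if (is.null(spectrum))
    spectrum <- estimate_k_from_low_expression(ext$low, ocs, aa_subset)
  k <- spectrum$k
  ph <- pooled_P(ext$high, ocs, aa_subset)
  S_obs <- estimate_S(ph$P, k)

  null_S <- numeric(0)
  p_value <- NA_real_
  if (reps > 0) {
    if (!is.null(seed)) set.seed(seed)
    oc <- optimal_count_matrix(gs, ocs, aa_subset)
    pool <- seq_len(nrow(oc))
    if (exclude_extremes) {
      high_ids <- names(ext$high$genes)
      pool <- pool[!rownames(oc) %in% high_ids]
    }
    null_S <- vapply(seq_len(reps), function(i) {
      idx <- sample(pool, n)
      P <- sum(oc[idx, "opt"]) / sum(oc[idx, "tot"])
      if (P <= 0 || P >= 1) return(NA_real_)
      estimate_S(P, k)
    }, numeric(1))
    ok <- !is.na(null_S)
    p_value <- (1 + sum(null_S[ok] >= S_obs)) / (1 + sum(ok))
  }
  signif <- if (is.na(p_value)) NA_character_
            else if (p_value < 0.01) "***"
            else if (p_value < 0.05) "*" else "ns"
  structure(
    list(S = S_obs, P = ph$P, k = k, spectrum = spectrum,
         p_value = p_value, signif = signif, null_S = null_S,
         n = n, reps = reps, seed = seed, aa_subset = aa_subset,
         n_genes = length(gs), n_codon_observations = ph$n_total,
         species = gs$species, call = match.call()),
    class = "cub_selection"
  )
}

#' @export
print.cub_selection <- function(x, digits = 4, ...) {
  cat("Selection on codon usage (mutation-selection-drift equilibrium)\n")
  cat(sprintf("  species: %s (%d genes; top/bottom %d by expression)\n",
              x$species, x$n_genes, x$n))
  cat(sprintf("  P = %.*f  k = %.*f (%s)  S = %.*f\n",
              digits, x$P, digits, x$k, x$spectrum$source, digits, x$S))
  if (!is.na(x$p_value))
    cat(sprintf("  resampling p = %.4g (%d sets of %d genes)  %s\n",
                x$p_value, x$reps, x$n, x$signif))
  invisible(x)
}

#' @export
summary.cub_selection <- function(object, ...) {
  out <- data.frame(
    species = object$species, S = object$S, P = object$P, k = object$k,
    k_source = object$spectrum$source, p_value = object$p_value,
    signif = object$signif, n_genes = object$n_genes,
    n_codon_observations = object$n_codon_observations,
    stringsAsFactors = FALSE
  )
  if (length(object$null_S)) {
    out$null_mean <- mean(object$null_S, na.rm = TRUE)
    out$null_sd <- stats::sd(object$null_S, na.rm = TRUE)
  }
  class(out) <- c("summary.cub_selection", "data.frame")
  out
}

#' @export
coef.cub_selection <- function(object, ...) {
  c(P = object$P, k = object$k, S = object$S)
}

#' Amino acids with a stable preferred codon across species
#'
#' Returns the two-fold degenerate amino acids whose single preferred codon
#' is identical in every supplied species, the subset suited to cross-species
#' S comparisons when preferred-codon sets have shifted within a clade.
#'
#' @param ocs_list List of [optimal_codon_set] objects (>= 2 species).
#' @return Character vector of amino acids; empty (with a warning) when no
#'   family is stable.
#' @export
restrict_to_stable_codons <- function(ocs_list) {
  stopifnot(length(ocs_list) >= 2)
  subsets <- lapply(ocs_list, twofold_subset)
  shared <- Reduce(intersect, subsets)
  stable <- shared[vapply(shared, function(aa) {
    prefs <- vapply(ocs_list, function(o) o$preferred[[aa]], character(1))
    length(unique(prefs)) == 1
  }, logical(1))]
  if (!length(stable))
    warning("no amino acid has a stable preferred codon across all species")
  stable
}

#' Write a selection summary table
#'
#' One row per species: strain, S, significance mark (Table-1 style layout).
#'
#' @param fits List of `cub_selection` objects (or a single one).
#' @param path Output TSV path.
#' @return The data.frame, invisibly.
#' @export
write_selection_table <- function(fits, path) {
  if (inherits(fits, "cub_selection")) fits <- list(fits)
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(species = f$species, S = f$S, signif = f$signif,
               p_value = f$p_value, k = f$k, P = f$P,
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
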