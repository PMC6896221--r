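# Pairwise synonymous divergence (Nei-Gojobori 1986 with Jukes-Cantor
# correction), silent-site diversity, and the neutral-theory calculators
# Ne = pi/(4*mu) and t = dS/(2*mu).
#
# NG86 conventions used here (and documented in the vignette): synonymous
# site fractions exclude changes that generate stop codons from the
# per-position denominator; differences in multi-hit codons are averaged
# with equal weight over all mutational pathways that do not pass through a
# stop codon; codon pairs whose pathways are all blocked by stops are
# excluded from both site and difference totals.

# per-codon synonymous site count (sum over the 3 positions of the fraction
# of non-stop single-nucleotide changes that are synonymous)
syn_sites_codon <- function(codon, code) {
  aa <- code$code[[codon]]
  s <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    syn <- 0L
    valid <- 0L
    for (nt in setdiff(NT, base)) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      alt_aa <- code$code[[alt]]
      if (alt_aa == "*") next
      valid <- valid + 1L
      if (alt_aa == aa) syn <- syn + 1L
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

# all permutations of a small integer vector
.perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# pathway-averaged (synonymous, nonsynonymous) difference counts between two
# codons; NA when every pathway passes through a stop codon
syn_diffs_pair <- function(a, b, code) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  paths <- .perms(pos)
  sd_tot <- 0
  nd_tot <- 0
  n_ok <- 0L
  for (p in paths) {
    cur <- a
    sd <- 0L
    nd <- 0L
    blocked <- FALSE
    for (j in p) {
      nxt <- cur
      substr(nxt, j, j) <- substr(b, j, j)
      if (code$code[[nxt]] == "*") { blocked <- TRUE; break }
      if (code$code[[nxt]] == code$code[[cur]]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    if (!blocked) {
      sd_tot <- sd_tot + sd
      nd_tot <- nd_tot + nd
      n_ok <- n_ok + 1L
    }
  }
  if (n_ok == 0L) return(c(syn = NA_real_, nonsyn = NA_real_))
  c(syn = sd_tot / n_ok, nonsyn = nd_tot / n_ok)
}

# lazily built lookup tables for the standard code
.ng_cache <- new.env(parent = emptyenv())

.ng_sites <- function(code) {
  key <- paste0("sites", code$table)
  if (is.null(.ng_cache[[key]])) {
    v <- vapply(code$sense, syn_sites_codon, numeric(1), code = code)
    .ng_cache[[key]] <- v
  }
  .ng_cache[[key]]
}

#' Construct an aligned codon pair
#'
#' Columns containing gaps, ambiguity characters or stop codons in either
#' sequence are dropped pairwise before analysis.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings (length a multiple of
#'   3) or codon character vectors.
#' @param label_a,label_b Sequence labels.
#' @param genetic_code NCBI translation table id.
#' @return An object of class `aligned_codon_pair` with codon vectors `a`
#'   and `b` and the number of dropped columns.
#' @export
aligned_codon_pair <- function(seq_a, seq_b, label_a = "a", label_b = "b",
                               genetic_code = "1") {
  to_codons <- function(s) {
    if (length(s) == 1 && nchar(s[1]) > 3) s <- split_codons(toupper(s))
    toupper(s)
  }
  a <- to_codons(seq_a)
  b <- to_codons(seq_b)
  if (length(a) != length(b))
    stop("sequences differ in codon count (", length(a), " vs ", length(b), ")")
  code <- .code(genetic_code)
  ok <- is_clean_codon(a) & is_clean_codon(b) &
    !(a %in% code$stops) & !(b %in% code$stops)
  structure(
    list(a = a[ok], b = b[ok], label_a = label_a, label_b = label_b,
         n_dropped = sum(!ok), genetic_code = genetic_code),
    class = "aligned_codon_pair"
  )
}

#' Nei-Gojobori synonymous divergence
#'
#' Synonymous site counts are averaged over the two sequences; pathway-
#' averaged synonymous differences are summed over codon columns;
#' `pS = diffs/sites` is Jukes-Cantor corrected to
#' `dS = -(3/4) * log(1 - (4/3) * pS)`.
#'
#' @param pair An [aligned_codon_pair] (or two sequences, coerced via
#'   [aligned_codon_pair()]).
#' @param seq_b,label_a,label_b Passed to [aligned_codon_pair()] when `pair`
#'   is a bare sequence.
#' @param mu Optional mutation rate per site per generation; when supplied,
#'   divergence times are attached via [time_from_ds()].
#' @param generations_per_year Used with `mu` for the year conversion.
#' @return Object of class `divergence_estimate`: `ds`, `ps`, `syn_sites`,
#'   `syn_diffs`, `n_codons`, `n_excluded` (stop-blocked columns), labels,
#'   and `t_generations`/`t_years` when `mu` is given.
#' @export
ng86_ds <- function(pair, seq_b = NULL, label_a = "a", label_b = "b",
                    mu = NULL, generations_per_year = 100) {
  if (!inherits(pair, "aligned_codon_pair"))
    pair <- aligned_codon_pair(pair, seq_b, label_a, label_b)
  code <- .code(pair$genetic_code)
  if (!length(pair$a)) stop("no analysable codon columns")
  sites_tab <- .ng_sites(code)
  sa <- sites_tab[pair$a]
  sb <- sites_tab[pair$b]
  diff_idx <- which(pair$a != pair$b)
  sd <- 0
  excluded <- 0L
  for (i in diff_idx) {
    d <- syn_diffs_pair(pair$a[i], pair$b[i], code)
    if (is.na(d["syn"])) {
      excluded <- excluded + 1L
      sa[i] <- 0
      sb[i] <- 0
      next
    }
    sd <- sd + d[["syn"]]
  }
  ss <- (sum(sa) + sum(sb)) / 2
  if (ss <= 0) stop("zero synonymous sites; dS undefined")
  ps <- sd / ss
  if (ps >= 3 / 4)
    stop("pS = ", round(ps, 3), " >= 3/4: synonymous sites saturated, ",
         "Jukes-Cantor correction undefined")
  ds <- -0.75 * log(1 - 4 * ps / 3)
  out <- structure(
    list(ds = ds, ps = ps, syn_sites = ss, syn_diffs = sd,
         n_codons = length(pair$a), n_excluded = excluded,
         label_a = pair$label_a, label_b = pair$label_b),
    class = "divergence_estimate"
  )
  if (!is.null(mu)) {
    tt <- time_from_ds(ds, mu, generations_per_year)
    out$t_generations <- tt$t_generations
    out$t_years <- tt$t_years
  }
  out
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("dS(%s, %s) = %.4f  (pS = %.4f; %.1f syn sites, %.2f syn diffs)\n",
              x$label_a, x$label_b, x$ds, x$ps, x$syn_sites, x$syn_diffs))
  if (!is.null(x$t_generations))
    cat(sprintf("  t = %.3g generations = %.3g years\n",
                x$t_generations, x$t_years))
  invisible(x)
}

#' Silent-site nucleotide diversity
#'
#' Average over all unordered sequence pairs of the uncorrected proportion of
#' synonymous differences per synonymous site (NG86 counting). Left
#' uncorrected for multiple hits: pi is an intra-species quantity where
#' distances are small.
#'
#' @param seqs Named list of aligned codon vectors (or nucleotide strings),
#'   at least two.
#' @param mu Optional mutation rate; when supplied, `Ne = pi/(4*mu)` is
#'   attached.
#' @param genetic_code NCBI translation table id.
#' @return Object of class `diversity_estimate`: `pi_silent`,
#'   `n_sequences`, per-pair values, and `Ne` when `mu` is given.
#' @export
silent_pi <- function(seqs, mu = NULL, genetic_code = "1") {
  stopifnot(length(seqs) >= 2)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ids <- names(seqs)
  pairs <- utils::combn(length(seqs), 2)
  pvals <- apply(pairs, 2, function(ij) {
    p <- aligned_codon_pair(seqs[[ij[1]]], seqs[[ij[2]]],
                            ids[ij[1]], ids[ij[2]], genetic_code)
    code <- .code(genetic_code)
    sites_tab <- .ng_sites(code)
    sa <- sites_tab[p$a]
    sb <- sites_tab[p$b]
    sd <- 0
    for (i in which(p$a != p$b)) {
      d <- syn_diffs_pair(p$a[i], p$b[i], code)
      if (is.na(d["syn"])) { sa[i] <- 0; sb[i] <- 0; next }
      sd <- sd + d[["syn"]]
    }
    ss <- (sum(sa) + sum(sb)) / 2
    if (ss <= 0) return(NA_real_)
    sd / ss
  })
  pi_s <- mean(pvals, na.rm = TRUE)
  out <- structure(
    list(pi_silent = pi_s, n_sequences = length(seqs),
         pairwise = data.frame(a = ids[pairs[1, ]], b = ids[pairs[2, ]],
                               ps = pvals, stringsAsFactors = FALSE)),
    class = "diversity_estimate"
  )
  if (!is.null(mu)) out$Ne <- ne_from_pi(pi_s, mu)
  out
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("silent-site pi = %.4g over %d sequences\n",
              x$pi_silent, x$n_sequences))
  if (!is.null(x$Ne)) cat(sprintf("  Ne = %.3g\n", x$Ne))
  invisible(x)
}

#' Effective population size from silent-site diversity
#'
#' Neutral equilibrium expectation `pi = 4*Ne*mu`, inverted.
#'
#' @param pi Silent-site nucleotide diversity (>= 0).
#' @param mu Mutation rate per site per generation (> 0); the default is the
#'   directly measured rate for *Phaeodactylum tricornutum*, 4.77e-10.
#' @return Ne = pi / (4 * mu).
#' @export
ne_from_pi <- function(pi, mu = 4.77e-10) {
  stopifnot(mu > 0, all(pi >= 0))
  pi / (4 * mu)
}

#' Divergence time from synonymous divergence
#'
#' `dS = 2 * t * mu` inverted to `t = dS/(2*mu)` generations, converted to
#' years with a generations-per-year assumption (default 100, a plausible
#' rate for wild diatom populations).
#'
#' @param ds Synonymous substitutions per synonymous site (>= 0).
#' @param mu Mutation rate per site per generation (default 4.77e-10).
#' @param generations_per_year Generations per year (default 100).
#' @return List with `t_generations` and `t_years`.
#' @export
time_from_ds <- function(ds, mu = 4.77e-10, generations_per_year = 100) {
  stopifnot(mu > 0, all(ds >= 0), generations_per_year > 0)
  t_gen <- ds / (2 * mu)
  list(t_generations = t_gen, t_years = t_gen / generations_per_year)
}

#' Read an aligned codon FASTA
#'
#' @param path FASTA of equal-length aligned nucleotide sequences.
#' @return Named list of codon character vectors (gap columns retained;
#'   downstream constructors drop them pairwise).
#' @export
read_codon_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(seqs))
  if (length(unique(nchar(seqs))) != 1)
    stop("aligned sequences must have equal length")
  if (nchar(seqs[1]) %% 3 != 0)
    stop("alignment length must be a multiple of 3")
  out <- lapply(seqs, split_codons)
  names(out) <- ids
  out
}

#' Pairwise dS matrix for a multiple codon alignment
#'
#' @param seqs Named list of aligned codon vectors.
#' @param genetic_code NCBI translation table id.
#' @return Symmetric numeric matrix of NG86 dS values (0 diagonal).
#' @export
ds_matrix <- function(seqs, genetic_code = "1") {
  ids <- names(seqs)
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- aligned_codon_pair(seqs[[i]], seqs[[j]], ids[i], ids[j],
                            genetic_code)
    m[i, j] <- m[j, i] <- ng86_ds(p)$ds
  }
  m
}
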