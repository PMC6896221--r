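# Data-driven identification of preferred/unpreferred codons:
# correspondence analysis of the gene x codon RSCU matrix, extreme-group
# contrast, and per-codon 2x2 chi-squared contingency tests.

#' Correspondence analysis of a codon usage matrix
#'
#' Standard chi-square-distance CA (row-profile decomposition via SVD of the
#' matrix of standardized residuals). Axis 1 can be oriented so that a larger
#' gene coordinate means stronger codon bias by supplying a per-gene bias
#' covariate (typically ENC, which decreases with bias): the axis is flipped
#' so that it correlates negatively with `orient_by`. Without a covariate the
#' sign is fixed by requiring the largest-magnitude axis-1 column loading to
#' be positive, which makes the result deterministic.
#'
#' @param m Non-negative numeric matrix, genes x codons (RSCU or counts).
#'   NA entries (masked zero-total families) are treated as 0.
#' @param orient_by Optional numeric vector (one value per row of `m`) that
#'   decreases with codon bias, e.g. per-gene ENC.
#' @return An object of class `ca_result`: list with `row_coords` and
#'   `col_coords` (principal coordinates), `inertia` (per-axis, descending),
#'   `flipped` (was axis 1 negated), `rows` and `cols` (labels kept).
#' @export
correspondence_analysis <- function(m, orient_by = NULL) {
  m <- as.matrix(m)
  m[is.na(m)] <- 0
  if (any(m < 0)) stop("matrix must be non-negative")
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (!is.null(orient_by)) orient_by <- orient_by[keep_r]
  m <- m[keep_r, keep_c, drop = FALSE]
  if (nrow(m) < 3 || ncol(m) < 2)
    stop("need at least 3 genes and 2 codon columns with usage")
  P <- m / sum(m)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  pos <- sv$d > max(sv$d) * 1e-10
  n_ax <- max(1L, sum(pos))
  d <- sv$d[seq_len(n_ax)]
  row_coords <- sweep(sv$u[, seq_len(n_ax), drop = FALSE] %*% diag(d, n_ax),
                      1, sqrt(r), "/")
  col_coords <- sweep(sv$v[, seq_len(n_ax), drop = FALSE] %*% diag(d, n_ax),
                      1, sqrt(cc), "/")
  flipped <- FALSE
  if (d[1] > 0) {
    if (!is.null(orient_by)) {
      ok <- stats::complete.cases(row_coords[, 1], orient_by)
      if (sum(ok) > 2 && stats::sd(row_coords[ok, 1]) > 0 &&
          stats::sd(orient_by[ok]) > 0) {
        flipped <- stats::cor(row_coords[ok, 1], orient_by[ok]) > 0
      }
    } else {
      flipped <- col_coords[which.max(abs(col_coords[, 1])), 1] < 0
    }
  }
  if (flipped) {
    row_coords[, 1] <- -row_coords[, 1]
    col_coords[, 1] <- -col_coords[, 1]
  }
  rownames(row_coords) <- rownames(m)
  rownames(col_coords) <- colnames(m)
  structure(
    list(row_coords = row_coords, col_coords = col_coords,
         inertia = d^2, flipped = flipped,
         rows = rownames(m), cols = colnames(m)),
    class = "ca_result"
  )
}

#' @export
print.ca_result <- function(x, ...) {
  cat("ca_result:", length(x$rows), "genes x", length(x$cols), "codons;",
      length(x$inertia), "axes\n")
  cat("  axis-1 inertia share:",
      sprintf("%.1f%%", 100 * x$inertia[1] / sum(x$inertia)), "\n")
  invisible(x)
}

#' Construct an optimal codon set
#'
#' @param preferred,unpreferred Named lists (amino acid -> codon vector).
#' @param alpha Significance level used to flag codons.
#' @param extremes_fraction Fraction of genes per extreme group.
#' @param flags Optional per-codon data.frame of test results.
#' @param genetic_code NCBI translation table id.
#' @return An object of class `optimal_codon_set` with `gc3_preferred` (GC
#'   fraction at third positions of the preferred codons) and `gc_class`
#'   filled in.
#' @export
optimal_codon_set <- function(preferred, unpreferred = list(), alpha = NA,
                              extremes_fraction = NA, flags = NULL,
                              genetic_code = "1") {
  preferred <- preferred[lengths(preferred) > 0]
  unpreferred <- unpreferred[lengths(unpreferred) > 0]
  both <- intersect(unlist(preferred), unlist(unpreferred))
  if (length(both))
    stop("codon(s) flagged both preferred and unpreferred: ",
         paste(both, collapse = ", "))
  pref <- unlist(preferred, use.names = FALSE)
  gc3p <- if (length(pref)) mean(is_gc_ending(pref)) else NA_real_
  ocs <- structure(
    list(preferred = preferred, unpreferred = unpreferred,
         gc3_preferred = gc3p, gc_class = NA_character_,
         alpha = alpha, extremes_fraction = extremes_fraction,
         flags = flags, genetic_code = genetic_code),
    class = "optimal_codon_set"
  )
  ocs$gc_class <- classify_preferred_gc(ocs)
  ocs
}

#' @export
print.optimal_codon_set <- function(x, ...) {
  cat("optimal_codon_set:", length(x$preferred), "amino acids with a",
      "preferred codon\n")
  if (length(x$preferred)) {
    cat(sprintf("  GC3 of preferred codons: %.2f (%s)\n",
                x$gc3_preferred, x$gc_class))
  }
  invisible(x)
}

#' Identify preferred and unpreferred codons
#'
#' Genes are ordered along axis 1 of a correspondence analysis of their RSCU
#' (or raw count) matrix, oriented so that high coordinates mean strong bias.
#' The top and bottom `extremes_fraction` of genes form the high- and
#' low-bias groups. For every codon of a synonymously variable amino acid, a
#' 2x2 contingency table {high-bias, low-bias} x {this codon, other synonyms}
#' is tested with Pearson's chi-squared (no continuity correction). A codon
#' is flagged preferred when p < alpha and its within-family relative usage
#' is higher in the high-bias group, unpreferred when significantly lower.
#'
#' @param gs A filtered [gene_set] (at least 40 genes).
#' @param extremes_fraction Fraction of genes per extreme group (default 0.05).
#' @param alpha Per-codon significance level (default 0.01, uncorrected).
#' @param use_rscu Run the CA on RSCU values (default) or raw counts.
#' @param correction `"none"` (default) or `"bonferroni"` across tested codons.
#' @return An [optimal_codon_set]; its `flags` element records per-codon
#'   p-values, group usage and the skipped codons (family absent from an
#'   extreme group). The `ca` attribute carries the [correspondence_analysis]
#'   result.
#' @export
identify_optimal_codons <- function(gs, extremes_fraction = 0.05,
                                    alpha = 0.01, use_rscu = TRUE,
                                    correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (length(gs) < 40)
    stop("need at least 40 genes for meaningful extreme groups")
  code <- .code(gs$genetic_code)
  counts <- codon_count_matrix(gs)
  enc_gene <- apply(counts, 1, enc, genetic_code = gs$genetic_code)
  m <- if (use_rscu) {
    t(apply(counts, 1, rscu, genetic_code = gs$genetic_code))
  } else {
    counts[, code$variable, drop = FALSE]
  }
  ca <- correspondence_analysis(m, orient_by = enc_gene)
  ax1 <- ca$row_coords[, 1]
  ord <- order(ax1, names(ax1), method = "radix")  # low to high bias
  n_ext <- max(1L, round(extremes_fraction * length(ord)))
  low_ids <- names(ax1)[ord[seq_len(n_ext)]]
  high_ids <- names(ax1)[rev(ord)[seq_len(n_ext)]]
  high_tot <- colSums(counts[high_ids, , drop = FALSE])
  low_tot <- colSums(counts[low_ids, , drop = FALSE])

  rows <- list()
  for (aa in names(code$families)[code$degeneracy >= 2]) {
    fam <- code$families[[aa]]
    fh <- sum(high_tot[fam])
    fl <- sum(low_tot[fam])
    for (cod in fam) {
      if (fh == 0 || fl == 0) {
        rows[[cod]] <- data.frame(codon = cod, aa = aa, p = NA_real_,
                                  rel_high = NA_real_, rel_low = NA_real_,
                                  status = "skipped")
        next
      }
      tab <- rbind(high = c(high_tot[cod], fh - high_tot[cod]),
                   low = c(low_tot[cod], fl - low_tot[cod]))
      p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        NA_real_
      } else {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      }
      rows[[cod]] <- data.frame(codon = cod, aa = aa, p = p,
                                rel_high = high_tot[cod] / fh,
                                rel_low = low_tot[cod] / fl,
                                status = "tested")
    }
  }
  flags <- do.call(rbind, rows)
  rownames(flags) <- NULL
  tested <- flags$status == "tested" & !is.na(flags$p)
  p_adj <- flags$p
  if (correction == "bonferroni")
    p_adj[tested] <- pmin(1, flags$p[tested] * sum(tested))
  flags$p_adj <- p_adj
  sig <- tested & p_adj < alpha
  flags$status[sig & flags$rel_high > flags$rel_low] <- "preferred"
  flags$status[sig & flags$rel_high < flags$rel_low] <- "unpreferred"

  pick <- function(st) {
    f <- flags[flags$status == st, ]
    split(f$codon, f$aa)
  }
  ocs <- optimal_codon_set(pick("preferred"), pick("unpreferred"),
                           alpha = alpha,
                           extremes_fraction = extremes_fraction,
                           flags = flags, genetic_code = gs$genetic_code)
  attr(ocs, "ca") <- ca
  attr(ocs, "groups") <- list(high = high_ids, low = low_ids)
  ocs
}

#' Classify the GC content of a preferred codon set
#'
#' Bands: GC3 of preferred codons below 0.40 is `AT-rich`, 0.40 to 0.75 is
#' `moderate-GC`, above 0.75 is `GC-rich`. The band edges are midpoints of
#' the empirical gaps between the observed groups of diatom strains
#' (29--46% and 72--79%).
#'
#' @param ocs An [optimal_codon_set], or a bare GC3 fraction in `[0, 1]`.
#' @return `"AT-rich"`, `"moderate-GC"`, `"GC-rich"`, or NA for an empty set.
#' @export
classify_preferred_gc <- function(ocs) {
  x <- if (inherits(ocs, "optimal_codon_set")) ocs$gc3_preferred else ocs
  if (is.na(x)) return(NA_character_)
  stopifnot(x >= 0, x <= 1)
  if (x < 0.40) "AT-rich" else if (x <= 0.75) "moderate-GC" else "GC-rich"
}

#' Serialize an optimal codon set to JSON
#'
#' @param ocs An [optimal_codon_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ocs_json <- function(ocs, path) {
  jsonlite::write_json(
    list(preferred = ocs$preferred, unpreferred = ocs$unpreferred,
         gc3_preferred = ocs$gc3_preferred, gc_class = ocs$gc_class,
         alpha = ocs$alpha, extremes_fraction = ocs$extremes_fraction),
    path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read an optimal codon set from JSON
#'
#' @param path Path written by [write_ocs_json()].
#' @param genetic_code NCBI translation table id.
#' @return An [optimal_codon_set].
#' @export
read_ocs_json <- function(path, genetic_code = "1") {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_list <- function(v) if (is.null(v)) list() else as.list(as.data.frame(v, stringsAsFactors = FALSE))
  pref <- lapply(x$preferred, as.character)
  unpref <- lapply(x$unpreferred, as.character)
  optimal_codon_set(pref, unpref, alpha = x$alpha %||% NA,
                    extremes_fraction = x$extremes_fraction %||% NA,
                    genetic_code = genetic_code)
}

#' Write a 64-entry codon flag table
#'
#' A plain-text interoperability table with one row per codon: codon, amino
#' acid (one-letter, `*` for stops), and flag (`preferred`, `unpreferred`,
#' `none`, or `stop`).
#'
#' @param ocs An [optimal_codon_set].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ocs_table <- function(ocs, path) {
  code <- .code(ocs$genetic_code)
  all_codons <- names(code$code)
  flag <- rep("none", length(all_codons))
  names(flag) <- all_codons
  flag[code$stops] <- "stop"
  flag[unlist(ocs$preferred, use.names = FALSE)] <- "preferred"
  flag[unlist(ocs$unpreferred, use.names = FALSE)] <- "unpreferred"
  df <- data.frame(codon = all_codons, aa = unname(code$code[all_codons]),
                   flag = unname(flag))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
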