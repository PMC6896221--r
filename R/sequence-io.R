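# Reading, filtering and stratifying coding-sequence sets.
#
# A gene_set holds one species' in-frame CDS collection: a named list of codon
# vectors, an aligned expression vector (FPKM; NA when unknown) and a log of
# how many records each filter removed.

#' Construct a gene set
#'
#' @param genes Named list of character vectors of codons (uppercase 3-mers).
#' @param species Species or strain label.
#' @param expression Optional named numeric vector of expression values
#'   (FPKM); matched to `genes` by name, NA where absent.
#' @param filter_log Named integer vector of per-rule removal counts.
#' @param genetic_code NCBI translation table id.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(genes, species = "unnamed", expression = NULL,
                     filter_log = integer(), genetic_code = "1") {
  stopifnot(is.list(genes))
  ids <- names(genes)
  if (length(genes) && (is.null(ids) || anyNA(ids) || any(ids == "")))
    stop("all genes must be named")
  if (anyDuplicated(ids)) stop("gene ids must be unique within a set")
  expr <- rep(NA_real_, length(genes))
  names(expr) <- ids
  if (!is.null(expression)) {
    hit <- intersect(names(expression), ids)
    expr[hit] <- as.numeric(expression[hit])
  }
  structure(
    list(species = species, genes = genes, expression = expr,
         filter_log = filter_log, genetic_code = genetic_code),
    class = "gene_set"
  )
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", x$species, "-", length(x$genes), "genes\n")
  n_expr <- sum(!is.na(x$expression))
  cat("  expression values:", n_expr, "of", length(x$genes), "\n")
  if (length(x$filter_log)) {
    cat("  filtered:",
        paste(names(x$filter_log), x$filter_log, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
`[.gene_set` <- function(x, i) {
  gene_set(x$genes[i], species = x$species,
           expression = x$expression[i], filter_log = x$filter_log,
           genetic_code = x$genetic_code)
}

#' Read coding sequences from a FASTA file
#'
#' Parses case-insensitively; each record becomes one gene. Records whose
#' length is not a multiple of 3 are excluded and logged under `"frame"`.
#' Codons containing ambiguity characters are retained in the codon list and
#' skipped later by the counting functions.
#'
#' @param path Path to a (possibly multi-record) nucleotide FASTA file.
#' @param species Label for the set; defaults to the file name.
#' @param genetic_code NCBI translation table id.
#' @return A [gene_set].
#' @export
read_cds_fasta <- function(path, species = NULL, genetic_code = "1") {
  stopifnot(file.exists(path))
  if (is.null(species))
    species <- sub("\\.(fa|fasta|fna)$", "", basename(path), ignore.case = TRUE)
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(seqs))
  seqs <- chartr("U", "T", seqs)
  in_frame <- nchar(seqs) %% 3L == 0L & nchar(seqs) > 0L
  log <- c(frame = sum(!in_frame))
  genes <- lapply(seqs[in_frame], split_codons)
  names(genes) <- ids[in_frame]
  if (anyDuplicated(names(genes))) {
    warning("duplicate gene ids made unique")
    names(genes) <- make.unique(names(genes))
  }
  gene_set(genes, species = species, filter_log = log,
           genetic_code = genetic_code)
}

#' Write a gene set to FASTA
#'
#' @param gs A [gene_set].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(gs, path) {
  seqs <- vapply(gs$genes, paste, character(1), collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Apply the standard gene filters
#'
#' Strips the terminal stop codon (not counted toward gene length), removes
#' genes containing an internal stop codon, and removes genes shorter than
#' `min_codons` codons. Removal counts are appended to the filter log under
#' `"internal_stop"` and `"short"`. Idempotent.
#'
#' @param gs A [gene_set].
#' @param min_codons Minimum gene length in codons (default 200).
#' @return The filtered [gene_set].
#' @export
filter_genes <- function(gs, min_codons = 200) {
  stopifnot(inherits(gs, "gene_set"))
  code <- .code(gs$genetic_code)
  genes <- lapply(gs$genes, function(cod) {
    n <- length(cod)
    if (n && cod[n] %in% code$stops) cod <- cod[-n]
    cod
  })
  has_stop <- vapply(genes, function(cod) any(cod %in% code$stops), logical(1))
  short <- !has_stop & lengths(genes) < min_codons
  keep <- !has_stop & !short
  log <- gs$filter_log
  log["internal_stop"] <- sum(has_stop) + (log["internal_stop"] %||% 0L)
  log["short"] <- sum(short) + (log["short"] %||% 0L)
  out <- gene_set(genes[keep], species = gs$species,
                  expression = gs$expression[keep], filter_log = log,
                  genetic_code = gs$genetic_code)
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Read an expression table
#'
#' Accepts a TSV with header columns either `(gene_id, count, length_bp)` or
#' `(gene_id, fpkm)`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame; counts tables gain an `fpkm` column via
#'   [compute_fpkm()] when read as counts.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need_counts <- all(c("gene_id", "count", "length_bp") %in% names(tab))
  need_fpkm <- all(c("gene_id", "fpkm") %in% names(tab))
  if (!need_counts && !need_fpkm)
    stop("expression table must have columns (gene_id, count, length_bp) ",
         "or (gene_id, fpkm)")
  tab
}

#' Compute FPKM from read counts and transcript lengths
#'
#' FPKM for gene i is `count_i * 1e9 / (length_bp_i * total)`, where `total`
#' is the sum of counts over the supplied table (the library size computable
#' from the table itself).
#'
#' @param tab Data.frame with columns `gene_id`, `count`, `length_bp`.
#' @return The table with an `fpkm` column added.
#' @export
compute_fpkm <- function(tab) {
  stopifnot(all(c("gene_id", "count", "length_bp") %in% names(tab)))
  if (any(tab$count < 0)) stop("read counts must be non-negative")
  if (any(tab$length_bp < 3)) stop("transcript lengths must be >= 3 bp")
  total <- sum(tab$count)
  if (total == 0) stop("empty library: total mapped count is zero")
  tab$fpkm <- tab$count * 1e9 / (tab$length_bp * total)
  tab
}

#' Attach expression values to a gene set
#'
#' @param gs A [gene_set].
#' @param tab Expression data.frame with `gene_id` and either `fpkm` or
#'   `count`+`length_bp` columns (the latter converted via [compute_fpkm()]).
#' @return The gene set with its `expression` slot filled.
#' @export
set_expression <- function(gs, tab) {
  if (!"fpkm" %in% names(tab)) tab <- compute_fpkm(tab)
  expr <- stats::setNames(tab$fpkm, tab$gene_id)
  gene_set(gs$genes, species = gs$species, expression = expr,
           filter_log = gs$filter_log, genetic_code = gs$genetic_code)
}

#' Extract the highest- and lowest-expressed genes
#'
#' Ties are broken by lexicographic gene id so the split is deterministic.
#' Zero-FPKM genes are eligible for the low set (flagged in the returned
#' attribute `n_zero_low`).
#'
#' @param gs A [gene_set] whose genes all carry expression values.
#' @param n Number of genes per extreme set (default 500).
#' @return List with elements `high` and `low`, each a [gene_set] of size `n`.
#' @export
expression_extremes <- function(gs, n = 500) {
  expr <- gs$expression
  if (anyNA(expr)) stop("all genes must carry expression values")
  if (length(gs) < 2 * n)
    stop("gene set has ", length(gs), " genes; need at least 2*n = ", 2 * n,
         " - lower n")
  ord <- order(expr, names(gs$genes), method = "radix")
  low_idx <- ord[seq_len(n)]
  high_idx <- rev(ord)[seq_len(n)]
  high <- gs[high_idx]
  low <- gs[low_idx]
  attr(low, "n_zero_low") <- sum(expr[low_idx] == 0)
  list(high = high, low = low)
}

#' Write a filter report
#'
#' @param gs A filtered [gene_set].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(gs, path) {
  df <- data.frame(rule = names(gs$filter_log),
                   n_removed = as.integer(gs$filter_log))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
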