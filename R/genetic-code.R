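# Genetic code bookkeeping shared by every module. Codons are DNA 3-mers
# (A/C/G/T, uppercase). All indices operate on sense codons only; stop codons
# are excluded from counting, and Met/Trp (single-codon families) are excluded
# from "synonymously variable" statistics.

NT <- c("A", "C", "G", "T")

#' Genetic code tables for a translation table id
#'
#' Builds the lookup structures used by the codon-usage machinery: the
#' codon-to-amino-acid map, stop codons, synonymous families and their
#' degeneracy/fold classification (with the three six-codon amino acids Leu,
#' Ser and Arg treated as single 6-fold families, as in Wright's ENC).
#'
#' @param table NCBI translation table id as a string (default `"1"`, the
#'   standard nuclear code used by diatom nuclear genes).
#' @return A list with elements `code` (named character, codon -> one-letter
#'   amino acid, `*` for stop), `stops`, `sense` (61 sense codons for table 1),
#'   `families` (amino acid -> synonymous codon vector), `degeneracy`,
#'   `fold` (ENC fold class per amino acid: 2, 3, 4 or 6; 1 for Met/Trp)
#'   and `variable` (codons of amino acids with degeneracy >= 2).
#' @export
genetic_code <- function(table = "1") {
  code <- Biostrings::getGeneticCode(table)
  stops <- names(code)[code == "*"]
  sense <- names(code)[code != "*"]
  families <- split(sense, code[sense])
  families <- lapply(families, sort)
  degeneracy <- vapply(families, length, integer(1))
  fold <- degeneracy  # for the standard code degeneracy is the fold class
  variable <- unlist(families[degeneracy >= 2], use.names = FALSE)
  list(
    table = table,
    code = code,
    stops = stops,
    sense = sense,
    families = families,
    degeneracy = degeneracy,
    fold = fold,
    variable = variable
  )
}

# cache: the standard code is used everywhere
.gc_cache <- new.env(parent = emptyenv())

.code <- function(table = "1") {
  key <- paste0("t", table)
  if (is.null(.gc_cache[[key]])) .gc_cache[[key]] <- genetic_code(table)
  .gc_cache[[key]]
}

# third-position base of a codon vector
codon3 <- function(codons) substr(codons, 3L, 3L)

# TRUE where the codon's third base is G or C
is_gc_ending <- function(codons) codon3(codons) %in% c("G", "C")

# TRUE where the 3-mer is unambiguous DNA
is_clean_codon <- function(codons) {
  grepl("^[ACGT]{3}$", codons)
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
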