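# Shared fixture builders. Everything is generated in code; no data files.

.std_code <- cubevol:::.code()

# named 61-slot count vector; `...` are codon = count pairs
make_counts <- function(...) {
  v <- stats::setNames(rep(0L, length(.std_code$sense)), .std_code$sense)
  args <- list(...)
  for (cod in names(args)) v[cod] <- as.integer(args[[cod]])
  v
}

# uniform counts over every sense codon
uniform_counts <- function(per_codon = 600L) {
  stats::setNames(rep(as.integer(per_codon), length(.std_code$sense)),
                  .std_code$sense)
}

# counts using exactly one codon per amino acid
single_codon_counts <- function(per_aa = 600L) {
  v <- make_counts()
  for (aa in names(.std_code$families)) v[.std_code$families[[aa]][1]] <- per_aa
  v
}

# a tiny gene set from explicit codon strings
make_gene_set <- function(seqs, expression = NULL, species = "test") {
  genes <- lapply(seqs, function(s) cubevol:::split_codons(toupper(s)))
  gene_set(genes, species = species, expression = expression)
}

# random in-frame CDS string of n_codons sense codons (no stops)
random_cds <- function(n_codons, gc_bias = 0.5) {
  paste(sample(.std_code$sense, n_codons, replace = TRUE), collapse = "")
}

# write a FASTA fixture to a temp file
write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", unlist(seqs)), path)
  path
}

# independent NG86 oracle: recursive enumeration of all single-nucleotide
# mutational pathways between two codons, dropping paths through stops, and
# per-position synonymous site fractions computed from first principles.
# Deliberately written without the package's lookup tables.
oracle_ng86 <- function(codons_a, codons_b) {
  code <- Biostrings::GENETIC_CODE
  translate1 <- function(cod) unname(code[cod])
  site_count <- function(cod) {
    s <- 0
    for (pos in 1:3) {
      syn <- 0; valid <- 0
      for (nt in c("A", "C", "G", "T")) {
        if (nt == substr(cod, pos, pos)) next
        alt <- paste0(substr(cod, 1, pos - 1), nt, substr(cod, pos + 1, 3))
        if (translate1(alt) == "*") next
        valid <- valid + 1
        if (translate1(alt) == translate1(cod)) syn <- syn + 1
      }
      if (valid > 0) s <- s + syn / valid
    }
    s
  }
  # enumerate paths: at each step, change any one position still differing
  enumerate <- function(cur, target) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(pos)) return(list(c(syn = 0, nonsyn = 0)))
    out <- list()
    for (p in pos) {
      nxt <- paste0(substr(cur, 1, p - 1), substr(target, p, p),
                    substr(cur, p + 1, 3))
      if (translate1(nxt) == "*") next
      step_syn <- as.numeric(translate1(nxt) == translate1(cur))
      for (tail in enumerate(nxt, target)) {
        out[[length(out) + 1]] <- c(syn = step_syn + tail[["syn"]],
                                    nonsyn = (1 - step_syn) + tail[["nonsyn"]])
      }
    }
    out
  }
  ss <- 0; sd <- 0
  for (i in seq_along(codons_a)) {
    a <- codons_a[i]; b <- codons_b[i]
    paths <- enumerate(a, b)
    if (!length(paths)) next  # all pathways stop-blocked: column excluded
    ss <- ss + (site_count(a) + site_count(b)) / 2
    sd <- sd + mean(vapply(paths, `[[`, numeric(1), "syn"))
  }
  ps <- sd / ss
  list(syn_sites = ss, syn_diffs = sd, ps = ps,
       ds = -0.75 * log(1 - 4 * ps / 3))
}

# random sense-codon pair sequences with a controlled difference density
random_codon_pair <- function(n_codons = 30, p_mut = 0.15) {
  a <- sample(.std_code$sense, n_codons, replace = TRUE)
  b <- a
  for (i in seq_len(n_codons)) {
    cod <- b[i]
    for (pos in 1:3) {
      if (stats::runif(1) < p_mut) {
        nts <- setdiff(c("A", "C", "G", "T"), substr(cod, pos, pos))
        substr(cod, pos, pos) <- sample(nts, 1)
      }
    }
    if (!cod %in% .std_code$stops) b[i] <- cod
  }
  list(a = a, b = b)
}
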