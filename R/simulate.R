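# Synthetic gene sets and ancestor -> descendant branches drawn from the
# mutation-selection-drift equilibrium model, with full ground-truth records.
#
# Gene sets are sampled directly from the stationary law (the equilibrium
# frequency P = e^S/(e^S + k) is itself the model's stationary distribution,
# so direct sampling is exact and fast). Branches use a small forward
# simulation: a two-state continuous-time chain per synonymous site with
# relative substitution rates k away from the currently preferred codon and
# e^S toward it, which has exactly the equilibrium above as its stationary
# distribution.

#' Step expression-quantile to S profile
#'
#' @param s_low S for genes below the threshold quantile.
#' @param s_high S for genes at or above it.
#' @param threshold Expression-rank quantile separating the regimes.
#' @return A function mapping quantiles in `[0, 1]` to S.
#' @export
s_profile_step <- function(s_low = 0, s_high = 0.5, threshold = 0.75) {
  force(s_low); force(s_high); force(threshold)
  function(q) ifelse(q >= threshold, s_high, s_low)
}

#' Default preferred codon set for simulations
#'
#' For every synonymously variable amino acid, one preferred codon with a
#' G/C-ending (or A/T-ending) third position: the C-ending codon where the
#' family has one, else the G-ending one (conversely T then A for `"AT"`).
#' The remaining synonyms are flagged unpreferred.
#'
#' @param gc `"GC"` (default) or `"AT"`.
#' @param genetic_code NCBI translation table id.
#' @return An [optimal_codon_set].
#' @export
default_preferred_set <- function(gc = c("GC", "AT"), genetic_code = "1") {
  gc <- match.arg(gc)
  code <- .code(genetic_code)
  order3 <- if (gc == "GC") c("C", "G") else c("T", "A")
  pref <- list()
  unpref <- list()
  for (aa in names(code$families)[code$degeneracy >= 2]) {
    fam <- code$families[[aa]]
    third <- codon3(fam)
    hit <- fam[match(order3, third)]
    hit <- hit[!is.na(hit)][1]
    pref[[aa]] <- hit
    unpref[[aa]] <- setdiff(fam, hit)
  }
  optimal_codon_set(pref, unpref, genetic_code = genetic_code)
}

#' Simulation configuration
#'
#' Bundles the parameters of the equilibrium generator and the branch
#' process. Defaults emulate the study conditions of the diatom analyses: an
#' AT-biased mutation spectrum k = 2.21 (the directly measured
#' *P. tricornutum* ratio), GC-ending preferred codons, selection S = 0.5 (a
#' mid-range diatom estimate) confined to the top expression quartile, genes
#' of 300 codons, and 2000 genes per species.
#'
#' @param n_genes Number of genes.
#' @param codons_per_gene Gene length in codons (>= 200, matching the gene
#'   length filter of the analysis).
#' @param k Mutation bias ratio preferred->unpreferred over reverse (> 0).
#' @param s_profile Function mapping expression-rank quantile to S (see
#'   [s_profile_step()]).
#' @param preferred_set Ground-truth [optimal_codon_set] (default
#'   [default_preferred_set()] with GC-ending codons).
#' @param branch_length Expected synonymous substitutions per evolving site
#'   on a simulated branch.
#' @param shift_time Optional fraction of the branch after which the
#'   preferred and alternative codons swap roles (the moving-target
#'   scenario); NULL for a stable optimum.
#' @param amino_acid_frequencies Named composition weights (default uniform
#'   over all amino acids).
#' @param seed Optional integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, codons_per_gene = 300,
                              k = 2.21, s_profile = s_profile_step(),
                              preferred_set = NULL, branch_length = 0.3,
                              shift_time = NULL,
                              amino_acid_frequencies = NULL, seed = NULL) {
  stopifnot(n_genes >= 1, codons_per_gene >= 200, k > 0, branch_length >= 0)
  if (!is.null(shift_time))
    stopifnot(shift_time >= 0, shift_time <= 1)
  if (is.null(preferred_set)) preferred_set <- default_preferred_set()
  code <- .code(preferred_set$genetic_code)
  if (is.null(amino_acid_frequencies)) {
    amino_acid_frequencies <- stats::setNames(
      rep(1, length(code$families)), names(code$families))
  }
  stopifnot(is.function(s_profile))
  structure(
    list(n_genes = as.integer(n_genes),
         codons_per_gene = as.integer(codons_per_gene),
         k = k, s_profile = s_profile, preferred_set = preferred_set,
         branch_length = branch_length, shift_time = shift_time,
         amino_acid_frequencies = amino_acid_frequencies, seed = seed),
    class = "simulation_config"
  )
}

# shared site layout: amino acids, per-gene S, per-site preferred codon
.sim_layout <- function(cfg, S_gene = NULL) {
  code <- .code(cfg$preferred_set$genetic_code)
  n <- cfg$n_genes
  cpg <- cfg$codons_per_gene
  N <- n * cpg
  q <- (seq_len(n) - 0.5) / n
  if (is.null(S_gene)) S_gene <- cfg$s_profile(q)
  w <- cfg$amino_acid_frequencies
  aa_vec <- sample(names(w), N, replace = TRUE, prob = as.numeric(w))
  gene_idx <- rep(seq_len(n), each = cpg)
  pref_map <- vapply(cfg$preferred_set$preferred, `[`, character(1), 1L)
  list(code = code, n = n, cpg = cpg, N = N, q = q, S_gene = S_gene,
       aa_vec = aa_vec, gene_idx = gene_idx, pref_map = pref_map,
       S_site = S_gene[gene_idx])
}

# uniform draw from the synonym family of each amino acid in aa (vectorized)
.sample_family <- function(aa, code) {
  out <- character(length(aa))
  for (a in unique(aa)) {
    fam <- code$families[[a]]
    idx <- which(aa == a)
    out[idx] <- fam[sample.int(length(fam), length(idx), replace = TRUE)]
  }
  out
}

#' Simulate a gene set at mutation-selection-drift equilibrium
#'
#' Amino acids are drawn from the composition weights; within each family
#' possessing a ground-truth preferred codon, the preferred codon is chosen
#' with probability `P = exp(S)/(exp(S) + k)` (S from the gene's expression
#' quantile), otherwise a uniform draw among the remaining synonyms
#' (two-state reduction for higher-degeneracy families). Expression values
#' are a monotone transform of a latent gene rank with lognormal noise; S is
#' assigned from the realized expression rank, so `s_profile` is literally a
#' function of each gene's expression-rank quantile and the expression
#' extremes select exactly the genes carrying the profiled S values.
#'
#' @param cfg A [simulation_config].
#' @return A [gene_set] whose `truth` attribute records per-gene S, k, the
#'   preferred set and the config.
#' @export
simulate_gene_set <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_genes
  q_lat <- (seq_len(n) - 0.5) / n
  expr <- exp(4 * q_lat + stats::rnorm(n, 0, 0.25))
  q_expr <- (rank(expr, ties.method = "first") - 0.5) / n
  L <- .sim_layout(cfg, S_gene = cfg$s_profile(q_expr))
  evolves <- L$aa_vec %in% names(L$pref_map)
  P_site <- equilibrium_P(L$S_site, cfg$k)
  codon <- character(L$N)
  take_pref <- evolves & stats::runif(L$N) < P_site
  codon[take_pref] <- L$pref_map[L$aa_vec[take_pref]]
  rest <- evolves & !take_pref
  for (a in unique(L$aa_vec[rest])) {
    others <- setdiff(L$code$families[[a]], L$pref_map[[a]])
    idx <- which(rest & L$aa_vec == a)
    codon[idx] <- others[sample.int(length(others), length(idx),
                                    replace = TRUE)]
  }
  codon[!evolves] <- .sample_family(L$aa_vec[!evolves], L$code)

  ids <- sprintf("g%05d", seq_len(L$n))
  genes <- split(codon, L$gene_idx)
  names(genes) <- ids
  names(expr) <- ids
  gs <- gene_set(genes, species = "simulated", expression = expr,
                 genetic_code = cfg$preferred_set$genetic_code)
  attr(gs, "truth") <- list(S = stats::setNames(L$S_gene, ids), k = cfg$k,
                            preferred_set = cfg$preferred_set, config = cfg)
  gs
}

# forward two-state evolution of one phase; `at_p` marks sites at their c_p
# codon, `pref_at_p` says whether c_p is the currently preferred codon
.sim_phase <- function(at_p, t_now, t_end, S_site, k, pref_at_p, phase) {
  ev_site <- integer(0)
  ev_time <- numeric(0)
  ev_from_p <- logical(0)
  active <- which(t_now < t_end)
  while (length(active)) {
    on_pref <- at_p[active] == pref_at_p
    rate <- ifelse(on_pref, k, exp(S_site[active]))
    dt <- stats::rexp(length(active), rate)
    t_new <- t_now[active] + dt
    flip <- t_new <= t_end[active]
    fidx <- active[flip]
    ev_site <- c(ev_site, fidx)
    ev_time <- c(ev_time, t_new[flip])
    ev_from_p <- c(ev_from_p, at_p[fidx])
    at_p[fidx] <- !at_p[fidx]
    t_now[fidx] <- t_new[flip]
    active <- fidx
  }
  list(at_p = at_p,
       events = data.frame(site = ev_site, time = ev_time,
                           from_at_p = ev_from_p,
                           phase = rep(phase, length(ev_site))))
}

#' Simulate an ancestor -> descendant branch
#'
#' The ancestor is drawn from the equilibrium of the initial preferred set.
#' Each synonymous site then follows a two-state chain between its preferred
#' codon and a third-position alternative with the opposite GC ending, with
#' relative rates k away from and `exp(S)` toward the currently preferred
#' codon; site time is scaled so the expected number of substitutions per
#' evolving site equals `branch_length` (at the initial stationary rate).
#' With `shift_time` set, the preferred and alternative codons swap roles at
#' that fraction of the branch (the moving-target scenario).
#'
#' @param cfg A [simulation_config].
#' @return List with `pairs` (one [aligned_codon_pair] per gene, ancestor
#'   first), `events` (data.frame: gene, site, codon position, time, from,
#'   to, and whether the event moved the site to the codon preferred at that
#'   moment), and `truth` (initial/final preferred sets, per-gene S, k,
#'   config).
#' @export
simulate_branch <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- .sim_layout(cfg)
  code <- L$code
  evolves <- L$aa_vec %in% names(L$pref_map)
  N <- L$N

  c_p <- rep(NA_character_, N)
  c_u <- rep(NA_character_, N)
  c_p[evolves] <- L$pref_map[L$aa_vec[evolves]]
  for (a in unique(L$aa_vec[evolves])) {
    cp <- L$pref_map[[a]]
    fam <- code$families[[a]]
    box <- fam[substr(fam, 1, 2) == substr(cp, 1, 2) & fam != cp]
    opp <- box[is_gc_ending(box) != is_gc_ending(cp)]
    ch <- if (length(opp)) opp else box
    idx <- which(evolves & L$aa_vec == a)
    c_u[idx] <- ch[sample.int(length(ch), length(idx), replace = TRUE)]
  }

  P_site <- equilibrium_P(L$S_site, cfg$k)
  at_p <- rep(NA, N)
  at_p[evolves] <- stats::runif(N)[evolves] < P_site[evolves]
  anc <- character(N)
  anc[evolves] <- ifelse(at_p[evolves], c_p[evolves], c_u[evolves])
  anc[!evolves] <- .sample_family(L$aa_vec[!evolves], code)

  # site-specific total time so E[substitutions per site] = branch_length
  rho <- P_site * cfg$k + (1 - P_site) * exp(L$S_site)
  T_tot <- ifelse(evolves, cfg$branch_length / rho, 0)
  shift <- !is.null(cfg$shift_time) && cfg$shift_time < 1
  t_split <- if (shift) cfg$shift_time * T_tot else T_tot

  ph1 <- .sim_phase(at_p, rep(0, N), t_split, L$S_site, cfg$k,
                    pref_at_p = TRUE, phase = 1L)
  at_p <- ph1$at_p
  events <- ph1$events
  final_pref_at_p <- TRUE
  if (shift) {
    ph2 <- .sim_phase(at_p, t_split, T_tot, L$S_site, cfg$k,
                      pref_at_p = FALSE, phase = 2L)
    at_p <- ph2$at_p
    events <- rbind(events, ph2$events)
    final_pref_at_p <- FALSE
  }
  dec <- anc
  dec[evolves] <- ifelse(at_p[evolves], c_p[evolves], c_u[evolves])

  if (nrow(events)) {
    events <- events[order(events$site, events$time), ]
    s <- events$site
    events <- data.frame(
      gene = sprintf("g%05d", L$gene_idx[s]),
      site = ((s - 1L) %% L$cpg) + 1L,
      time = events$time,
      from = ifelse(events$from_at_p, c_p[s], c_u[s]),
      to = ifelse(events$from_at_p, c_u[s], c_p[s]),
      # preferred codon at event time: c_p in phase 1, c_u in phase 2
      to_preferred = ifelse(events$phase == 1L, !events$from_at_p,
                            events$from_at_p),
      phase = events$phase,
      stringsAsFactors = FALSE
    )
  } else {
    events <- data.frame(gene = character(), site = integer(),
                         time = numeric(), from = character(),
                         to = character(), to_preferred = logical(),
                         phase = integer())
  }

  gidx <- L$gene_idx
  ids <- sprintf("g%05d", seq_len(L$n))
  pairs <- lapply(seq_len(L$n), function(i) {
    sel <- gidx == i
    aligned_codon_pair(anc[sel], dec[sel], "ancestor",
                       paste0("descendant_", ids[i]),
                       genetic_code = cfg$preferred_set$genetic_code)
  })
  names(pairs) <- ids

  final_set <- cfg$preferred_set
  if (!final_pref_at_p) {
    # after the shift the per-site alternatives are the preferred targets;
    # summarised at the family level by the opposite-GC default set
    flip_to <- if (cfg$preferred_set$gc_class == "AT-rich") "GC" else "AT"
    final_set <- default_preferred_set(flip_to,
                                       cfg$preferred_set$genetic_code)
  }
  list(pairs = pairs, events = events,
       truth = list(initial_preferred = cfg$preferred_set,
                    final_preferred = final_set,
                    S = stats::setNames(L$S_gene, ids), k = cfg$k,
                    config = cfg))
}
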