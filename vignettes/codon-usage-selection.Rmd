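---
title: "Measuring selection on codon usage: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selection on codon usage: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(cubevol)
```

cubevol quantifies codon usage bias (CUB) in protein-coding gene sets,
identifies each species' preferred (optimal) codons, and estimates the
population-scaled strength of natural selection maintaining them under a
mutation-selection-drift equilibrium model. It also provides the
comparative layer — synonymous divergence, silent-site diversity, and
polarized substitution counting — needed to ask how codon preferences
evolve across a clade, plus a simulator for validating every estimator on
data with known ground truth.

This vignette documents the statistical methods, the modelling
conventions, and the reasoning behind the defaults.

## Codon usage indices

`count_codons()` tallies the 61 sense codons of a gene, skipping stop
codons and any triplet containing a non-ACGT character. All downstream
indices work from these counts.

**RSCU** (relative synonymous codon usage) is the observed count of a
codon divided by the mean count over its synonymous family; 1 means no
bias. Families with zero observations are masked `NA` rather than zero so
absence of evidence is not mistaken for absence of bias.

**ENC** (the effective number of codons) summarises how far usage departs
from uniformity. For each amino-acid family the homozygosity is
estimated as

$$\hat F = \frac{n \sum_i p_i^2 - 1}{n - 1},$$

with $n$ the family's codon total and $p_i$ the within-family codon
frequencies. $\hat F$ is averaged within each degeneracy class
(2-, 3-, 4-, 6-fold; the three 6-fold amino acids are treated as single
families), and

$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} +
  \frac{5}{\bar F_4} + \frac{3}{\bar F_6},$$

capped at 61. A missing 3-fold class is interpolated as
$(\bar F_2 + \bar F_4)/2$; a missing 2-, 4- or 6-fold class, or a
non-positive $\bar F$, makes ENC `NA`. The two limits are exact: uniform
usage gives 61 and one codon per amino acid gives 20.

**GC3s** is the G+C fraction at third positions of synonymously variable
codons (Met, Trp and stops excluded). **FOP**, the frequency of optimal
codons, divides the optimal-codon count by the count of all codons
belonging to amino acids that possess at least one optimal codon — the
denominator matters, because amino acids without an identified optimal
codon carry no information about optimal-codon use.

`aggregate_indices()` returns per-gene values, a pooled (concatenated
counts) row, and per-species means.

## Identifying optimal codons

Optimal codons are identified from usage alone, without expression data:

1. Build the gene × codon RSCU (or raw count) matrix and run a
   correspondence analysis (`correspondence_analysis()`): the singular
   value decomposition of the standardized residual matrix
   $(P - rc^\top)/\sqrt{rc^\top}$ of the row-profile table, the standard
   chi-square-distance ordination. Axis 1 is oriented so that it
   correlates *negatively* with per-gene ENC, i.e. larger coordinates
   mean stronger bias; orientation is a free sign in any SVD, so fixing
   it makes runs and species comparable.
2. Take the genes in the top and bottom 5% of axis 1
   (`extremes_fraction = 0.05`) as the high-bias and low-bias groups.
3. For every codon, test the 2×2 contingency table
   {high, low} × {this codon, other synonyms} with Pearson's chi-squared
   test (no continuity correction). A codon significantly
   over-represented in the high-bias group at `alpha = 0.01` is flagged
   *preferred*; significantly under-represented codons are
   *unpreferred*. A Bonferroni option (`correction = "bonferroni"`) is
   available; the default keeps the conventional uncorrected
   per-codon threshold.

`classify_preferred_gc()` labels the preferred set by the G+C fraction
at its third positions: below 0.40 "AT-rich", 0.40–0.75 "moderate-GC",
above 0.75 "GC-rich". The band edges sit in the gaps of the empirical
distribution observed across diatoms, which is strongly bimodal.

```{r, eval = FALSE}
gs <- read_cds_fasta("species_cds.fa")
gs <- filter_genes(gs, min_codons = 200)
ocs <- identify_optimal_codons(gs)
ocs$gc_class
```

## The mutation-selection-drift equilibrium and S

For an amino acid with one preferred codon $C_1$ and one unpreferred
codon $C_2$, mutation rates $u$ ($C_1 \to C_2$) and $v$ ($C_2 \to C_1$),
effective population size $N_e$ and selection differential $s$ in favour
of $C_1$, the stationary frequency of the preferred codon is

$$P = \frac{e^{S}}{e^{S} + k}, \qquad S = 2 N_e s, \quad k = u/v,$$

and inverting it gives the estimator

$$S = \ln\!\left(\frac{P\,k}{1 - P}\right).$$

Only the ratio $k$ enters; $N_e$ and $s$ are never separated. The model
is two-state, so estimation pools the two-fold degenerate amino acids
(`twofold_subset()`), where one preferred and one unpreferred codon is
exactly the model's state space.

`selection_analysis()` implements the full procedure:

* $P$ is the pooled optimal-codon frequency in the `n = 500` most highly
  expressed genes (pooling counts across genes and amino acids minimises
  the variance of the frequency estimate).
* $k$ comes from a measured mutation spectrum when one is available
  (`mutation_spectrum()`; e.g. mutation-accumulation estimates), and is
  otherwise inferred from the 500 *least* expressed genes by assuming
  selection on their codon usage is negligible, so that
  $P_{\mathrm{low}} = v/(u+v)$ and $k = (1-P_{\mathrm{low}})/P_{\mathrm{low}}$.
  When the weakly expressed genes are in fact under selection this
  inference absorbs part of the signal and the resulting S is biased
  toward zero — a conservative direction, demonstrated in the test
  suite.
* Significance comes from a resampling test: S is recomputed on
  `reps = 1000` random sets of 500 genes drawn from the whole filtered
  set, and the upper-tail p-value is
  $(1 + \#\{S_{\mathrm{null}} \ge S_{\mathrm{obs}}\})/(1 + \mathrm{reps})$,
  the standard positively biased permutation estimator, marked
  `***` ($p < 0.01$), `*` ($p < 0.05$) or `ns`.

```{r, eval = FALSE}
fit <- selection_analysis(gs, ocs, n = 500, reps = 1000, seed = 1)
summary(fit)
```

For cross-species comparisons within a clade whose preferred codons have
shifted, `restrict_to_stable_codons()` returns the two-fold amino acids
whose preferred codon is identical in every species, so that the same
quantity is compared everywhere.

## Divergence, diversity and the neutral calculators

`ng86_ds()` computes synonymous divergence by the Nei–Gojobori (1986)
counting method with a Jukes–Cantor correction,
$d_S = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3} p_S)$. Conventions, which the
test suite pins against an independent pathway-enumeration oracle:

* Per-codon synonymous site fractions exclude changes that create stop
  codons from the per-position denominator.
* Multi-position codon differences are averaged with equal weight over
  all mutational pathways that avoid stop codons.
* Codon pairs whose every pathway passes through a stop are excluded
  from both the site and the difference totals.
* $p_S \ge 3/4$ raises an error (saturation; the correction is
  undefined) rather than returning a silent `NA`.

`silent_pi()` is the within-species analogue: the mean over all sequence
pairs of the uncorrected proportion of synonymous differences per
synonymous site. It is left uncorrected because π is an intra-species
quantity where distances are small.

Two deliberately tiny calculators close the neutral-theory loop:
`ne_from_pi()` inverts $\pi = 4 N_e \mu$ and `time_from_ds()` inverts
$d_S = 2 t \mu$, with defaults $\mu = 4.77 \times 10^{-10}$ per site per
generation (the directly measured *Phaeodactylum tricornutum* rate) and
100 generations per year, a plausible figure for wild diatom
populations. Both defaults are arguments precisely because they are the
least certain numbers in any such calculation.

## Polarized substitution counting

Given an ancestor–descendant `aligned_codon_pair()`,
`polarize_branch()` counts synonymous substitutions — columns that
differ only at the third position and conserve the amino acid — and
classifies each by its descendant codon: into the preferred set
("to preferred") or not ("to unpreferred"). The rule is binary, so the
two classes always sum to the total, an invariant the tests enforce on
every input. Columns with amino-acid changes or multi-position changes
are excluded (single-event parsimony). GC percentages are reported for
the third positions of substituted sites, ancestral versus current.

`gc_shift_test()` asks whether the flux toward preferred codons exceeds
mutational opportunity: a 2×2 chi-squared test of the observed
(to-preferred, to-unpreferred) counts against the numbers of ancestral
codons able to gain versus lose preferred status. Under no directional
excess the observed counts are proportional to opportunity.
`branch_report()` assembles the per-branch table.

## The simulator

`simulate_gene_set()` samples species directly from the stationary law:
amino acids from composition weights, and within each family the
ground-truth preferred codon with probability $P = e^S/(e^S + k)$,
otherwise a uniform draw among the remaining synonyms. Direct sampling
is exact — the equilibrium frequency *is* the model's stationary
distribution — and fast.

Per-gene S comes from `s_profile`, a function of the gene's
expression-rank quantile (default: S = 0.5 in the top quartile, 0
below, emulating selection confined to highly expressed genes).
Expression values are a monotone transform of a latent rank with
lognormal noise, and S is assigned from the *realized* expression rank,
so the profile is literally a function of each gene's expression-rank
quantile: the 500 most-expressed genes of a simulation carry exactly the
S values the profile puts there, which is what makes recovery tests
sharp rather than diluted by rank noise.

`simulate_branch()` adds time: the ancestor is drawn from equilibrium,
and each synonymous site then follows a two-state continuous-time chain
between its preferred codon and a third-position alternative with the
opposite GC ending, with relative rates $k$ away from and $e^S$ toward
the currently preferred codon — a chain whose stationary distribution is
exactly the equilibrium above. Site time is scaled so the expected
number of substitutions per evolving site equals `branch_length`. With
`shift_time` set, the preferred and alternative codons swap roles
partway along the branch: the *moving-target* scenario, in which codon
usage chases a shifting optimum and equilibrium bias is never reached.
Every substitution is written to an event log with its time and
polarity, so polarization and divergence estimators can be audited
against the exact history.

Scope and limitations, stated plainly:

* The branch process is two-state per site (preferred versus one
  alternative), so simulated descendants never wander across a whole
  4-fold family; that is sufficient for validating two-state estimators
  and polarity counting, and it keeps every event synonymous and
  third-position by construction.
* Default parameters (k = 2.21, S = 0.5, 300-codon genes, 2000 genes)
  are round mid-range values for diatom-like data; they are
  conveniences, not estimates.
* Expression noise is lognormal with a fixed scale; the simulator makes
  no attempt to model real expression distributions.

```{r}
cfg <- simulation_config(n_genes = 300, codons_per_gene = 200, seed = 42)
gs <- simulate_gene_set(cfg)
ocs <- identify_optimal_codons(gs)
fit <- selection_analysis(gs, ocs, n = 75, reps = 200, seed = 43)
fit
```

## The pipelines

`run_species()` chains filtering (genes of at least 200 codons, internal
stops removed), index computation, optimal-codon identification and the
selection analysis, writing a TSV/JSON report bundle plus a run log
carrying the seed and a config hash. `run_clade()` produces the pairwise
dS matrix, divergence-time table and polarity report for a set of
species. Both take a `pipeline_config()`, which can be read from YAML
(`read_pipeline_config()`), so an analysis is reproducible from a single
small text file.
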