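test_that("an identical pair yields zero substitutions and undefined GC", {
  p <- aligned_codon_pair(c("AAA", "GGC"), c("AAA", "GGC"))
  s <- polarize_branch(p, default_preferred_set("GC"))
  expect_equal(s$total_synonymous, 0)
  expect_equal(s$to_preferred, 0)
  expect_true(is.na(s$gc_ancestral))
  expect_true(is.na(s$gc_current))
})

test_that("a single AAA -> AAG substitution is polarized toward preferred", {
  ocs <- default_preferred_set("GC")   # AAG is the preferred Lys codon
  p <- aligned_codon_pair(c("AAA", "GGC"), c("AAG", "GGC"))
  s <- polarize_branch(p, ocs)
  expect_equal(s$to_preferred, 1)
  expect_equal(s$to_unpreferred, 0)
  expect_equal(s$total_synonymous, 1)
  expect_equal(s$gc_ancestral, 0)
  expect_equal(s$gc_current, 100)
})

test_that("to-preferred and to-unpreferred always sum to the total", {
  set.seed(81)
  ocs <- default_preferred_set("GC")
  for (i in 1:10) {
    pr <- random_codon_pair(60, p_mut = 0.2)
    p <- aligned_codon_pair(pr$a, pr$b)
    s <- polarize_branch(p, ocs)
    expect_identical(s$to_preferred + s$to_unpreferred, s$total_synonymous)
    expect_lte(s$total_synonymous + s$excluded, s$n_columns)
  }
})

test_that("swapping ancestor and descendant swaps the two polarities", {
  ocs <- default_preferred_set("GC")
  a <- c("AAA", "GAA", "TTC", "CAG")
  b <- c("AAG", "GAG", "TTT", "CAA")
  f <- polarize_branch(aligned_codon_pair(a, b), ocs)
  r <- polarize_branch(aligned_codon_pair(b, a), ocs)
  expect_identical(f$to_preferred, r$to_unpreferred)
  expect_identical(f$to_unpreferred, r$to_preferred)
  expect_identical(f$total_synonymous, r$total_synonymous)
  expect_equal(f$gc_ancestral, r$gc_current)
  expect_equal(f$gc_current, r$gc_ancestral)
})

test_that("amino-acid changes and multi-position changes are excluded", {
  ocs <- default_preferred_set("GC")
  # ATT -> ATG changes Ile to Met; AAA -> GGG changes everything
  p <- aligned_codon_pair(c("ATT", "AAA"), c("ATG", "GGG"))
  s <- polarize_branch(p, ocs)
  expect_equal(s$total_synonymous, 0)
  expect_equal(s$excluded, 2)
})

test_that("the GC fallback classifies unflagged families by third-position GC", {
  ocs <- optimal_codon_set(list(K = "AAG"), list(K = "AAA"))
  expect_equal(ocs$gc_class, "GC-rich")
  p <- aligned_codon_pair(c("GGA", "AAA"), c("GGG", "AAA"))  # Gly unflagged
  strict <- polarize_branch(p, ocs)
  expect_equal(strict$to_preferred, 0)
  expect_equal(strict$to_unpreferred, 1)
  loose <- polarize_branch(p, ocs, gc_fallback = TRUE)
  expect_equal(loose$to_preferred, 1)
  expect_equal(loose$to_unpreferred, 0)
})

test_that("polarized counts match the simulator event log at single-event sites", {
  cfg <- simulation_config(n_genes = 10, codons_per_gene = 200,
                           branch_length = 0.2, seed = 810)
  br <- simulate_branch(cfg)
  ev <- br$events
  ocs <- br$truth$initial_preferred
  key <- paste(ev$gene, ev$site)
  single <- names(which(table(key) == 1))
  ev1 <- ev[key %in% single, ]
  got_pref <- 0L
  got_tot <- 0L
  for (g in names(br$pairs)) {
    sites <- ev1$site[ev1$gene == g]
    if (!length(sites)) next
    p <- br$pairs[[g]]
    expect_equal(p$n_dropped, 0)
    sub <- aligned_codon_pair(p$a[sites], p$b[sites])
    s <- polarize_branch(sub, ocs)
    expect_equal(s$total_synonymous, length(sites))
    got_pref <- got_pref + s$to_preferred
    got_tot <- got_tot + s$total_synonymous
  }
  expect_identical(got_tot, nrow(ev1))
  expect_identical(got_pref, sum(ev1$to_preferred))
})

test_that("opportunity test gives p = 1 under proportionality, small p on excess", {
  base <- polarize_branch(
    aligned_codon_pair(c("AAA", "GGC"), c("AAG", "GGC")),
    default_preferred_set("GC"))
  prop <- base
  prop$to_preferred <- 30; prop$to_unpreferred <- 70
  prop$total_synonymous <- 100
  prop$opportunity <- c(gain = 300, loss = 700)
  expect_equal(gc_shift_test(prop)$chi2_p, 1)
  skew <- base
  skew$to_preferred <- 3000; skew$to_unpreferred <- 1000
  skew$total_synonymous <- 4000
  skew$opportunity <- c(gain = 2000, loss = 2000)
  expect_lt(gc_shift_test(skew)$chi2_p, 1e-4)
  expect_lt(gc_shift_test(skew, method = "equal")$chi2_p, 1e-4)
  none <- base
  none$to_preferred <- 0; none$to_unpreferred <- 0
  none$total_synonymous <- 0
  expect_true(is.na(gc_shift_test(none)$chi2_p))
  zero_opp <- skew
  zero_opp$opportunity <- c(gain = 0, loss = 0)
  expect_true(is.na(gc_shift_test(zero_opp)$chi2_p))
})

test_that("a branch evolving toward a new GC optimum gains third-position GC", {
  # ancestor at an AT-preferred equilibrium; the optimum flips to GC-ending
  # codons at the start of the branch, so substitutions run toward GC
  cfg <- simulation_config(n_genes = 20, codons_per_gene = 300, k = 1,
                           s_profile = s_profile_step(1, 1, 0),
                           preferred_set = default_preferred_set("AT"),
                           branch_length = 0.3, shift_time = 0, seed = 811)
  br <- simulate_branch(cfg)
  ocs <- br$truth$final_preferred
  expect_equal(ocs$gc_class, "GC-rich")
  sums <- lapply(br$pairs[1:20], polarize_branch, ocs = ocs)
  rep_df <- branch_report(sums)
  expect_equal(nrow(rep_df), 20)
  tot <- colSums(rep_df[, c("to_preferred", "to_unpreferred",
                            "total_substitutions")])
  expect_identical(unname(tot["to_preferred"] + tot["to_unpreferred"]),
                   unname(tot["total_substitutions"]))
  expect_gt(tot[["to_preferred"]], tot[["to_unpreferred"]])
  expect_gt(mean(rep_df$gc_current), mean(rep_df$gc_ancestral))
  expect_true(all(!is.na(rep_df$chi2_p)))
})

test_that("branch_report handles an empty branch list", {
  df <- branch_report(list())
  expect_equal(nrow(df), 0)
  expect_true(all(c("branch", "to_preferred", "to_unpreferred",
                    "total_substitutions", "gc_ancestral", "gc_current",
                    "chi2_p") %in% names(df)))
})
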