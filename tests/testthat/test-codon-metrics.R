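test_that("codon counting skips ambiguous and stop codons", {
  expect_equal(count_codons(c("ATG", "AAA", "AAG"))[c("ATG", "AAA", "AAG")],
               c(ATG = 1L, AAA = 1L, AAG = 1L))
  codons <- c(rep("GGG", 200), "GNG")
  expect_equal(sum(count_codons(codons)), 200)
  expect_equal(sum(count_codons(c("TAA", "NNN"))), 0)  # zero vector, no error
})

test_that("RSCU matches its definition and masks empty families", {
  v <- make_counts(AAA = 6, AAG = 2)   # Lys 2-fold family
  r <- rscu(v)
  expect_equal(unname(r[c("AAA", "AAG")]), c(1.5, 0.5))
  expect_true(all(is.na(r[setdiff(names(r), c("AAA", "AAG"))])))
  u <- rscu(uniform_counts())
  expect_true(all(abs(u - 1) < 1e-12))
})

test_that("mean RSCU within any observed family is 1", {
  set.seed(21)
  for (i in 1:20) {
    v <- make_counts()
    v[] <- rpois(length(v), lambda = sample(0:6, 1))
    r <- rscu(v)
    for (aa in names(.std_code$families)[.std_code$degeneracy >= 2]) {
      fam <- .std_code$families[[aa]]
      if (sum(v[fam]) > 0) expect_equal(mean(r[fam]), 1)
      else expect_true(all(is.na(r[fam])))
    }
  }
})

test_that("ENC hits its theoretical bounds", {
  expect_equal(enc(uniform_counts()), 61)
  expect_equal(enc(single_codon_counts()), 20)
})

test_that("ENC class averaging follows Wright's homozygosity formula", {
  # every family used as (3,1,0,...): F-hat = (4*0.625-1)/3 = 0.5 in every
  # fold class, so ENC = 2 + 9/0.5 + 1/0.5 + 5/0.5 + 3/0.5 = 38
  v <- make_counts()
  for (aa in names(.std_code$families)[.std_code$degeneracy >= 2]) {
    fam <- .std_code$families[[aa]]
    v[fam[1]] <- 3L
    v[fam[2]] <- 1L
  }
  expect_equal(enc(v), 38)
})

test_that("ENC is undefined when a fold class is missing, and interpolates 3-fold", {
  # only Lys used: 4- and 6-fold classes missing -> NA
  expect_true(is.na(enc(make_counts(AAA = 3, AAG = 1))))
  # all classes but Ile present: 3-fold interpolated, ENC defined
  v <- uniform_counts()
  v[.std_code$families[["I"]]] <- 0L
  expect_false(is.na(enc(v)))
})

test_that("ENC stays in [20, 61] and stabilizes in the large-count limit", {
  # the family homozygosity (n*sum(p^2)-1)/(n-1) depends on the count total
  # n, so ENC is only scale-invariant asymptotically: scaling the same
  # proportions to large totals must converge
  set.seed(33)
  for (i in 1:25) {
    g <- cubevol:::split_codons(random_cds(300))
    v <- count_codons(g)
    e <- enc(v)
    if (!is.na(e)) {
      expect_gte(e, 20)
      expect_lte(e, 61)
      expect_lt(abs(enc(v * 100L) - enc(v * 10000L)), 0.1)
    }
  }
})

test_that("GC3s covers only synonymously variable third positions", {
  gc_end <- .std_code$variable[cubevol:::is_gc_ending(.std_code$variable)]
  at_end <- setdiff(.std_code$variable, gc_end)
  v <- make_counts()
  v[gc_end] <- 5L
  expect_equal(gc3s(v), 1.0)
  v <- make_counts()
  v[at_end] <- 5L
  expect_equal(gc3s(v), 0.0)
  expect_true(is.na(gc3s(make_counts(ATG = 10, TGG = 10))))
})

test_that("FOP uses the eligible-amino-acid denominator", {
  ocs <- default_preferred_set("GC")
  pref <- unlist(ocs$preferred, use.names = FALSE)
  v <- make_counts()
  v[pref] <- 2L
  expect_equal(fop(v, ocs), 1.0)
  v2 <- make_counts()
  v2[unlist(ocs$unpreferred, use.names = FALSE)] <- 2L
  expect_equal(fop(v2, ocs), 0.0)
  # 30 optimal of 60 eligible codons
  v3 <- make_counts(AAG = 30, AAA = 30)  # Lys: AAG preferred in the GC set
  expect_equal(fop(v3, ocs), 0.5)
  empty <- optimal_codon_set(list())
  expect_true(is.na(fop(v3, empty)))
})

test_that("aggregate indices: single gene pools to itself", {
  gs <- make_gene_set(list(only = random_cds(220)))
  idx <- aggregate_indices(gs)
  expect_equal(idx$pooled$enc, idx$per_gene$enc[1])
  expect_equal(idx$pooled$gc3s, idx$per_gene$gc3s[1])
})

test_that("stronger selection lowers ENC and raises FOP monotonically", {
  s_grid <- c(0, 0.5, 1, 1.5, 2)
  truth <- default_preferred_set("GC")
  stats_at <- vapply(seq_along(s_grid), function(i) {
    cfg <- simulation_config(n_genes = 60, codons_per_gene = 200,
                            s_profile = s_profile_step(s_grid[i], s_grid[i], 0),
                            seed = 100 + i)
    gs <- simulate_gene_set(cfg)
    idx <- aggregate_indices(gs, truth)
    c(enc = idx$means[["enc"]], fop = idx$means[["fop"]])
  }, numeric(2))
  expect_gt(stats::cor(stats_at["fop", ], s_grid, method = "spearman"), 0)
  expect_lt(stats::cor(stats_at["enc", ], s_grid, method = "spearman"), 0)
  # high-S set has lower mean ENC than the neutral set
  expect_lt(stats_at["enc", 5], stats_at["enc", 1])
})

test_that("high-expression genes show stronger bias than low-expression genes", {
  cfg <- simulation_config(n_genes = 1000, codons_per_gene = 200,
                           s_profile = s_profile_step(0, 1.5, 0.75),
                           seed = 17)
  gs <- simulate_gene_set(cfg)
  ext <- expression_extremes(gs, n = 100)
  truth <- attr(gs, "truth")$preferred_set
  enc_high <- aggregate_indices(ext$high, truth)$means[["enc"]]
  enc_low <- aggregate_indices(ext$low, truth)$means[["enc"]]
  expect_lt(enc_high, enc_low)
})
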