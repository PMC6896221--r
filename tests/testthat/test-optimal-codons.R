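test_that("CA of identical usage profiles has zero inertia and coordinates", {
  m <- matrix(rep(c(3, 1, 2, 2, 4, 4), each = 5), nrow = 5)
  ca <- correspondence_analysis(m)
  expect_lt(sum(ca$inertia), 1e-20)
  expect_true(all(abs(ca$row_coords[, 1]) < 1e-10))
})

test_that("CA axis 1 separates two clusters with opposite codon preference", {
  # genes 1-5 favour codon A of a 2-fold pair, genes 6-10 favour codon B
  m <- rbind(matrix(rep(c(9, 1, 5, 5), each = 5), nrow = 5),
             matrix(rep(c(1, 9, 5, 5), each = 5), nrow = 5))
  ca <- correspondence_analysis(m)
  ax1 <- ca$row_coords[, 1]
  expect_true(all(sign(ax1[1:5]) == sign(ax1[1])))
  expect_true(all(sign(ax1[6:10]) == -sign(ax1[1])))
})

test_that("CA principal coordinates match a chi-square-distance MDS oracle", {
  set.seed(7)
  # equal row sums so the unweighted classical-MDS oracle applies exactly
  m <- matrix(stats::runif(30, 0.2, 1), 5, 6)
  m <- m / rowSums(m)
  ca <- correspondence_analysis(m)
  # oracle: classical MDS of pairwise chi-square distances between profiles
  P <- m / sum(m)
  prof <- P / rowSums(P)
  cmass <- colSums(P)
  D <- as.matrix(stats::dist(sweep(prof, 2, sqrt(cmass), "/")))
  mds <- stats::cmdscale(D, k = ncol(ca$row_coords))
  for (ax in seq_len(ncol(mds))) {
    a <- ca$row_coords[, ax]
    b <- mds[, ax]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
})

test_that("CA axis 1 agrees with vegan's correspondence analysis up to scale", {
  set.seed(8)
  m <- matrix(stats::rpois(200, 10) + 1, 20, 10)
  ca <- correspondence_analysis(m)
  cca_fit <- vegan::cca(m)
  v <- vegan::scores(cca_fit, display = "sites", choices = 1)[, 1]
  expect_gt(abs(stats::cor(ca$row_coords[, 1], v)), 1 - 1e-8)
})

test_that("simulated GC-preferred usage is recovered exactly for 2-fold families", {
  cfg <- simulation_config(n_genes = 1000, codons_per_gene = 200,
                           s_profile = s_profile_step(0, 2, 0.75), seed = 301)
  gs <- simulate_gene_set(cfg)
  ocs <- identify_optimal_codons(gs)
  truth <- attr(gs, "truth")$preferred_set
  for (aa in twofold_subset(truth)) {
    expect_identical(ocs$preferred[[aa]], truth$preferred[[aa]])
  }
  # axis-1 coordinates anticorrelate with per-gene ENC
  ca <- attr(ocs, "ca")
  counts <- codon_count_matrix(gs)
  enc_gene <- apply(counts, 1, enc)
  ct <- stats::cor.test(ca$row_coords[names(enc_gene), 1], enc_gene)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("an AT-preferred species yields an AT-rich optimal set", {
  cfg <- simulation_config(n_genes = 600, codons_per_gene = 200,
                           s_profile = s_profile_step(0, 2, 0.75),
                           preferred_set = default_preferred_set("AT"),
                           seed = 302)
  gs <- simulate_gene_set(cfg)
  ocs <- identify_optimal_codons(gs)
  expect_lt(ocs$gc3_preferred, 0.3)
  expect_equal(ocs$gc_class, "AT-rich")
})

test_that("homogeneous usage yields an empty preferred set", {
  set.seed(40)
  n <- 60
  one <- sample(.std_code$sense, 220, replace = TRUE)
  genes <- stats::setNames(rep(list(one), n), sprintf("g%02d", seq_len(n)))
  gs <- gene_set(genes)
  ocs <- identify_optimal_codons(gs)
  expect_length(ocs$preferred, 0)
})

test_that("optimal codon identification is invariant to gene order", {
  cfg <- simulation_config(n_genes = 200, codons_per_gene = 200,
                           s_profile = s_profile_step(0, 2, 0.75), seed = 303)
  gs <- simulate_gene_set(cfg)
  set.seed(1)
  perm <- sample(length(gs))
  ocs1 <- identify_optimal_codons(gs)
  ocs2 <- identify_optimal_codons(gs[perm])
  expect_equal(ocs1$preferred, ocs2$preferred)
  expect_equal(ocs1$unpreferred, ocs2$unpreferred)
})

test_that("preferred and unpreferred sets are always disjoint", {
  cfg <- simulation_config(n_genes = 100, codons_per_gene = 200, seed = 304)
  ocs <- identify_optimal_codons(simulate_gene_set(cfg))
  for (aa in union(names(ocs$preferred), names(ocs$unpreferred))) {
    expect_length(intersect(ocs$preferred[[aa]], ocs$unpreferred[[aa]]), 0)
  }
  expect_error(optimal_codon_set(list(K = "AAG"), list(K = c("AAG", "AAA"))),
               "both preferred and unpreferred")
})

test_that("GC classification bands follow the empirical gaps", {
  expect_equal(classify_preferred_gc(0.10), "AT-rich")
  expect_equal(classify_preferred_gc(1.00), "GC-rich")
  expect_equal(classify_preferred_gc(0.60), "moderate-GC")
  expect_equal(classify_preferred_gc(0.39), "AT-rich")
  expect_equal(classify_preferred_gc(0.40), "moderate-GC")
  expect_equal(classify_preferred_gc(0.75), "moderate-GC")
  expect_equal(classify_preferred_gc(0.76), "GC-rich")
})

test_that("optimal codon sets round-trip through JSON and the flag table", {
  ocs <- default_preferred_set("GC")
  jp <- tempfile(fileext = ".json")
  write_ocs_json(ocs, jp)
  back <- read_ocs_json(jp)
  expect_equal(back$preferred, ocs$preferred)
  expect_equal(back$gc3_preferred, ocs$gc3_preferred)
  tp <- tempfile(fileext = ".tsv")
  write_ocs_table(ocs, tp)
  tab <- utils::read.delim(tp)
  expect_equal(nrow(tab), 64)
  expect_equal(sum(tab$flag == "preferred"),
               length(unlist(ocs$preferred)))
  expect_equal(sum(tab$flag == "stop"), 3)
})
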