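test_that("He, pi and F_IS match their closed forms", {
  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(expected_heterozygosity(c(1, 0)), 0)
  expect_equal(expected_heterozygosity(c(0.25, 0.75)), 0.375)
  expect_error(expected_heterozygosity(c(0.2, 0.2)), "sum to 1")

  expect_equal(nucleotide_diversity(4, 0.5), 2 / 3)  # 4 of 6 pairs differ
  expect_equal(nucleotide_diversity(6, 0), 0)
  expect_equal(nucleotide_diversity(2, 0.5), 1)      # one pair, differing
  expect_error(nucleotide_diversity(1, 0.5), ">= 2")

  expect_equal(inbreeding_coefficient(0.5, 0.5), 0)
  expect_equal(inbreeding_coefficient(0, 0.5), 1)
  expect_equal(inbreeding_coefficient(0.3, 0.5), 0.4)
  expect_true(is.na(inbreeding_coefficient(numeric(0), numeric(0))))
})

test_that("He and pi are invariant under allele-label swap", {
  tab <- random_toy_table(21, n_ind = 10, missing = 0.1)
  st1 <- diversity_stats(tab)
  swapped <- tab
  swapped$geno <- 2L - tab$geno
  st2 <- diversity_stats(swapped)
  expect_equal(st1$He, st2$He)
  expect_equal(st1$pi, st2$pi)
  expect_equal(st1$Fis, st2$Fis)
})

test_that("populations fixed for alternate alleles give F_ST = 1", {
  g <- rbind(matrix(0L, 3, 5), matrix(2L, 3, 5))
  expect_equal(fst_wc(g, rep(c("A", "B"), each = 3)), 1)
})

test_that("F_ST equals the aov variance-components oracle on toy tables", {
  for (s in 1:25) {
    tab <- random_toy_table(400 + s, n_ind = 10, missing = 0.1)
    got <- fst_wc(tab$geno, tab$population_ids)
    want <- oracle_fst_aov(tab$geno, tab$population_ids)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("two samples from one panmictic population give F_ST near zero", {
  tab <- simulate_genotypes_with_missingness(
    single_pop_model(5000), sample_sizes = 24, n_loci = 5000,
    snps_per_locus = 1, missing_rate = 0, seed = 31)
  grp <- rep(c("A", "B"), each = 12)
  expect_lt(abs(fst_wc(tab$geno, grp)), 0.01)
})

test_that("long divergence without migration pushes F_ST towards one", {
  tab <- simulate_genotypes_with_missingness(
    two_pop_split(T_split = 2e5, N = 1000, n_anc = 1000),
    sample_sizes = c(10, 10), n_loci = 800, snps_per_locus = 1,
    missing_rate = 0, seed = 32)
  fst <- pairwise_fst(tab)
  expect_gt(fst["pop1", "pop2"], 0.8)
})

test_that("PCA separates simulated populations and reports variance", {
  tab <- simulate_genotypes_with_missingness(
    two_pop_split(T_split = 2000, N = 5000, n_anc = 5000),
    sample_sizes = c(20, 20), n_loci = 500, snps_per_locus = 1,
    missing_rate = 0.1, seed = 33)
  sc <- pca_scores(tab, n_components = 4)
  lab <- as.integer(factor(tab$population_ids))
  r <- abs(stats::cor(sc$scores[, 1], lab))
  expect_gt(r, 0.9)
  expect_true(all(diff(sc$explained) <= 1e-12))
  expect_lte(sum(sc$explained), 1 + 1e-8)
  # duplicated individual lands on identical coordinates
  dup <- subset_table(tab, individuals = c(1, 1, 2:10))
  sc2 <- pca_scores(dup, 2)
  expect_equal(sc2$scores[1, ], sc2$scores[2, ])
})

test_that("PCA on all-monomorphic input is fatal", {
  tab <- genotype_table(matrix(1L, 4, 3), paste0("i", 1:4), rep("x", 4))
  expect_error(pca_scores(tab), "monomorphic")
})

test_that("subsampled statistics behave as specified", {
  tab <- random_toy_table(55, n_ind = 12, n_loci = 6, snps_per_locus = 2,
                          missing = 0.05)
  out <- subsampled_stats(tab, n_per_locality = 4, replicates = 20, seed = 2)
  expect_equal(nrow(out$replicates), 20 * length(unique(tab$locality_ids)))
  expect_equal(max(out$replicates$replicate), 20)
  # a locality with exactly n_per_locality individuals: replicates identical
  small <- subset_table(tab, individuals = which(tab$locality_ids == "pop1")[1:4])
  out2 <- subsampled_stats(small, n_per_locality = 4, replicates = 5, seed = 3)
  expect_equal(length(unique(out2$replicates$He)), 1L)
  # undersized locality flagged, not dropped
  out3 <- subsampled_stats(small, n_per_locality = 10, replicates = 3, seed = 4)
  expect_true("pop1" %in% out3$flagged)
})

test_that("median subsampled He tracks the full-sample value under panmixia", {
  tab <- simulate_genotypes_with_missingness(
    single_pop_model(5000), sample_sizes = 16, n_loci = 800,
    snps_per_locus = 1, missing_rate = 0, seed = 44)
  full <- diversity_stats(tab)
  sub <- subsampled_stats(tab, n_per_locality = 4, replicates = 20, seed = 5)
  agree <- abs(sub$medians$He - full$He[match(sub$medians$group, full$group)])
  expect_true(all(agree < 0.05))
})
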