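test_that("per-locus Watterson theta matches hand-computed values", {
  # locus L1: 2 polymorphic sites, 2 individuals all called -> n_hap 4,
  # a = 1 + 1/2 + 1/3 = 11/6, theta = 2 / (11/6) = 12/11
  g <- rbind(c(0L, 1L, 0L), c(1L, 2L, 0L))
  tab <- genotype_table(g, c("a", "b"), c("x", "x"),
                        sites = data.frame(locus_id = c("L1", "L1", "L2"),
                                           pos = c(0L, 1L, 0L)))
  rec <- per_locus_theta(tab)
  expect_equal(rec$S[rec$locus_id == "L1"], 2L)
  expect_equal(rec$n_hap[rec$locus_id == "L1"], 4L)
  expect_equal(rec$theta_w[rec$locus_id == "L1"], 12 / 11)
  # monomorphic locus: S = 0 -> theta 0
  expect_equal(rec$theta_w[rec$locus_id == "L2"], 0)
})

test_that("theta with two haplotypes uses a = 1", {
  g <- matrix(c(0L, 2L, 1L, 1L, 0L, 1L, 2L, 0L, 1L, 0L), 1, 10)
  tab <- genotype_table(g, "a", "x",
                        sites = data.frame(locus_id = rep("L", 10),
                                           pos = 0:9))
  rec <- per_locus_theta(tab)
  # single diploid: n_hap = 2, every non-monomorphic site counts into S
  expect_equal(rec$n_hap, 2L)
  expect_equal(rec$theta_w, rec$S / 1)
})

test_that("loci with fewer than two genotyped haplotypes are flagged", {
  g <- matrix(NA_integer_, 2, 1)
  tab <- genotype_table(g, c("a", "b"), c("x", "x"),
                        sites = data.frame(locus_id = "L0", pos = 0L))
  rec <- per_locus_theta(tab)
  expect_false(rec$valid)
  expect_true(is.na(rec$theta_w))
  expect_error(whitelist_by_quantile(rec), "no valid")
})

test_that("95% quantile whitelist keeps 95 of theta values 1..100", {
  rec <- data.frame(locus_id = paste0("L", 1:100), S = 1L, n_hap = 4L,
                    theta_w = as.numeric(1:100), valid = TRUE)
  wl <- whitelist_by_quantile(rec, 0.95)
  expect_length(wl, 95)
  expect_equal(attr(wl, "cutoff"), 95.05)
  expect_setequal(attr(wl, "excluded"), paste0("L", 96:100))
  # all-equal thetas: everything retained; single locus retained
  rec2 <- rec; rec2$theta_w <- 1
  expect_length(whitelist_by_quantile(rec2, 0.95), 100)
  expect_length(whitelist_by_quantile(rec[1, ], 0.95), 1)
})

test_that("whitelist size is monotone non-decreasing in q", {
  set.seed(3)
  rec <- data.frame(locus_id = paste0("L", 1:60), S = 1L, n_hap = 6L,
                    theta_w = rexp(60), valid = TRUE)
  sizes <- vapply(c(0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 1),
                  function(q) length(whitelist_by_quantile(rec, q)),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("missingness filters drop sites then individuals by hand counts", {
  # per-site missing fractions 0, 1/3, 2/3, 1 -> only the last exceeds 0.70
  g <- rbind(c(0L, 1L, NA, NA), c(0L, 0L, NA, NA), c(1L, NA, 0L, NA))
  tab <- genotype_table(g, paste0("i", 1:3), rep("x", 3))
  out <- filter_missingness(tab)
  expect_equal(ncol(out$geno), 3L)
  expect_equal(attr(out, "n_sites_dropped"), 1L)
  expect_equal(attr(out, "n_individuals_dropped"), 0L)

  # individual missing all surviving sites (fraction 1 > 0.90) is dropped
  g2 <- rbind(c(NA, NA), c(0L, 1L), c(1L, 0L))
  tab2 <- genotype_table(g2, paste0("i", 1:3), rep("x", 3))
  out2 <- filter_missingness(tab2)
  expect_equal(nrow(out2$geno), 2L)
  expect_equal(attr(out2, "n_individuals_dropped"), 1L)
  expect_false("i1" %in% out2$individual_ids)

  # no missing data: unchanged
  tab3 <- random_toy_table(5, missing = 0)
  out3 <- filter_missingness(tab3)
  expect_identical(out3$geno, tab3$geno)
})

test_that("filtering is idempotent", {
  tab <- random_toy_table(11, n_ind = 10, missing = 0.4)
  once <- filter_missingness(tab, 0.5, 0.6)
  twice <- filter_missingness(once, 0.5, 0.6)
  expect_identical(once$geno, twice$geno)
  expect_equal(attr(twice, "n_sites_dropped"), 0L)
  expect_equal(attr(twice, "n_individuals_dropped"), 0L)
})

test_that("everything filtered is a fatal diagnostic", {
  g <- matrix(NA_integer_, 3, 3)
  g[1, 1] <- 0L
  tab <- genotype_table(g, paste0("i", 1:3), rep("x", 3))
  expect_error(filter_missingness(tab, 0.1, 0.1), "removed everything")
})

test_that("one SNP per locus keeps one site per locus, reproducibly", {
  tab <- random_toy_table(2, n_ind = 4, n_loci = 100, snps_per_locus = 3,
                          missing = 0)
  thin1 <- one_snp_per_locus(tab, seed = 9)
  expect_equal(ncol(thin1$geno), 100L)
  expect_equal(sort(unique(thin1$sites$locus_id)),
               sort(unique(tab$sites$locus_id)))
  expect_true(all(table(thin1$sites$locus_id) == 1))
  thin2 <- one_snp_per_locus(tab, seed = 9)
  expect_identical(thin1$sites, thin2$sites)
  thin3 <- one_snp_per_locus(tab, seed = 10)
  expect_false(identical(thin1$sites, thin3$sites))
  # single-SNP locus keeps its only site
  one <- subset_table(tab, sites = 1)
  expect_equal(one_snp_per_locus(one, seed = 1)$sites$pos, one$sites$pos)
})
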