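test_that("single-population TMRCA and tree length match coalescent theory", {
  N <- 1000
  tt <- simulate_tmrca(single_pop_model(N), 2, 10000, seed = 1)
  # n = 2: E[TMRCA] = 2N, E[total length] = 4N
  expect_lt(abs(mean(tt$tmrca) - 2 * N), 3 * mc_se(tt$tmrca))
  expect_lt(abs(mean(tt$total_length) - 4 * N), 3 * mc_se(tt$total_length))
  # n = 6: E[total length] = 4N * sum(1/k), k = 1..5
  t6 <- simulate_tmrca(single_pop_model(N), 6, 10000, seed = 2)
  expect_lt(abs(mean(t6$total_length) - 4 * N * sum(1 / (1:5))),
            3 * mc_se(t6$total_length))
})

test_that("lineages split without migration cannot coalesce before the merge", {
  tt <- simulate_tmrca(two_pop_split(5000, N = 500, n_anc = 500), c(1, 1),
                       500, seed = 3)
  expect_true(all(tt$tmrca > 5000))
})

test_that("genealogies are reproducible and returned as valid phylo trees", {
  md <- demographic_model(3, bluebunch_params(3))
  tr1 <- simulate_genealogy(md, c(4, 4, 4, 4), seed = 5)
  tr2 <- simulate_genealogy(md, c(4, 4, 4, 4), seed = 5)
  expect_s3_class(tr1, "phylo")
  expect_equal(ape::Ntip(tr1), 16)
  expect_identical(tr1$edge, tr2$edge)
  expect_identical(tr1$edge.length, tr2$edge.length)
  expect_true(ape::is.binary(tr1))
  expect_true(ape::is.ultrametric(tr1, tol = 0.01))
  # total branch length consistent with the attribute
  expect_equal(sum(tr1$edge.length), attr(tr1, "total_length"),
               tolerance = 1e-9)
})

test_that("the folded single-population SFS follows the 1/i law", {
  # n = 4: folded mass proportional to (1 + 1/3, 1/2) = (8/11, 3/11)
  eb <- expected_branch_sfs(single_pop_model(2000), 4, 20000, seed = 6)
  marg <- eb$marginal[[1]]
  folded <- c(marg[2] + marg[4], marg[3]) / sum(marg[2:4])
  expect_equal(folded, c(8 / 11, 3 / 11), tolerance = 0.02)
  sim <- simulate_sfs(single_pop_model(2000), 4, 50000, seed = 7)
  k <- pmin(sim$configs[, 1], 4 - sim$configs[, 1])
  prop <- tabulate(k, 2) / sum(k > 0)
  se <- sqrt(8 / 11 * 3 / 11 / 50000)
  expect_lt(abs(prop[1] - 8 / 11), 3 * se + 1e-3)
})

test_that("mutation placement conditions every SNP on polymorphism", {
  sim <- simulate_sfs(two_pop_split(3000, N = 2000), c(6, 6), 3000, seed = 8)
  tot <- rowSums(sim$configs)
  expect_true(all(tot >= 1 & tot <= 11))
  expect_identical(sim$configs,
                   simulate_sfs(two_pop_split(3000, N = 2000), c(6, 6), 3000,
                                seed = 8)$configs)
})

test_that("long-isolated populations accumulate private polymorphism", {
  sim <- simulate_sfs(two_pop_split(5e4, N = 1000, n_anc = 1000), c(6, 6),
                      4000, seed = 9)
  private <- sim$configs[, 1] == 0 | sim$configs[, 2] == 0 |
             sim$configs[, 1] == 6 | sim$configs[, 2] == 6
  expect_gt(mean(private), 0.9)
})

test_that("high symmetric migration converges to the panmictic joint SFS", {
  # island model: TV distance to the panmictic spectrum shrinks as 2Nm grows
  tv <- vapply(c(0.5, 5, 50), function(twoNm) {
    m <- twoNm / (2 * 2000)
    island <- list(n_demes = 2L, event_times = 1e7, event_src = 1L,
                   event_dst = 0L, sizes = rbind(c(2000, 2000), c(2000, 2000)),
                   mig = c(0, m, m, 0, 0, 0, 0, 0))
    pan <- two_pop_split(1, N = 2000, n_anc = 2000)
    pi_ <- estimate_expected_sfs(island, c(6, 6), 30000, seed = 10)[["pop1|pop2"]]
    pp <- estimate_expected_sfs(pan, c(6, 6), 30000, seed = 10)[["pop1|pop2"]]
    sum(abs(pi_ - pp)) / 2
  }, numeric(1))
  expect_true(all(diff(tv) < 0))
  expect_lt(tv[3], 0.05)
})

test_that("genotype simulation pairs haplotypes and applies missingness", {
  md <- demographic_model(3, bluebunch_params(3))
  tab <- simulate_genotypes_with_missingness(md, c(4, 4, 4, 4), n_loci = 300,
                                             snps_per_locus = 2,
                                             missing_rate = 0.3, seed = 11)
  expect_equal(dim(tab$geno), c(16L, 600L))
  expect_equal(as.integer(table(tab$population_ids)[c("WAS", "EGB", "PW", "WGB")]),
               rep(4L, 4))
  expect_equal(length(unique(tab$sites$locus_id)), 300L)
  miss <- mean(is.na(tab$geno))
  se <- sqrt(0.3 * 0.7 / length(tab$geno))
  expect_lt(abs(miss - 0.3), 3 * se)
  none <- simulate_genotypes_with_missingness(md, c(2, 2, 2, 2), 50, 1,
                                              missing_rate = 0, seed = 12)
  expect_equal(sum(is.na(none$geno)), 0L)
  all_m <- simulate_genotypes_with_missingness(md, c(2, 2, 2, 2), 50, 1,
                                               missing_rate = 1, seed = 13)
  expect_true(all(is.na(all_m$geno)))
})

test_that("sequence mode reproduces theta_pi = 4*N*mu", {
  # per-site mutation input kept small so recurrent-mutation (finite-sites)
  # bias stays far below Monte-Carlo error
  N <- 1000; mu <- 2e-6; L <- 500; n_loci <- 300
  hap <- simulate_sequences(single_pop_model(N), 10, n_loci, L, mu, seed = 14)
  per_locus <- vapply(seq_len(n_loci), function(l) {
    cols <- ((l - 1) * L + 1):(l * L)
    haplotype_pi(hap[, cols, drop = FALSE], L)
  }, numeric(1))
  expect_lt(abs(mean(per_locus) - 4 * N * mu), 3 * mc_se(per_locus))
})

test_that("between-population divergence matches 4*N_anc*mu + 2*T*mu", {
  N <- 1000; Tsplit <- 2000; mu <- 1e-6; L <- 500; n_loci <- 500
  hap <- simulate_sequences(two_pop_split(Tsplit, N = N, n_anc = N),
                            c(1, 1), n_loci, L, mu, seed = 15)
  per_locus <- vapply(seq_len(n_loci), function(l) {
    cols <- ((l - 1) * L + 1):(l * L)
    mean(hap[1, cols] != hap[2, cols])
  }, numeric(1))
  expect_lt(abs(mean(per_locus) - (4 * N * mu + 2 * Tsplit * mu)),
            3 * mc_se(per_locus))
})

test_that("the joint SFS agrees with an independent coalescent engine", {
  # msprime as external oracle: expected branch-length joint spectra for the
  # stepping-stone model at the published point estimates
  p <- bluebunch_params(3)
  py <- sprintf('
import json, msprime, numpy as np
p = dict(N_1=%f, N_2=%f, N_WAS=%f, N_EGB=%f, N_PW=%f, N_WGB=%f,
         T_1=%f, T_2=%f, T_3=%f, m_we=%f, m_ew=%f, m_ep=%f, m_pe=%f,
         m_pw=%f, m_wp=%f)
dem = msprime.Demography()
for name, size in [("WAS", p["N_WAS"]), ("EGB", p["N_EGB"]),
                   ("PW", p["N_PW"]), ("WGB", p["N_WGB"]),
                   ("ANC1", p["N_1"]), ("ANC2", p["N_2"]),
                   ("ROOT", 60000)]:
    dem.add_population(name=name, initial_size=size)
dem.set_migration_rate("WAS", "EGB", p["m_we"] / (2 * p["N_WAS"]))
dem.set_migration_rate("EGB", "WAS", p["m_ew"] / (2 * p["N_EGB"]))
dem.set_migration_rate("EGB", "PW", p["m_ep"] / (2 * p["N_EGB"]))
dem.set_migration_rate("PW", "EGB", p["m_pe"] / (2 * p["N_PW"]))
dem.set_migration_rate("PW", "WGB", p["m_pw"] / (2 * p["N_PW"]))
dem.set_migration_rate("WGB", "PW", p["m_wp"] / (2 * p["N_WGB"]))
dem.add_population_split(time=p["T_1"], derived=["PW", "WGB"], ancestral="ANC1")
dem.add_population_split(time=p["T_2"], derived=["ANC1", "EGB"], ancestral="ANC2")
dem.add_population_split(time=p["T_3"], derived=["ANC2", "WAS"], ancestral="ROOT")
dem.sort_events()
n = 8
afs_pw = np.zeros((n + 1, n + 1))
afs_we = np.zeros((n + 1, n + 1))
reps = msprime.sim_ancestry(
    samples={"WAS": 4, "EGB": 4, "PW": 4, "WGB": 4}, demography=dem,
    ploidy=2, num_replicates=3000, random_seed=7)
for ts in reps:
    sets = [ts.samples(population=i) for i in range(4)]
    afs_pw += ts.allele_frequency_spectrum([sets[2], sets[3]], mode="branch",
                                           polarised=True, span_normalise=False)
    afs_we += ts.allele_frequency_spectrum([sets[0], sets[1]], mode="branch",
                                           polarised=True, span_normalise=False)
print(json.dumps({"pw": afs_pw.tolist(), "we": afs_we.tolist()}))
', p[["N_1"]], p[["N_2"]], p[["N_WAS"]], p[["N_EGB"]], p[["N_PW"]],
   p[["N_WGB"]], p[["T_1"]], p[["T_2"]], p[["T_3"]], p[["m_we"]],
   p[["m_ew"]], p[["m_ep"]], p[["m_pe"]], p[["m_pw"]], p[["m_wp"]])
  script <- tempfile(fileext = ".py")
  writeLines(py, script)
  out <- system2("python", script, stdout = TRUE, stderr = FALSE)
  ref <- jsonlite::fromJSON(paste(out, collapse = ""))

  md <- demographic_model(3, p)
  probs <- estimate_expected_sfs(md, c(8, 8, 8, 8), 30000, seed = 16)
  norm_fold <- function(U) {
    Fm <- fold_matrix(U, 8, 8)
    mask <- folded_joint_sfs(Fm, "A", "B", 8, 8)$mask
    Fm[mask] <- 0
    Fm / sum(Fm)
  }
  for (pair in list(c("PW|WGB", "pw"), c("WAS|EGB", "we"))) {
    ours <- probs[[pair[1]]]
    theirs <- norm_fold(ref[[pair[2]]])
    tv <- sum(abs(ours - theirs)) / 2
    expect_lt(tv, 0.05)
  }
})
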