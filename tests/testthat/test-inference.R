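# small folded SFS with known unmasked cells for likelihood arithmetic
toy_obs <- function(c01, c10) {
  counts <- matrix(0, 3, 3)
  counts[1, 2] <- c01  # configuration (0, 1)
  counts[2, 1] <- c10  # configuration (1, 0)
  folded_joint_sfs(counts, "pop1", "pop2", 2, 2)
}

test_that("composite log-likelihood reproduces multinomial arithmetic", {
  obs <- toy_obs(10, 30)
  p <- matrix(0, 3, 3); p[1, 2] <- 0.25; p[2, 1] <- 0.75
  expect_equal(composite_log_likelihood(obs, p),
               10 * log(0.25) + 30 * log(0.75), tolerance = 1e-10)
  expect_equal(round(composite_log_likelihood(obs, p), 4), -22.4934)
  # all mass on one cell with probability one
  obs1 <- toy_obs(40, 0)
  p1 <- matrix(0, 3, 3); p1[1, 2] <- 1
  expect_equal(composite_log_likelihood(obs1, p1), 0)
  expect_error(composite_log_likelihood(obs, matrix(0.5, 2, 2)),
               "shapes")
})

test_that("the multinomial MLE maximises the composite likelihood", {
  set.seed(12)
  counts <- matrix(0, 3, 3)
  cells <- rbind(c(1, 2), c(2, 1), c(1, 3), c(2, 2), c(3, 1))
  counts[cells] <- c(12, 30, 7, 20, 5)
  obs <- folded_joint_sfs(counts, "pop1", "pop2", 2, 2)
  phat <- matrix(0, 3, 3)
  phat[!obs$mask] <- counts[!obs$mask] / sum(counts[!obs$mask])
  ll_hat <- composite_log_likelihood(obs, phat)
  for (r in 1:30) {
    q <- matrix(0, 3, 3)
    w <- rexp(sum(!obs$mask))
    q[!obs$mask] <- w / sum(w)
    expect_lte(composite_log_likelihood(obs, q), ll_hat + 1e-9)
  }
})

test_that("expected SFS probabilities are normalised, floored, reproducible", {
  md <- two_pop_split(3000, N = 2000)
  p1 <- estimate_expected_sfs(md, c(6, 6), 4000, seed = 21)
  p2 <- estimate_expected_sfs(md, c(6, 6), 4000, seed = 21)
  expect_identical(p1, p2)
  mask <- folded_joint_sfs(p1[["pop1|pop2"]], "a", "b", 6, 6)$mask
  expect_equal(sum(p1[["pop1|pop2"]][!mask]), 1, tolerance = 1e-12)
  expect_true(all(p1[["pop1|pop2"]][!mask] >= 0.1 / 4000 / 2))
  # Monte-Carlo convergence: estimates at 1e4 and 1e5 sims agree closely
  lo <- estimate_expected_sfs(md, c(6, 6), 1e4, seed = 22)[["pop1|pop2"]]
  hi <- estimate_expected_sfs(md, c(6, 6), 1e5, seed = 23)[["pop1|pop2"]]
  expect_lt(sum(abs(lo - hi)) / 2, 0.02)
})

test_that("single-parameter fits recover a known split time", {
  truth <- 8000
  builder <- split_time_builder(N = 10000, n_anc = 10000)
  sim <- simulate_sfs(builder(c(T_split = truth), NULL), c(8, 8), 2000,
                      seed = 24)
  fit <- ecm_fit(sim$sfs, builder = builder, param_names = "T_split",
                 init = c(T_split = 2000), n_cycles = 5, n_sims = 2000,
                 seed = 25, crn_fixed = TRUE,
                 search_ranges = data.frame(lo = 500, hi = 6e4,
                                            row.names = "T_split"))
  expect_lt(abs(fit$params[["T_split"]] / truth - 1), 0.10)
})

test_that("lnCL is non-decreasing across cycles under common random numbers", {
  builder <- function(params, n_anc)
    two_pop_split(params[["T_split"]], N = params[["N"]], n_anc = 10000)
  sim <- simulate_sfs(builder(c(T_split = 5000, N = 8000), NULL), c(6, 6),
                      800, seed = 26)
  fit <- ecm_fit(sim$sfs, builder = builder,
                 param_names = c("T_split", "N"),
                 init = c(T_split = 1000, N = 2000), n_cycles = 5,
                 n_sims = 600, seed = 27, crn_fixed = TRUE, tol = -1,
                 polish = FALSE,
                 search_ranges = data.frame(lo = c(300, 500),
                                            hi = c(5e4, 1e5),
                                            row.names = c("T_split", "N")))
  expect_true(all(diff(fit$trajectory) >= -1e-8))
})

test_that("a degenerate observed SFS with no polymorphic SNPs is fatal", {
  counts <- matrix(0, 3, 3)
  counts[1, 1] <- 50
  obs <- list(`pop1|pop2` = folded_joint_sfs(counts, "pop1", "pop2", 2, 2))
  expect_error(ecm_fit(obs, builder = split_time_builder(),
                       param_names = "T_split", n_sims = 100),
               "no polymorphic")
})

test_that("the best of several runs dominates and is deterministic", {
  builder <- split_time_builder()
  sim <- simulate_sfs(builder(c(T_split = 6000), NULL), c(6, 6), 500,
                      seed = 28)
  args <- list(sim$sfs, builder = builder, param_names = "T_split",
               n_runs = 2, n_cycles = 2, n_sims = 400, seed = 29,
               search_ranges = data.frame(lo = 500, hi = 5e4,
                                          row.names = "T_split"))
  fit1 <- do.call(multi_run_fit, args)
  fit2 <- do.call(multi_run_fit, args)
  expect_true(all(fit1$lnCL >= fit1$runs$lnCL_common - 1e-9))
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$lnCL, fit2$lnCL)
  # AIC recomputed from lnCL with k free parameters
  expect_equal(fit1$AIC, 2 * 1 - 2 * fit1$lnCL)
  expect_equal(fit1$log10CL, fit1$lnCL / log(10))
})

test_that("AIC ranking orders models and reports relative likelihoods", {
  stub <- function(id, aic, ll) {
    structure(list(model_id = id, k = 15, lnCL = ll, AIC = aic,
                   observed_signature = c(a = 100, b = 200)),
              class = "fit_result")
  }
  # the three published AIC values rank the stepping-stone model first and
  # give its rivals relative likelihood 0 to double precision
  fits <- list(stub(1, 149266, -(149266 - 30) / 2),
               stub(2, 149388, -(149388 - 30) / 2),
               stub(3, 148750, -(148750 - 30) / 2))
  tab <- aic_select(fits)
  expect_equal(tab$model_id, c("3", "1", "2"))
  expect_equal(tab$delta_AIC, c(0, 516, 638))
  expect_equal(tab$relative_likelihood[1], 1)
  expect_lt(tab$relative_likelihood[2], 1e-100)
  # exact ties give relative likelihood one for both
  tied <- aic_select(list(stub(1, 100, -35), stub(2, 100, -35)))
  expect_equal(tied$relative_likelihood, c(1, 1))
  # refusing to rank fits of different data
  other <- stub(2, 90, -30)
  other$observed_signature <- c(a = 1, b = 2)
  expect_error(aic_select(list(stub(1, 100, -35), other)), "different")
})

test_that("percentile intervals use linear-interpolation quantiles", {
  expect_equal(percentile_ci(1:100), c(3.475, 97.525))
  expect_equal(percentile_ci(c(5, 5, 5)), c(5, 5))
})

test_that("parametric bootstrap returns intervals around the estimate", {
  builder <- split_time_builder()
  truth <- 6000
  sim <- simulate_sfs(builder(c(T_split = truth), NULL), c(8, 8), 400,
                      seed = 31)
  rng <- data.frame(lo = 500, hi = 5e4, row.names = "T_split")
  fit <- multi_run_fit(sim$sfs, builder = builder, param_names = "T_split",
                       n_runs = 1, n_cycles = 3, n_sims = 500, seed = 32,
                       search_ranges = rng)
  expect_warning(
    boot <- parametric_bootstrap(fit, n_snps = 400, n_reps = 1, runs = 1,
                                 cycles = 2, n_sims = 300, seed = 33),
    "degenerate")
  expect_equal(boot$ci[1, "lower"], boot$ci[1, "upper"])
  boot2 <- parametric_bootstrap(fit, n_snps = 400, n_reps = 12, runs = 1,
                                cycles = 2, n_sims = 300, seed = 34)
  expect_equal(nrow(boot2$estimates), 12)
  expect_lt(boot2$ci[1, "lower"], boot2$ci[1, "upper"])
  expect_equal(boot2$n_failed, 0)
})
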