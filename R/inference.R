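.deme_labels <- function(K) {
  if (K == 4) c("WAS", "EGB", "PW", "WGB") else paste0("pop", seq_len(K))
}

# haploid sample size per deme implied by a named list of folded joint SFS
.sizes_from_observed <- function(observed) {
  ss <- c()
  for (s in observed) {
    for (side in list(c(s$popA, s$nA), c(s$popB, s$nB))) {
      lab <- side[1]; n <- as.integer(side[2])
      if (lab %in% names(ss) && ss[[lab]] != n)
        stop("inconsistent haplotype sizes for population ", lab)
      ss[lab] <- n
    }
  }
  ss
}

# full-length, deme-ordered haploid sample sizes for the simulator
.ordered_sizes <- function(observed) {
  ss_named <- .sizes_from_observed(observed)
  four <- c("WAS", "EGB", "PW", "WGB")
  if (all(names(ss_named) %in% four)) {
    K <- 4L
  } else if (all(grepl("^pop[0-9]+$", names(ss_named)))) {
    K <- max(as.integer(sub("^pop", "", names(ss_named))))
  } else {
    stop("observed pairs name unknown populations: ",
         paste(names(ss_named), collapse = ", "))
  }
  labels <- .deme_labels(K)
  ss <- structure(rep(0L, K), names = labels)
  ss[names(ss_named)] <- ss_named
  ss
}

#' Composite log-likelihood of folded joint SFS counts
#'
#' lnCL = sum over pairs and unmasked configurations of
#' count * log(probability); sites are treated as independent, so this is a
#' sum of per-SNP multinomial log-probabilities (a composite likelihood:
#' valid for point estimation, not for analytic standard errors).
#'
#' @param observed named list of [folded_joint_sfs()] (or a single one).
#' @param expected_probs named list of matching probability matrices (masked
#'   cells zero, unmasked summing to 1), as from [estimate_expected_sfs()].
#' @return lnCL (natural log).
#' @export
composite_log_likelihood <- function(observed, expected_probs) {
  if (inherits(observed, "folded_joint_sfs")) observed <- list(observed)
  if (is.matrix(expected_probs)) expected_probs <- list(expected_probs)
  if (length(observed) != length(expected_probs))
    stop("observed and expected pair lists differ in length")
  if (!is.null(names(observed)) && !is.null(names(expected_probs)))
    expected_probs <- expected_probs[names(observed)]
  ll <- 0
  for (k in seq_along(observed)) {
    o <- observed[[k]]; p <- expected_probs[[k]]
    if (!all(dim(o$counts) == dim(p)))
      stop("observed and expected SFS shapes do not match")
    use <- !o$mask & o$counts > 0
    ll <- ll + sum(o$counts[use] * log(p[use]))
  }
  ll
}

#' Monte-Carlo expected SFS probabilities for a model
#'
#' Runs the branch-length-weighted simulator ([expected_branch_sfs()]),
#' folds each pair's spectrum, masks the pair-monomorphic cells, renormalises
#' over the polymorphic configurations and floors empty cells at
#' p_min = 0.1 / n_sims (then renormalises again) so that configurations
#' unseen in a finite simulation never contribute -Inf to the likelihood.
#'
#' @param model a [demographic_model()] (or epoch list).
#' @param sample_sizes haploid sample size per deme.
#' @param n_sims number of simulated genealogies (>= 1000 recommended).
#' @param seed integer seed (fixing it gives identical estimates).
#' @return named list of probability matrices over folded configurations.
#' @export
estimate_expected_sfs <- function(model, sample_sizes, n_sims, seed = NULL) {
  br <- expected_branch_sfs(model, sample_sizes, n_sims, seed = seed)
  floor_p <- 0.1 / n_sims
  out <- lapply(seq_along(br$pair_lengths), function(k) {
    U <- br$pair_lengths[[k]]
    nA <- nrow(U) - 1L; nB <- ncol(U) - 1L
    F <- fold_matrix(U, nA, nB)
    mask <- folded_joint_sfs(F, "A", "B", nA, nB)$mask
    p <- matrix(0, nA + 1, nB + 1)
    tot <- sum(F[!mask])
    if (tot <= 0) stop("no polymorphic mass simulated for a pair")
    p[!mask] <- F[!mask] / tot
    z <- !mask & p < floor_p
    p[z] <- floor_p
    p[!mask] <- p[!mask] / sum(p[!mask])
    p
  })
  names(out) <- names(br$pair_lengths)
  out
}

.default_ranges <- function(par_names) {
  lo <- ifelse(grepl("^N_", par_names), 1e2,
               ifelse(grepl("^T_", par_names), 1e2, 1e-3))
  hi <- ifelse(grepl("^N_", par_names), 1e6,
               ifelse(grepl("^T_", par_names), 1e5, 1e2))
  data.frame(param = par_names, lo = lo, hi = hi,
             row.names = par_names, stringsAsFactors = FALSE)
}

# bounds for one parameter given the others (keeps merge times ordered)
.param_bounds <- function(pname, params, ranges, model_id) {
  lo <- ranges[pname, "lo"]; hi <- ranges[pname, "hi"]
  eps <- 1.001
  if (!is.null(model_id) && model_id %in% 2:3) {
    if (pname == "T_1") hi <- min(hi, params[["T_2"]] / eps)
    if (pname == "T_2") { lo <- max(lo, params[["T_1"]] * eps)
                          hi <- min(hi, params[["T_3"]] / eps) }
    if (pname == "T_3") lo <- max(lo, params[["T_2"]] * eps)
  } else if (!is.null(model_id) && model_id == 1) {
    if (pname %in% c("T_1", "T_2")) hi <- min(hi, params[["T_3"]] / eps)
    if (pname == "T_3") lo <- max(lo, eps * max(params[["T_1"]], params[["T_2"]]))
  }
  c(lo = lo, hi = hi)
}

# golden-section maximisation in log space; returns best evaluated point
.golden_max <- function(f, lo, hi, n_iter) {
  gr <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  if (!is.finite(a) || !is.finite(b) || a >= b)
    return(list(x = sqrt(lo * hi), f = -Inf))
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(exp(x1)); f2 <- f(exp(x2))
  best <- if (f1 >= f2) c(x1, f1) else c(x2, f2)
  for (i in seq_len(n_iter)) {
    if (f1 >= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(exp(x1))
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(exp(x2))
    }
    if (f1 > best[2]) best <- c(x1, f1)
    if (f2 > best[2]) best <- c(x2, f2)
  }
  list(x = exp(best[1]), f = best[2])
}

# robust conditional 1-D maximisation: coarse log-spaced scan to locate the
# best basin (conditional slices can be multimodal when other parameters are
# off), then golden-section refinement inside the bracketing interval
.line_max <- function(f, lo, hi, n_grid = 7, n_refine = 4) {
  if (!is.finite(log(lo)) || !is.finite(log(hi)) || lo >= hi)
    return(list(x = sqrt(lo * hi), f = -Inf))
  xs <- exp(seq(log(lo), log(hi), length.out = n_grid))
  fs <- vapply(xs, f, numeric(1))
  i <- which.max(fs)
  blo <- xs[max(1, i - 1)]; bhi <- xs[min(n_grid, i + 1)]
  ref <- .golden_max(f, blo, bhi, n_refine)
  if (is.finite(fs[i]) && fs[i] >= ref$f) list(x = xs[i], f = fs[i]) else ref
}

#' Fit a demographic model by expectation-conditional-maximisation cycles
#'
#' Coordinate ascent on the composite log-likelihood: each cycle sweeps the
#' free parameters one at a time, maximising lnCL by a bounded golden-section
#' search in log space while the others are held fixed.  Every likelihood
#' evaluation re-estimates the expected SFS by simulation; within a cycle all
#' evaluations share one RNG seed (common random numbers), which makes the
#' sweep a true ascent despite Monte-Carlo noise.  Cycling stops after
#' `n_cycles` or when a full cycle gains less than `tol` log-units.
#'
#' @param observed named list of [folded_joint_sfs()] (the data).
#' @param model_id 1, 2 or 3 (four-population histories), or `NULL` when a
#'   `builder` is supplied.
#' @param search_ranges data.frame with rownames = parameter names and
#'   columns `lo`, `hi`; defaults to N in \[1e2, 1e6\], T in \[1e2, 1e5\],
#'   2Nm in \[1e-3, 1e2\].
#' @param n_cycles maximum ECM cycles (default 40).
#' @param n_sims simulated genealogies per likelihood evaluation.
#' @param seed integer seed (drives initial point and per-cycle streams).
#' @param init named starting vector; drawn log-uniformly from the ranges if
#'   `NULL`.
#' @param free names of parameters to optimise (others stay at `init`).
#' @param n_anc fixed ancestral size.
#' @param mu,gen_time mutation rate and generation time (bookkeeping only;
#'   the SFS likelihood is invariant to them once N_ANC is fixed).
#' @param tol lnCL gain per cycle below which cycling stops (default 0.01).
#' @param n_grid coarse log-spaced evaluations locating the best basin of
#'   each conditional slice (default 7).
#' @param n_refine golden-section refinements inside the winning bracket
#'   (default 4).
#' @param crn_fixed if `TRUE` every cycle reuses the same simulation seed
#'   (exact monotonicity across cycles; default `FALSE` refreshes per cycle).
#' @param polish run a bounded Nelder-Mead simplex over all free parameters
#'   on the final common-random-numbers surface after cycling (default
#'   `TRUE`); joint moves along likelihood ridges that single-parameter
#'   sweeps cannot follow.
#' @param polish_maxit simplex iteration cap per restart (default 200).
#' @param polish_restarts maximum simplex restarts; polishing stops early
#'   once a restart gains less than 0.5 log-units (default 3).
#' @param block_grid if > 0, each cycle ends with a 2-D conditional
#'   maximisation (log grid of this many points per axis) over each pair in
#'   `block_pairs`; confounded pairs (the two directions of a migration
#'   rate, a merge time with the size of the epoch it opens) trade off in
#'   ways one-parameter moves cannot resolve.
#' @param block_pairs list of character pairs for the 2-D blocks; `NULL`
#'   uses the built-in set for the four-population models.
#' @param builder optional function(params, n_anc) returning a model object,
#'   for non-standard (e.g. toy) demographies; `param_names` must then name
#'   its parameters.
#' @param param_names parameter names when `builder` is used.
#' @return list with `params`, `lnCL`, `trajectory` (per-cycle lnCL),
#'   `cycles_run`, `seed`.
#' @export
ecm_fit <- function(observed, model_id = NULL, search_ranges = NULL,
                    n_cycles = 40, n_sims = 200000, seed = 1L, init = NULL,
                    free = NULL, n_anc = 60000, mu = 7e-9, gen_time = 1,
                    tol = 0.01, n_grid = 7, n_refine = 4, crn_fixed = FALSE,
                    polish = TRUE, polish_maxit = 200, polish_restarts = 3,
                    block_grid = 0, block_pairs = NULL,
                    builder = NULL, param_names = NULL) {
  if (is.null(builder)) {
    if (is.null(model_id)) stop("supply model_id or a builder")
    param_names <- model_param_names()
    builder <- function(params, n_anc)
      demographic_model(model_id, params, n_anc = n_anc, mu = mu,
                        gen_time = gen_time)
  }
  total_obs <- sum(vapply(observed, function(o) sum(o$counts[!o$mask]),
                          numeric(1)))
  if (total_obs <= 0)
    stop("observed SFS contains no polymorphic SNPs; nothing to fit")
  ranges <- if (is.null(search_ranges)) .default_ranges(param_names)
            else search_ranges
  if (any(ranges$lo >= ranges$hi)) stop("inverted search range")
  if (is.null(free)) free <- param_names
  ss <- .ordered_sizes(observed)
  set.seed(seed)
  if (is.null(init)) {
    init <- structure(exp(stats::runif(length(param_names),
                                       log(ranges[param_names, "lo"]),
                                       log(ranges[param_names, "hi"]))),
                      names = param_names)
    tnames <- intersect(c("T_1", "T_2", "T_3"), param_names)
    if (length(tnames) > 1) init[tnames] <- sort(init[tnames])
  }
  params <- init
  eval_ll <- function(p, eval_seed) {
    m <- tryCatch(builder(p, n_anc), error = function(e) NULL)
    if (is.null(m)) return(-Inf)
    ep <- tryCatch(
      suppressWarnings(estimate_expected_sfs(m, ss, n_sims, seed = eval_seed)),
      error = function(e) NULL)
    if (is.null(ep)) return(-Inf)
    composite_log_likelihood(observed, ep)
  }
  traj <- numeric(0)
  cyc_seed <- seed
  ll_cur <- if (n_cycles == 0) eval_ll(params, cyc_seed) else -Inf
  for (cycle in seq_len(n_cycles)) {
    if (!crn_fixed) cyc_seed <- seed + 104729L * cycle
    ll_cur <- eval_ll(params, cyc_seed)
    ll_start <- ll_cur
    for (pname in free) {
      bounds <- .param_bounds(pname, params, ranges, model_id)
      f1 <- function(x) {
        p <- params; p[[pname]] <- x
        eval_ll(p, cyc_seed)
      }
      res <- .line_max(f1, bounds[["lo"]], bounds[["hi"]], n_grid, n_refine)
      if (res$f > ll_cur) {
        params[[pname]] <- res$x
        ll_cur <- res$f
      }
    }
    # optional 2-D conditional blocks over confounded parameter pairs:
    # the two migration directions of a pair, and each merge time with the
    # size of the ancestral epoch it opens, trade off against each other in
    # ways one-parameter moves cannot resolve (coordinate ascent stalls in
    # bottleneck-compensated basins)
    if (block_grid > 0) {
      prs <- block_pairs
      if (is.null(prs))
        prs <- list(c("m_we", "m_ew"), c("m_ep", "m_pe"), c("m_pw", "m_wp"),
                    c("T_1", "N_1"), c("T_2", "N_2"), c("T_3", "N_2"))
      for (pr in prs) {
        if (!all(pr %in% free)) next
        b1 <- .param_bounds(pr[1], params, ranges, model_id)
        b2 <- .param_bounds(pr[2], params, ranges, model_id)
        xs <- exp(seq(log(b1[["lo"]]), log(b1[["hi"]]),
                      length.out = block_grid))
        ys <- exp(seq(log(b2[["lo"]]), log(b2[["hi"]]),
                      length.out = block_grid))
        best <- NULL
        for (x in xs) for (y in ys) {
          p <- params; p[[pr[1]]] <- x; p[[pr[2]]] <- y
          v <- eval_ll(p, cyc_seed)
          if (v > ll_cur) { ll_cur <- v; best <- c(x, y) }
        }
        if (!is.null(best)) {
          params[[pr[1]]] <- best[1]
          params[[pr[2]]] <- best[2]
        }
      }
    }
    traj <- c(traj, ll_cur)
    if (is.finite(ll_start) && (ll_cur - ll_start) < tol) break
  }
  # joint simplex polish on the same CRN surface: supplies the multi-parameter
  # ridge moves (e.g. divergence time against migration rate) that
  # one-at-a-time conditional maximisation cannot make
  if (polish && length(free) > 1 && is.finite(ll_cur)) {
    lo <- ranges[free, "lo"]; hi <- ranges[free, "hi"]
    neg <- function(z) {
      x <- exp(z)
      if (any(x < lo) || any(x > hi)) return(1e10)
      p <- params; p[free] <- x
      -eval_ll(p, cyc_seed)
    }
    # restarting rebuilds a full-size simplex at the incumbent, which lets
    # the search keep tracking a curved ridge after the simplex collapses
    for (rst in seq_len(polish_restarts)) {
      op <- tryCatch(
        stats::optim(log(unlist(params[free])), neg, method = "Nelder-Mead",
                     control = list(maxit = polish_maxit)),
        error = function(e) NULL)
      if (is.null(op) || -op$value <= ll_cur + 0.5) {
        if (!is.null(op) && -op$value > ll_cur) {
          params[free] <- exp(op$par)
          ll_cur <- -op$value
        }
        break
      }
      params[free] <- exp(op$par)
      ll_cur <- -op$value
    }
  }
  list(params = params, lnCL = ll_cur, trajectory = traj,
       cycles_run = length(traj), seed = seed)
}

#' Best-of-many ECM fits from random starting points
#'
#' Runs `n_runs` independent [ecm_fit()]s from log-uniform initial points and
#' returns the global maximum-composite-likelihood solution; all runs' end
#' points are re-evaluated under one common simulation seed so they are
#' compared on the same Monte-Carlo draw.
#'
#' @inheritParams ecm_fit
#' @param n_runs number of independent runs (default 100).
#' @param final_n_sims simulation count for the common-seed re-evaluation of
#'   every run's end point (and for the final polish); defaults to `n_sims`.
#'   A larger value sharpens the comparison between runs (and between models
#'   fitted with the same `seed`) at negligible cost.
#' @param final_polish_maxit if > 0, the best run is refined once more on
#'   the `final_n_sims` common-random-numbers surface: one conditional sweep,
#'   then a Nelder-Mead simplex (useful when the per-run effort is small).
#' @param final_block_grid passed to the final sweep as `block_grid`.
#' @return a `fit_result`: list with `model_id`, `params`, `lnCL`, `AIC`,
#'   `k` (free-parameter count), `runs` (per-run table), `n_runs`,
#'   `observed_signature`.
#' @export
multi_run_fit <- function(observed, model_id = NULL, n_runs = 100,
                          n_cycles = 40, n_sims = 200000, seed = 1L,
                          final_n_sims = NULL, final_polish_maxit = 0,
                          final_block_grid = 0, ...) {
  dots <- list(...)
  if (is.null(final_n_sims)) final_n_sims <- n_sims
  fits <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    fits[[r]] <- ecm_fit(observed, model_id = model_id, n_cycles = n_cycles,
                         n_sims = n_sims, seed = seed + 7919L * r, ...)
  }
  k_free <- length(fits[[1]]$params)
  if (!is.null(dots$free)) k_free <- length(dots$free)
  reval <- function(init, maxit, cycles = 0L) {
    args <- dots
    args$model_id <- model_id
    args$n_cycles <- cycles
    args$n_sims <- final_n_sims
    args$seed <- seed
    args$init <- init
    args$crn_fixed <- TRUE
    args$polish <- maxit > 0
    args$polish_maxit <- maxit
    if (cycles > 0) args$block_grid <- final_block_grid
    do.call(ecm_fit, c(list(observed), args))
  }
  # common-seed re-evaluation of each run's solution
  relc <- vapply(fits, function(ft) reval(ft$params, 0)$lnCL, numeric(1))
  best <- which.max(relc)
  best_params <- fits[[best]]$params
  best_ll <- relc[best]
  if (final_polish_maxit > 0) {
    # refine the winner on the sharper common surface: one conditional sweep
    # (pins weakly identified parameters individually), then the joint simplex
    pol <- reval(best_params, final_polish_maxit, cycles = 1L)
    if (pol$lnCL > best_ll) {
      best_params <- pol$params
      best_ll <- pol$lnCL
    }
  }
  runs <- data.frame(run = seq_len(n_runs),
                     lnCL = vapply(fits, `[[`, numeric(1), "lnCL"),
                     lnCL_common = relc,
                     cycles = vapply(fits, `[[`, numeric(1), "cycles_run"))
  runs <- cbind(runs, do.call(rbind, lapply(fits, `[[`, "params")))
  sig <- vapply(observed, function(o) sum(o$counts), numeric(1))
  out <- list(model_id = model_id, params = best_params,
              lnCL = best_ll, log10CL = best_ll / log(10),
              k = k_free, AIC = 2 * k_free - 2 * best_ll,
              runs = runs, n_runs = n_runs, best_run = best,
              observed_signature = sig,
              sample_sizes = .ordered_sizes(observed),
              fit_args = c(list(model_id = model_id, n_cycles = n_cycles,
                                n_sims = n_sims), dots))
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("model %s fit: lnCL = %.2f (AIC = %.1f, k = %d, %d runs)\n",
              as.character(x$model_id), x$lnCL, x$AIC, x$k, x$n_runs))
  print(round(x$params, 4))
  invisible(x)
}

#' Rank fitted models by the Akaike information criterion
#'
#' AIC = 2k - 2 lnCL; relative likelihoods are exp(-deltaAIC / 2).  All fits
#' must refer to the same observed data.
#'
#' @param fits list of `fit_result` objects.
#' @return data.frame sorted by AIC: model_id, k, lnCL, AIC, delta_AIC,
#'   relative_likelihood.
#' @export
aic_select <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits to rank")
  sig <- lapply(fits, `[[`, "observed_signature")
  for (s in sig[-1])
    if (length(s) != length(sig[[1]]) ||
        any(abs(s - sig[[1]]) > 1e-8 * (1 + abs(sig[[1]]))))
      stop("fits were made to different observed data")
  tab <- data.frame(
    model_id = vapply(fits, function(f) as.character(f$model_id), ""),
    k = vapply(fits, `[[`, numeric(1), "k"),
    lnCL = vapply(fits, `[[`, numeric(1), "lnCL"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC), ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  tab$relative_likelihood <- exp(-tab$delta_AIC / 2)
  rownames(tab) <- NULL
  tab
}

#' Percentile interval (linear-interpolation quantiles)
#'
#' @param x replicate estimates.
#' @param level interval coverage (default 0.95).
#' @return c(lower, upper) from [stats::quantile()] type 7.
#' @export
percentile_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), type = 7, names = FALSE)
}

#' Parametric-bootstrap confidence intervals for a fitted model
#'
#' Simulates `n_reps` datasets at the maximum-composite-likelihood estimates
#' with the same number of SNPs as the data, refits each one (with reduced
#' effort by default: `runs` x `cycles`), and returns 2.5/97.5 percentile
#' intervals per free parameter.
#'
#' @param fit a `fit_result` from [multi_run_fit()].
#' @param n_snps SNPs per replicate dataset (use the observed count).
#' @param sample_sizes haploid sample size per deme used for the observed
#'   SFS (derived from the fit's data shape when `NULL`).
#' @param n_reps bootstrap replicates (default 100).
#' @param runs,cycles,n_sims per-replicate refit effort (defaults 10, 20,
#'   and the fit's own `n_sims`).
#' @param seed integer seed.
#' @param builder,param_names,n_anc passed through for non-standard models.
#' @return list with `ci` (parameter x c(lower, upper) matrix), `estimates`
#'   (replicates x parameters), `n_failed`.
#' @export
parametric_bootstrap <- function(fit, n_snps, sample_sizes = NULL,
                                 n_reps = 100, runs = 10, cycles = 20,
                                 n_sims = NULL, seed = 1L, builder = NULL,
                                 param_names = NULL, n_anc = 60000) {
  if (n_reps < 2) warning("n_reps < 2 gives a degenerate interval")
  fa <- fit$fit_args
  if (is.null(n_sims)) n_sims <- fa$n_sims
  if (is.null(builder)) builder <- fa$builder
  if (is.null(param_names)) param_names <- fa$param_names
  if (!is.null(fa$n_anc)) n_anc <- fa$n_anc
  model <- if (is.null(builder))
    demographic_model(fit$model_id, fit$params, n_anc = n_anc)
  else builder(fit$params, n_anc)
  if (is.null(sample_sizes)) sample_sizes <- fit$sample_sizes
  pair_names <- names(fit$observed_signature)
  est <- list()
  n_failed <- 0
  for (rep in seq_len(n_reps)) {
    rep_seed <- seed + 7717L * rep
    ok <- tryCatch({
      sim <- simulate_sfs(model, sample_sizes, n_snps, seed = rep_seed)
      obs <- sim$sfs[pair_names]
      args <- fa[setdiff(names(fa),
                         c("model_id", "n_cycles", "n_sims", "init", "seed"))]
      args$model_id <- fit$model_id
      args$n_runs <- runs
      args$n_cycles <- cycles
      args$n_sims <- n_sims
      args$seed <- rep_seed
      ft <- do.call(multi_run_fit, c(list(obs), args))
      est[[length(est) + 1L]] <- ft$params
      TRUE
    }, error = function(e) FALSE)
    if (!isTRUE(ok)) n_failed <- n_failed + 1
  }
  if (length(est) == 0) stop("all bootstrap replicates failed")
  if (n_failed > 0.1 * n_reps)
    warning(sprintf("%d of %d bootstrap replicates failed", n_failed, n_reps))
  em <- do.call(rbind, est)
  ci <- t(apply(em, 2, percentile_ci))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, estimates = em, n_failed = n_failed)
}
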