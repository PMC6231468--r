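#' @useDynLib sfscoal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# single-population constant-size model expressed in the same epoch encoding
.single_pop_epochs <- function(N) {
  list(n_demes = 1L, event_times = numeric(0), event_src = integer(0),
       event_dst = integer(0), sizes = matrix(N, 1, 1), mig = 0)
}

.epochs_of <- function(model) {
  if (inherits(model, "demog_model")) demog_epochs(model)
  else if (is.list(model) && !is.null(model$n_demes)) model
  else stop("model must be a demog_model or an epoch list")
}

.check_samples <- function(ep, sample_sizes) {
  if (length(sample_sizes) != ep$n_demes)
    stop("sample_sizes must have one entry per deme")
  if (sum(sample_sizes) < 2) stop("need at least two sampled haplotypes")
  as.integer(sample_sizes)
}

#' Simulate one genealogy under a structured-coalescent model
#'
#' Lineages coalesce pairwise within demes at rate 1/(2N), migrate between
#' demes at the model's backward rates and are relocated at merge events.
#' Branch lengths are in generations.
#'
#' @param model a [demographic_model()] (or a low-level epoch list).
#' @param sample_sizes haploid sample size per extant deme (WAS, EGB, P/W,
#'   WGB order for the four-population models).
#' @param seed integer seed.
#' @return an [ape::phylo] tree with `tmrca` and `total_length` attributes;
#'   tip labels are `<deme>_<index>`.
#' @export
simulate_genealogy <- function(model, sample_sizes, seed = NULL) {
  ep <- .epochs_of(model)
  ss <- .check_samples(ep, sample_sizes)
  if (!is.null(seed)) set.seed(seed)
  res <- sim_tree_cpp(ss, ep$event_times, ep$event_src, ep$event_dst,
                      ep$sizes, ep$mig)
  n <- res$n_leaves
  ntot <- 2 * n - 1
  internal <- which(res$child1 > 0)           # 1-based node ids with children
  # ape numbering: tips 1..n, root n+1, other internals n+2..
  root_old <- ntot                            # last created node is the root
  old2new <- integer(ntot)
  old2new[seq_len(n)] <- seq_len(n)
  old2new[root_old] <- n + 1L
  rest <- setdiff(internal, root_old)
  old2new[rest] <- n + 1L + seq_along(rest)
  edge <- matrix(0L, ntot - 1, 2)
  elen <- numeric(ntot - 1)
  k <- 0L
  for (v in internal) for (ch in c(res$child1[v], res$child2[v])) {
    k <- k + 1L
    edge[k, ] <- c(old2new[v], old2new[ch])
    elen[k] <- res$time[v] - res$time[ch]
  }
  demes <- rep(seq_along(ss), ss)
  labels <- if (ep$n_demes == 4)
    c("WAS", "EGB", "PW", "WGB")[demes] else paste0("pop", demes)
  tip.label <- paste0(labels, "_", unlist(lapply(ss, seq_len)))
  tr <- structure(list(edge = edge, edge.length = elen, Nnode = n - 1L,
                       tip.label = tip.label), class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "tmrca") <- res$tmrca
  attr(tr, "total_length") <- res$total_length
  tr
}

#' TMRCA and total branch length over replicate genealogies
#'
#' @inheritParams simulate_genealogy
#' @param n_reps number of independent genealogies.
#' @return data.frame with columns `tmrca` and `total_length` (generations).
#' @export
simulate_tmrca <- function(model, sample_sizes, n_reps, seed = NULL) {
  ep <- .epochs_of(model)
  ss <- .check_samples(ep, sample_sizes)
  if (!is.null(seed)) set.seed(seed)
  as.data.frame(sim_tmrca_cpp(ss, ep$event_times, ep$event_src, ep$event_dst,
                              ep$sizes, ep$mig, n_reps))
}

#' Simulate SNP configurations and their folded pairwise joint SFS
#'
#' Each SNP gets an independent genealogy (free recombination between loci)
#' and a single mutation on a branch drawn with probability proportional to
#' branch length, so every SNP is polymorphic in the pooled sample
#' (infinite-sites).  Derived counts per deme are returned together with the
#' folded joint SFS of every deme pair (SNPs monomorphic within a pair fall
#' into that pair's masked cell).
#'
#' @inheritParams simulate_genealogy
#' @param n_snps number of SNPs.
#' @return list with `configs` (n_snps x demes derived counts) and `sfs`
#'   (named list of [folded_joint_sfs()], names "A|B").
#' @export
simulate_sfs <- function(model, sample_sizes, n_snps, seed = NULL) {
  ep <- .epochs_of(model)
  ss <- .check_samples(ep, sample_sizes)
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim_snp_configs_cpp(ss, ep$event_times, ep$event_src, ep$event_dst,
                             ep$sizes, ep$mig, n_snps)
  labels <- if (ep$n_demes == 4) c("WAS", "EGB", "PW", "WGB")
            else paste0("pop", seq_len(ep$n_demes))
  colnames(cfg) <- labels
  sfs <- list()
  K <- ep$n_demes
  if (K >= 2) for (a in 1:(K - 1)) for (b in (a + 1):K) {
    nA <- ss[a]; nB <- ss[b]
    unf <- matrix(0, nA + 1, nB + 1)
    tab <- table(factor(cfg[, a], levels = 0:nA),
                 factor(cfg[, b], levels = 0:nB))
    unf[] <- as.numeric(tab)
    counts <- fold_matrix(unf, nA, nB)
    sfs[[paste(labels[a], labels[b], sep = "|")]] <-
      folded_joint_sfs(counts, labels[a], labels[b], nA, nB)
  }
  list(configs = cfg, sfs = sfs)
}

#' Monte-Carlo expected folded joint SFS by branch-length weighting
#'
#' Simulates `n_sims` genealogies and accumulates, for every deme pair and
#' configuration, the expected branch length carrying that configuration;
#' normalised over a pair's polymorphic (unmasked) cells this is the expected
#' sampling distribution of a SNP used by the composite likelihood.
#' Averaging over all mutation placements on each genealogy instead of
#' drawing one gives a lower-variance estimate at the same simulation count.
#'
#' @inheritParams simulate_genealogy
#' @param n_sims number of genealogies.
#' @return list with `pair_lengths` (named list of unfolded expected-length
#'   matrices), `marginal` (per-deme expected-length vectors over derived
#'   counts) and `total_length`.
#' @export
expected_branch_sfs <- function(model, sample_sizes, n_sims, seed = NULL) {
  ep <- .epochs_of(model)
  ss <- .check_samples(ep, sample_sizes)
  if (!is.null(seed)) set.seed(seed)
  res <- sim_pair_sfs_branch_cpp(ss, ep$event_times, ep$event_src,
                                 ep$event_dst, ep$sizes, ep$mig, n_sims)
  if (res$n_failed > 0)
    warning(res$n_failed, " replicate(s) hit the event cap and were dropped")
  labels <- if (ep$n_demes == 4) c("WAS", "EGB", "PW", "WGB")
            else paste0("pop", seq_len(ep$n_demes))
  pl <- res$pairs
  names(pl) <- paste(labels[res$pair_a], labels[res$pair_b], sep = "|")
  names(res$marginal) <- labels
  list(pair_lengths = pl, marginal = res$marginal,
       total_length = res$total_length)
}

#' Simulate a GBS-style genotype table with missingness
#'
#' Haplotypes are simulated locus by locus (one genealogy per locus,
#' `snps_per_locus` mutations placed on branches proportional to length),
#' paired into diploid individuals within demes, and masked independently
#' with probability `missing_rate`.  Localities are assigned by splitting
#' each population's individuals into consecutive groups of
#' `locality_size`.
#'
#' @inheritParams simulate_genealogy
#' @param sample_sizes diploid individuals per population here (haplotypes
#'   are paired within demes).
#' @param n_loci number of GBS loci.
#' @param snps_per_locus SNPs per locus (linked within a locus).
#' @param missing_rate probability a genotype call is missing, in `[0, 1]`.
#' @param locality_size individuals per synthetic locality (default 4).
#' @return a [genotype_table()].
#' @export
simulate_genotypes_with_missingness <- function(model, sample_sizes, n_loci,
                                                snps_per_locus = 1,
                                                missing_rate = 0,
                                                locality_size = 4,
                                                seed = NULL) {
  stopifnot(missing_rate >= 0, missing_rate <= 1)
  ep <- .epochs_of(model)
  ss_hap <- .check_samples(ep, 2 * sample_sizes)
  if (!is.null(seed)) set.seed(seed)
  hap <- sim_haplotypes_cpp(ss_hap, ep$event_times, ep$event_src,
                            ep$event_dst, ep$sizes, ep$mig,
                            n_loci, snps_per_locus)
  n_ind <- sum(sample_sizes)
  g <- hap[seq(1, 2 * n_ind, by = 2), , drop = FALSE] +
       hap[seq(2, 2 * n_ind, by = 2), , drop = FALSE]
  if (missing_rate > 0)
    g[matrix(stats::runif(length(g)) < missing_rate, nrow(g))] <- NA
  labels <- if (ep$n_demes == 4) c("WAS", "EGB", "PW", "WGB")
            else paste0("pop", seq_len(ep$n_demes))
  pop <- rep(labels[seq_along(sample_sizes)], sample_sizes)
  loc_idx <- unlist(lapply(sample_sizes, function(k)
    rep(seq_len(ceiling(k / locality_size)), each = locality_size)[seq_len(k)]))
  locality <- paste0(pop, "-L", loc_idx)
  ind <- paste0(pop, "_", unlist(lapply(sample_sizes, seq_len)))
  sites <- data.frame(
    locus_id = paste0("locus", rep(seq_len(n_loci), each = snps_per_locus)),
    pos = rep(seq_len(snps_per_locus) - 1L, times = n_loci),
    stringsAsFactors = FALSE)
  genotype_table(g, ind, locality, pop, sites)
}

#' Simulate finite-length sequences for diversity checks
#'
#' One genealogy per locus; the mutation count is Poisson with mean
#' mu * L * total branch length and mutations hit uniform sites, so mean
#' pairwise diversity per site estimates theta_pi = 4 N mu in a single
#' population.
#'
#' @inheritParams simulate_genealogy
#' @param n_loci independent loci.
#' @param L sites per locus.
#' @param mu mutation rate per site per generation.
#' @return 0/1 haplotype matrix (haplotypes x n_loci*L sites).
#' @export
simulate_sequences <- function(model, sample_sizes, n_loci, L, mu,
                               seed = NULL) {
  ep <- .epochs_of(model)
  ss <- .check_samples(ep, sample_sizes)
  if (!is.null(seed)) set.seed(seed)
  sim_sequences_cpp(ss, ep$event_times, ep$event_src, ep$event_dst,
                    ep$sizes, ep$mig, n_loci, L, mu)
}

#' Mean pairwise nucleotide diversity of a haplotype matrix
#'
#' @param hap 0/1 matrix, haplotypes x sites.
#' @param n_sites total sites represented (defaults to `ncol(hap)`).
#' @return mean pairwise differences per site.
#' @export
haplotype_pi <- function(hap, n_sites = ncol(hap)) {
  n <- nrow(hap)
  p <- colMeans(hap)
  sum(2 * p * (1 - p) * n / (n - 1)) / n_sites
}
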