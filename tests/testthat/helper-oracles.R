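# Independent brute-force oracles.  These deliberately re-derive every
# quantity from first principles (enumeration, direct sums, stats::aov) and
# share no code with the package implementation.

oracle_fold <- function(i, j, nA, nB) {
  a <- c(i, j); b <- c(nA - i, nB - j)
  if (i + j > (nA + nB) / 2) return(b)
  if (i + j == (nA + nB) / 2) {
    # keep the lexicographically smaller representative
    if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) return(b)
  }
  a
}

# exhaustive subset enumeration of the hypergeometric projection
oracle_project <- function(k, n_from, n_to) {
  pool <- c(rep(1, k), rep(0, n_from - k))
  subs <- utils::combn(n_from, n_to)
  counts <- apply(subs, 2, function(ix) sum(pool[ix]))
  as.numeric(table(factor(counts, levels = 0:n_to)) / ncol(subs))
}

oracle_watterson <- function(S, n_hap) {
  if (n_hap < 2) return(NA_real_)
  a <- 0
  for (k in 1:(n_hap - 1)) a <- a + 1 / k
  S / a
}

# per-site pi by explicit pairwise comparison of haplotype counts
oracle_pi_site <- function(k_alt, n_hap) {
  if (n_hap < 2) return(NA_real_)
  diff_pairs <- k_alt * (n_hap - k_alt)
  diff_pairs / choose(n_hap, 2)
}

oracle_he <- function(p) 1 - p^2 - (1 - p)^2

# per-locality statistics from a dosage matrix, written as naive loops
oracle_locality_stats <- function(g) {
  he <- pi <- hob <- hex <- c()
  for (s in seq_len(ncol(g))) {
    x <- g[, s]
    x <- x[!is.na(x)]
    n_hap <- 2 * length(x)
    if (n_hap < 2) next
    p <- sum(x) / n_hap
    he <- c(he, oracle_he(p))
    pi <- c(pi, oracle_pi_site(sum(x), n_hap))
    if (oracle_he(p) > 0) {
      hob <- c(hob, mean(x == 1))
      hex <- c(hex, oracle_he(p))
    }
  }
  c(He = mean(he), pi = mean(pi),
    Fis = if (length(hex)) 1 - sum(hob) / sum(hex) else NA_real_)
}

# two-level variance components via stats::aov mean squares on allele copies
oracle_fst_aov <- function(geno, grp) {
  grp <- as.factor(grp)
  num <- den <- 0
  any_site <- FALSE
  for (s in seq_len(ncol(geno))) {
    x <- geno[, s]
    ok <- !is.na(x)
    if (!any(ok)) next
    copies <- c(ifelse(x[ok] >= 1, 1, 0), ifelse(x[ok] == 2, 1, 0))
    gcopy <- factor(c(as.character(grp[ok]), as.character(grp[ok])))
    tab <- table(gcopy)
    keep_groups <- names(tab)[tab >= 2]
    use <- gcopy %in% keep_groups
    if (length(keep_groups) < 2) next
    y <- copies[use]; gg <- droplevels(gcopy[use])
    sm <- suppressWarnings(stats::anova(stats::aov(y ~ gg)))
    msb <- sm$`Mean Sq`[1]; msw <- sm$`Mean Sq`[2]
    ni <- as.numeric(table(gg)); N <- sum(ni); r <- length(ni)
    nc <- (N - sum(ni^2) / N) / (r - 1)
    a <- (msb - msw) / nc
    tot <- a + msw
    if (!is.na(tot) && tot != 0) {
      num <- num + a
      den <- den + tot
      any_site <- TRUE
    }
  }
  if (!any_site) return(NA_real_)
  num / den
}

# random GBS-style toy tables with localities, populations and missingness
random_toy_table <- function(seed, n_ind = 8, n_loci = 3, snps_per_locus = 2,
                             missing = 0.15, n_pops = 2) {
  set.seed(seed)
  n_sites <- n_loci * snps_per_locus
  g <- matrix(sample(0:2, n_ind * n_sites, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2)), n_ind, n_sites)
  g[matrix(runif(length(g)) < missing, n_ind)] <- NA
  pop <- rep(paste0("pop", seq_len(n_pops)), length.out = n_ind)
  genotype_table(
    g,
    individual_ids = paste0("ind", seq_len(n_ind)),
    locality_ids = pop,
    population_ids = pop,
    sites = data.frame(locus_id = rep(paste0("L", seq_len(n_loci)),
                                      each = snps_per_locus),
                       pos = rep(seq_len(snps_per_locus) - 1L, n_loci),
                       stringsAsFactors = FALSE))
}
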