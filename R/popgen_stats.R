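#' Expected heterozygosity from allele frequencies
#'
#' He = 1 - sum(p_i^2).  For a biallelic site this is 2p(1-p) <= 0.5.
#'
#' @param allele_freqs numeric vector of allele frequencies summing to 1.
#' @return He.
#' @export
expected_heterozygosity <- function(allele_freqs) {
  if (abs(sum(allele_freqs) - 1) > 1e-8)
    stop("allele frequencies must sum to 1")
  1 - sum(allele_freqs^2)
}

#' Unbiased per-site nucleotide diversity
#'
#' pi = n/(n-1) * (1 - sum(p_hat^2)) with n the number of genotyped
#' haplotypes at the site; identical to the mean number of pairwise
#' differences per site.
#'
#' @param n_hap haplotypes genotyped at the site (>= 2).
#' @param p_alt sample frequency of the alternate allele.
#' @return per-site pi.
#' @export
nucleotide_diversity <- function(n_hap, p_alt) {
  if (n_hap < 2) stop("need >= 2 genotyped haplotypes")
  n_hap / (n_hap - 1) * (1 - p_alt^2 - (1 - p_alt)^2)
}

#' Inbreeding coefficient from observed and expected heterozygosity
#'
#' F_IS = 1 - sum(H_obs) / sum(H_exp) over sites with H_exp > 0 (the
#' ratio-of-sums form; for a single site this is 1 - H_obs/H_exp).
#'
#' @param obs_het numeric vector of per-site observed heterozygosities.
#' @param exp_het numeric vector of per-site expected heterozygosities.
#' @return F_IS, or `NA` if no site has H_exp > 0.
#' @export
inbreeding_coefficient <- function(obs_het, exp_het) {
  use <- !is.na(exp_het) & exp_het > 0 & !is.na(obs_het)
  if (!any(use)) return(NA_real_)
  1 - sum(obs_het[use]) / sum(exp_het[use])
}

# per-locality per-site summaries used by diversity_stats
.site_freqs <- function(g) {
  called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  n_hap <- 2 * called
  p <- ifelse(n_hap > 0, alt / n_hap, NA_real_)
  hobs <- ifelse(called > 0, colMeans(g == 1L, na.rm = TRUE), NA_real_)
  list(n_hap = n_hap, p = p, hobs = hobs)
}

.locality_stats <- function(g) {
  f <- .site_freqs(g)
  use <- f$n_hap >= 2
  he_site <- 1 - f$p^2 - (1 - f$p)^2
  pi_site <- ifelse(use, f$n_hap / (f$n_hap - 1) * he_site, NA_real_)
  c(He = mean(he_site[use]),
    pi = mean(pi_site[use]),
    Fis = inbreeding_coefficient(f$hobs[use], he_site[use]))
}

#' Per-locality diversity statistics
#'
#' Mean expected heterozygosity, mean unbiased nucleotide diversity and the
#' inbreeding coefficient for each sampling locality (or population), averaged
#' over the variant sites in the table with at least two genotyped haplotypes
#' in the group.
#'
#' @param table a `geno_table`.
#' @param by `"locality"` (default) or `"population"`.
#' @return data.frame: group, n_individuals, He, pi, Fis.
#' @export
diversity_stats <- function(table, by = c("locality", "population")) {
  by <- match.arg(by)
  grp <- if (by == "locality") table$locality_ids else table$population_ids
  if (is.null(grp)) stop("table has no population assignments")
  groups <- sort(unique(grp))
  out <- lapply(groups, function(gid) {
    g <- table$geno[grp == gid, , drop = FALSE]
    st <- .locality_stats(g)
    data.frame(group = gid, n_individuals = nrow(g),
               He = st[["He"]], pi = st[["pi"]], Fis = st[["Fis"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Diversity statistics under repeated subsampling
#'
#' Each replicate draws `n_per_locality` individuals without replacement from
#' every locality (localities smaller than that are used in full and flagged)
#' and recomputes He, pi and F_IS; medians across replicates are attached.
#' Equalised sample sizes make diversity comparable across unevenly sampled
#' localities.
#'
#' @param table a `geno_table`.
#' @param n_per_locality individuals drawn per locality (default 4).
#' @param replicates number of independent draws (default 20).
#' @param seed integer seed.
#' @param by `"locality"` or `"population"`.
#' @return list with `replicates` (long data.frame: group, replicate, He, pi,
#'   Fis), `medians`, and `flagged` (groups smaller than the subsample size).
#' @export
subsampled_stats <- function(table, n_per_locality = 4, replicates = 20,
                             seed = 1L, by = c("locality", "population")) {
  by <- match.arg(by)
  grp <- if (by == "locality") table$locality_ids else table$population_ids
  if (is.null(grp)) stop("table has no population assignments")
  groups <- sort(unique(grp))
  small <- groups[table(grp)[groups] < n_per_locality]
  set.seed(seed)
  rows <- list()
  for (r in seq_len(replicates)) {
    for (gid in groups) {
      ix <- which(grp == gid)
      if (length(ix) > n_per_locality)
        ix <- sample(ix, n_per_locality)
      st <- .locality_stats(table$geno[ix, , drop = FALSE])
      rows[[length(rows) + 1L]] <-
        data.frame(group = gid, replicate = r, He = st[["He"]],
                   pi = st[["pi"]], Fis = st[["Fis"]],
                   stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rows)
  med <- stats::aggregate(reps[c("He", "pi", "Fis")],
                          by = list(group = reps$group), stats::median)
  list(replicates = reps, medians = med, flagged = as.character(small))
}

# Weir-Cockerham two-level variance components for one site.
# grp_p: per-group alt-allele sample frequencies; grp_n: allele copies per
# group.  Returns c(a, total) = (among-group component, a + within component).
.wc_site_components <- function(grp_p, grp_n) {
  use <- grp_n >= 2
  grp_p <- grp_p[use]; grp_n <- grp_n[use]
  r <- length(grp_n)
  if (r < 2) return(c(NA_real_, NA_real_))
  N <- sum(grp_n)
  nc <- (N - sum(grp_n^2) / N) / (r - 1)
  pbar <- sum(grp_n * grp_p) / N
  msb <- sum(grp_n * (grp_p - pbar)^2) / (r - 1)
  ssw <- sum(grp_n * grp_p * (1 - grp_p))
  msw <- ssw / (N - r)
  a <- (msb - msw) / nc
  c(a, a + msw)
}

#' Multi-locus Weir-Cockerham F_ST between groups of individuals
#'
#' Two-level (among-group / within-group) variance-components estimator on
#' allele copies, combined across sites as the ratio of summed among-group
#' components to summed total components ("corrected AMOVA" F_ST).  Estimates
#' may be slightly negative when differentiation is absent; they are reported
#' untruncated.
#'
#' @param geno dosage matrix (individuals x sites, NA = missing).
#' @param grp group label per individual (2+ groups).
#' @return F_ST, or `NA` if no usable site.
#' @export
fst_wc <- function(geno, grp) {
  grp <- as.factor(grp)
  if (nlevels(grp) < 2) stop("need at least two groups")
  comp <- vapply(seq_len(ncol(geno)), function(s) {
    x <- geno[, s]
    ok <- !is.na(x)
    gp <- grp[ok]; xs <- x[ok]
    n <- 2 * tabulate(gp, nbins = nlevels(grp))
    alt <- vapply(seq_len(nlevels(grp)),
                  function(k) sum(xs[as.integer(gp) == k]), numeric(1))
    p <- ifelse(n > 0, alt / n, NA_real_)
    .wc_site_components(p[n > 0], n[n > 0])
  }, numeric(2))
  a <- comp[1, ]; tot <- comp[2, ]
  use <- !is.na(a) & !is.na(tot) & tot != 0
  if (!any(use)) return(NA_real_)
  sum(a[use]) / sum(tot[use])
}

#' Pairwise F_ST matrix between populations
#'
#' @param table a `geno_table` with population (or locality) labels.
#' @param by `"population"` (default) or `"locality"`.
#' @return symmetric matrix of pairwise Weir-Cockerham F_ST values.
#' @export
pairwise_fst <- function(table, by = c("population", "locality")) {
  by <- match.arg(by)
  grp <- if (by == "population") table$population_ids else table$locality_ids
  if (is.null(grp)) stop("table has no population assignments")
  pops <- sort(unique(grp))
  k <- length(pops)
  out <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  diag(out) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ix <- grp %in% c(pops[i], pops[j])
    out[i, j] <- out[j, i] <- fst_wc(table$geno[ix, , drop = FALSE], grp[ix])
  }
  out
}

#' Principal component analysis of the dosage matrix
#'
#' Missing dosages are imputed with the per-site mean (the mean-allele-
#' frequency convention), columns are centred and scaled to unit variance,
#' monomorphic columns are dropped, and the eigendecomposition is taken via
#' [stats::prcomp()].
#'
#' @param table a `geno_table`.
#' @param n_components number of axes to return (default 2).
#' @return list with `scores` (individuals x components), `explained`
#'   (per-axis variance fractions) and `dropped_monomorphic` (count).
#' @export
pca_scores <- function(table, n_components = 2) {
  g <- table$geno
  if (nrow(g) < 2 || ncol(g) < 2) stop("need >= 2 individuals and >= 2 sites")
  storage.mode(g) <- "double"
  mu <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]
  sdv <- apply(g, 2, stats::sd)
  keep <- !is.na(sdv) & sdv > 0
  if (!any(keep)) stop("all sites monomorphic after imputation")
  pc <- stats::prcomp(g[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  nc <- min(n_components, ncol(pc$x))
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(nc), drop = FALSE],
       explained = expl[seq_len(nc)],
       dropped_monomorphic = sum(!keep))
}

#' Write diversity statistics / F_ST matrices as tab-separated text
#'
#' @param x data.frame or matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_table <- function(x, path) {
  if (is.matrix(x))
    utils::write.table(x, path, sep = "\t", quote = FALSE, col.names = NA)
  else
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
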