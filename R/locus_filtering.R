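#' Per-locus Watterson theta
#'
#' For each GBS locus, theta_W = S / a_n with S the number of segregating
#' (polymorphic) sites at the locus and a_n the harmonic number
#' sum_{k=1}^{n-1} 1/k.  The haplotype sample size n is taken as the median
#' number of non-missing haplotypes (2 x called genotypes) across the locus's
#' sites, rounded to the nearest integer — robust to per-site missingness.
#' Loci with fewer than 2 genotyped haplotypes get `NA` theta and are flagged.
#'
#' @param table a `geno_table`.
#' @return data.frame with columns `locus_id`, `S`, `n_hap`, `theta_w`,
#'   `valid`.
#' @export
per_locus_theta <- function(table) {
  g <- table$geno
  locus <- table$sites$locus_id
  called <- colSums(!is.na(g))
  poly <- apply(g, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && any(x != x[1])
  })
  # heterozygous-only columns count as polymorphic (two alleles observed)
  het_only <- apply(g, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && all(x == 1L)
  })
  poly <- poly | het_only
  S <- tapply(poly, locus, sum)
  n_hap <- tapply(2L * called, locus, function(x) as.integer(round(stats::median(x))))
  ids <- names(S)
  theta <- rep(NA_real_, length(ids))
  valid <- n_hap >= 2
  a_n <- vapply(n_hap, function(n) {
    if (is.na(n) || n < 2) NA_real_ else sum(1 / seq_len(n - 1))
  }, numeric(1))
  theta[valid] <- as.numeric(S[valid]) / a_n[valid]
  data.frame(locus_id = ids, S = as.integer(S), n_hap = as.integer(n_hap),
             theta_w = theta, valid = as.logical(valid),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Whitelist loci by a theta quantile cutoff
#'
#' Retains loci whose Watterson theta does not exceed the `q` quantile of the
#' valid per-locus values (linear-interpolation quantile, R type 7); the
#' excessively variable loci above the cutoff — putative paralog collapses in
#' GBS assemblies — are excluded.
#'
#' @param records data.frame from [per_locus_theta()].
#' @param q quantile cutoff, default 0.95.
#' @return character vector of whitelisted locus IDs, with the cutoff in
#'   attribute `"cutoff"` and excluded loci in `"excluded"`.
#' @export
whitelist_by_quantile <- function(records, q = 0.95) {
  rec <- records[records$valid & !is.na(records$theta_w), , drop = FALSE]
  if (nrow(rec) == 0) stop("no valid per-locus theta records")
  cutoff <- stats::quantile(rec$theta_w, q, type = 7, names = FALSE)
  keep <- rec$theta_w <= cutoff
  wl <- rec$locus_id[keep]
  attr(wl, "cutoff") <- cutoff
  attr(wl, "excluded") <- rec$locus_id[!keep]
  wl
}

#' Write / read a locus whitelist (one locus ID per line)
#'
#' @param whitelist character vector of locus IDs.
#' @param path file path.
#' @return `path` invisibly; the reader returns the ID vector.
#' @export
write_whitelist <- function(whitelist, path) {
  writeLines(as.character(whitelist), path)
  invisible(path)
}

#' @rdname write_whitelist
#' @export
read_whitelist <- function(path) readLines(path)

#' Restrict a table to whitelisted loci
#'
#' @param table a `geno_table`.
#' @param whitelist character vector of locus IDs to keep.
#' @return filtered `geno_table`.
#' @export
apply_whitelist <- function(table, whitelist) {
  subset_table(table, sites = which(table$sites$locus_id %in% whitelist))
}

#' Missing-data filters for SNPs and individuals
#'
#' First drops SNPs whose missing fraction across individuals is strictly
#' greater than `snp_max_missing`, then drops individuals whose missing
#' fraction across the surviving SNPs is strictly greater than
#' `ind_max_missing` (the order matters and follows the dataset-construction
#' convention: site filter before individual filter).
#'
#' @param table a `geno_table`.
#' @param snp_max_missing maximum tolerated per-SNP missing fraction (default
#'   0.70).
#' @param ind_max_missing maximum tolerated per-individual missing fraction
#'   (default 0.90).
#' @return filtered `geno_table` with attributes `"n_sites_dropped"` and
#'   `"n_individuals_dropped"`.
#' @export
filter_missingness <- function(table, snp_max_missing = 0.70,
                               ind_max_missing = 0.90) {
  stopifnot(snp_max_missing > 0, snp_max_missing <= 1,
            ind_max_missing > 0, ind_max_missing <= 1)
  g <- table$geno
  site_miss <- colMeans(is.na(g))
  keep_sites <- site_miss <= snp_max_missing
  ind_miss <- rowMeans(is.na(g[, keep_sites, drop = FALSE]))
  keep_inds <- ind_miss <= ind_max_missing
  if (!any(keep_sites) || !any(keep_inds))
    stop(sprintf(
      "missingness filters removed everything (%d/%d sites, %d/%d individuals kept)",
      sum(keep_sites), length(keep_sites), sum(keep_inds), length(keep_inds)))
  out <- subset_table(table, individuals = which(keep_inds),
                      sites = which(keep_sites))
  attr(out, "n_sites_dropped") <- sum(!keep_sites)
  attr(out, "n_individuals_dropped") <- sum(!keep_inds)
  out
}

#' Thin to one randomly chosen SNP per locus
#'
#' @param table a `geno_table` with locus IDs.
#' @param seed integer seed; the choice is uniform per locus and reproducible.
#' @return thinned `geno_table` (site order preserved).
#' @export
one_snp_per_locus <- function(table, seed = 1L) {
  locus <- table$sites$locus_id
  idx <- seq_along(locus)
  set.seed(seed)
  pick <- unlist(lapply(split(idx, locus), function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  }), use.names = FALSE)
  subset_table(table, sites = sort(pick))
}

#' Flag outlier individuals in PCA space
#'
#' Individuals farther than `k` median-absolute-deviations from the PC1-PC2
#' centroid are reported (not removed): outlier handling in GBS datasets is an
#' operator decision, typically iterated with refiltering.
#'
#' @param table a `geno_table`.
#' @param k MAD multiplier, default 6.
#' @return data.frame of flagged individuals with their robust distances.
#' @export
pca_outlier_report <- function(table, k = 6) {
  sc <- pca_scores(table, n_components = 2)
  z <- sc$scores[, 1:2, drop = FALSE]
  ctr <- apply(z, 2, stats::median)
  dist <- sqrt(rowSums(sweep(z, 2, ctr)^2))
  md <- stats::mad(dist, constant = 1.4826)
  thr <- stats::median(dist) + k * md
  flag <- dist > thr
  data.frame(individual = table$individual_ids[flag],
             distance = dist[flag], threshold = thr,
             row.names = NULL, stringsAsFactors = FALSE)
}
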