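#' Fold a two-population allele-count configuration
#'
#' A configuration (i, j) of alternate/derived-allele copies in samples of
#' nA and nB haplotypes is mapped to its minor-allele representative: if the
#' pooled count i + j exceeds (nA + nB)/2 the complementary configuration
#' (nA - i, nB - j) is returned; at exactly half, the lexicographically
#' smaller of the two is kept (a deterministic tie rule that makes folding an
#' involution).
#'
#' @param i,j allele copies in population A and B.
#' @param nA,nB haplotype sample sizes.
#' @return integer vector c(i', j').
#' @export
fold_configuration <- function(i, j, nA, nB) {
  if (i < 0 || j < 0 || i > nA || j > nB)
    stop("allele counts out of range")
  tot <- i + j
  half <- (nA + nB) / 2
  if (tot > half) return(c(nA - i, nB - j))
  if (tot == half) {
    a <- c(i, j); b <- c(nA - i, nB - j)
    if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) return(b)
  }
  c(as.integer(i), as.integer(j))
}

# vectorised fold over a matrix of configurations (rows = sites)
.fold_rows <- function(ij, nA, nB) {
  i <- ij[, 1]; j <- ij[, 2]
  tot <- i + j
  half <- (nA + nB) / 2
  flip <- tot > half
  tie <- tot == half
  if (any(tie)) {
    ci <- nA - i[tie]; cj <- nB - j[tie]
    flip[tie] <- ci < i[tie] | (ci == i[tie] & cj < j[tie])
  }
  cbind(ifelse(flip, nA - i, i), ifelse(flip, nB - j, j))
}

#' Fold a matrix of unfolded configuration mass
#'
#' Applies [fold_configuration()] to every cell of an (nA+1) x (nB+1) matrix
#' indexed by derived/alternate counts, summing mass that folds to the same
#' minor-allele configuration (folding is linear, so a whole spectrum can be
#' folded in one pass).  The fixed-in-pair cell (nA, nB) folds onto (0, 0);
#' both are excluded from likelihoods by the mask.
#'
#' @param m numeric (nA+1) x (nB+1) matrix over unfolded counts.
#' @param nA,nB haplotype sample sizes.
#' @return folded matrix of the same shape.
#' @export
fold_matrix <- function(m, nA, nB) {
  ij <- cbind(rep(0:nA, times = nB + 1), rep(0:nB, each = nA + 1))
  f <- .fold_rows(ij, nA, nB)
  lin <- f[, 1] + 1L + f[, 2] * (nA + 1L)
  agg <- rowsum(as.vector(m), lin)
  out <- matrix(0, nA + 1, nB + 1)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Hypergeometric projection of a site to a smaller sample
#'
#' Distributes one site's minor-allele count `k_minor` out of `n_from`
#' sampled haplotypes onto the possible counts in a subsample of `n_to`
#' haplotypes, with mass C(k, m) C(n_from - k, n_to - m) / C(n_from, n_to)
#' at count m — the expectation over all subsamples, which removes missing
#' data deterministically instead of by a single random draw.
#'
#' @param k_minor allele copies observed (0..n_from).
#' @param n_from haplotypes genotyped at the site.
#' @param n_to target haplotype number (<= n_from).
#' @return numeric vector of length `n_to + 1` summing to 1.
#' @export
project_site <- function(k_minor, n_from, n_to) {
  if (n_to > n_from) stop("cannot project up: n_to > n_from")
  if (k_minor < 0 || k_minor > n_from) stop("allele count out of range")
  stats::dhyper(0:n_to, k_minor, n_from - k_minor, n_to)
}

#' Folded joint SFS container
#'
#' @param counts (nA+1) x (nB+1) matrix of (possibly fractional) SNP counts
#'   over folded minor-allele configurations.
#' @param popA,popB pair labels.
#' @param nA,nB haplotype sample sizes.
#' @return object of class `folded_joint_sfs`; the `mask` (entries excluded
#'   from likelihood) marks the monomorphic (0, 0) cell and the structurally
#'   empty upper fold.
#' @export
folded_joint_sfs <- function(counts, popA, popB, nA, nB) {
  stopifnot(nrow(counts) == nA + 1, ncol(counts) == nB + 1)
  ii <- matrix(0:nA, nA + 1, nB + 1)
  jj <- matrix(0:nB, nA + 1, nB + 1, byrow = TRUE)
  half <- (nA + nB) / 2
  upper <- ii + jj > half
  tie <- ii + jj == half
  # at the tie line only the lexicographically smaller representative is kept
  tie_dropped <- tie & ((nA - ii) < ii | ((nA - ii) == ii & (nB - jj) < jj))
  mask <- upper | tie_dropped
  mask[1, 1] <- TRUE  # monomorphic-in-pair mass
  obj <- list(counts = counts, mask = mask, popA = popA, popB = popB,
              nA = as.integer(nA), nB = as.integer(nB))
  class(obj) <- "folded_joint_sfs"
  obj
}

#' @export
print.folded_joint_sfs <- function(x, ...) {
  cat(sprintf("folded joint SFS %s (n=%d) x %s (n=%d): %.1f polymorphic SNPs\n",
              x$popA, x$nA, x$popB, x$nB, sum(x$counts[!x$mask])))
  invisible(x)
}

#' Build the folded joint SFS for one population pair
#'
#' Sites genotyped in at least `min_individuals` individuals in each of the
#' two populations are retained; each site's allele counts are projected down
#' to 2 x min_individuals haplotypes per population by hypergeometric
#' expectation, folded to minor-allele configurations, and accumulated.
#' Projection mass landing on the pair-monomorphic configurations goes into
#' the masked (0, 0) cell.  Counts stay fractional internally.
#'
#' @param table a `geno_table`, thinned to one SNP per locus.
#' @param popA,popB population labels present in `table$population_ids`.
#' @param min_individuals length-2 integer: minimum (and target) individuals
#'   genotyped per site in popA and popB.
#' @return a [folded_joint_sfs()], with attribute `"n_sites_used"`.
#' @export
build_pairwise_sfs <- function(table, popA, popB, min_individuals) {
  stopifnot(length(min_individuals) == 2)
  pop <- table$population_ids
  if (is.null(pop)) stop("table has no population assignments")
  gA <- table$geno[pop == popA, , drop = FALSE]
  gB <- table$geno[pop == popB, , drop = FALSE]
  nA <- 2L * as.integer(min_individuals[1])
  nB <- 2L * as.integer(min_individuals[2])
  calledA <- colSums(!is.na(gA)); calledB <- colSums(!is.na(gB))
  use <- calledA >= min_individuals[1] & calledB >= min_individuals[2]
  if (!any(use)) stop("no sites pass the minimum-individual thresholds")
  altA <- colSums(gA, na.rm = TRUE)[use]
  altB <- colSums(gB, na.rm = TRUE)[use]
  fromA <- 2 * calledA[use]; fromB <- 2 * calledB[use]
  unfolded <- matrix(0, nA + 1, nB + 1)
  for (s in seq_along(altA)) {
    vA <- project_site(altA[s], fromA[s], nA)
    vB <- project_site(altB[s], fromB[s], nB)
    unfolded <- unfolded + outer(vA, vB)
  }
  counts <- fold_matrix(unfolded, nA, nB)
  out <- folded_joint_sfs(counts, popA, popB, nA, nB)
  attr(out, "n_sites_used") <- sum(use)
  out
}

#' Build all six pairwise folded joint SFS for four populations
#'
#' @param table a `geno_table` (one SNP per locus).
#' @param min_individuals named integer vector: minimum individuals per
#'   population, e.g. `c(WAS = 13, EGB = 13, `P-W` = 24, WGB = 22)`.
#' @return named list of [folded_joint_sfs()] objects, names "A|B".
#' @export
build_all_pairwise_sfs <- function(table, min_individuals) {
  pops <- names(min_individuals)
  if (is.null(pops)) stop("min_individuals must be named by population")
  out <- list()
  for (i in seq_along(pops)[-length(pops)]) for (j in (i + 1):length(pops)) {
    key <- paste(pops[i], pops[j], sep = "|")
    out[[key]] <- build_pairwise_sfs(table, pops[i], pops[j],
                                     c(min_individuals[[i]], min_individuals[[j]]))
  }
  out
}

#' Write / read a folded joint SFS as plain text
#'
#' Layout: line 1 `# pair <popA> <popB>`, line 2 `# nhap <nA> <nB>`, then the
#' (nA+1) x (nB+1) count matrix, rows = popA minor-allele count, tab-separated.
#'
#' @param sfs a `folded_joint_sfs`.
#' @param path file path.
#' @return `path` invisibly; the reader returns the `folded_joint_sfs`.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# pair", sfs$popA, sfs$popB),
               paste("# nhap", sfs$nA, sfs$nB)), con)
  utils::write.table(sfs$counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  hdr <- readLines(path, n = 2)
  pair <- strsplit(hdr[1], "[ \t]+")[[1]]
  nh <- strsplit(hdr[2], "[ \t]+")[[1]]
  counts <- as.matrix(utils::read.table(path, skip = 2, sep = "\t"))
  dimnames(counts) <- NULL
  folded_joint_sfs(counts, pair[3], pair[4],
                   as.integer(nh[3]), as.integer(nh[4]))
}
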