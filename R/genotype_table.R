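#' Genotype table
#'
#' Container for diploid biallelic SNP genotypes: an individuals-by-sites
#' matrix of alternate-allele dosages (0, 1, 2) with `NA` as the explicit
#' missing state.  Each site carries a locus identifier (the GBS stack it
#' belongs to) and a within-locus position; each individual carries a sampling
#' locality and, optionally, a population label.
#'
#' @param geno integer matrix, individuals x sites, values in \{0, 1, 2, NA\}.
#' @param individual_ids character vector, one label per row of `geno`.
#' @param locality_ids character vector, sampling locality per individual.
#' @param population_ids optional character vector, population per individual
#'   (e.g. WAS/EGB/P-W/WGB); `NULL` if unassigned.
#' @param sites data.frame with columns `locus_id` (character) and `pos`
#'   (integer, 0-based within-locus position), one row per column of `geno`.
#' @return An object of class `geno_table`.
#' @export
genotype_table <- function(geno, individual_ids, locality_ids,
                           population_ids = NULL, sites = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n <- nrow(geno); s <- ncol(geno)
  if (length(individual_ids) != n)
    stop("individual_ids length does not match genotype rows")
  if (length(locality_ids) != n)
    stop("locality_ids length does not match genotype rows")
  if (!is.null(population_ids) && length(population_ids) != n)
    stop("population_ids length does not match genotype rows")
  if (is.null(sites))
    sites <- data.frame(locus_id = as.character(seq_len(s)),
                        pos = rep(0L, s), stringsAsFactors = FALSE)
  if (nrow(sites) != s)
    stop("sites rows do not match genotype columns")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must lie in {0, 1, 2} or be NA (diploid biallelic only)")
  rownames(geno) <- individual_ids
  obj <- list(geno = geno,
              individual_ids = as.character(individual_ids),
              locality_ids = as.character(locality_ids),
              population_ids = if (is.null(population_ids)) NULL
                               else as.character(population_ids),
              sites = sites)
  class(obj) <- "geno_table"
  obj
}

#' @export
print.geno_table <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf("geno_table: %d individuals x %d sites (%d loci), %.1f%% missing\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$sites$locus_id)),
              100 * miss))
  if (!is.null(x$population_ids)) {
    tab <- table(x$population_ids)
    cat("populations:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.geno_table <- function(x) dim(x$geno)

#' Subset a genotype table
#'
#' @param x a `geno_table`.
#' @param individuals row (individual) index vector.
#' @param sites column (site) index vector.
#' @return The subsetted `geno_table`.
#' @export
subset_table <- function(x, individuals = NULL, sites = NULL) {
  if (is.null(individuals)) individuals <- seq_len(nrow(x$geno))
  if (is.null(sites)) sites <- seq_len(ncol(x$geno))
  genotype_table(x$geno[individuals, sites, drop = FALSE],
                 x$individual_ids[individuals],
                 x$locality_ids[individuals],
                 if (is.null(x$population_ids)) NULL
                 else x$population_ids[individuals],
                 x$sites[sites, , drop = FALSE])
}
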