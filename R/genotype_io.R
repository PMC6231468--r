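#' Read a population map
#'
#' Tab-separated text with three columns and no header: individual, sampling
#' locality, population.  Populations must partition localities: a locality
#' may not be assigned to two populations.
#'
#' @param path file path.
#' @return data.frame with columns `individual`, `locality`, `population`.
#' @export
read_population_map <- function(path) {
  pm <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("individual", "locality", "population"))
  if (anyDuplicated(pm$individual))
    stop("population map assigns an individual more than once")
  split_pop <- tapply(pm$population, pm$locality,
                      function(p) length(unique(p)))
  if (any(split_pop > 1))
    stop("populations must partition localities; locality assigned to >1 population: ",
         paste(names(split_pop)[split_pop > 1], collapse = ", "))
  pm
}

#' Read genotypes from a VCF file
#'
#' Parses diploid GT fields into alternate-allele dosages.  Phased (`|`) and
#' unphased (`/`) genotypes are treated identically; `./.` (or `.`) becomes
#' missing.  Sites with more than two observed alleles, or with indel alleles,
#' are skipped with a warning giving the count.  VCF POS is 1-based; internal
#' within-locus positions are 0-based.
#'
#' @param path VCF 4.x file (plain text or gzipped).
#' @param population_map optional data.frame from [read_population_map()]; if
#'   supplied, individuals absent from the map are dropped and locality /
#'   population labels are attached.
#' @param locus_id_from where the GBS locus identifier lives: `"chrom"` (one
#'   locus per CHROM record, the stacks convention) or `"id"` (locus taken
#'   from the ID column, text before the last `locus_id_sep`).
#' @param locus_id_sep separator used when `locus_id_from = "id"`.
#' @return A [genotype_table()].
#' @export
read_vcf <- function(path, population_map = NULL,
                     locus_id_from = c("chrom", "id"), locus_id_sep = "_") {
  locus_id_from <- match.arg(locus_id_from)
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0) stop("no parseable sites in VCF: ", path)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  indel <- nchar(ref) != 1L | (nchar(alt) != 1L & !multi)
  skip <- multi | indel | is.na(alt) | alt == "."
  n_skip <- sum(skip)
  if (n_skip == length(skip))
    stop("no parseable biallelic SNPs in VCF: ", path)
  if (n_skip > 0)
    warning(sprintf("skipped %d non-biallelic-SNP site(s)", n_skip))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!skip, , drop = FALSE]
  fix <- fix[!skip, , drop = FALSE]
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  # haploid-style single-allele entries: treat second allele as missing marker
  one <- nchar(gt) == 1 & !is.na(gt)
  a2[one] <- a1[one]
  d <- (a1 == "1") + (a2 == "1")
  d[a1 == "." | a2 == "." | is.na(gt)] <- NA
  d <- t(matrix(as.integer(d), nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt)))  # individuals x sites
  ind <- colnames(gt)
  locus <- if (locus_id_from == "chrom") fix[, "CHROM"]
           else sub(paste0(locus_id_sep, "[^", locus_id_sep, "]*$"), "",
                    fix[, "ID"])
  sites <- data.frame(locus_id = as.character(locus),
                      pos = as.integer(fix[, "POS"]) - 1L,
                      stringsAsFactors = FALSE)
  locality <- rep(NA_character_, length(ind))
  population <- NULL
  if (!is.null(population_map)) {
    keep <- ind %in% population_map$individual
    if (!all(keep)) {
      warning(sprintf("dropped %d individual(s) absent from population map",
                      sum(!keep)))
      d <- d[keep, , drop = FALSE]
      ind <- ind[keep]
    }
    m <- match(ind, population_map$individual)
    locality <- population_map$locality[m]
    population <- population_map$population[m]
  }
  tab <- genotype_table(d, ind, locality, population, sites)
  message(sprintf("read %d individuals x %d sites from %s",
                  nrow(tab$geno), ncol(tab$geno), path))
  tab
}

#' Write genotypes to a minimal VCF
#'
#' Synthetic alleles (REF=A, ALT=C) are used; CHROM carries the locus ID and
#' POS the 1-based within-locus position, so [read_vcf()] round-trips the
#' dosage matrix exactly.
#'
#' @param table a `geno_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  g <- table$geno
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  ok <- !is.na(g)
  gt[ok] <- gt_map[as.character(g[ok])]
  body <- cbind(table$sites$locus_id, table$sites$pos + 1L,
                paste0(table$sites$locus_id, "_", table$sites$pos),
                "A", "C", ".", "PASS", ".", "GT", t(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", table$individual_ids),
                     collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a STRUCTURE-format genotype file
#'
#' Two rows per individual (one allele per row); the first two columns are the
#' individual and locality labels, followed by one column per site.  A
#' heterozygote contributes alleles (0, 1), dosage 2 contributes (1, 1) and
#' missing genotypes are encoded as -9 on both rows.
#'
#' @param table a `geno_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(table, path) {
  g <- table$geno
  if (nrow(g) == 0 || ncol(g) == 0) stop("empty genotype table")
  n <- nrow(g)
  row1 <- matrix(-9L, n, ncol(g))
  row2 <- matrix(-9L, n, ncol(g))
  ok <- !is.na(g)
  row1[ok] <- ifelse(g[ok] == 2L, 1L, 0L)  # first allele: 1 only when homozygous alt
  row2[ok] <- ifelse(g[ok] >= 1L, 1L, 0L)  # second allele: 1 when dosage >= 1
  out <- matrix("", 2 * n, ncol(g) + 2)
  out[seq(1, 2 * n, by = 2), ] <- cbind(table$individual_ids,
                                        table$locality_ids, row1)
  out[seq(2, 2 * n, by = 2), ] <- cbind(table$individual_ids,
                                        table$locality_ids, row2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a STRUCTURE-format genotype file written by [write_structure_file()]
#'
#' @param path file path.
#' @return A [genotype_table()] (site metadata is synthesised: one locus per
#'   column).
#' @export
read_structure_file <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) %% 2 != 0) stop("STRUCTURE file must have two rows per individual")
  odd <- raw[seq(1, nrow(raw), by = 2), , drop = FALSE]
  even <- raw[seq(2, nrow(raw), by = 2), , drop = FALSE]
  if (!all(odd[[1]] == even[[1]]))
    stop("row pairs disagree on individual labels")
  a1 <- as.matrix(odd[, -(1:2), drop = FALSE])
  a2 <- as.matrix(even[, -(1:2), drop = FALSE])
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  d <- a1 + a2
  d[a1 == -9L | a2 == -9L] <- NA
  genotype_table(d, odd[[1]], odd[[2]])
}
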