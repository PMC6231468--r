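# shared toy demographies and fixtures built in code

single_pop_model <- function(N) {
  list(n_demes = 1L, event_times = numeric(0), event_src = integer(0),
       event_dst = integer(0), sizes = matrix(N, 1, 1), mig = 0)
}

# two populations of size N merging into an ancestor of size n_anc at T,
# optional symmetric backward migration rate m (per generation)
two_pop_split <- function(T_split, N = 10000, n_anc = 10000, m = 0) {
  list(n_demes = 2L, event_times = T_split, event_src = 1L, event_dst = 0L,
       sizes = rbind(c(N, N), c(n_anc, N)),
       mig = c(0, m, m, 0, 0, 0, 0, 0))
}

# builder + names for the one-parameter (split time) toy used in fitting and
# bootstrap-coverage checks
split_time_builder <- function(N = 10000, n_anc = 10000) {
  function(params, n_anc_arg) two_pop_split(params[["T_split"]], N = N,
                                            n_anc = n_anc)
}

# small deterministic VCF written as text; returns the path
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("loc1", 5, "loc1_4", "A", "C", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("loc1", 9, "loc1_8", "G", "T", ".", "PASS", ".", "GT",
          "0|0", "0/0", "./.", sep = "\t"),
    paste("loc2", 2, "loc2_1", "A", "C,T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "2/2", sep = "\t"))
  writeLines(lines, path)
  path
}

write_toy_popmap <- function(path = tempfile(fileext = ".tsv"),
                             individuals = c("s1", "s2", "s3"),
                             localities = c("locA", "locA", "locB"),
                             populations = c("WAS", "WAS", "EGB")) {
  writeLines(paste(individuals, localities, populations, sep = "\t"), path)
  path
}

table2_truth <- function() bluebunch_params(3)

mc_se <- function(x) stats::sd(x) / sqrt(length(x))
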