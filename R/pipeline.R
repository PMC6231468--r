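#' Default pipeline configuration
#'
#' Thresholds and run settings reproducing the study's stated analysis
#' conditions: theta whitelist quantile 0.95; SNPs dropped above 70% missing
#' and individuals above 90%; diversity subsampling of 4 individuals x 20
#' replicates; minimum individuals per population 13 (WAS), 13 (EGB),
#' 24 (P/W), 22 (WGB) for the joint SFS; mu = 7e-9, generation time 1 year,
#' N_ANC = 60,000; 100 runs x 40 ECM cycles x 200,000 simulations per
#' likelihood estimation and 100 parametric-bootstrap replicates.  Every
#' value can be overridden.
#'
#' @param ... overrides for any default element.
#' @return named list of settings.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    vcf = NULL, population_map = NULL, out_dir = "sfscoal-out",
    locus_id_from = "chrom",
    theta_quantile = 0.95,
    snp_max_missing = 0.70,
    ind_max_missing = 0.90,
    n_per_locality = 4,
    subsample_replicates = 20,
    min_individuals = c(WAS = 13, EGB = 13, PW = 24, WGB = 22),
    mu = 7e-9, gen_time = 1, n_anc = 60000,
    n_runs = 100, n_cycles = 40, n_sims = 200000,
    n_bootstrap = 100, bootstrap_runs = 10, bootstrap_cycles = 20,
    models = 1:3,
    run_bootstrap = TRUE,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path file path.
#' @return a config list (reader) or `path` invisibly (writer).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$min_individuals)) raw$min_individuals <- unlist(raw$min_individuals)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a config list from [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- config
  cfg$min_individuals <- as.list(cfg$min_individuals)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' read VCF -> theta whitelist -> missingness filters -> diversity statistics
#' and pairwise F_ST -> one SNP per locus -> six pairwise folded joint SFS ->
#' composite-likelihood fits of the configured models -> AIC selection ->
#' parametric bootstrap of the best model.  All stage outputs plus a run
#' manifest (settings, seed, input checksum, stage seeds) are written to
#' `config$out_dir`.
#'
#' @param config list from [pipeline_config()]; `vcf` and `population_map`
#'   paths are required.
#' @return list with the principal objects: `table` (filtered), `stats`,
#'   `fst`, `sfs`, `fits`, `selection`, `bootstrap`.
#' @export
run_pipeline <- function(config) {
  for (field in c("vcf", "population_map")) {
    if (is.null(config[[field]]))
      stop("config field '", field, "' is required")
    if (!file.exists(config[[field]]))
      stop("config field '", field, "' points to a missing file: ",
           config[[field]])
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  stage_seed <- function(i) as.integer(config$seed + 1000L * i)
  log_msg <- function(...) message("[sfscoal] ", sprintf(...))

  log_msg("stage 1: read")
  pm <- read_population_map(config$population_map)
  tab <- read_vcf(config$vcf, pm, locus_id_from = config$locus_id_from)

  log_msg("stage 2: theta whitelist")
  rec <- per_locus_theta(tab)
  wl <- whitelist_by_quantile(rec, config$theta_quantile)
  write_whitelist(wl, out("whitelist.txt"))
  tab <- apply_whitelist(tab, wl)

  log_msg("stage 3: missingness filters")
  tab <- filter_missingness(tab, config$snp_max_missing, config$ind_max_missing)
  log_msg("  dropped %d sites, %d individuals",
          attr(tab, "n_sites_dropped"), attr(tab, "n_individuals_dropped"))

  log_msg("stage 4: diversity statistics and F_ST")
  stats <- diversity_stats(tab)
  write_stats_table(stats, out("diversity.tsv"))
  sub <- subsampled_stats(tab, config$n_per_locality,
                          config$subsample_replicates, seed = stage_seed(4))
  write_stats_table(sub$replicates, out("diversity_subsampled.tsv"))
  fst <- pairwise_fst(tab)
  write_stats_table(fst, out("fst.tsv"))

  log_msg("stage 5: one SNP per locus + joint SFS")
  thin <- one_snp_per_locus(tab, seed = stage_seed(5))
  sfs <- build_all_pairwise_sfs(thin, config$min_individuals)
  for (nm in names(sfs))
    write_sfs(sfs[[nm]], out(paste0("sfs_", gsub("[|/]", "-", nm), ".txt")))

  log_msg("stage 6: model fitting (%d models)", length(config$models))
  fits <- list()
  for (m in config$models) {
    fits[[as.character(m)]] <- multi_run_fit(
      sfs, model_id = m, n_runs = config$n_runs, n_cycles = config$n_cycles,
      n_sims = config$n_sims, seed = stage_seed(6) + m,
      n_anc = config$n_anc, mu = config$mu, gen_time = config$gen_time)
    utils::write.table(fits[[as.character(m)]]$runs,
                       out(paste0("fit_model", m, "_runs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  selection <- NULL
  if (length(fits) >= 2) {
    log_msg("stage 7: AIC selection")
    selection <- aic_select(fits)
    write_stats_table(selection, out("model_selection.tsv"))
  }

  boot <- NULL
  if (isTRUE(config$run_bootstrap)) {
    log_msg("stage 8: parametric bootstrap")
    best <- if (is.null(selection)) fits[[1]]
            else fits[[selection$model_id[1]]]
    # every SNP appears in each pair's spectrum; the per-pair total (masked
    # cells included) is the SNP count of the largest-coverage pair
    n_snps <- round(max(best$observed_signature))
    boot <- parametric_bootstrap(best, n_snps = n_snps,
                                 n_reps = config$n_bootstrap,
                                 runs = config$bootstrap_runs,
                                 cycles = config$bootstrap_cycles,
                                 n_sims = config$n_sims,
                                 seed = stage_seed(8))
    write_stats_table(cbind(estimate = best$params, boot$ci),
                      out("bootstrap_ci.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sfscoal")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[setdiff(names(config), c("vcf", "population_map"))],
    inputs = list(vcf = config$vcf,
                  vcf_md5 = unname(tools::md5sum(config$vcf)),
                  population_map = config$population_map,
                  population_map_md5 = unname(tools::md5sum(config$population_map))),
    stage_seeds = vapply(1:8, stage_seed, integer(1)))
  manifest$config$min_individuals <- as.list(manifest$config$min_individuals)
  yaml::write_yaml(manifest, out("manifest.yaml"))
  log_msg("done; outputs in %s", config$out_dir)

  invisible(list(table = tab, stats = stats, fst = fst, sfs = sfs,
                 fits = fits, selection = selection, bootstrap = boot))
}
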