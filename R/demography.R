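#' Ancestral effective population size from nucleotide diversity
#'
#' N_ANC = theta_pi / 2 / (mu * g): per-site nucleotide diversity converted
#' to a diploid effective size under theta_pi = 4 N mu g (g in years per
#' generation, mu per site per generation).
#'
#' @param theta_pi_per_site per-site nucleotide diversity (> 0).
#' @param mu mutation rate per site per generation (default 7e-9, the
#'   genome-wide SNP rate measured in *Arabidopsis thaliana*).
#' @param gen_time generation time in years (default 1: time to first
#'   potential reproduction for a perennial bunchgrass).
#' @return diploid N_ANC.
#' @export
ancestral_ne <- function(theta_pi_per_site, mu = 7e-9, gen_time = 1) {
  if (theta_pi_per_site <= 0 || mu <= 0 || gen_time <= 0)
    stop("all inputs must be positive")
  theta_pi_per_site / 2 / (mu * gen_time)
}

#' Convert a 2Nm-scaled migration rate to a per-generation rate
#'
#' The 2Nm scale reports the expected number of migrant gene copies per
#' generation; dividing by twice the (diploid) size of the deme that receives
#' the migrants recovers the per-generation per-lineage rate m.  On the
#' backward-in-time view used by the simulator, that deme is the one whose
#' lineages trace away (the first subscript of the rate label).
#'
#' @param two_Nm migration rate on the 2Nm scale (>= 0).
#' @param N_receiving diploid size of the receiving deme (> 0).
#' @return per-generation rate m.
#' @export
scaled_to_raw_migration <- function(two_Nm, N_receiving) {
  if (N_receiving <= 0) stop("N_receiving must be positive")
  if (two_Nm < 0) stop("2Nm must be non-negative")
  two_Nm / (2 * N_receiving)
}

#' @rdname scaled_to_raw_migration
#' @param m per-generation migration rate.
#' @export
raw_to_scaled_migration <- function(m, N_receiving) {
  if (N_receiving <= 0) stop("N_receiving must be positive")
  m * 2 * N_receiving
}

#' Names of the 15 estimated parameters
#'
#' Sizes in diploid individuals, times in generations before present,
#' migration on the 2Nm scale.  Migration subscripts name the population
#' pairs WAS-EGB (we/ew), EGB-P/W (ep/pe) and P/W-WGB (pw/wp); the first
#' letter is the deme whose lineages move backward in time (equivalently,
#' the forward-time recipient of migrants).
#'
#' @return character vector of length 15.
#' @export
model_param_names <- function() {
  c("N_1", "N_2", "N_WAS", "N_EGB", "N_PW", "N_WGB",
    "T_1", "T_2", "T_3",
    "m_we", "m_ew", "m_ep", "m_pe", "m_pw", "m_wp")
}

#' Point estimates from the bluebunch wheatgrass four-population study
#'
#' Published composite maximum-likelihood estimates for the three divergence/
#' migration models, used as synthetic ground truth in recovery experiments.
#' Sizes are diploid individuals, times generations, migration 2Nm.
#'
#' @param model_id 1, 2 or 3.
#' @return named numeric vector over [model_param_names()].
#' @export
bluebunch_params <- function(model_id = 3) {
  tab <- list(
    `1` = c(N_1 = 3699, N_2 = 288066, N_WAS = 53347, N_EGB = 34107,
            N_PW = 21833, N_WGB = 11813, T_1 = 16007, T_2 = 13513,
            T_3 = 21781, m_we = 0.03, m_ew = 0.05, m_ep = 0.65,
            m_pe = 1.02, m_pw = 4.94, m_wp = 9.13),
    `2` = c(N_1 = 506615, N_2 = 116398, N_WAS = 49589, N_EGB = 37414,
            N_PW = 37272, N_WGB = 6858, T_1 = 13835, T_2 = 29483,
            T_3 = 30923, m_we = 0.13, m_ew = 0.18, m_ep = 0.66,
            m_pe = 0.67, m_pw = 4.72, m_wp = 25.64),
    `3` = c(N_1 = 8033, N_2 = 3014, N_WAS = 62936, N_EGB = 45907,
            N_PW = 30800, N_WGB = 10363, T_1 = 15211, T_2 = 23171,
            T_3 = 24740, m_we = 0.46, m_ew = 0.64, m_ep = 0.68,
            m_pe = 1.02, m_pw = 4.23, m_wp = 12.57))
  tab[[as.character(model_id)]]
}

#' Build a four-population divergence/migration model
#'
#' The four present-day populations are WAS, EGB, P/W and WGB.  Three merge
#' events (backward in time) define the history; which populations merge when
#' depends on the model:
#' \describe{
#'   \item{Model 1 (tree)}{P/W+WGB merge at T_1 (ancestor size N_1) and
#'     WAS+EGB at T_2 (size N_2); the two ancestors join at T_3 (N_ANC).
#'     T_1 and T_2 sit on different branches, so only T_1 < T_3 and
#'     T_2 < T_3 are required.}
#'   \item{Model 2 (stepping-stone, WGB last)}{WAS+EGB at T_1 (N_1), +P/W at
#'     T_2 (N_2), +WGB at T_3 (N_ANC); T_1 < T_2 < T_3.}
#'   \item{Model 3 (stepping-stone, WAS last)}{P/W+WGB at T_1 (N_1), +EGB at
#'     T_2 (N_2), +WAS at T_3 (N_ANC); T_1 < T_2 < T_3.}
#' }
#' Migration runs only between geographically adjacent extant pairs
#' (WAS-EGB, EGB-P/W, P/W-WGB) while both partners exist; ancestral demes
#' exchange no migrants.  Rates are taken on the 2Nm scale and divided by
#' twice the present size of the first-subscript deme.
#'
#' @param model_id 1, 2 or 3.
#' @param params named numeric vector over [model_param_names()].
#' @param n_anc fixed ancestral diploid size (default 60000, obtained from
#'   [ancestral_ne()] at theta_pi = 8.4e-4, mu = 7e-9, g = 1).
#' @param mu mutation rate per site per generation.
#' @param gen_time generation time in years.
#' @return object of class `demog_model`.
#' @export
demographic_model <- function(model_id, params, n_anc = 60000,
                              mu = 7e-9, gen_time = 1) {
  if (!model_id %in% 1:3) stop("model_id must be 1, 2 or 3")
  need <- model_param_names()
  if (!all(need %in% names(params)))
    stop("missing parameters: ", paste(setdiff(need, names(params)), collapse = ", "))
  p <- params[need]
  if (any(p[c("N_1", "N_2", "N_WAS", "N_EGB", "N_PW", "N_WGB")] <= 0))
    stop("population sizes must be positive")
  if (any(p[c("m_we", "m_ew", "m_ep", "m_pe", "m_pw", "m_wp")] < 0))
    stop("migration rates must be non-negative")
  if (n_anc <= 0) stop("n_anc must be positive")
  T1 <- p[["T_1"]]; T2 <- p[["T_2"]]; T3 <- p[["T_3"]]
  if (min(T1, T2, T3) <= 0) stop("divergence times must be positive")
  if (model_id == 1) {
    if (T1 >= T3 || T2 >= T3)
      stop("model 1 requires T_1 < T_3 and T_2 < T_3")
  } else if (T1 >= T2 || T2 >= T3) {
    stop("models 2 and 3 require T_1 < T_2 < T_3")
  }
  # demes 1..4 = WAS, EGB, PW, WGB; merges: (time, src -> dst, new dst size)
  events <- switch(model_id,
    list(c(T1, 4, 3, p[["N_1"]]), c(T2, 2, 1, p[["N_2"]]),
         c(T3, 1, 3, n_anc)),
    list(c(T1, 2, 1, p[["N_1"]]), c(T2, 3, 1, p[["N_2"]]),
         c(T3, 4, 1, n_anc)),
    list(c(T1, 4, 3, p[["N_1"]]), c(T2, 2, 3, p[["N_2"]]),
         c(T3, 1, 3, n_anc)))
  events <- events[order(vapply(events, `[`, numeric(1), 1))]
  obj <- list(model_id = model_id, params = p, n_anc = n_anc, mu = mu,
              gen_time = gen_time, labels = c("WAS", "EGB", "PW", "WGB"),
              events = events)
  class(obj) <- "demog_model"
  obj
}

#' @export
print.demog_model <- function(x, ...) {
  cat(sprintf("four-population model %d (N_ANC = %g fixed)\n", x$model_id,
              x$n_anc))
  cat("  sizes:", paste(sprintf("%s=%g", c("WAS", "EGB", "P/W", "WGB"),
      x$params[c("N_WAS", "N_EGB", "N_PW", "N_WGB")]), collapse = " "), "\n")
  for (e in x$events)
    cat(sprintf("  t=%g: %s -> %s (N=%g)\n", e[1], x$labels[e[2]],
                x$labels[e[3]], e[4]))
  invisible(x)
}

# piecewise-constant epoch encoding consumed by the C++ simulator
demog_epochs <- function(model) {
  K <- 4L
  p <- model$params
  E <- length(model$events)
  etimes <- vapply(model$events, `[`, numeric(1), 1)
  esrc <- vapply(model$events, `[`, numeric(1), 2)
  edst <- vapply(model$events, `[`, numeric(1), 3)
  sizes <- matrix(0, E + 1, K)
  sizes[1, ] <- p[c("N_WAS", "N_EGB", "N_PW", "N_WGB")]
  present <- sizes[1, ]
  alive <- rep(TRUE, K)      # original populations still extant
  ancestor <- rep(FALSE, K)  # deme slot currently holds an ancestral pop
  # raw backward rates between adjacent pairs; [i, j]: lineage in i -> j
  base <- matrix(0, K, K)
  base[1, 2] <- scaled_to_raw_migration(p[["m_we"]], present[1])
  base[2, 1] <- scaled_to_raw_migration(p[["m_ew"]], present[2])
  base[2, 3] <- scaled_to_raw_migration(p[["m_ep"]], present[2])
  base[3, 2] <- scaled_to_raw_migration(p[["m_pe"]], present[3])
  base[3, 4] <- scaled_to_raw_migration(p[["m_pw"]], present[3])
  base[4, 3] <- scaled_to_raw_migration(p[["m_wp"]], present[4])
  mig <- array(0, c(E + 1, K, K))
  epoch_mig <- function() {
    m <- base
    off <- !alive | ancestor
    m[off, ] <- 0
    m[, off] <- 0
    m
  }
  mig[1, , ] <- epoch_mig()
  for (e in seq_len(E)) {
    sizes[e + 1, ] <- sizes[e, ]
    sizes[e + 1, edst[e]] <- model$events[[e]][4]
    alive[esrc[e]] <- FALSE
    ancestor[edst[e]] <- TRUE
    mig[e + 1, , ] <- epoch_mig()
  }
  list(n_demes = K, event_times = etimes, event_src = as.integer(esrc - 1),
       event_dst = as.integer(edst - 1), sizes = sizes,
       mig = as.numeric(aperm(mig, c(3, 2, 1))))  # j fastest, then i, then epoch
}

#' Serialise / read a demographic model as a YAML configuration
#'
#' @param model a `demog_model`.
#' @param path file path.
#' @return `path` invisibly; the reader returns the `demog_model`.
#' @export
write_model <- function(model, path) {
  yaml::write_yaml(list(model_id = model$model_id,
                        params = as.list(model$params),
                        n_anc = model$n_anc, mu = model$mu,
                        gen_time = model$gen_time), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  demographic_model(cfg$model_id, unlist(cfg$params), n_anc = cfg$n_anc,
                    mu = cfg$mu, gen_time = cfg$gen_time)
}
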