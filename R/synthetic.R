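#' Configuration of the synthetic-data generator
#'
#' Describes the statistical world the generator emulates: a CCM2-like
#' subbasin size distribution (lognormal, mean ~7 km2, interquartile range
#' ~1-8 km2), a random tree topology with discharge accumulating
#' downstream, a 5-25 C water-temperature gradient, clustered population
#' with density-ranked treatment levels, patchy livestock densities
#' spanning the 25 LU/km2 intensive threshold, a few industrial TOC
#' point emitters, and noisy mean-annual observations at a subset of
#' subbasins. See the methods vignette for the rationale of each default.
#'
#' @param n_subbasins Number of subbasins (>= 1).
#' @param seed Integer seed; every generator draw derives from it.
#' @param n_outlets Number of independent trees (sea outlets).
#' @param area_meanlog,area_sdlog Lognormal area parameters (km2); the
#'   defaults give mean 7 km2 and IQR ~1-7 km2.
#' @param runoff_l_s_km2 Specific runoff feeding discharge accumulation.
#' @param temp_range Water-temperature range (degrees C).
#' @param rural_density_per_km2 Baseline population density.
#' @param n_clusters Number of population clusters (towns).
#' @param cluster_pop_meanlog,cluster_pop_sdlog Lognormal town sizes.
#' @param treatment_shares Named national shares over
#'   tertiary/secondary/primary/none (connected population).
#' @param ias_frac,sd_frac Fractions of population on Individual
#'   Appropriate Systems and in scattered dwellings (disconnected).
#' @param ruminant_density_meanlog,ruminant_density_sdlog Lognormal
#'   cattle + sheep/goat density (LU/km2), spanning the 25 LU/km2
#'   threshold.
#' @param pig_subbasin_frac Fraction of subbasins hosting pig/chicken
#'   production.
#' @param pig_lu_meanlog,pig_lu_sdlog Lognormal pig/chicken LU per hosting
#'   subbasin.
#' @param facility_frac Fraction of subbasins hosting an industrial
#'   facility.
#' @param toc_meanlog,toc_sdlog Lognormal facility TOC emissions (t/y).
#' @param coverage Fraction of subbasins with a monitoring station.
#' @param sigma Multiplicative lognormal noise (log-sd) on observed
#'   concentrations.
#' @param n_samples_range Integer range of yearly sample counts; values
#'   below 6 make a record unreliable and excluded from scoring.
#' @param bod7_frac Fraction of stations reporting BOD7 instead of BOD5.
#' @return An object of class `bod_synth_config` (named list).
#' @export
synth_config <- function(n_subbasins = 200, seed = 42L,
                         n_outlets = max(1L, round(n_subbasins / 100)),
                         area_meanlog = log(7) - 1.4^2 / 2, area_sdlog = 1.4,
                         runoff_l_s_km2 = 10,
                         temp_range = c(5, 25),
                         rural_density_per_km2 = 30,
                         n_clusters = max(1L, round(n_subbasins / 25)),
                         cluster_pop_meanlog = log(2e4),
                         cluster_pop_sdlog = 1,
                         treatment_shares = c(tertiary = 0.60,
                                              secondary = 0.25,
                                              primary = 0.10, none = 0.05),
                         ias_frac = 0.05, sd_frac = 0.05,
                         ruminant_density_meanlog = log(10),
                         ruminant_density_sdlog = 1,
                         pig_subbasin_frac = 0.2,
                         pig_lu_meanlog = log(500), pig_lu_sdlog = 1,
                         facility_frac = 0.02,
                         toc_meanlog = log(50), toc_sdlog = 1,
                         coverage = 0.3, sigma = 0.1,
                         n_samples_range = c(4L, 12L),
                         bod7_frac = 0.15) {
  cfg <- as.list(environment())
  if (cfg$n_subbasins < 1) stop("'n_subbasins' must be >= 1")
  if (cfg$sigma < 0) stop("'sigma' must be >= 0")
  if (cfg$coverage < 0 || cfg$coverage > 1) stop("'coverage' must be in [0, 1]")
  if (abs(sum(cfg$treatment_shares) - 1) > 1e-9)
    stop("'treatment_shares' must sum to 1")
  structure(cfg, class = "bod_synth_config")
}

#' Generate a synthetic river network and all model inputs
#'
#' Builds a random forest of `n_outlets` trees by preferential downstream
#' attachment, draws physical attributes from the configured distributions,
#' accumulates discharge downstream (so a node's discharge is never below
#' any upstream node's), and emits the demographic, livestock and
#' industrial input tables. Identical seeds reproduce identical outputs.
#'
#' @param cfg A [synth_config()] object.
#' @return An object of class `bod_synth_inputs`: list with `network`
#'   (a [build_network()] object), `demographics`, `livestock`,
#'   `industrial` (input tables) and `config`.
#' @export
generate_network <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "bod_synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_subbasins
  k <- min(cfg$n_outlets, n)
  ids <- sprintf("sb%04d", seq_len(n))

  # preferential downstream attachment: trees grow headwards from outlets
  down <- rep(NA_integer_, n)
  weight <- rep(1, n)  # 1 + number of already-attached upstream nodes
  if (n > k) {
    for (i in (k + 1L):n) {
      parent <- sample.int(i - 1L, 1L, prob = weight[seq_len(i - 1L)])
      down[i] <- parent
      weight[parent] <- weight[parent] + 1
    }
  }

  area <- stats::rlnorm(n, cfg$area_meanlog, cfg$area_sdlog)
  temp <- stats::runif(n, cfg$temp_range[1L], cfg$temp_range[2L])
  urban_frac <- stats::runif(n, 0.01, 0.08)
  natural_frac <- stats::runif(n, 0.2, 0.8) * (1 - urban_frac)
  velocity <- stats::rlnorm(n, log(0.8), 0.3)

  # discharge: local runoff accumulated downstream in attachment order
  local_q <- area * cfg$runoff_l_s_km2 / 1000
  q <- local_q
  for (i in rev(seq_len(n))) if (!is.na(down[i])) q[down[i]] <- q[down[i]] + q[i]

  sb <- data.frame(
    id = ids,
    downstream_id = ifelse(is.na(down), "sea", ids[down]),
    area_km2 = area,
    natural_area_km2 = area * natural_frac,
    urban_runoff_m3s = area * urban_frac * 15 / 1000,
    reach_length_km = 1.2 * sqrt(area),
    discharge_m3s = q,
    water_temp_C = temp,
    velocity_ms = velocity,
    stringsAsFactors = FALSE
  )
  net <- build_network(sb)

  pop <- area * cfg$rural_density_per_km2 *
    stats::rlnorm(n, -0.125, 0.5)
  clusters <- sample.int(n, min(cfg$n_clusters, n))
  pop[clusters] <- pop[clusters] +
    stats::rlnorm(length(clusters), cfg$cluster_pop_meanlog,
                  cfg$cluster_pop_sdlog)
  shares <- allocate_treatment_levels(
    data.frame(id = ids, inhabitants = pop, area_km2 = area,
               stringsAsFactors = FALSE),
    cfg$treatment_shares)
  pe <- population_to_pe(pop)
  connected <- pe * (1 - cfg$ias_frac - cfg$sd_frac)
  demographics <- data.frame(
    id = ids,
    pe_untreated = connected * shares$none,
    pe_primary = connected * shares$primary,
    pe_secondary = connected * shares$secondary,
    pe_tertiary = connected * shares$tertiary,
    pe_ias = pe * cfg$ias_frac,
    pe_sd = pe * cfg$sd_frac,
    stringsAsFactors = FALSE
  )

  rum_density <- stats::rlnorm(n, cfg$ruminant_density_meanlog,
                               cfg$ruminant_density_sdlog)
  pig_hosts <- stats::runif(n) < cfg$pig_subbasin_frac
  livestock <- data.frame(
    id = ids,
    lu_cattle = 0.7 * rum_density * area,
    lu_sheep_goat = 0.3 * rum_density * area,
    lu_pig = ifelse(pig_hosts,
                    stats::rlnorm(n, cfg$pig_lu_meanlog, cfg$pig_lu_sdlog), 0),
    lu_chicken = ifelse(pig_hosts,
                        0.3 * stats::rlnorm(n, cfg$pig_lu_meanlog,
                                            cfg$pig_lu_sdlog), 0),
    stringsAsFactors = FALSE
  )

  hosts <- which(stats::runif(n) < cfg$facility_frac)
  if (!length(hosts)) hosts <- sample.int(n, 1L)
  industrial <- data.frame(
    id = ids[hosts],
    toc_t_y = stats::rlnorm(length(hosts), cfg$toc_meanlog, cfg$toc_sdlog),
    stringsAsFactors = FALSE
  )

  structure(list(network = net, demographics = demographics,
                 livestock = livestock, industrial = industrial,
                 config = cfg),
            class = "bod_synth_inputs")
}

#' Generate noisy observations from a known truth
#'
#' Routes the synthetic inputs at the generating parameter set, picks a
#' seeded random subset of subbasins as monitoring stations, and perturbs
#' the true concentrations with multiplicative lognormal noise
#' (concentrations are positive and right-skewed). Yearly sample counts are
#' drawn so that some records fall below the six-sample reliability filter;
#' a fraction of stations report BOD7 (stored as `conc * 1.16`).
#'
#' @param synth A [generate_network()] result.
#' @param params The generating ("true") [bod_params()].
#' @param cfg Configuration; defaults to the one inside `synth`.
#' @param seed Seed for station choice and noise (distinct from the
#'   network seed so the same network supports many observation draws).
#' @param constants A [bod_constants()] object.
#' @return Data frame `station_id`, `subbasin_id`, `mean_conc_mg_l`,
#'   `n_samples`, `variant`, plus the noise-free `true_conc_mg_l`.
#' @export
generate_observations <- function(synth, params = bod_params(),
                                  cfg = synth$config,
                                  seed = cfg$seed + 1L,
                                  constants = bod_constants()) {
  stopifnot(inherits(synth, "bod_synth_inputs"))
  net <- synth$network
  fl <- route_network(net, compute_emissions(net, synth$demographics,
                                             synth$livestock,
                                             synth$industrial, params,
                                             constants),
                      params, constants)
  set.seed(seed)
  n <- nrow(net$subbasins)
  n_st <- round(cfg$coverage * n)
  if (n_st == 0L)
    return(data.frame(station_id = character(), subbasin_id = character(),
                      mean_conc_mg_l = numeric(), n_samples = integer(),
                      variant = character(), true_conc_mg_l = numeric(),
                      stringsAsFactors = FALSE))
  st <- sort(sample.int(n, n_st))
  true_conc <- fl$concentration_mg_l[st]
  noisy <- true_conc * exp(stats::rnorm(n_st, 0, cfg$sigma))
  is7 <- stats::runif(n_st) < cfg$bod7_frac
  data.frame(
    station_id = sprintf("st%04d", seq_len(n_st)),
    subbasin_id = net$subbasins$id[st],
    mean_conc_mg_l = ifelse(is7, noisy * constants$bod7_to_bod5_divisor,
                            noisy),
    n_samples = sample(cfg$n_samples_range[1L]:cfg$n_samples_range[2L],
                       n_st, replace = TRUE),
    variant = ifelse(is7, "BOD7", "BOD5"),
    true_conc_mg_l = true_conc,
    stringsAsFactors = FALSE
  )
}

#' Parameter-recovery experiment on synthetic data
#'
#' End-to-end validation of the calibration machinery: generates a network
#' and noisy observations at a known parameter set, runs the Latin
#' Hypercube calibration, and reports whether the behavioral envelope
#' (per-parameter min-max over behavioral sets) covers the truth, plus the
#' rank correlation of each parameter with KGE across all sampled sets.
#'
#' @param cfg A [synth_config()]; its `seed` drives the whole experiment.
#' @param n_lhs Number of Latin Hypercube parameter sets.
#' @param seed Overrides `cfg$seed` when given.
#' @param params The generating truth (default: the calibrated set).
#' @return List with `coverage` (named logical: truth inside the behavioral
#'   envelope), `envelope` (2 x 10 matrix), `kge_cor` (named Spearman
#'   correlations with KGE), `best_gof` (GOF of the max-KGE behavioral
#'   set), `run` (the full [run_calibration()] object) and `truth`.
#' @export
recovery_experiment <- function(cfg = synth_config(), n_lhs = 300,
                                seed = NULL, params = bod_params()) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  synth <- generate_network(cfg)
  obs <- generate_observations(synth, params, cfg)
  run <- run_calibration(synth$network,
                         list(demographics = synth$demographics,
                              livestock = synth$livestock,
                              industrial = synth$industrial),
                         obs, n = n_lhs, seed = cfg$seed + 1L)
  pnames <- param_ranges()$parameter
  beh <- run$sets[run$sets$behavioral, pnames, drop = FALSE]
  envelope <- rbind(lower = apply(beh, 2L, min), upper = apply(beh, 2L, max))
  truth <- unlist(unclass(params))[pnames]
  coverage <- truth >= envelope["lower", ] & truth <= envelope["upper", ]
  kge_cor <- vapply(pnames, function(p)
    stats::cor(run$sets[[p]], run$sets$kge, method = "spearman"),
    numeric(1L))
  best_i <- which(run$sets$behavioral)[which.max(run$sets$kge[run$sets$behavioral])]
  list(coverage = coverage, envelope = envelope, kge_cor = kge_cor,
       best_gof = run$sets[best_i, c("kge", "r2", "mae", "rmse", "pbias")],
       run = run, truth = truth)
}
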