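#' Build a simulation scenario
#'
#' A `scenario_config` parameterizes every synthetic table the package can
#' generate: belt-transect fish censuses (40 m2 = 20 x 2 m strips), 2 m2 /
#' 10 min remote-video feeding plots, 50-point photoquadrats and stomach
#' spreads, multiple-choice herbivory assays with a caged autogenic control,
#' and 10 x 10 cm algal-turf scrapes with their cryptofauna.
#'
#' Habitat effects enter only through the configured rates: expected counts,
#' bite rates, cover probabilities and turf means are all habitat-indexed.
#'
#' @param habitats character vector of habitat labels.
#' @param n_transects_per_habitat named integer vector (or single integer
#'   recycled) of belt transects per habitat.
#' @param n_video_plots_per_habitat named integer vector of 2 m2 video plots
#'   per habitat; habitats absent from the vector get no plots.
#' @param species_pool data.frame with columns `species`, `group`,
#'   `feeding_group`, `a`, `b` (length-weight W = a L^b, g and cm),
#'   `mean_length_cm`, `length_cv`.
#' @param abundance_means habitat x species matrix of expected counts per
#'   40 m2 transect.
#' @param bite_rate_means habitat x species matrix of expected bites per
#'   individual per 10 min plot observation (rows restricted to habitats
#'   with video plots).
#' @param dispersion_k negative-binomial dispersion for counts; `Inf` gives
#'   the Poisson limit.
#' @param cover_profiles habitat x benthic-category probability matrix
#'   (rows sum to 1).
#' @param stomach_profiles consumer-species x diet-item probability matrix
#'   (rows sum to 1).
#' @param n_stomachs_per_species stomach spreads generated per consumer.
#' @param assay_profile list describing the multiple-choice assay: `algae`
#'   (names), `bite_share` (per-alga probability vector), `loss_fraction`
#'   (per-alga control mass-loss fraction in [0,1)), `offered_mass_mean_g`,
#'   `offered_mass_cv`, `species_share` (named vector over herbivore
#'   species), `total_bites_mean` (Poisson mean per trial),
#'   `mass_per_bite_g`, `bite_mass_cv` (lognormal noise on removed mass),
#'   `control_noise_cv`.
#' @param n_assay_trials number of assay trials (the study ran 13 over
#'   3 days).
#' @param turf_params list: `pools` (habitat -> pool-name vector),
#'   `n_samples_per_pool`, `mean_dry_weight_g` (named by habitat, g per
#'   100 cm2), `dry_weight_cv`, `taxon_shares` (habitat x turf-taxon
#'   proportion matrix), `crypto_intercept`, `crypto_slope` (individuals per
#'   g), `crypto_noise_sd` (lognormal SD on the Poisson rate),
#'   `crypto_group_shares` (named proportions over cryptofauna groups).
#' @param n_points_per_set point-intercept points per photoquadrat/stomach
#'   (50 in the study design).
#' @param n_quadrats_per_plot photoquadrats per video plot (5 in the study).
#' @param transect_area_m2,plot_area_m2 sampled areas.
#' @param seed integer root seed; each table derives its own stream.
#' @return an object of class `scenario_config` (a validated list).
#' @seealso [default_scenario()], [simulate_tables()]
#' @export
scenario_config <- function(habitats,
                            n_transects_per_habitat,
                            n_video_plots_per_habitat,
                            species_pool,
                            abundance_means,
                            bite_rate_means,
                            dispersion_k = 5,
                            cover_profiles,
                            stomach_profiles,
                            n_stomachs_per_species = 10L,
                            assay_profile,
                            n_assay_trials = 13L,
                            turf_params,
                            n_points_per_set = 50L,
                            n_quadrats_per_plot = 5L,
                            transect_area_m2 = 40,
                            plot_area_m2 = 2,
                            seed = 1L) {
  if (length(n_transects_per_habitat) == 1L && is.null(names(n_transects_per_habitat)))
    n_transects_per_habitat <- stats::setNames(rep(n_transects_per_habitat, length(habitats)), habitats)
  cfg <- structure(list(
    habitats = as.character(habitats),
    n_transects_per_habitat = n_transects_per_habitat,
    n_video_plots_per_habitat = n_video_plots_per_habitat,
    species_pool = species_pool,
    abundance_means = abundance_means,
    bite_rate_means = bite_rate_means,
    dispersion_k = dispersion_k,
    cover_profiles = cover_profiles,
    stomach_profiles = stomach_profiles,
    n_stomachs_per_species = as.integer(n_stomachs_per_species),
    assay_profile = assay_profile,
    n_assay_trials = as.integer(n_assay_trials),
    turf_params = turf_params,
    n_points_per_set = as.integer(n_points_per_set),
    n_quadrats_per_plot = as.integer(n_quadrats_per_plot),
    transect_area_m2 = transect_area_m2,
    plot_area_m2 = plot_area_m2,
    seed = as.integer(seed)
  ), class = "scenario_config")
  validate_scenario(cfg)
}

check_prob_rows <- function(m, what) {
  if (any(m < 0)) config_error(sprintf("%s has negative probabilities", what))
  bad <- abs(rowSums(m) - 1) > 1e-9
  if (any(bad))
    config_error(sprintf("%s rows must sum to 1 (offending: %s)",
                         what, paste(rownames(m)[bad], collapse = ", ")))
  invisible(m)
}

# Full structural validation; returns the config invisibly augmented.
validate_scenario <- function(cfg) {
  if (!inherits(cfg, "scenario_config")) config_error("not a scenario_config")
  sp <- cfg$species_pool
  need_cols(sp, c("species", "group", "feeding_group", "a", "b",
                  "mean_length_cm", "length_cv"), "species_pool")
  if (anyDuplicated(sp$species)) config_error("duplicate species in species_pool")
  if (any(sp$a <= 0)) config_error("length-weight a must be > 0")
  if (any(sp$b < 1 | sp$b > 4))
    warning("length-weight exponent b outside [1, 4] sanity bounds")
  nt <- cfg$n_transects_per_habitat
  if (is.null(names(nt)) || !all(cfg$habitats %in% names(nt)))
    config_error("n_transects_per_habitat must be named by habitat")
  if (any(nt[cfg$habitats] < 1)) config_error("each habitat needs >= 1 transect")
  am <- cfg$abundance_means
  if (!all(cfg$habitats %in% rownames(am)) || !all(colnames(am) %in% sp$species))
    config_error("abundance_means must be habitat x species (species from species_pool)")
  if (any(am < 0)) config_error("abundance means must be non-negative")
  if (any(cfg$bite_rate_means < 0)) config_error("bite rates must be non-negative")
  vp <- cfg$n_video_plots_per_habitat
  if (length(vp) && (is.null(names(vp)) || !all(names(vp) %in% cfg$habitats)))
    config_error("n_video_plots_per_habitat names must be habitats")
  if (!all(names(vp) %in% rownames(cfg$bite_rate_means)))
    config_error("bite_rate_means must cover every habitat with video plots")
  check_prob_rows(cfg$cover_profiles, "cover_profiles")
  check_prob_rows(cfg$stomach_profiles, "stomach_profiles")
  ap <- cfg$assay_profile
  if (length(ap$algae) < 2L) config_error("assay profile needs >= 2 algae")
  if (abs(sum(ap$bite_share) - 1) > 1e-9) config_error("assay bite_share must sum to 1")
  if (any(ap$loss_fraction < 0 | ap$loss_fraction >= 1))
    config_error("assay loss_fraction must lie in [0, 1)")
  if (abs(sum(ap$species_share) - 1) > 1e-9)
    config_error("assay species_share must sum to 1")
  tp <- cfg$turf_params
  if (any(tp$mean_dry_weight_g < 0)) config_error("turf dry-weight means must be >= 0")
  check_prob_rows(tp$taxon_shares, "turf taxon_shares")
  if (cfg$n_points_per_set < 1L) config_error("n_points_per_set must be >= 1")
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Tide-pool sampling scenario\n")
  cat("  habitats:   ", paste(x$habitats, collapse = ", "), "\n")
  cat("  transects:  ", paste(sprintf("%s=%d", names(x$n_transects_per_habitat),
                                      x$n_transects_per_habitat), collapse = ", "), "\n")
  cat("  video plots:", paste(sprintf("%s=%d", names(x$n_video_plots_per_habitat),
                                      x$n_video_plots_per_habitat), collapse = ", "), "\n")
  cat("  species pool:", nrow(x$species_pool), "species;",
      length(x$assay_profile$algae), "assay algae;",
      x$n_assay_trials, "assay trials\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Expected per-plot feeding pressure under a scenario
#'
#' Closed form for the expected (bites x kg) / (2 m2 x 10 min) of one video
#' plot: sum over species of E(foragers per plot) * bite rate * E(mass),
#' with E(mass) = a exp(b mu + b^2 sigma^2 / 2) from the lognormal length
#' model. Used to verify the configured closed:open pressure ratio.
#'
#' @param config a [scenario_config()].
#' @param habitat habitat label (must have video plots).
#' @return expected pressure in bites.kg per plot.
#' @export
expected_plot_pressure <- function(config, habitat) {
  sp <- config$species_pool
  lp <- lnorm_pars(sp$mean_length_cm, sp$length_cv)
  mass_kg <- sp$a * exp(sp$b * lp$meanlog + sp$b^2 * lp$sdlog^2 / 2) / 1000
  dens <- config$abundance_means[habitat, sp$species] *
    config$plot_area_m2 / config$transect_area_m2
  rates <- config$bite_rate_means[habitat, sp$species]
  sum(dens * rates * mass_kg)
}

#' Rescale bite rates so two habitats have a target expected pressure ratio
#'
#' Scales the bite rates of `denominator` so that
#' `expected_plot_pressure(numerator) / expected_plot_pressure(denominator)`
#' equals `ratio` exactly.
#'
#' @param config a [scenario_config()].
#' @param ratio target expected ratio (the study reported a roughly 20-fold
#'   closed:open contrast).
#' @param numerator,denominator habitat labels.
#' @return the adjusted config.
#' @export
set_pressure_ratio <- function(config, ratio = 20,
                               numerator = "closed", denominator = "open") {
  cur <- expected_plot_pressure(config, numerator) /
    expected_plot_pressure(config, denominator)
  config$bite_rate_means[denominator, ] <-
    config$bite_rate_means[denominator, ] * (cur / ratio)
  validate_scenario(config)
  config
}

#' The default tide-pool scenario
#'
#' Emulates the study design this package reproduces: 153 belt transects
#' over four habitats, 45 closed + 40 open video plots, five 50-point
#' photoquadrats per plot, 13 assay trials over 3 days offering seven
#' macroalgae on equal initial masses, 50-point stomach spreads for the two
#' roving herbivores, and 20 turf scrapes (five per pool, two pools per
#' habitat). The closed:open expected feeding-pressure ratio is calibrated
#' to 20 and the dominant scraper takes ~60% of assay bites.
#'
#' @param seed integer root seed.
#' @return a [scenario_config()].
#' @export
default_scenario <- function(seed = 1L) {
  sp <- data.frame(
    species = c("Acanthurus chirurgus", "Acanthurus coeruleus",
                "Stegastes rocasensis", "Thalassoma noronhanum",
                "Melichthys niger", "Sparisoma axillare",
                "Halichoeres radiatus", "Abudefduf saxatilis",
                "Cephalopholis fulva", "Malacoctenus triangulatus"),
    group = c("scraper", "fine_browser", "territorial_herbivore",
              "planktivore", "omnivore", "scraper",
              "mobile_invertebrate_feeder", "omnivore", "carnivore",
              "mobile_invertebrate_feeder"),
    # dual-role species: planktivore in the assemblage, mobile invertebrate
    # feeder when recorded feeding on the benthos
    feeding_group = c("scraper", "fine_browser", "territorial_herbivore",
                      "mobile_invertebrate_feeder", "omnivore", "scraper",
                      "mobile_invertebrate_feeder", "omnivore", "carnivore",
                      "mobile_invertebrate_feeder"),
    a = c(0.0286, 0.0247, 0.0213, 0.0098, 0.0315, 0.0118,
          0.0101, 0.0276, 0.0135, 0.0079),
    b = c(2.95, 2.99, 3.04, 3.02, 2.93, 3.11, 3.05, 2.98, 3.01, 3.08),
    mean_length_cm = c(22, 18, 8, 7, 25, 20, 15, 12, 20, 5),
    length_cv = c(0.25, 0.25, 0.2, 0.3, 0.2, 0.25, 0.3, 0.3, 0.25, 0.2),
    stringsAsFactors = FALSE
  )
  habitats <- c("closed", "open", "lagoon", "outer_reef")
  am <- rbind(
    closed     = c(6, 4, 8, 30, 1, 2, 2, 4, 0.5, 3),
    open       = c(1.5, 0.5, 6, 35, 5, 1, 3, 3, 1, 2),
    lagoon     = c(5, 3, 7, 25, 1, 2, 2, 5, 0.5, 3),
    outer_reef = c(1, 0.5, 2, 20, 6, 0.5, 4, 2, 2, 1)
  )
  colnames(am) <- sp$species
  # bites per individual per 10 min; herbivores dominate, scraper most
  br <- rbind(
    closed = c(60, 35, 25, 2, 4, 30, 1, 3, 0, 0.5),
    open   = c(60, 35, 25, 2, 4, 30, 1, 3, 0, 0.5)
  )
  colnames(br) <- sp$species
  cover_cats <- c("non_calcified_turf", "calcareous_turf", "sediment",
                  "crustose_coralline", "Caulerpa_verticillata",
                  "hard_coral", "sponge", "cyanobacteria", "zoanthid",
                  "other")
  cov <- rbind(
    closed = c(0.51, 0.02, 0.31, 0.06, 0.01, 0.03, 0.02, 0.02, 0.01, 0.01),
    open   = c(0.14, 0.33, 0.10, 0.07, 0.15, 0.08, 0.04, 0.03, 0.03, 0.03)
  )
  colnames(cov) <- cover_cats
  diet_items <- c("sediment", "detritus", "articulated_calcareous",
                  "red_corticated", "green_filamentous", "cyanophyceae",
                  "other")
  stomach <- rbind(
    "Acanthurus chirurgus" = c(0.44, 0.30, 0.12, 0.08, 0.02, 0.02, 0.02),
    "Acanthurus coeruleus" = c(0.03, 0.01, 0.03, 0.78, 0.07, 0.06, 0.02)
  )
  colnames(stomach) <- diet_items
  algae <- c("Digenea simplex", "Sargassum sp.", "Dictyopteris plagiogramma",
             "Dictyopteris jolyana", "Canistrocarpus cervicornis",
             "Caulerpa verticillata", "Padina gymnospora")
  assay <- list(
    algae = algae,
    bite_share = stats::setNames(c(0.60, 0.10, 0.08, 0.055, 0.055, 0.055, 0.055), algae),
    loss_fraction = stats::setNames(rep(0.08, 7), algae),
    offered_mass_mean_g = stats::setNames(rep(10, 7), algae),
    offered_mass_cv = 0.05,
    species_share = c("Acanthurus chirurgus" = 0.95,
                      "Acanthurus coeruleus" = 0.05),
    total_bites_mean = 300,
    mass_per_bite_g = 0.05,
    bite_mass_cv = 0.3,
    control_noise_cv = 0.02
  )
  turf_taxa <- c("Digenea simplex", "Gelidium crinale", "Jania sp.",
                 "Amphiroa sp.", "other_non_calcified")
  shares <- rbind(
    closed = c(0.45, 0.20, 0.05, 0.05, 0.25),
    open   = c(0.10, 0.10, 0.35, 0.35, 0.10)
  )
  colnames(shares) <- turf_taxa
  turf <- list(
    pools = list(closed = c("Tartarugas", "Rocas"),
                 open = c("Falsa Barreta", "Podes Crer")),
    n_samples_per_pool = 5L,
    mean_dry_weight_g = c(closed = 1.2, open = 3.6),
    dry_weight_cv = 0.5,
    taxon_shares = shares,
    crypto_intercept = 2,
    crypto_slope = 8,
    crypto_noise_sd = 0.2,
    crypto_group_shares = c(amphipods = 0.55, polychaetes = 0.2,
                            gastropods = 0.15, others = 0.1)
  )
  cfg <- scenario_config(
    habitats = habitats,
    n_transects_per_habitat = c(closed = 64L, open = 59L, lagoon = 20L,
                                outer_reef = 10L),
    n_video_plots_per_habitat = c(closed = 45L, open = 40L),
    species_pool = sp,
    abundance_means = am,
    bite_rate_means = br,
    dispersion_k = 5,
    cover_profiles = cov,
    stomach_profiles = stomach,
    assay_profile = assay,
    n_assay_trials = 13L,
    turf_params = turf,
    seed = seed
  )
  set_pressure_ratio(cfg, ratio = 20)
}
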