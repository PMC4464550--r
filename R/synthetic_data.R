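# Seeded generators for every input table the pipeline consumes. Each table
# draws from its own RNG sub-stream keyed by (config$seed, table name), so
# generating one table never perturbs another.

site_labels <- function(habitat, n_transects) {
  n_sites <- max(1L, min(5L, ceiling(n_transects / 13)))
  paste0(habitat, "_S", ((seq_len(n_transects) - 1L) %% n_sites) + 1L)
}

#' Generate belt-transect fish censuses
#'
#' Emulates underwater visual censuses on 40 m2 (20 x 2 m) belt transects:
#' per transect and species, the number of individuals is negative-binomial
#' (Poisson at `dispersion_k = Inf`) around the habitat's configured
#' abundance mean, and each individual's total length is lognormal around
#' the species' mean length with its CV, truncated at 1 cm. One row per
#' individual (`count = 1`).
#'
#' @param config a [scenario_config()].
#' @return data.frame with columns `transect_id`, `habitat`, `site`,
#'   `species`, `count`, `total_length_cm`.
#' @export
generate_censuses <- function(config) {
  validate_scenario(config)
  with_stream(config$seed, "censuses", {
    sp <- config$species_pool
    out <- vector("list", length(config$habitats))
    for (h in config$habitats) {
      nt <- config$n_transects_per_habitat[[h]]
      if (nt < 1L) config_error(sprintf("habitat %s has no transects", h))
      sites <- site_labels(h, nt)
      rows <- vector("list", nt)
      for (t in seq_len(nt)) {
        counts <- vapply(sp$species, function(s)
          rcounts(1L, config$abundance_means[h, s], config$dispersion_k),
          integer(1))
        if (sum(counts) == 0L) {
          # keep empty transects: they are legitimate zero observations
          rows[[t]] <- data.frame(
            transect_id = sprintf("%s_T%02d", h, t),
            habitat = h, site = sites[t],
            species = NA_character_, count = NA_integer_,
            total_length_cm = NA_real_, stringsAsFactors = FALSE)
          next
        }
        idx <- rep(seq_len(nrow(sp)), counts)
        lp <- lnorm_pars(sp$mean_length_cm[idx], sp$length_cv[idx])
        len <- pmax(stats::rlnorm(length(idx), lp$meanlog, lp$sdlog), 1)
        rows[[t]] <- data.frame(
          transect_id = sprintf("%s_T%02d", h, t),
          habitat = h, site = sites[t],
          species = sp$species[idx], count = 1L,
          total_length_cm = round(len, 2),
          stringsAsFactors = FALSE)
      }
      out[[match(h, config$habitats)]] <- do.call(rbind, rows)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Generate remote-video feeding plots
#'
#' Emulates 2 m2 reef areas filmed for 10 analyzed minutes: foraging
#' individuals per plot are drawn like census counts but scaled to the plot
#' area, and each individual's bite total is Poisson around the habitat x
#' species bite rate. Plots where no fish fed are kept as one placeholder
#' row with `species = NA` so the plot count (the sampling unit) survives a
#' CSV round trip.
#'
#' @param config a [scenario_config()].
#' @return data.frame with columns `plot_id`, `habitat`, `species`,
#'   `total_length_cm`, `bites`.
#' @export
generate_video_plots <- function(config) {
  validate_scenario(config)
  with_stream(config$seed, "video_plots", {
    sp <- config$species_pool
    scale <- config$plot_area_m2 / config$transect_area_m2
    out <- list()
    for (h in names(config$n_video_plots_per_habitat)) {
      np <- config$n_video_plots_per_habitat[[h]]
      if (np < 1L) config_error(sprintf("habitat %s has no video plots", h))
      for (p in seq_len(np)) {
        pid <- sprintf("%s_P%02d", h, p)
        counts <- vapply(sp$species, function(s)
          rcounts(1L, config$abundance_means[h, s] * scale, config$dispersion_k),
          integer(1))
        if (sum(counts) == 0L) {
          out[[length(out) + 1L]] <- data.frame(
            plot_id = pid, habitat = h, species = NA_character_,
            total_length_cm = NA_real_, bites = NA_integer_,
            stringsAsFactors = FALSE)
          next
        }
        idx <- rep(seq_len(nrow(sp)), counts)
        lp <- lnorm_pars(sp$mean_length_cm[idx], sp$length_cv[idx])
        len <- pmax(stats::rlnorm(length(idx), lp$meanlog, lp$sdlog), 1)
        bites <- stats::rpois(length(idx),
                              config$bite_rate_means[h, sp$species[idx]])
        out[[length(out) + 1L]] <- data.frame(
          plot_id = pid, habitat = h, species = sp$species[idx],
          total_length_cm = round(len, 2), bites = bites,
          stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Generate 50-point point-intercept label sets
#'
#' Each set is one multinomial draw of `n_points_per_set` (50 in the study
#' design) category labels. Photoquadrats come in groups of
#' `n_quadrats_per_plot` (five 25 x 25 cm quadrats per video plot) from the
#' habitat's cover profile; stomach spreads are one set each from the
#' consumer's diet profile.
#'
#' @param config a [scenario_config()].
#' @param kind `"photoquadrat"` or `"stomach"`.
#' @return long data.frame: `set_id`, `plot_id`/`consumer`, `habitat` (for
#'   photoquadrats), `point_index`, `label`.
#' @export
generate_point_labels <- function(config, kind = c("photoquadrat", "stomach")) {
  validate_scenario(config)
  kind <- match.arg(kind)
  npts <- config$n_points_per_set
  if (kind == "photoquadrat") {
    prof <- config$cover_profiles
    with_stream(config$seed, "photoquadrats", {
      out <- list()
      for (h in names(config$n_video_plots_per_habitat)) {
        if (!h %in% rownames(prof))
          config_error(sprintf("no cover profile for habitat %s", h))
        p <- prof[h, ]
        for (pl in seq_len(config$n_video_plots_per_habitat[[h]])) {
          for (q in seq_len(config$n_quadrats_per_plot)) {
            lab <- sample(colnames(prof), npts, replace = TRUE, prob = p)
            out[[length(out) + 1L]] <- data.frame(
              set_id = sprintf("%s_P%02d_Q%d", h, pl, q),
              plot_id = sprintf("%s_P%02d", h, pl),
              habitat = h, point_index = seq_len(npts), label = lab,
              stringsAsFactors = FALSE)
          }
        }
      }
      res <- do.call(rbind, out); rownames(res) <- NULL; res
    })
  } else {
    prof <- config$stomach_profiles
    if (is.null(prof) || nrow(prof) == 0L)
      config_error("no stomach profiles configured")
    with_stream(config$seed, "stomachs", {
      out <- list()
      for (cs in rownames(prof)) {
        for (s in seq_len(config$n_stomachs_per_species)) {
          lab <- sample(colnames(prof), npts, replace = TRUE, prob = prof[cs, ])
          out[[length(out) + 1L]] <- data.frame(
            set_id = sprintf("%s_stomach%02d", gsub(" ", "_", cs), s),
            consumer = cs, point_index = seq_len(npts), label = lab,
            stringsAsFactors = FALSE)
        }
      }
      res <- do.call(rbind, out); rownames(res) <- NULL; res
    })
  }
}

#' Generate multiple-choice herbivory assay trials
#'
#' Each trial offers every configured alga on a rope alongside a caged
#' control rope. Initial wet weights are lognormal around the offered-mass
#' means; the control loses its handling/hydrodynamic fraction with small
#' multiplicative noise; the trial rope additionally loses consumed mass,
#' where total bites per trial are Poisson, split multinomially over
#' herbivore species and then over algae by the configured bite shares, and
#' each bite removes `mass_per_bite_g` grams with lognormal noise.
#'
#' @param config a [scenario_config()].
#' @param n_trials number of trials (defaults to the configured 13).
#' @return long data.frame: `trial`, `day`, `alga`, `Wr_i`, `Wr_F`, `Wc_i`,
#'   `Wc_F`, `species`, `bites` (one row per trial x alga x herbivore).
#' @export
generate_assays <- function(config, n_trials = config$n_assay_trials) {
  validate_scenario(config)
  if (n_trials < 1L) config_error("n_trials must be >= 1")
  ap <- config$assay_profile
  algae <- ap$algae
  spp <- names(ap$species_share)
  days <- ceiling(seq_len(n_trials) / ceiling(n_trials / 3))
  with_stream(config$seed, "assays", {
    out <- list()
    for (tr in seq_len(n_trials)) {
      lp <- lnorm_pars(ap$offered_mass_mean_g[algae], ap$offered_mass_cv)
      Wr_i <- stats::rlnorm(length(algae), lp$meanlog, lp$sdlog)
      Wc_i <- stats::rlnorm(length(algae), lp$meanlog, lp$sdlog)
      cn <- lnorm_pars(1, ap$control_noise_cv)
      Wc_F <- Wc_i * (1 - ap$loss_fraction[algae]) *
        stats::rlnorm(length(algae), cn$meanlog, cn$sdlog)
      total_bites <- stats::rpois(1L, ap$total_bites_mean)
      by_sp <- if (total_bites > 0)
        as.integer(stats::rmultinom(1L, total_bites, ap$species_share))
      else integer(length(spp))
      bites <- matrix(0L, length(algae), length(spp),
                      dimnames = list(algae, spp))
      for (i in seq_along(spp)) {
        if (by_sp[i] > 0)
          bites[, i] <- as.integer(stats::rmultinom(1L, by_sp[i],
                                                    ap$bite_share[algae]))
      }
      bm <- lnorm_pars(1, ap$bite_mass_cv)
      consumed <- rowSums(bites) * ap$mass_per_bite_g *
        stats::rlnorm(length(algae), bm$meanlog, bm$sdlog)
      Wr_F <- pmax(Wr_i * (1 - ap$loss_fraction[algae]) - consumed, 0)
      for (i in seq_along(spp)) {
        out[[length(out) + 1L]] <- data.frame(
          trial = tr, day = days[tr], alga = algae,
          Wr_i = round(Wr_i, 4), Wr_F = round(Wr_F, 4),
          Wc_i = round(Wc_i, 4), Wc_F = round(Wc_F, 4),
          species = spp[i], bites = bites[, i],
          stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out); rownames(res) <- NULL; res
  })
}

#' Generate algal-turf scrape samples with cryptofauna
#'
#' Emulates 10 x 10 cm turf scrapes (five per pool): per-sample total dry
#' weight is lognormal around the habitat mean and split across turf taxa by
#' gamma-perturbed habitat shares; total cryptofauna counts are Poisson
#' around `max(intercept + slope * dry weight, 0)` with lognormal rate
#' noise, split over cryptofauna groups.
#'
#' @param config a [scenario_config()].
#' @return long data.frame: `sample_id`, `habitat`, `pool`, `component`
#'   (`"alga"` dry weight in g/100 cm2 or `"cryptofauna"` count per
#'   100 cm2), `taxon`, `value`.
#' @export
generate_turf_samples <- function(config) {
  validate_scenario(config)
  tp <- config$turf_params
  with_stream(config$seed, "turf", {
    out <- list()
    floored <- FALSE
    for (h in names(tp$pools)) {
      shares <- tp$taxon_shares[h, ]
      for (pool in tp$pools[[h]]) {
        for (s in seq_len(tp$n_samples_per_pool)) {
          sid <- sprintf("%s_%s_%02d", h, gsub(" ", "_", pool), s)
          lp <- lnorm_pars(tp$mean_dry_weight_g[[h]], tp$dry_weight_cv)
          total <- stats::rlnorm(1L, lp$meanlog, lp$sdlog)
          g <- stats::rgamma(length(shares), shape = shares * 20)
          w <- total * g / sum(g)
          mu <- tp$crypto_intercept + tp$crypto_slope * total
          if (mu < 0) { mu <- 0; floored <- TRUE }
          ns <- tp$crypto_noise_sd
          rate <- mu * stats::rlnorm(1L, -ns^2 / 2, ns)
          counts <- stats::rpois(length(tp$crypto_group_shares),
                                 rate * tp$crypto_group_shares)
          out[[length(out) + 1L]] <- rbind(
            data.frame(sample_id = sid, habitat = h, pool = pool,
                       component = "alga", taxon = names(shares),
                       value = round(w, 4), stringsAsFactors = FALSE),
            data.frame(sample_id = sid, habitat = h, pool = pool,
                       component = "cryptofauna",
                       taxon = names(tp$crypto_group_shares),
                       value = counts, stringsAsFactors = FALSE))
        }
      }
    }
    if (floored)
      warning("negative cryptofauna mean(s) floored at 0")
    res <- do.call(rbind, out); rownames(res) <- NULL; res
  })
}

#' Generate every input table of the pipeline
#'
#' @param config a [scenario_config()].
#' @return named list of data.frames: `censuses`, `video_plots`,
#'   `photoquadrats`, `stomachs`, `assays`, `turf`, plus the derived
#'   `length_weight` and `groups` lookup tables.
#' @export
simulate_tables <- function(config) {
  validate_scenario(config)
  sp <- config$species_pool
  list(
    censuses = generate_censuses(config),
    video_plots = generate_video_plots(config),
    photoquadrats = generate_point_labels(config, "photoquadrat"),
    stomachs = generate_point_labels(config, "stomach"),
    assays = generate_assays(config),
    turf = generate_turf_samples(config),
    length_weight = data.frame(species = sp$species, a = sp$a, b = sp$b,
                               stringsAsFactors = FALSE),
    groups = data.frame(species = sp$species, group = sp$group,
                        feeding_group = sp$feeding_group,
                        stringsAsFactors = FALSE)
  )
}

#' Write simulated tables as CSV
#'
#' One UTF-8 CSV per table (header row, "." decimal separator).
#'
#' @param tables list from [simulate_tables()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  invisible(paths)
}
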