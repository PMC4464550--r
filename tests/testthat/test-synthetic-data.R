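# The generators define the study conditions; these tests pin their
# statistical structure and the determinism contract.

test_that("identical seed and config give byte-identical tables", {
  cfg <- small_scenario(seed = 42L)
  t1 <- simulate_tables(cfg)
  t2 <- simulate_tables(cfg)
  expect_identical(t1, t2)
  cfg2 <- small_scenario(seed = 43L)
  expect_false(identical(generate_censuses(cfg), generate_censuses(cfg2)))
})

test_that("generating one table does not shift another's stream", {
  cfg <- small_scenario(seed = 5L)
  a1 <- generate_assays(cfg)
  # drawing censuses in between must not perturb the assay stream
  invisible(generate_censuses(cfg))
  a2 <- generate_assays(cfg)
  expect_identical(a1, a2)
})

test_that("zero abundance mean means the species never appears", {
  cfg <- small_scenario(seed = 3L)
  cfg$abundance_means["closed", "Acanthurus chirurgus"] <- 0
  cz <- generate_censuses(cfg)
  expect_false(any(cz$habitat == "closed" &
                     cz$species %in% "Acanthurus chirurgus"))
})

test_that("Poisson limit recovers the configured abundance mean", {
  cfg <- small_scenario(seed = 11L)
  cfg$habitats <- "closed"
  cfg$n_transects_per_habitat <- c(closed = 1000L)
  cfg$n_video_plots_per_habitat <- c(closed = 2L)
  cfg$abundance_means <- cfg$abundance_means["closed", , drop = FALSE]
  cfg$dispersion_k <- Inf
  cz <- generate_censuses(cfg)
  mu <- cfg$abundance_means["closed", "Thalassoma noronhanum"]
  n_obs <- sum(cz$species %in% "Thalassoma noronhanum")
  se <- sqrt(mu / 1000) # Poisson closed form
  expect_lt(abs(n_obs / 1000 - mu), 3 * se)
})

test_that("all-zero bite rates give all-zero plots", {
  cfg <- small_scenario(seed = 9L)
  cfg$bite_rate_means[] <- 0
  vp <- generate_video_plots(cfg)
  expect_true(all(is.na(vp$bites) | vp$bites == 0))
})

test_that("mean plot pressure converges to rate x mass for one known fish", {
  # one species, deterministic length, Poisson bites: E[pressure] = n * lambda * m
  cfg <- small_scenario(seed = 21L)
  sp <- cfg$species_pool[1, ]
  sp$mean_length_cm <- 20
  sp$length_cv <- 1e-6
  cfg$species_pool <- sp
  cfg$abundance_means <- matrix(20, 2, 1,
                                dimnames = list(c("closed", "open"), sp$species))
  cfg$bite_rate_means <- matrix(5, 2, 1,
                                dimnames = list(c("closed", "open"), sp$species))
  cfg$n_video_plots_per_habitat <- c(closed = 400L, open = 2L)
  cfg$dispersion_k <- Inf
  vp <- generate_video_plots(cfg)
  pp <- plot_pressure(vp, data.frame(species = sp$species, a = sp$a, b = sp$b))
  m_kg <- estimate_mass(20, sp$a, sp$b) / 1000
  expected <- 20 * (2 / 40) * 5 * m_kg
  got <- mean(pp$pressure[pp$habitat == "closed"])
  se <- sd(pp$pressure[pp$habitat == "closed"]) / sqrt(400)
  expect_lt(abs(got - expected), 4 * se)
})

test_that("point-label sets have exactly the configured 50 points", {
  cfg <- small_scenario(seed = 2L)
  pq <- generate_point_labels(cfg, "photoquadrat")
  expect_true(all(table(pq$set_id) == 50L))
  st <- generate_point_labels(cfg, "stomach")
  expect_true(all(table(st$set_id) == 50L))
  # five quadrats per plot, the field design
  expect_true(all(table(unique(pq[, c("set_id", "plot_id")])$plot_id) == 5L))
})

test_that("a degenerate cover profile yields a single label", {
  cfg <- small_scenario(seed = 2L)
  cfg$cover_profiles[] <- 0
  cfg$cover_profiles[, "sediment"] <- 1
  pq <- generate_point_labels(cfg, "photoquadrat")
  expect_true(all(pq$label == "sediment"))
})

test_that("cover estimates are unbiased for the generating profile", {
  cfg <- small_scenario(seed = 8L)
  cfg$habitats <- c("closed", "open")
  cfg$n_video_plots_per_habitat <- c(closed = 60L)
  pq <- generate_point_labels(cfg, "photoquadrat")
  cov <- plot_cover(pq, categories = colnames(cfg$cover_profiles))
  p <- cfg$cover_profiles["closed", ]
  for (cat in names(p)) {
    got <- mean(cov$cover_pct[cov$category == cat]) / 100
    se <- sqrt(p[cat] * (1 - p[cat]) / 50) / sqrt(300)
    expect_lt(abs(got - p[cat]), 3 * se + 1e-12)
  }
})

test_that("assays echo the design size and respect the loss model", {
  cfg <- small_scenario(seed = 6L)
  a <- generate_assays(cfg, n_trials = 13L)
  expect_equal(length(unique(a$trial)), 13L)
  expect_equal(sort(unique(a$day)), 1:3)
  expect_setequal(unique(a$alga), cfg$assay_profile$algae)
  # control loses only the configured fraction (small noise)
  expect_true(all(abs(a$Wc_F / a$Wc_i - 0.92) < 0.92 * 0.15))
})

test_that("zero per-bite mass removal leaves consumption near zero", {
  cfg <- small_scenario(seed = 13L)
  cfg$assay_profile$mass_per_bite_g <- 0
  a <- generate_assays(cfg, n_trials = 10L)
  cons <- assay_consumption(a)
  expect_lt(abs(mean(cons$consumed_proportion)), 0.03)
})

test_that("invalid assay loss fractions are a configuration error", {
  cfg <- small_scenario()
  cfg$assay_profile$loss_fraction[1] <- 1.2
  expect_error(generate_assays(cfg), class = "reefpress_config_error")
})

test_that("turf sampling follows the five-per-pool design", {
  cfg <- default_scenario(seed = 4L)
  tf <- generate_turf_samples(cfg)
  tt <- turf_totals(tf)
  expect_equal(nrow(tt), 20L) # 2 habitats x 2 pools x 5 samples
  expect_true(all(table(tt$pool) == 5L))
  expect_true(all(tt$total_dry_weight_g > 0))
})

test_that("turf regression recovers the configured slope within 15%", {
  cfg <- small_scenario(seed = 17L)
  cfg$turf_params$pools <- list(closed = "A", open = "B")
  cfg$turf_params$n_samples_per_pool <- 100L # 200 samples total
  tf <- generate_turf_samples(cfg)
  reg <- turf_regression(turf_totals(tf))
  expect_lt(abs(reg$slope - cfg$turf_params$crypto_slope) /
              cfg$turf_params$crypto_slope, 0.15)
})

test_that("generated tables pass downstream schema validation", {
  cfg <- small_scenario(seed = 1L)
  report <- validate_tables(simulate_tables(cfg))
  expect_equal(nrow(report), 0L)
})
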