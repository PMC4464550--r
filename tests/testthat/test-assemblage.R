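# Length-weight allometry, transect summaries and matrix building.

test_that("estimate_mass follows W = a L^b", {
  expect_equal(estimate_mass(10, a = 0.01, b = 3), 10)
  expect_equal(estimate_mass(37, a = 1, b = 0), 1)
  # frozen from a 30-digit arbitrary-precision evaluation of 0.0089 * 23^3.12
  expect_equal(estimate_mass(23, a = 0.0089, b = 3.12),
               157.754172547979271, tolerance = 1e-14)
  expect_error(estimate_mass(-1, 0.01, 3), class = "reefpress_validation_error")
})

test_that("estimate_mass is strictly increasing in length for b > 0", {
  L <- sort(runif(50, 1, 60))
  w <- estimate_mass(L, a = 0.02, b = 2.9)
  expect_true(all(diff(w) > 0))
})

test_that("missing length-weight entries are reported by species name", {
  obs <- data.frame(transect_id = "T1", habitat = "closed",
                    species = "Unknownus fishus", count = 1,
                    total_length_cm = 10)
  lw <- data.frame(species = "sp1", a = 0.01, b = 3)
  gm <- data.frame(species = "sp1", group = "g")
  expect_error(transect_summaries(obs, lw, gm), "Unknownus fishus",
               class = "reefpress_validation_error")
})

test_that("transect summaries compute density and biomass", {
  obs <- data.frame(
    transect_id = c("T1", "T1", "T2"), habitat = "closed",
    species = c("sp1", "sp1", "sp2"), count = c(2, 1, 4),
    total_length_cm = c(10, 10, 5))
  lw <- data.frame(species = c("sp1", "sp2"), a = c(0.01, 0.02), b = c(3, 3))
  gm <- data.frame(species = c("sp1", "sp2"), group = c("g1", "g2"))
  ts <- transect_summaries(obs, lw, gm)
  t1 <- ts$transects[ts$transects$transect_id == "T1", ]
  expect_equal(t1$density, 3)
  expect_equal(t1$biomass_g, 3 * 0.01 * 1000) # 30 g
  expect_equal(t1$biomass_g_per_m2, 30 / 40)
  t2 <- ts$transects[ts$transects$transect_id == "T2", ]
  expect_equal(t2$biomass_g, 4 * 0.02 * 125)
})

test_that("empty transects (placeholder rows) summarize to zero", {
  obs <- data.frame(transect_id = c("T1", "T2"), habitat = "closed",
                    species = c("sp1", NA), count = c(2, NA),
                    total_length_cm = c(10, NA))
  lw <- data.frame(species = "sp1", a = 0.01, b = 3)
  gm <- data.frame(species = "sp1", group = "g")
  ts <- transect_summaries(obs, lw, gm)
  t2 <- ts$transects[ts$transects$transect_id == "T2", ]
  expect_equal(t2$density, 0)
  expect_equal(t2$biomass_g, 0)
})

test_that("functional-group totals partition the transect totals", {
  cfg <- small_scenario(seed = 31L)
  ts <- transect_summaries(generate_censuses(cfg), lw_of(cfg), groups_of(cfg))
  by_grp <- tapply(ts$groups$biomass_g, ts$groups$transect_id, sum)
  tot <- ts$transects$biomass_g[match(names(by_grp),
                                      ts$transects$transect_id)]
  expect_equal(unname(as.numeric(by_grp)), tot, tolerance = 1e-12)
})

test_that("mean density estimates converge to configured abundance means", {
  cfg <- small_scenario(seed = 77L)
  cfg$habitats <- "closed"
  cfg$n_transects_per_habitat <- c(closed = 1000L)
  cfg$n_video_plots_per_habitat <- c(closed = 2L)
  cfg$abundance_means <- cfg$abundance_means["closed", , drop = FALSE]
  ts <- transect_summaries(generate_censuses(cfg), lw_of(cfg), groups_of(cfg))
  m <- build_matrix(ts, "density")
  for (s in c("Acanthurus chirurgus", "Thalassoma noronhanum")) {
    mu <- cfg$abundance_means["closed", s]
    # negative binomial variance mu + mu^2/k
    se <- sqrt((mu + mu^2 / cfg$dispersion_k) / 1000)
    expect_lt(abs(mean(m[, s]) - mu), 3 * se)
  }
})

test_that("build_matrix applies transform, exclusions and conserves totals", {
  obs <- data.frame(
    transect_id = c("T1", "T1", "T2"), habitat = "closed",
    species = c("sp1", "sp2", "sp1"), count = c(16, 2, 9),
    total_length_cm = 10)
  lw <- data.frame(species = c("sp1", "sp2"), a = 0.01, b = 3)
  gm <- data.frame(species = c("sp1", "sp2"), group = "g")
  ts <- transect_summaries(obs, lw, gm)
  m <- build_matrix(ts, "density", "sqrt")
  expect_equal(m["T1", "sp1"], 4) # sqrt(16)
  raw <- build_matrix(ts, "density", "none")
  expect_equal(unname(rowSums(raw)),
               ts$transects$density[match(rownames(raw),
                                          ts$transects$transect_id)])
  excl <- build_matrix(ts, "density", exclude_species = "sp2")
  expect_false("sp2" %in% colnames(excl))
  expect_error(build_matrix(ts, "density", transform = "log"),
               class = "reefpress_validation_error")
})
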