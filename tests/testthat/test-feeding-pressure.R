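# The (bites x kg) / (2 m2 x 10 min) statistic and its aggregations.

test_that("plot pressure is the sum of bites x mass over fish", {
  # one fish of 0.2 kg taking 50 bites: 10 bites.kg
  lw <- data.frame(species = "sp1", a = 0.2 * 1000 / 10^3, b = 3)
  rec <- data.frame(plot_id = "P1", habitat = "closed", species = "sp1",
                    total_length_cm = 10, bites = 50)
  expect_equal(plot_pressure(rec, lw)$pressure, 10)
  # additivity over fish
  rec2 <- rbind(rec, rec)
  expect_equal(plot_pressure(rec2, lw)$pressure, 20)
  # empty plot (placeholder row) contributes a zero-pressure plot
  rec3 <- rbind(rec, data.frame(plot_id = "P2", habitat = "closed",
                                species = NA, total_length_cm = NA,
                                bites = NA))
  pp <- plot_pressure(rec3, lw)
  expect_equal(pp$pressure[pp$plot_id == "P2"], 0)
  expect_equal(nrow(pp), 2L)
})

test_that("pressure is invariant to splitting one fish's bites", {
  lw <- data.frame(species = "sp1", a = 0.01, b = 3)
  one <- data.frame(plot_id = "P1", habitat = "closed", species = "sp1",
                    total_length_cm = 17, bites = 40)
  split <- rbind(one, one)
  split$bites <- c(15, 25)
  expect_equal(plot_pressure(one, lw)$pressure,
               plot_pressure(split, lw)$pressure)
})

test_that("scaling all masses by c scales every pressure by c", {
  cfg <- small_scenario(seed = 19L)
  vp <- generate_video_plots(cfg)
  lw <- lw_of(cfg)
  lw2 <- lw; lw2$a <- lw2$a * 3
  expect_equal(plot_pressure(vp, lw2)$pressure,
               3 * plot_pressure(vp, lw)$pressure, tolerance = 1e-12)
})

test_that("habitat totals decompose into functional-group components", {
  cfg <- small_scenario(seed = 23L)
  vp <- generate_video_plots(cfg)
  br <- pressure_breakdown(vp, lw_of(cfg), groups_of(cfg))
  for (h in br$habitats$habitat) {
    expect_equal(sum(br$groups$mean_pressure[br$groups$habitat == h]),
                 br$habitats$mean_pressure[br$habitats$habitat == h],
                 tolerance = 1e-12)
    expect_equal(sum(br$species$share_pct[br$species$habitat == h]), 100,
                 tolerance = 1e-9)
  }
})

test_that("a single feeding species holds a 100% share", {
  lw <- data.frame(species = "sp1", a = 0.01, b = 3)
  gm <- data.frame(species = "sp1", group = "scraper",
                   feeding_group = "scraper")
  rec <- one_fish_records(3, bites = c(5, 2, 7))
  br <- pressure_breakdown(rec, lw, gm)
  expect_equal(br$species$share_pct, 100)
})

test_that("a dominant species' configured share is recovered", {
  # two species; sp1 configured to ~90% of expected bites x mass
  sp <- data.frame(species = c("sp1", "sp2"),
                   group = c("scraper", "fine_browser"),
                   feeding_group = c("scraper", "fine_browser"),
                   a = 0.01, b = 3, mean_length_cm = c(20, 10),
                   length_cv = 1e-6)
  cfg <- small_scenario(seed = 41L)
  cfg$species_pool <- sp
  cfg$abundance_means <- matrix(c(20, 20, 20, 20), 2, 2,
                                dimnames = list(c("closed", "open"), sp$species))
  # expected contribution ratio = (rate1 * m1) : (rate2 * m2); m1/m2 = 8
  cfg$bite_rate_means <- matrix(c(9, 9, 8, 8), 2, 2,
                                dimnames = list(c("closed", "open"), sp$species))
  cfg$n_video_plots_per_habitat <- c(closed = 200L)
  expected_share <- 100 * (9 * 8) / (9 * 8 + 8 * 1)
  # Monte-Carlo SE of the share from replicate generations
  shares <- vapply(1:8, function(i) {
    cfg$seed <- 100L + i
    br <- pressure_breakdown(generate_video_plots(cfg), lw_of(cfg),
                             groups_of(cfg))
    br$species$share_pct[br$species$species == "sp1"]
  }, 0)
  se <- sd(shares) / sqrt(8)
  expect_lt(abs(mean(shares) - expected_share), 3 * se + 0.5)
})

test_that("identical plot sets contrast to ratio 1 with a CI containing 1", {
  pr <- data.frame(habitat = rep(c("A", "B"), each = 10),
                   pressure = rep(c(1, 3, 5, 2, 4), 4))
  ct <- habitat_contrast(pr, "A", "B", n_boot = 500, seed = 2)
  expect_equal(ct$ratio, 1)
  expect_true(ct$ci[1] <= 1 && 1 <= ct$ci[2])
  expect_equal(ct$flag, "ok")
})

test_that("an all-zero denominator habitat flags the ratio undefined", {
  pr <- data.frame(habitat = rep(c("A", "B"), each = 5),
                   pressure = c(1, 2, 3, 4, 5, 0, 0, 0, 0, 0))
  ct <- habitat_contrast(pr, "A", "B", n_boot = 100, seed = 1)
  expect_equal(ct$flag, "undefined_ratio")
  expect_true(is.na(ct$ratio))
})

test_that("the plot-unit conversion helper is exact", {
  expect_equal(pressure_per_m2_min(10), 0.5)
})
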