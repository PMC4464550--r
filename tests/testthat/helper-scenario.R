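# Shared fixtures, all built in code.

# A scaled-down two-habitat scenario for fast end-to-end tests.
small_scenario <- function(seed = 1L) {
  cfg <- default_scenario(seed = seed)
  cfg$habitats <- c("closed", "open")
  cfg$n_transects_per_habitat <- c(closed = 8L, open = 8L)
  cfg$n_video_plots_per_habitat <- c(closed = 6L, open = 6L)
  cfg$abundance_means <- cfg$abundance_means[c("closed", "open"), ]
  cfg$n_stomachs_per_species <- 4L
  cfg$n_assay_trials <- 6L
  cfg$turf_params$pools <- list(closed = "Tartarugas", open = "Podes Crer")
  cfg$turf_params$n_samples_per_pool <- 4L
  validate_scenario <- getFromNamespace("validate_scenario", "reefpress")
  validate_scenario(cfg)
  cfg
}

lw_of <- function(cfg) {
  data.frame(species = cfg$species_pool$species, a = cfg$species_pool$a,
             b = cfg$species_pool$b, stringsAsFactors = FALSE)
}

groups_of <- function(cfg) {
  data.frame(species = cfg$species_pool$species,
             group = cfg$species_pool$group,
             feeding_group = cfg$species_pool$feeding_group,
             stringsAsFactors = FALSE)
}

# one-species configuration useful for expectation identities
one_fish_records <- function(n_plots, bites, length_cm = 10) {
  data.frame(plot_id = paste0("P", seq_len(n_plots)), habitat = "closed",
             species = "sp1", total_length_cm = length_cm,
             bites = bites, stringsAsFactors = FALSE)
}

lw1 <- data.frame(species = "sp1", a = 0.01, b = 3)
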