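# Orchestration: simulate -> validate -> compute -> write a result bundle
# mirroring the study's analysis set, with a reproducibility manifest.

utils::globalVariables(character(0))

read_tables <- function(dir) {
  nms <- c("censuses", "video_plots", "photoquadrats", "stomachs",
           "assays", "turf", "length_weight", "groups")
  out <- list()
  for (nm in nms) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(p))
      out[[nm]] <- utils::read.csv(p, stringsAsFactors = FALSE)
  }
  out
}

#' Validate a set of input tables
#'
#' Schema, invariant and cross-file referential checks for the pipeline's
#' input tables. Never throws: every violation becomes one report row.
#'
#' @param tables named list of data.frames (as from [simulate_tables()] or
#'   `read_tables`); recognised names: `censuses`, `video_plots`,
#'   `photoquadrats`, `stomachs`, `assays`, `turf`, `length_weight`,
#'   `groups`.
#' @return data.frame with columns `table`, `row`, `column`, `message`;
#'   zero rows when everything passes.
#' @export
validate_tables <- function(tables) {
  fails <- list()
  add <- function(table, row, column, message)
    fails[[length(fails) + 1L]] <<- data.frame(
      table = table, row = row, column = column, message = message,
      stringsAsFactors = FALSE)
  check_cols <- function(nm, cols) {
    miss <- setdiff(cols, names(tables[[nm]]))
    for (cc in miss) add(nm, NA_integer_, cc, "missing column")
    length(miss) == 0L
  }
  bad_rows <- function(nm, column, bad, message) {
    for (r in which(bad)) add(nm, r, column, message)
  }
  if (!is.null(tables$censuses) &&
      check_cols("censuses", c("transect_id", "habitat", "species",
                               "count", "total_length_cm"))) {
    cz <- tables$censuses
    bad_rows("censuses", "count", !is.na(cz$count) & cz$count < 1,
             "count must be >= 1")
    bad_rows("censuses", "total_length_cm",
             !is.na(cz$total_length_cm) & cz$total_length_cm <= 0,
             "total length must be > 0")
  }
  if (!is.null(tables$video_plots) &&
      check_cols("video_plots", c("plot_id", "habitat", "species",
                                  "total_length_cm", "bites"))) {
    vp <- tables$video_plots
    real <- !is.na(vp$species)
    bad_rows("video_plots", "bites", real & (is.na(vp$bites) | vp$bites < 0),
             "bites must be >= 0")
    bad_rows("video_plots", "total_length_cm",
             real & (is.na(vp$total_length_cm) | vp$total_length_cm <= 0),
             "total length must be > 0")
  }
  for (nm in c("photoquadrats", "stomachs")) {
    if (is.null(tables[[nm]])) next
    if (!check_cols(nm, c("set_id", "point_index", "label"))) next
    pt <- tables[[nm]]
    sizes <- table(pt$set_id)
    if (length(unique(sizes)) > 1L)
      add(nm, NA_integer_, "set_id",
          sprintf("unequal point counts per set (%s)",
                  paste(sort(unique(sizes)), collapse = ", ")))
    bad_rows(nm, "label", is.na(pt$label) | pt$label == "",
             "empty label")
  }
  if (!is.null(tables$assays) &&
      check_cols("assays", c("trial", "alga", "Wr_i", "Wr_F", "Wc_i",
                             "Wc_F", "species", "bites"))) {
    as_ <- tables$assays
    for (cc in c("Wr_i", "Wc_i", "Wc_F"))
      bad_rows("assays", cc, !is.na(as_[[cc]]) & as_[[cc]] <= 0,
               "weight must be > 0")
    bad_rows("assays", "Wr_F", !is.na(as_$Wr_F) & as_$Wr_F < 0,
             "final weight must be >= 0")
    bad_rows("assays", "bites", !is.na(as_$bites) & as_$bites < 0,
             "bites must be >= 0")
    sets <- tapply(as_$alga, as_$trial, function(a) paste(sort(unique(a)),
                                                          collapse = "|"))
    if (length(unique(sets)) > 1L)
      add("assays", NA_integer_, "alga",
          "alga set differs between trials")
  }
  if (!is.null(tables$turf) &&
      check_cols("turf", c("sample_id", "habitat", "component", "taxon",
                           "value"))) {
    bad_rows("turf", "value",
             !is.na(tables$turf$value) & tables$turf$value < 0,
             "value must be >= 0")
  }
  ref_check <- function(nm, species_col, lookup, lookup_nm) {
    if (is.null(tables[[nm]]) || is.null(tables[[lookup_nm]])) return()
    sp <- tables[[nm]][[species_col]]
    miss <- !is.na(sp) & !(sp %in% tables[[lookup_nm]]$species)
    bad_rows(nm, species_col, miss,
             sprintf("species missing from %s", lookup_nm))
  }
  ref_check("censuses", "species", NULL, "length_weight")
  ref_check("censuses", "species", NULL, "groups")
  ref_check("video_plots", "species", NULL, "length_weight")
  ref_check("video_plots", "species", NULL, "groups")
  if (length(fails) == 0L)
    return(data.frame(table = character(0), row = integer(0),
                      column = character(0), message = character(0)))
  res <- do.call(rbind, fails)
  rownames(res) <- NULL
  res
}

write_result <- function(df, dir, name, outputs) {
  p <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(df, p, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  c(outputs, p)
}

friedman_row <- function(fr, label) {
  data.frame(analysis = label, chi_squared = fr$statistic, df = fr$df,
             p_value = fr$p_value, n_blocks = fr$n_blocks,
             k_treatments = fr$k_treatments, stringsAsFactors = FALSE)
}

# wide trial x alga matrix of a value column from a long assay-shaped table
blocks_matrix <- function(df, block, treatment, value) {
  bl <- sort(unique(df[[block]]))
  tr <- sort(unique(df[[treatment]]))
  m <- matrix(NA_real_, length(bl), length(tr), dimnames = list(bl, tr))
  m[cbind(match(df[[block]], bl), match(df[[treatment]], tr))] <- df[[value]]
  m
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the input tables, validates them, and produces the
#' study's analysis set: transect summaries with assemblage ANOSIM and
#' ordination; benthic cover tables with ANOSIM and PCA; the
#' feeding-pressure breakdown and habitat contrast; the turf regression and
#' habitat t-tests; assay consumption, Strauss selectivity with bootstrap
#' classification and Friedman comparisons; diet profiles with Friedman
#' tests; and a JSON manifest with seed, checksums and the output list.
#'
#' @param config a [scenario_config()]; its seed drives every stage unless
#'   `seed` overrides it.
#' @param out_dir bundle directory (created; inputs under `inputs/`).
#' @param seed optional integer overriding `config$seed`.
#' @param input_dir optional directory of existing input CSVs to analyse
#'   instead of simulating.
#' @param n_boot bootstrap iterations (selectivity, pressure ratio).
#' @param n_perm ANOSIM permutations.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_scenario(), out_dir,
                         seed = NULL, input_dir = NULL,
                         n_boot = 1000L, n_perm = 999L) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_scenario(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  in_dir <- file.path(out_dir, "inputs")
  if (is.null(input_dir)) {
    tables <- simulate_tables(config)
    write_tables(tables, in_dir)
  } else {
    tables <- read_tables(input_dir)
    if (!dir.exists(in_dir)) dir.create(in_dir)
    file.copy(list.files(input_dir, full.names = TRUE), in_dir,
              overwrite = TRUE)
  }
  report <- validate_tables(tables)
  if (nrow(report) > 0L) {
    first <- report[1L, ]
    validation_error(sprintf(
      "input validation failed (%d problem(s)); first: table %s, row %s, column %s: %s",
      nrow(report), first$table, as.character(first$row), first$column,
      first$message))
  }
  outputs <- character(0)
  log_stage <- function(stage, n_in, n_out)
    message(sprintf("[reefpress] stage=%s seed=%d rows_in=%d rows_out=%d",
                    stage, config$seed, n_in, n_out))

  # --- assemblage -----------------------------------------------------
  ts <- transect_summaries(tables$censuses, tables$length_weight,
                           tables$groups, area_m2 = config$transect_area_m2)
  outputs <- write_result(ts$transects, out_dir, "transect_summaries", outputs)
  outputs <- write_result(ts$groups, out_dir, "group_summaries", outputs)
  bm <- build_matrix(ts, "biomass", "sqrt")
  hab <- attr(bm, "habitat")
  keep <- hab %in% names(which(table(hab) >= 2))
  d_bray <- dissimilarity_matrix(bm[keep, , drop = FALSE], "bray_curtis")
  an_fish <- anosim(d_bray, hab[keep], n_perm = n_perm, seed = config$seed)
  ord <- pcoa(d_bray, k = 2L)
  outputs <- write_result(
    data.frame(analysis = "assemblage_biomass", statistic = an_fish$statistic,
               p_value = an_fish$p_value, n_perm = an_fish$n_perm,
               distance = "bray_curtis", transform = "sqrt",
               ordination = "pcoa", stringsAsFactors = FALSE),
    out_dir, "assemblage_anosim", outputs)
  outputs <- write_result(
    data.frame(sample_id = rownames(ord$points), habitat = hab[keep],
               PCo1 = ord$points[, 1], PCo2 = ord$points[, 2],
               stringsAsFactors = FALSE),
    out_dir, "assemblage_ordination", outputs)
  log_stage("assemblage", nrow(tables$censuses), nrow(ts$transects))

  # --- benthic cover --------------------------------------------------
  cov <- plot_cover(tables$photoquadrats,
                    categories = colnames(config$cover_profiles))
  outputs <- write_result(cov, out_dir, "cover_by_plot", outputs)
  cm <- cover_matrix(cov, "arcsine")
  chab <- attr(cm, "habitat")
  d_euc <- dissimilarity_matrix(cm, "euclidean")
  an_cov <- anosim(d_euc, chab, n_perm = n_perm, seed = config$seed)
  pc <- pca(cm, k = 2L)
  outputs <- write_result(
    data.frame(analysis = "benthic_cover", statistic = an_cov$statistic,
               p_value = an_cov$p_value, n_perm = an_cov$n_perm,
               distance = "euclidean", transform = "arcsine_sqrt",
               ordination = "pca", stringsAsFactors = FALSE),
    out_dir, "cover_anosim", outputs)
  outputs <- write_result(
    data.frame(plot_id = rownames(pc$scores), habitat = chab,
               PC1 = pc$scores[, 1], PC2 = pc$scores[, 2],
               explained_1 = pc$explained[1], explained_2 = pc$explained[2],
               stringsAsFactors = FALSE),
    out_dir, "cover_pca", outputs)
  log_stage("benthic_cover", nrow(tables$photoquadrats), nrow(cov))

  # --- feeding pressure -----------------------------------------------
  pp <- plot_pressure(tables$video_plots, tables$length_weight)
  outputs <- write_result(pp, out_dir, "pressure_by_plot", outputs)
  br <- pressure_breakdown(tables$video_plots, tables$length_weight,
                           tables$groups)
  outputs <- write_result(br$species, out_dir, "pressure_by_species", outputs)
  outputs <- write_result(br$groups, out_dir, "pressure_by_group", outputs)
  habs <- unique(pp$habitat)
  if (all(c("closed", "open") %in% habs)) {
    ct <- habitat_contrast(pp, "closed", "open", n_boot = n_boot,
                           seed = config$seed)
    outputs <- write_result(
      data.frame(numerator = "closed", denominator = "open",
                 ratio = ct$ratio, ci_low = ct$ci[1], ci_high = ct$ci[2],
                 t_statistic = ct$t_statistic, df = ct$df,
                 p_value = ct$p_value, n_closed = ct$n[1], n_open = ct$n[2],
                 flag = ct$flag, stringsAsFactors = FALSE),
      out_dir, "pressure_contrast", outputs)
  }
  log_stage("feeding_pressure", nrow(tables$video_plots), nrow(pp))

  # --- algal turfs ----------------------------------------------------
  tt <- turf_totals(tables$turf)
  reg <- turf_regression(tt)
  outputs <- write_result(
    data.frame(slope = reg$slope, intercept = reg$intercept,
               r_squared = reg$r_squared, p_value = reg$p_value,
               n = reg$n, flag = reg$flag, stringsAsFactors = FALSE),
    out_dir, "turf_regression", outputs)
  if (length(unique(tt$habitat)) == 2L) {
    h12 <- sort(unique(tt$habitat))
    tw <- t_test_sqrt(tt$total_dry_weight_g[tt$habitat == h12[1]],
                      tt$total_dry_weight_g[tt$habitat == h12[2]])
    tc <- t_test_sqrt(tt$total_cryptofauna[tt$habitat == h12[1]],
                      tt$total_cryptofauna[tt$habitat == h12[2]])
    tw$analysis <- "turf_dry_weight"; tc$analysis <- "cryptofauna_density"
    outputs <- write_result(rbind(tw, tc), out_dir, "turf_tests", outputs)
  }
  log_stage("algal_turfs", nrow(tables$turf), nrow(tt))

  # --- herbivory assays -----------------------------------------------
  cons <- assay_consumption(tables$assays)
  outputs <- write_result(cons, out_dir, "consumption", outputs)
  fr_cons <- friedman_test(blocks_matrix(cons, "trial", "alga",
                                         "consumed_proportion"))
  frs <- friedman_row(fr_cons, "consumed_proportion")
  L <- strauss_assays(tables$assays)
  sel <- bootstrap_selectivity(L, n_iter = n_boot, seed = config$seed)
  outputs <- write_result(sel, out_dir, "selectivity", outputs)
  for (sp in unique(tables$assays$species)) {
    sub <- tables$assays[tables$assays$species == sp, ]
    bm_sp <- blocks_matrix(sub, "trial", "alga", "bites")
    frs <- rbind(frs, friedman_row(friedman_test(bm_sp),
                                   paste0("bites_", gsub(" ", "_", sp))))
  }
  outputs <- write_result(frs, out_dir, "assay_friedman", outputs)
  spp <- unique(tables$assays$species)
  if (length(spp) >= 2L) {
    bs <- bite_share_comparison(tables$assays, spp[1:2])
    outputs <- write_result(bs$tests, out_dir, "bite_share_tests", outputs)
  }
  log_stage("selectivity", nrow(tables$assays), nrow(sel))

  # --- diet -----------------------------------------------------------
  diet <- diet_composition(tables$stomachs)
  outputs <- write_result(diet$full, out_dir, "diet_profiles", outputs)
  outputs <- write_result(diet$excluding, out_dir,
                          "diet_profiles_excluding_sediment_detritus",
                          outputs)
  dfr <- NULL
  for (cs in unique(tables$stomachs$consumer)) {
    sub <- tables$stomachs[tables$stomachs$consumer == cs, ]
    m <- cover_by_set(sub)
    dfr <- rbind(dfr, friedman_row(friedman_test(m),
                                   paste0("diet_", gsub(" ", "_", cs))))
  }
  outputs <- write_result(dfr, out_dir, "diet_friedman", outputs)
  log_stage("diet", nrow(tables$stomachs), nrow(diet$full))

  # --- manifest -------------------------------------------------------
  cfg_yaml <- file.path(out_dir, "config.yaml")
  writeLines(yaml::as.yaml(rapply(unclass(config), function(z)
    if (is.matrix(z)) as.data.frame(z) else z, how = "replace")), cfg_yaml)
  input_files <- sort(list.files(in_dir, full.names = TRUE))
  manifest <- list(
    package = "reefpress",
    version = as.character(utils::packageVersion("reefpress")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_yaml)),
    inputs = as.list(stats::setNames(unname(tools::md5sum(input_files)),
                                     basename(input_files))),
    outputs = basename(sort(outputs)),
    ordination_note = paste("metric PCoA/PCA used for ordination;",
                            "deterministic substitute for nMDS display")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
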