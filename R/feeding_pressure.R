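# Mass-scaled feeding pressure from remote-video bite records. The unit is
# kept as printed in field studies of this design: (bites x kg) per
# (2 m2 x 10 min) plot; the plot is the sampling unit throughout.

#' Per-plot feeding pressure
#'
#' For every plot, the sum over recorded fish of bites x body mass (kg),
#' with mass from the length-weight conversion. Placeholder rows
#' (`species = NA`, written by the generator for plots where no fish fed)
#' contribute zero but keep the plot in the output.
#'
#' @param records data.frame with columns `plot_id`, `habitat`, `species`,
#'   `total_length_cm`, `bites`.
#' @param lw_table data.frame `species`, `a`, `b`.
#' @return data.frame with one row per plot: `plot_id`, `habitat`,
#'   `pressure` (bites.kg per 2 m2 x 10 min), `n_fish`.
#' @export
plot_pressure <- function(records, lw_table) {
  need_cols(records, c("plot_id", "habitat", "species", "total_length_cm",
                       "bites"), "video-plot table")
  plots <- unique(records[, c("plot_id", "habitat")])
  fish <- records[!is.na(records$species), , drop = FALSE]
  if (nrow(fish) > 0 && any(fish$bites < 0))
    validation_error("bite counts must be >= 0")
  pr <- stats::setNames(numeric(nrow(plots)), plots$plot_id)
  nf <- stats::setNames(integer(nrow(plots)), plots$plot_id)
  if (nrow(fish) > 0) {
    lw <- lw_lookup(fish$species, lw_table)
    contrib <- fish$bites *
      estimate_mass(fish$total_length_cm, lw$a, lw$b) / 1000
    s <- tapply(contrib, fish$plot_id, sum)
    pr[names(s)] <- as.numeric(s)
    n <- tapply(fish$plot_id, fish$plot_id, length)
    nf[names(n)] <- as.integer(n)
  }
  data.frame(plot_id = plots$plot_id, habitat = plots$habitat,
             pressure = as.numeric(pr[plots$plot_id]),
             n_fish = as.integer(nf[plots$plot_id]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Feeding-pressure breakdown by species, functional group and habitat
#'
#' Species and group values are means over a habitat's plots of the
#' within-plot contribution (plots without the species contribute zero), so
#' the habitat total decomposes exactly into its group components.
#' Percentage shares are relative to the habitat total.
#'
#' @inheritParams plot_pressure
#' @param group_map data.frame `species`, `group`, optionally
#'   `feeding_group` (used here, since dual-role species feed under a
#'   different functional label than they are censused under).
#' @return list of data.frames `species`, `groups`, `habitats`, each with
#'   `mean_pressure` (bites.kg per plot), `share_pct` and `n_plots`.
#' @export
pressure_breakdown <- function(records, lw_table, group_map) {
  need_cols(records, c("plot_id", "habitat", "species", "total_length_cm",
                       "bites"), "video-plot table")
  plots <- unique(records[, c("plot_id", "habitat")])
  n_plots <- table(plots$habitat)
  fish <- records[!is.na(records$species), , drop = FALSE]
  lw <- lw_lookup(fish$species, lw_table)
  grp <- group_lookup(fish$species, group_map, "feeding")
  contrib <- fish$bites * estimate_mass(fish$total_length_cm, lw$a, lw$b) / 1000
  sum_by <- function(labels) {
    k <- paste(fish$habitat, labels, sep = "\r")
    tot <- tapply(contrib, k, sum)
    parts <- strsplit(names(tot), "\r", fixed = TRUE)
    hab <- vapply(parts, `[`, "", 1L)
    who <- vapply(parts, `[`, "", 2L)
    df <- data.frame(habitat = hab, label = who,
                     mean_pressure = as.numeric(tot) / as.numeric(n_plots[hab]),
                     n_plots = as.integer(n_plots[hab]),
                     stringsAsFactors = FALSE, row.names = NULL)
    hab_tot <- tapply(df$mean_pressure, df$habitat, sum)
    df$share_pct <- 100 * df$mean_pressure / as.numeric(hab_tot[df$habitat])
    df[order(df$habitat, -df$mean_pressure), ]
  }
  species <- sum_by(fish$species)
  names(species)[names(species) == "label"] <- "species"
  groups <- sum_by(grp)
  names(groups)[names(groups) == "label"] <- "group"
  habitats <- data.frame(
    habitat = names(n_plots),
    mean_pressure = vapply(names(n_plots), function(h)
      sum(contrib[fish$habitat == h]) / as.numeric(n_plots[[h]]), 0),
    n_plots = as.integer(n_plots), stringsAsFactors = FALSE,
    row.names = NULL)
  list(species = species, groups = groups, habitats = habitats)
}

#' Habitat contrast of total feeding pressure
#'
#' Ratio of mean per-plot pressures with a percentile bootstrap confidence
#' interval (resampling plots within each habitat), plus a Welch two-sample
#' t-test on square-root transformed plot pressures.
#'
#' @param pressures data.frame from [plot_pressure()].
#' @param habitat_a,habitat_b habitat labels (ratio is A over B).
#' @param n_boot bootstrap iterations.
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap resampling.
#' @return list of class `pressure_contrast`: `ratio`, `ci` (length-2),
#'   `t_statistic`, `df`, `p_value`, `n` (plots per habitat), `flag`
#'   (`"ok"` or `"undefined_ratio"`).
#' @export
habitat_contrast <- function(pressures, habitat_a, habitat_b,
                             n_boot = 1000L, conf = 0.95, seed = 1L) {
  need_cols(pressures, c("habitat", "pressure"), "pressure table")
  a <- pressures$pressure[pressures$habitat == habitat_a]
  b <- pressures$pressure[pressures$habitat == habitat_b]
  if (length(a) < 2L || length(b) < 2L)
    validation_error("need >= 2 plots per habitat for the contrast")
  tt <- stats::t.test(sqrt(a), sqrt(b))
  if (mean(b) == 0) {
    return(structure(list(ratio = NA_real_, ci = c(NA_real_, NA_real_),
                          t_statistic = unname(tt$statistic),
                          df = unname(tt$parameter),
                          p_value = tt$p.value,
                          n = c(length(a), length(b)),
                          n_boot = n_boot, flag = "undefined_ratio"),
                     class = "pressure_contrast"))
  }
  ratio <- mean(a) / mean(b)
  boot <- with_stream(seed, "pressure_contrast", {
    ia <- matrix(sample.int(length(a), length(a) * n_boot, replace = TRUE),
                 nrow = length(a))
    ib <- matrix(sample.int(length(b), length(b) * n_boot, replace = TRUE),
                 nrow = length(b))
    colMeans(matrix(a[ia], nrow = length(a))) /
      colMeans(matrix(b[ib], nrow = length(b)))
  })
  boot <- boot[is.finite(boot)]
  alpha <- 1 - conf
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2),
                               type = 7, names = FALSE))
  structure(list(ratio = ratio, ci = ci,
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 n = c(length(a), length(b)), n_boot = n_boot, flag = "ok"),
            class = "pressure_contrast")
}

#' @export
print.pressure_contrast <- function(x, ...) {
  if (x$flag == "undefined_ratio") {
    cat("Pressure ratio undefined (denominator habitat mean is 0)\n")
  } else {
    cat(sprintf("Pressure ratio %.3g (%.0f%% CI %.3g-%.3g), t = %.3g, p = %.3g\n",
                x$ratio, 95, x$ci[1], x$ci[2], x$t_statistic, x$p_value))
  }
  invisible(x)
}

#' Convert plot-unit pressure to per-m2-per-min
#'
#' @param pressure value(s) in bites.kg per (2 m2 x 10 min).
#' @param area_m2,minutes the plot standard (2 m2, 10 min).
#' @return bites.kg per m2 per min.
#' @export
pressure_per_m2_min <- function(pressure, area_m2 = 2, minutes = 10) {
  pressure / (area_m2 * minutes)
}
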