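# Point-intercept percent cover (photoquadrats and stomach spreads),
# category aggregation, and the turf-biomass ~ cryptofauna regression.

#' Arcsine-square-root transform of a percentage
#'
#' t(p) = asin(sqrt(p / 100)), the classical variance-stabilizing transform
#' for proportions used upstream of Euclidean-distance ordinations.
#'
#' @param pct percentage in [0, 100].
#' @return transformed value in [0, pi/2].
#' @export
arcsine_sqrt <- function(pct) {
  if (any(pct < -1e-9 | pct > 100 + 1e-9))
    validation_error("percentages must lie in [0, 100]")
  asin(sqrt(pmin(pmax(pct / 100, 0), 1)))
}

#' Percent cover of one point-intercept set
#'
#' cover_c = 100 n_c / n_scored, where unscorable points are excluded from
#' the denominator (the point-count software convention). Covers sum to 100
#' when any point is scorable.
#'
#' @param labels character vector of point labels (50 in the study design).
#' @param categories optional declared vocabulary; defaults to the labels
#'   observed. Scored categories absent from the set get 0.
#' @param unscorable the label treated as unscorable.
#' @return named numeric vector of percent covers; attribute `n_scored`
#'   carries the denominator. If every point is unscorable the vector is
#'   all-`NA` and attribute `flag` is `"all_unscorable"`.
#' @export
set_cover <- function(labels, categories = NULL, unscorable = "unscorable") {
  scored <- labels[labels != unscorable]
  if (is.null(categories)) categories <- sort(unique(scored))
  out <- stats::setNames(rep(0, length(categories)), categories)
  if (length(scored) == 0L) {
    out[] <- NA_real_
    attr(out, "n_scored") <- 0L
    attr(out, "flag") <- "all_unscorable"
    return(out)
  }
  extra <- setdiff(unique(scored), categories)
  if (length(extra) > 0L)
    validation_error(paste0("labels outside declared vocabulary: ",
                            paste(extra, collapse = ", ")))
  tab <- table(factor(scored, levels = categories))
  out[] <- 100 * as.numeric(tab) / length(scored)
  attr(out, "n_scored") <- length(scored)
  out
}

# long point table -> per-set cover matrix (sets x categories)
cover_by_set <- function(points, unscorable = "unscorable",
                         categories = NULL) {
  need_cols(points, c("set_id", "point_index", "label"), "point table")
  sets <- unique(points$set_id)
  if (is.null(categories))
    categories <- sort(unique(points$label[points$label != unscorable]))
  m <- matrix(NA_real_, length(sets), length(categories),
              dimnames = list(sets, categories))
  for (s in sets) {
    cv <- set_cover(points$label[points$set_id == s], categories, unscorable)
    m[s, ] <- as.numeric(cv)
  }
  m
}

#' Mean percent cover per plot
#'
#' Averages the per-set covers of each plot's photoquadrats (five 25 x 25 cm
#' quadrats per plot in the study design) and reports the
#' arcsine-square-root transform alongside.
#'
#' @param points long data.frame: `set_id`, `plot_id`, `habitat`,
#'   `point_index`, `label`.
#' @param unscorable label excluded from cover denominators.
#' @param categories optional declared category vocabulary.
#' @return data.frame: `plot_id`, `habitat`, `category`, `cover_pct`,
#'   `arcsine`.
#' @export
plot_cover <- function(points, unscorable = "unscorable",
                       categories = NULL) {
  need_cols(points, c("set_id", "plot_id", "habitat", "point_index",
                      "label"), "photoquadrat table")
  m <- cover_by_set(points, unscorable, categories)
  key <- unique(points[, c("set_id", "plot_id", "habitat")])
  plot_of <- stats::setNames(key$plot_id, key$set_id)
  hab_of <- stats::setNames(key$habitat, key$plot_id)
  plots <- unique(key$plot_id)
  out <- do.call(rbind, lapply(plots, function(p) {
    rows <- m[plot_of[rownames(m)] == p, , drop = FALSE]
    mu <- colMeans(rows, na.rm = TRUE)
    data.frame(plot_id = p, habitat = unname(hab_of[p]),
               category = colnames(m), cover_pct = as.numeric(mu),
               arcsine = arcsine_sqrt(as.numeric(mu)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Wide cover matrix for ordination
#'
#' @param cover data.frame from [plot_cover()] (or any long table with
#'   `plot_id`, `category` and the chosen value column).
#' @param value `"cover_pct"` or `"arcsine"`.
#' @return plots x categories numeric matrix with attribute `habitat`.
#' @export
cover_matrix <- function(cover, value = c("cover_pct", "arcsine")) {
  value <- match.arg(value)
  need_cols(cover, c("plot_id", "habitat", "category", value), "cover table")
  plots <- unique(cover$plot_id)
  cats <- sort(unique(cover$category))
  m <- matrix(0, length(plots), length(cats), dimnames = list(plots, cats))
  m[cbind(match(cover$plot_id, plots), match(cover$category, cats))] <-
    cover[[value]]
  attr(m, "habitat") <- cover$habitat[match(plots, cover$plot_id)]
  m
}

#' Diet composition from stomach point-intercept spreads
#'
#' Mean relative abundance of diet items per consumer species, reported
#' both on all items and renormalized after removing the sediment and
#' detritus fractions (to see the algal component of the diet).
#'
#' @param points long data.frame: `set_id`, `consumer`, `point_index`,
#'   `label`.
#' @param exclude items removed before renormalization.
#' @param unscorable label excluded from denominators.
#' @return list with data.frames `full` and `excluding` (`consumer`,
#'   `item`, `mean_pct`, `n_stomachs`); stomachs with nothing left after
#'   exclusion are dropped from the `excluding` means and counted in
#'   attribute `n_empty_after_exclusion`.
#' @export
diet_composition <- function(points, exclude = c("sediment", "detritus"),
                             unscorable = "unscorable") {
  need_cols(points, c("set_id", "consumer", "point_index", "label"),
            "stomach table")
  m <- cover_by_set(points, unscorable)
  key <- unique(points[, c("set_id", "consumer")])
  cons_of <- stats::setNames(key$consumer, key$set_id)
  profile <- function(mm) {
    do.call(rbind, lapply(unique(cons_of), function(cs) {
      rows <- mm[cons_of[rownames(mm)] == cs, , drop = FALSE]
      rows <- rows[stats::complete.cases(rows), , drop = FALSE]
      data.frame(consumer = cs, item = colnames(mm),
                 mean_pct = as.numeric(colMeans(rows)),
                 n_stomachs = nrow(rows), stringsAsFactors = FALSE)
    }))
  }
  full <- profile(m)
  keep <- !(colnames(m) %in% exclude)
  if (!any(keep)) validation_error("exclusion removes every diet item")
  m2 <- m[, keep, drop = FALSE]
  tot <- rowSums(m2)
  empty <- is.finite(tot) & tot <= 0
  m2 <- 100 * m2 / tot
  m2[empty, ] <- NA_real_
  excluding <- profile(m2)
  rownames(full) <- rownames(excluding) <- NULL
  out <- list(full = full, excluding = excluding)
  attr(out, "n_empty_after_exclusion") <- sum(empty, na.rm = TRUE)
  out
}

#' Per-sample turf totals
#'
#' @param turf long data.frame from [generate_turf_samples()] (columns
#'   `sample_id`, `habitat`, `pool`, `component`, `taxon`, `value`).
#' @return data.frame: `sample_id`, `habitat`, `pool`,
#'   `total_dry_weight_g` (g per 100 cm2), `total_cryptofauna` (individuals
#'   per 100 cm2).
#' @export
turf_totals <- function(turf) {
  need_cols(turf, c("sample_id", "habitat", "pool", "component", "taxon",
                    "value"), "turf table")
  if (any(turf$value < 0)) validation_error("turf values must be >= 0")
  ids <- unique(turf[, c("sample_id", "habitat", "pool")])
  w <- tapply(turf$value[turf$component == "alga"],
              turf$sample_id[turf$component == "alga"], sum)
  cf <- tapply(turf$value[turf$component == "cryptofauna"],
               turf$sample_id[turf$component == "cryptofauna"], sum)
  ids$total_dry_weight_g <- as.numeric(w[ids$sample_id])
  ids$total_cryptofauna <- as.numeric(cf[ids$sample_id])
  ids$total_cryptofauna[is.na(ids$total_cryptofauna)] <- 0
  rownames(ids) <- NULL
  ids
}

#' Cryptofauna-on-turf-biomass regression
#'
#' Ordinary least squares of total cryptofauna density on total turf dry
#' weight across scrape samples.
#'
#' @param samples data.frame from [turf_totals()] (or any table with
#'   `total_dry_weight_g` and `total_cryptofauna`).
#' @return list of class `turf_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, `flag` (`"ok"` or `"undefined_fit"` when
#'   the predictor has no variance).
#' @export
turf_regression <- function(samples) {
  need_cols(samples, c("total_dry_weight_g", "total_cryptofauna"),
            "turf totals")
  x <- samples$total_dry_weight_g
  y <- samples$total_cryptofauna
  if (length(x) < 3L) validation_error("need >= 3 samples for the regression")
  if (stats::var(x) == 0)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, p_value = NA_real_,
                          n = length(x), flag = "undefined_fit"),
                     class = "turf_regression"))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  # constant response: slope is exactly 0 and no variance is explained
  r2 <- if (stats::var(y) == 0) 0 else sm$r.squared
  p <- if (nrow(sm$coefficients) > 1L) sm$coefficients[2L, 4L] else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, p_value = p,
                 n = length(x), flag = "ok"),
            class = "turf_regression")
}

#' @export
print.turf_regression <- function(x, ...) {
  if (x$flag != "ok") cat("Turf regression undefined (constant predictor)\n")
  else cat(sprintf(
    "Cryptofauna ~ turf dry weight: slope %.3g, intercept %.3g, R2 = %.3f, p = %.3g (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}
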