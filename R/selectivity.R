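# Herbivory-assay arithmetic: control-corrected consumption, the Strauss
# linear selection index L = r_i - p_i, assay-level bootstrap confidence
# intervals and the selected/avoided/neutral classification.

#' Control-corrected proportion of offered algal mass consumed
#'
#' The caged control rope measures handling and hydrodynamic loss; the
#' expected trial-rope final mass absent consumption is
#' Wr_i * Wc_F / Wc_i, and the consumed proportion is one minus the
#' observed over expected final mass:
#' 1 - Wr_F / (Wr_i * Wc_F / Wc_i). Negative values (apparent growth or
#' noise in the control) are returned as-is and flagged. The historically
#' printed ratio form `(Wr_i * Wc_F / Wc_i) / Wr_F` — expected over
#' observed remaining mass, which exceeds 1 under consumption — is
#' available via `method = "as_printed"` for auditability.
#'
#' @param Wr_i,Wr_F initial/final trial-rope wet weights (g).
#' @param Wc_i,Wc_F initial/final control-rope wet weights (g).
#' @param method `"corrected"` (default) or `"as_printed"`.
#' @return numeric vector; for `"corrected"`, attribute `flagged_negative`
#'   marks entries below 0.
#' @examples
#' consumed_proportion(10, 4, 10, 8) # 0.5: expected 8 g remain, 4 g do
#' @export
consumed_proportion <- function(Wr_i, Wr_F, Wc_i, Wc_F,
                                method = c("corrected", "as_printed")) {
  method <- match.arg(method)
  if (any(Wr_i <= 0 | Wc_i <= 0 | Wc_F <= 0))
    validation_error("Wr_i, Wc_i and Wc_F must be > 0")
  if (any(Wr_F < 0)) validation_error("Wr_F must be >= 0")
  expected <- Wr_i * Wc_F / Wc_i
  if (method == "as_printed") return(expected / Wr_F)
  out <- 1 - Wr_F / expected
  attr(out, "flagged_negative") <- out < 0
  out
}

#' Strauss linear selection index for one assay
#'
#' L_i = r_i - p_i, where r_i is alga i's share of all bites in the assay
#' and p_i its share of the total offered (initial) mass. Each L_i lies in
#' [-1, 1] and they sum to zero by construction.
#'
#' @param bites non-negative per-alga bite counts of one fish species.
#' @param initial_masses per-alga initial offered masses (g).
#' @return named numeric vector of L values, or `NULL` when the species
#'   took no bites in the assay (r undefined): a skip, not a failure.
#' @export
strauss_index <- function(bites, initial_masses) {
  if (length(bites) != length(initial_masses))
    validation_error("bites and initial_masses must align")
  if (any(bites < 0) || any(initial_masses < 0))
    validation_error("bites and masses must be non-negative")
  if (sum(initial_masses) <= 0) validation_error("total offered mass is 0")
  if (sum(bites) == 0) return(NULL) # r undefined: skip this assay x species
  r <- bites / sum(bites)
  p <- initial_masses / sum(initial_masses)
  r - p
}

#' Per-assay Strauss indices for every species and alga
#'
#' @param assays long data.frame: `trial`, `alga`, `Wr_i`, `Wr_F`, `Wc_i`,
#'   `Wc_F`, `species`, `bites`.
#' @return data.frame `species`, `trial`, `alga`, `L`; attribute
#'   `n_excluded` is a table of zero-bite (species, trial) exclusions per
#'   species.
#' @export
strauss_assays <- function(assays) {
  need_cols(assays, c("trial", "alga", "Wr_i", "species", "bites"),
            "assay table")
  out <- list()
  excl <- integer(0)
  for (sp in unique(assays$species)) {
    for (tr in unique(assays$trial)) {
      sub <- assays[assays$species == sp & assays$trial == tr, ,
                    drop = FALSE]
      if (nrow(sub) == 0L) next
      L <- strauss_index(sub$bites, sub$Wr_i)
      if (is.null(L)) {
        excl[sp] <- if (is.na(excl[sp])) 1L else excl[sp] + 1L
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        species = sp, trial = tr, alga = sub$alga, L = as.numeric(L),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(species = character(0), trial = numeric(0),
                  alga = character(0), L = numeric(0))
  rownames(res) <- NULL
  attr(res, "n_excluded") <- excl[!is.na(excl)]
  res
}

# percentile bootstrap of a mean over assay-level values
boot_mean_ci <- function(values, n_iter, alpha, seed,
                         label = "selectivity_bootstrap") {
  n <- length(values)
  means <- with_stream(seed, label, {
    idx <- matrix(sample.int(n, n * n_iter, replace = TRUE), nrow = n)
    colMeans(matrix(values[idx], nrow = n))
  })
  unname(stats::quantile(means, c(alpha / 2, 1 - alpha / 2), names = FALSE))
}

classify_ci <- function(lo, hi) {
  if (is.na(lo) || is.na(hi)) NA_character_
  else if (lo > 0) "selected"
  else if (hi < 0) "avoided"
  else "neutral"
}

#' Bootstrap selectivity classification
#'
#' For every species x alga, the observed per-assay L values are resampled
#' with replacement at the assay level (`n_iter` resamples of the mean,
#' 1,000 by default as in the study's design) and a percentile
#' (alpha/2, 1 - alpha/2) confidence interval is taken over the resampled
#' means. A CI entirely above 0 classifies the alga as `selected`, entirely
#' below 0 as `avoided`, otherwise `neutral`.
#'
#' @param L data.frame from [strauss_assays()] (`species`, `trial`,
#'   `alga`, `L`), or a bare numeric vector of per-assay L values for one
#'   species x alga.
#' @param n_iter bootstrap iterations.
#' @param alpha two-sided error rate (0.05 for a 95% CI).
#' @param seed integer seed; each species x alga derives its own stream.
#' @return data.frame: `species`, `alga`, `mean_L`, `ci_low`, `ci_high`,
#'   `classification`, `n_assays`, `flag` (`"ok"` or
#'   `"insufficient_replication"` when fewer than two assays contribute).
#' @export
bootstrap_selectivity <- function(L, n_iter = 1000L, alpha = 0.05,
                                  seed = 1L) {
  if (is.numeric(L) && is.null(dim(L)))
    L <- data.frame(species = "species", trial = seq_along(L),
                    alga = "alga", L = L)
  need_cols(L, c("species", "trial", "alga", "L"), "Strauss index table")
  combos <- unique(L[, c("species", "alga")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sp <- combos$species[i]; al <- combos$alga[i]
    v <- L$L[L$species == sp & L$alga == al]
    if (length(v) < 2L) {
      return(data.frame(species = sp, alga = al, mean_L = mean(v),
                        ci_low = NA_real_, ci_high = NA_real_,
                        classification = NA_character_,
                        n_assays = length(v),
                        flag = "insufficient_replication",
                        stringsAsFactors = FALSE))
    }
    ci <- boot_mean_ci(v, n_iter, alpha, seed,
                       label = paste("selectivity", sp, al))
    data.frame(species = sp, alga = al, mean_L = mean(v),
               ci_low = ci[1], ci_high = ci[2],
               classification = classify_ci(ci[1], ci[2]),
               n_assays = length(v), flag = "ok",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare two species' shares of bites per alga
#'
#' For each assay and alga, each species' proportion of the two species'
#' combined bites; a paired t-test on square-root transformed proportions
#' contrasts the species per alga across assays (pairs with zero combined
#' bites are undefined and dropped).
#'
#' @param assays long assay table (see [strauss_assays()]).
#' @param species_pair character vector of two species names.
#' @return list: `shares` (per trial x alga shares) and `tests` (per alga:
#'   `mean_share_1`, `mean_share_2`, `t_statistic`, `df`, `p_value`,
#'   `n_pairs`, `flag`).
#' @export
bite_share_comparison <- function(assays, species_pair) {
  need_cols(assays, c("trial", "alga", "species", "bites"), "assay table")
  if (length(species_pair) != 2L)
    validation_error("species_pair must name exactly two species")
  a <- assays[assays$species == species_pair[1], c("trial", "alga", "bites")]
  b <- assays[assays$species == species_pair[2], c("trial", "alga", "bites")]
  mg <- merge(a, b, by = c("trial", "alga"), suffixes = c("_1", "_2"))
  if (nrow(mg) == 0L)
    validation_error("the two species share no assays")
  tot <- mg$bites_1 + mg$bites_2
  mg$share_1 <- ifelse(tot > 0, mg$bites_1 / tot, NA_real_)
  mg$share_2 <- ifelse(tot > 0, mg$bites_2 / tot, NA_real_)
  tests <- do.call(rbind, lapply(sort(unique(mg$alga)), function(al) {
    sub <- mg[mg$alga == al & !is.na(mg$share_1), , drop = FALSE]
    if (nrow(sub) < 2L || stats::sd(sub$share_1 - sub$share_2) == 0) {
      return(data.frame(alga = al, mean_share_1 = mean(sub$share_1),
                        mean_share_2 = mean(sub$share_2),
                        t_statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, n_pairs = nrow(sub),
                        flag = "degenerate", stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(sqrt(sub$share_1), sqrt(sub$share_2), paired = TRUE)
    data.frame(alga = al, mean_share_1 = mean(sub$share_1),
               mean_share_2 = mean(sub$share_2),
               t_statistic = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               n_pairs = nrow(sub), flag = "ok", stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  list(shares = mg, tests = tests)
}

#' Per-assay consumption table
#'
#' Applies [consumed_proportion()] to every trial x alga of a long assay
#' table (weights are constant across the species rows of a trial x alga).
#'
#' @param assays long assay table.
#' @param method passed to [consumed_proportion()].
#' @return data.frame: `trial`, `day` (if present), `alga`,
#'   `consumed_proportion`, `flagged_negative`.
#' @export
assay_consumption <- function(assays, method = "corrected") {
  need_cols(assays, c("trial", "alga", "Wr_i", "Wr_F", "Wc_i", "Wc_F"),
            "assay table")
  keep <- c("trial", intersect("day", names(assays)), "alga",
            "Wr_i", "Wr_F", "Wc_i", "Wc_F")
  u <- unique(assays[, keep])
  cp <- consumed_proportion(u$Wr_i, u$Wr_F, u$Wc_i, u$Wc_F, method = method)
  u$consumed_proportion <- as.numeric(cp)
  u$flagged_negative <- if (method == "corrected")
    attr(cp, "flagged_negative") else NA
  u[, c("Wr_i", "Wr_F", "Wc_i", "Wc_F")] <- NULL
  rownames(u) <- NULL
  u
}
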