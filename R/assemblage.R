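# Census records -> per-transect density/biomass, functional-group totals
# and sample-by-taxon matrices for the multivariate stage.

#' Allometric length-to-mass conversion
#'
#' Standard length-weight relationship W = a L^b with L in cm and W in g.
#'
#' @param length total length in cm (vectorized).
#' @param a,b allometric coefficient (g per cm^b) and exponent.
#' @return mass in g.
#' @examples
#' estimate_mass(10, a = 0.01, b = 3) # 10 g
#' @export
estimate_mass <- function(length, a, b) {
  if (any(length <= 0)) validation_error("length must be > 0")
  if (any(a <= 0)) validation_error("length-weight a must be > 0")
  a * length^b
}

# Look up length-weight parameters for species, erroring on missing entries.
lw_lookup <- function(species, lw_table) {
  need_cols(lw_table, c("species", "a", "b"), "length-weight table")
  i <- match(species, lw_table$species)
  if (anyNA(i)) {
    miss <- sort(unique(species[is.na(i)]))
    validation_error(paste0("no length-weight entry for: ",
                            paste(miss, collapse = ", ")))
  }
  lw_table[i, c("a", "b")]
}

# Map species -> functional group, honouring the assemblage/feeding context
# distinction for dual-role species.
group_lookup <- function(species, group_map,
                         context = c("assemblage", "feeding")) {
  context <- match.arg(context)
  col <- if (context == "feeding" && "feeding_group" %in% names(group_map))
    "feeding_group" else "group"
  need_cols(group_map, c("species", col), "group map")
  i <- match(species, group_map$species)
  if (anyNA(i)) {
    miss <- sort(unique(species[is.na(i)]))
    validation_error(paste0("no functional-group mapping for: ",
                            paste(miss, collapse = ", ")))
  }
  group_map[[col]][i]
}

#' Per-transect density, biomass and functional-group totals
#'
#' Density is the summed count per transect and species (individuals per
#' transect area, 40 m2 by default); biomass applies the length-weight
#' conversion to each record (`count` individuals at the recorded length).
#'
#' @param observations data.frame with columns `transect_id`, `habitat`,
#'   `species`, `count`, `total_length_cm`.
#' @param lw_table data.frame `species`, `a`, `b`.
#' @param group_map data.frame `species`, `group` (and optionally
#'   `feeding_group`).
#' @param area_m2 transect area, for the per-m2 conversion columns.
#' @return object of class `transect_summaries`: list with data.frames
#'   `species` (transect x species density and biomass), `groups`
#'   (functional-group totals) and `transects` (whole-transect totals, with
#'   per-m2 conversions).
#' @export
transect_summaries <- function(observations, lw_table, group_map,
                               area_m2 = 40) {
  need_cols(observations,
            c("transect_id", "habitat", "species", "count",
              "total_length_cm"), "census table")
  obs <- observations[!is.na(observations$species), , drop = FALSE]
  if (nrow(obs) > 0 && any(obs$count < 1))
    validation_error("census counts must be >= 1")
  transects <- unique(observations[, c("transect_id", "habitat")])
  if (nrow(obs) == 0) {
    sp_df <- data.frame(transect_id = character(0), habitat = character(0),
                        species = character(0), density = numeric(0),
                        biomass_g = numeric(0))
  } else {
    lw <- lw_lookup(obs$species, lw_table)
    grp <- group_lookup(obs$species, group_map, "assemblage")
    mass <- obs$count * estimate_mass(obs$total_length_cm, lw$a, lw$b)
    key <- interaction(obs$transect_id, obs$species, drop = TRUE)
    sp_df <- data.frame(
      transect_id = tapply(obs$transect_id, key, `[`, 1),
      habitat = tapply(obs$habitat, key, `[`, 1),
      species = tapply(obs$species, key, `[`, 1),
      group = tapply(grp, key, `[`, 1),
      density = as.numeric(tapply(obs$count, key, sum)),
      biomass_g = as.numeric(tapply(mass, key, sum)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  agg <- function(df, by) {
    if (nrow(df) == 0)
      return(data.frame(transect_id = character(0), habitat = character(0),
                        density = numeric(0), biomass_g = numeric(0)))
    k <- interaction(df$transect_id, df[[by]], drop = TRUE)
    data.frame(transect_id = tapply(df$transect_id, k, `[`, 1),
               habitat = tapply(df$habitat, k, `[`, 1),
               group = tapply(df[[by]], k, `[`, 1),
               density = as.numeric(tapply(df$density, k, sum)),
               biomass_g = as.numeric(tapply(df$biomass_g, k, sum)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  grp_df <- agg(sp_df, "group")
  tot <- merge(transects,
               if (nrow(sp_df) == 0)
                 data.frame(transect_id = character(0), density = numeric(0),
                            biomass_g = numeric(0))
               else data.frame(
                 transect_id = names(tapply(sp_df$density, sp_df$transect_id, sum)),
                 density = as.numeric(tapply(sp_df$density, sp_df$transect_id, sum)),
                 biomass_g = as.numeric(tapply(sp_df$biomass_g, sp_df$transect_id, sum)),
                 stringsAsFactors = FALSE),
               by = "transect_id", all.x = TRUE)
  tot$density[is.na(tot$density)] <- 0
  tot$biomass_g[is.na(tot$biomass_g)] <- 0
  tot$density_per_m2 <- tot$density / area_m2
  tot$biomass_g_per_m2 <- tot$biomass_g / area_m2
  tot <- tot[order(tot$transect_id), ]
  rownames(tot) <- NULL
  structure(list(species = sp_df, groups = grp_df, transects = tot,
                 area_m2 = area_m2),
            class = "transect_summaries")
}

#' @export
print.transect_summaries <- function(x, ...) {
  cat("Transect summaries:", nrow(x$transects), "transects,",
      length(unique(x$species$species)), "species\n")
  invisible(x)
}

#' Build a sample-by-taxon matrix from transect summaries
#'
#' One row per transect, one column per species; values are density
#' (ind./transect) or biomass (g/transect), optionally square-root
#' transformed as used upstream of Bray-Curtis dissimilarities. Ephemeral
#' schooling species (or whole samples) can be excluded by name, mirroring
#' the exclusion of transient schools from ordination.
#'
#' @param summaries a [transect_summaries()] result.
#' @param metric `"density"` or `"biomass"`.
#' @param transform `"none"` or `"sqrt"`.
#' @param exclude_species,exclude_samples optional character vectors.
#' @return numeric matrix with transect ids as rownames and species as
#'   colnames; attribute `habitat` carries the per-row habitat labels.
#' @export
build_matrix <- function(summaries, metric = c("density", "biomass"),
                         transform = c("none", "sqrt"),
                         exclude_species = NULL, exclude_samples = NULL) {
  metric <- match.arg(metric)
  if (!transform[1] %in% c("none", "sqrt"))
    validation_error(sprintf("unknown transform: %s", transform[1]))
  transform <- match.arg(transform)
  sp <- summaries$species
  sp <- sp[!(sp$species %in% exclude_species) &
             !(sp$transect_id %in% exclude_samples), , drop = FALSE]
  samples <- setdiff(summaries$transects$transect_id, exclude_samples)
  taxa <- sort(unique(sp$species))
  m <- matrix(0, length(samples), length(taxa),
              dimnames = list(samples, taxa))
  if (nrow(sp) > 0) {
    val <- if (metric == "density") sp$density else sp$biomass_g
    m[cbind(match(sp$transect_id, samples), match(sp$species, taxa))] <- val
  }
  if (transform == "sqrt") m <- sqrt(m)
  hab <- summaries$transects$habitat[match(samples,
                                           summaries$transects$transect_id)]
  attr(m, "habitat") <- hab
  attr(m, "metric") <- metric
  attr(m, "transform") <- transform
  m
}
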