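#' Load the shipped species/section parameter table
#'
#' Returns the fixture table of stem sections (one row per lab-style section)
#' with geometry, mean moisture content and density, and the species-level
#' water-loss-rate and moisture-profile parameters.
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return A data.frame with columns `species`, `tree`, `section`,
#'   `diameter_mm`, `bark_thickness_mm`, `moisture_pct`, `density_g_cm3`,
#'   `Wm`, `P1`, `P2`, `P3`.
#' @export
load_species_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "species_params.csv", package = "stemheat",
                        mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Species parameters for a given stem section
#'
#' Looks up one section of the shipped table and converts it into a
#' [species_params()] object plus a [stem_geometry()]. Density is converted
#' from g/cm^3 to kg/m^3 and moisture from percent to a dry-basis fraction.
#' The single tabulated bark thickness is split half outer / half inner bark
#' by default.
#'
#' @param species Binomial species name (e.g. `"Pinus strobus"`).
#' @param tree,section Tree and section numbers within the species.
#' @param n_wedges,radial_spacing Grid resolution passed to [stem_geometry()].
#' @param diameter_mm Optional override of the section diameter (mm), used by
#'   the virtual experiments.
#' @param bark_thickness_mm Optional override of total bark thickness (mm).
#' @param outer_bark_fraction Fraction of total bark thickness assigned to the
#'   outer (dead) bark layer.
#' @param table Parameter table, defaults to [load_species_table()].
#' @return A list with elements `params` ([species_params()]) and `geometry`
#'   ([stem_geometry()]).
#' @export
section_setup <- function(species, tree = NULL, section = NULL,
                          n_wedges = 16L, radial_spacing = 0.001,
                          diameter_mm = NULL, bark_thickness_mm = NULL,
                          outer_bark_fraction = 0.5,
                          table = load_species_table()) {
  rows <- table[table$species == species, , drop = FALSE]
  if (nrow(rows) == 0) stop("species not found in table: ", species)
  if (!is.null(tree)) rows <- rows[rows$tree == tree, , drop = FALSE]
  if (!is.null(section)) rows <- rows[rows$section == section, , drop = FALSE]
  if (nrow(rows) == 0) stop("no matching section for ", species)
  row <- rows[1L, ]

  d <- (if (is.null(diameter_mm)) row$diameter_mm else diameter_mm) / 1000
  bark <- (if (is.null(bark_thickness_mm)) row$bark_thickness_mm else
             bark_thickness_mm) / 1000
  params <- species_params(dry_wood_density = row$density_g_cm3 * 1000,
                           max_moisture = row$moisture_pct / 100,
                           P1 = row$P1, P2 = row$P2, P3 = row$P3,
                           water_loss_rate = row$Wm,
                           species = row$species)
  geometry <- stem_geometry(diameter = d,
                            outer_bark_thickness = bark * outer_bark_fraction,
                            inner_bark_thickness = bark * (1 - outer_bark_fraction),
                            n_wedges = n_wedges,
                            radial_spacing = radial_spacing)
  list(params = params, geometry = geometry)
}
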