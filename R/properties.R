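#' Species thermophysical and calibration parameters
#'
#' Bundles the per-species constants used by the property functions, the
#' desiccation/charring sinks and the moisture profile: dry densities, the
#' maximum (near-cambium) moisture content `M` on a dry-mass basis, the radial
#' moisture-profile fractions `P1`, `P2`, `P3`, the water-loss-rate parameter
#' `W_m` (dimensionless, bounded to `[0.01, 1]` for a drying fuel particle)
#' and the pyrolysis multiplier `P_m`.
#'
#' Bark moistures default to the live tissue value (`M`) for inner bark and to
#' half of it for the dead outer bark; both can be overridden where measured
#' values exist.
#'
#' @param dry_wood_density Dry wood density rho_w (kg/m^3).
#' @param max_moisture Maximum moisture content M near the cambium
#'   (water mass / dry mass, dimensionless).
#' @param P1,P2,P3 Fractions of `M` applying at the cambium, mid-radius and
#'   stem center respectively (linear interpolation between them).
#' @param water_loss_rate W_m, dimensionless, in `[0.01, 1]`.
#' @param dry_bark_density Dry bark density rho_b (kg/m^3); defaults to the
#'   wood value (a single mean density is typically measured per section).
#' @param pyrolysis_multiplier P_m (0 disables charring).
#' @param inner_bark_moisture,outer_bark_moisture Dry-basis moisture contents
#'   of the bark layers.
#' @param species Optional species label.
#'
#' @return An object of class `species_params`.
#' @export
species_params <- function(dry_wood_density, max_moisture,
                           P1 = 1, P2 = 0.5, P3 = 0.2,
                           water_loss_rate = 0.5,
                           dry_bark_density = dry_wood_density,
                           pyrolysis_multiplier = 0,
                           inner_bark_moisture = max_moisture,
                           outer_bark_moisture = 0.5 * max_moisture,
                           species = NA_character_) {
  stopifnot(dry_wood_density > 0, dry_bark_density > 0, max_moisture >= 0)
  if (any(c(P1, P2, P3) < 0) || any(c(P1, P2, P3) > 1))
    stop("P1, P2, P3 must lie in [0, 1]")
  if (water_loss_rate < 0.01 || water_loss_rate > 1)
    stop("water_loss_rate (W_m) must lie in [0.01, 1]")
  structure(list(dry_wood_density = dry_wood_density,
                 dry_bark_density = dry_bark_density,
                 max_moisture = max_moisture,
                 P1 = P1, P2 = P2, P3 = P3,
                 water_loss_rate = water_loss_rate,
                 pyrolysis_multiplier = pyrolysis_multiplier,
                 inner_bark_moisture = inner_bark_moisture,
                 outer_bark_moisture = outer_bark_moisture,
                 species = species),
            class = "species_params")
}

#' Initial radial moisture profile of the wood
#'
#' Moisture content at radius `r` (from the stem center) is the maximum
#' moisture `M` scaled by a piecewise-linear fraction anchored at `P1` at the
#' vascular cambium (`r = r_d`), `P2` at mid-radius (`0.5 r_d`) and `P3` at
#' the center, with linear interpolation between the breakpoints. Breakpoint
#' locations are configurable fractions of `r_d`.
#'
#' @param r Radius (m) from the stem center; vectorized.
#' @param r_d Radial distance to the vascular cambium (m).
#' @param params A [species_params()] object.
#' @param breakpoints Radial breakpoints as fractions of `r_d` (decreasing),
#'   matched to `c(P1, P2, P3)`.
#' @return Dry-basis moisture content (dimensionless), same length as `r`.
#' @export
initial_moisture_profile <- function(r, r_d, params,
                                     breakpoints = c(1, 0.5, 0)) {
  stopifnot(inherits(params, "species_params"), r_d > 0)
  if (any(r < 0) || any(r > r_d * (1 + 1e-12)))
    stop("r must lie in [0, r_d]")
  fr <- stats::approx(x = breakpoints * r_d,
                      y = c(params$P1, params$P2, params$P3),
                      xout = pmin(r, r_d), rule = 2)$y
  params$max_moisture * fr
}

#' Moist wood density
#'
#' Moist density at radius `r`: dry density inflated by the local dry-basis
#' moisture content, `rho = rho_w (1 + M(r))`.
#'
#' @inheritParams initial_moisture_profile
#' @return Moist density (kg/m^3).
#' @export
wood_moist_density <- function(r, r_d, params, breakpoints = c(1, 0.5, 0)) {
  m <- initial_moisture_profile(r, r_d, params, breakpoints)
  params$dry_wood_density * (1 + m)
}

#' Thermal conductivity of wood
#'
#' Empirical conductivity as a function of specific gravity and moisture
#' content: `k = G_M (0.1941 + 0.4064 M) + 0.01864` (W m^-1 K^-1), with
#' `G_M = rho / rho_w` and `M` the dry-basis moisture fraction. In the solver
#' `rho` is the node dry density and `rho_w` the density of water
#' (1000 kg/m^3), making `G_M` the standard specific gravity.
#'
#' @param rho Density (kg/m^3).
#' @param rho_w Reference density (kg/m^3).
#' @param M Dry-basis moisture content (dimensionless).
#' @return Conductivity (W m^-1 K^-1).
#' @export
wood_conductivity <- function(rho, rho_w, M) {
  if (any(rho < 0) || any(rho_w <= 0) || any(M < 0))
    stop("wood_conductivity: inputs must be non-negative (rho_w > 0)")
  G_M <- rho / rho_w
  G_M * (0.1941 + 0.4064 * M) + 0.01864
}

#' Heat capacity of moist wood
#'
#' Weighted sum of the dry-wood and water heat capacities plus a bond-energy
#' correction:
#' `c_p = (c_p0 + M c_pw) / (1 + M) + A_c` (kJ kg^-1 K^-1) where
#' `c_p0 = 0.1031 + 0.00386 T`,
#' `c_pw = 3.8 + 130 / (645 - T)` for `T <= 630 K` and `15` above, and
#' `A_c = M% (-0.06191 + 2.36e-4 T - 1.33e-4 M%)` with `M% = 100 M`.
#' The final `-1.33e-4 M%` term restores the moisture factor that the source
#' prints truncated. At exactly 630 K the low-temperature branch applies.
#'
#' @param T Temperature (K).
#' @param M Dry-basis moisture content (dimensionless).
#' @return Heat capacity (kJ kg^-1 K^-1).
#' @export
wood_heat_capacity <- function(T, M) {
  stopifnot(all(T > 0), all(M >= 0))
  cp0 <- 0.1031 + 0.00386 * T
  cpw <- ifelse(T <= 630, 3.8 + 130 / (645 - T), 15)
  Mp <- 100 * M
  Ac <- Mp * (-0.06191 + 2.36e-4 * T - 1.33e-4 * Mp)
  (cp0 + M * cpw) / (1 + M) + Ac
}

#' Moist bark density
#'
#' `rho = rho_b (1 + M_bark)` from the dry bark density and the local bark
#' moisture content (inner or outer bark alike).
#'
#' @param rho_b Dry bark density (kg/m^3).
#' @param M_bark Dry-basis bark moisture content.
#' @return Moist density (kg/m^3).
#' @export
bark_moist_density <- function(rho_b, M_bark) {
  stopifnot(all(rho_b > 0), all(M_bark >= 0))
  rho_b * (1 + M_bark)
}

#' Thermal conductivity of bark
#'
#' Three-term empirical sum in dry density, moisture and temperature:
#' `k = 2.104e-4 rho_b + 5.544e-4 rho_b M + 3.266e-4 T - 1.66216e-2`
#' (W m^-1 K^-1; constants already converted to SI from the calorie-based
#' original, 1 cal = 4.184 J). Increasing in each argument.
#'
#' @param rho_b Dry bark density (kg/m^3).
#' @param M_bark Dry-basis bark moisture content.
#' @param T Temperature (K).
#' @return Conductivity (W m^-1 K^-1).
#' @export
bark_conductivity <- function(rho_b, M_bark, T) {
  stopifnot(all(rho_b > 0), all(M_bark >= 0), all(T > 0))
  2.104e-4 * rho_b + 5.544e-4 * rho_b * M_bark + 3.266e-4 * T - 1.66216e-2
}

#' Heat capacity of moist bark
#'
#' Reconstructed calorie-based form converted to SI: dry bark
#' `c_dry = 0.264 + 0.00116 (T - 273.15)` (cal g^-1 K^-1), water mixing
#' `(c_dry + M c_w) / (1 + M)` with `c_w = 1 cal g^-1 K^-1`, plus an empirical
#' moisture correction of the same family as the wood bond term,
#' `Delta_c = M% (-0.06191 + 2.36e-4 T - 1.33e-4 M%) / 4.184` (cal g^-1 K^-1).
#' The sum is returned in kJ kg^-1 K^-1 (1 cal/g/K = 4.184 kJ/kg/K).
#'
#' @param T Temperature (K).
#' @param M_bark Dry-basis bark moisture content.
#' @return Heat capacity (kJ kg^-1 K^-1).
#' @export
bark_heat_capacity <- function(T, M_bark) {
  stopifnot(all(T > 0), all(M_bark >= 0))
  c_dry <- 0.264 + 0.00116 * (T - 273.15)
  Mp <- 100 * M_bark
  delta_c <- Mp * (-0.06191 + 2.36e-4 * T - 1.33e-4 * Mp) / 4.184
  4.184 * ((c_dry + M_bark * 1) / (1 + M_bark) + delta_c)
}
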