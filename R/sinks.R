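# Arrhenius constants for the desiccation and charring kinetics.
KW_WATER <- 6.05e5    # K^0.5 / s, water-loss prefactor
EW_OVER_R <- 5956     # K, water-loss activation temperature
CF_CHAR <- 0.30       # dimensionless char density fraction
AP_CHAR <- 7e7        # 1/s, pyrolysis prefactor
EP_OVER_R <- 15610    # K, pyrolysis activation temperature
LATENT_HEAT_VAP <- 2.26e6   # J/kg, water latent heat of vaporization
HEAT_OF_PYROLYSIS <- 2.5e5  # J/kg, endothermic charring default

#' Temperature-driven water-loss rate
#'
#' Arrhenius-type evaporation rate of tissue water in a control volume:
#' `dm/dt = W_m * k_w * T^(-1/2) * exp(-E_w / (R T)) * M * rho * V` (kg/s)
#' with `k_w = 6.05e5 K^0.5/s` and `E_w/R = 5956 K`. The `T^(-1/2)` prefactor
#' follows from the units of `k_w`. Zero when the tissue is dry (`M = 0`).
#'
#' @param M Dry-basis moisture content (dimensionless).
#' @param T Temperature (K).
#' @param rho Moist density (kg/m^3).
#' @param V Control volume (m^3).
#' @param W_m Species water-loss-rate parameter in `[0.01, 1]`.
#' @return Water mass-loss rate (kg/s), non-negative.
#' @export
water_loss_rate <- function(M, T, rho, V, W_m) {
  stopifnot(all(M >= 0), all(T > 0), all(rho >= 0), all(V >= 0),
            all(W_m >= 0.01), all(W_m <= 1))
  W_m * KW_WATER * T^(-0.5) * exp(-EW_OVER_R / T) * M * rho * V
}

#' Desiccation energy sink
#'
#' Volumetric energy sink from evaporating water:
#' `q = latent_heat * (dm/dt) / V` (W/m^3), always removing energy.
#'
#' @param mass_rate Water mass-loss rate (kg/s), non-negative.
#' @param V Control volume (m^3).
#' @param latent_heat Latent heat of vaporization (J/kg).
#' @return Volumetric sink (W/m^3), non-negative (to be subtracted).
#' @export
desiccation_flux <- function(mass_rate, V, latent_heat = LATENT_HEAT_VAP) {
  stopifnot(all(mass_rate >= 0), all(V > 0))
  latent_heat * mass_rate / V
}

#' Charring (pyrolysis) rate of desiccated bark
#'
#' Arrhenius conversion of the charrable mass above the char density floor:
#' `dm/dt = P_m * A_p * exp(-E_p / (R T)) * max(rho - c_f rho_dry, 0) * V`
#' (kg/s), with `c_f = 0.30`, `A_p = 7e7 1/s` and `E_p/R = 15610 K`. Setting
#' `P_m = 0` disables charring entirely.
#'
#' @param rho Current (moist or dry) density of the node (kg/m^3).
#' @param T Temperature (K).
#' @param P_m Pyrolysis multiplier (dimensionless).
#' @param rho_dry Original dry density of the node (kg/m^3).
#' @param V Control volume (m^3).
#' @return Charring mass rate (kg/s), non-negative.
#' @export
charring_rate <- function(rho, T, P_m, rho_dry = rho, V = 1) {
  stopifnot(all(rho >= 0), all(T > 0), all(P_m >= 0), all(V >= 0))
  P_m * AP_CHAR * exp(-EP_OVER_R / T) * pmax(rho - CF_CHAR * rho_dry, 0) * V
}

#' Per-wedge char-front state
#'
#' Tracks which nodes have charred. The front is contiguous from the bark
#' surface inward and, by construction of [advance_char_front()], can deepen
#' by at most one node per wedge per time step; char flags never revert.
#'
#' @param n_radial,n_wedges Grid dimensions.
#' @param charrable_mass `n_radial x n_wedges` matrix of pyrolyzable mass per
#'   node (kg), i.e. `(1 - c_f) *` dry mass.
#' @return An object of class `char_state` with `charred` (logical matrix),
#'   `front` (integer per wedge, 0 = none) and `remaining` (kg matrix).
#' @export
char_state <- function(n_radial, n_wedges, charrable_mass) {
  stopifnot(all(dim(charrable_mass) == c(n_radial, n_wedges)))
  structure(list(charred = matrix(FALSE, n_radial, n_wedges),
                 front = integer(n_wedges),
                 remaining = charrable_mass),
            class = "char_state")
}

#' Advance the char front by one time step
#'
#' In each wedge only the candidate node (the node just deeper than the
#' current front; the surface node if nothing has charred yet) can pyrolyze
#' this step. Its remaining charrable mass is depleted at `rates[candidate]`,
#' and the node is flagged charred when depleted, advancing the front exactly
#' one node.
#'
#' @param state A [char_state()].
#' @param rates `n_radial x n_wedges` matrix of charring mass rates (kg/s).
#' @param dt Time step (s).
#' @return List with the updated `state` and `mass_charred` (kg per wedge this
#'   step, used for the energy sink).
#' @export
advance_char_front <- function(state, rates, dt) {
  stopifnot(inherits(state, "char_state"), dt > 0)
  n_radial <- nrow(state$charred)
  nw <- ncol(state$charred)
  mass <- numeric(nw)
  for (j in seq_len(nw)) {
    cand <- state$front[j] + 1L
    if (cand > n_radial) next
    dm <- min(rates[cand, j] * dt, state$remaining[cand, j])
    if (dm <= 0) next
    mass[j] <- dm
    state$remaining[cand, j] <- state$remaining[cand, j] - dm
    if (state$remaining[cand, j] <= 1e-15) {
      state$charred[cand, j] <- TRUE
      state$front[j] <- cand
    }
  }
  list(state = state, mass_charred = mass)
}
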