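#' Tissue thermal-tolerance (viability) parameters
#'
#' Parameters of the Eyring-type rate-process model of thermally induced
#' tissue death, with a compensation law linking the activation entropy to
#' the activation enthalpy through `T_crit` and `b_comp`:
#' `Delta_S = Delta_H / T_crit + b_comp`.
#'
#' The shipped defaults are synthetic stand-ins (the published thermal
#' tolerance estimates are not redistributable here), chosen so that tissue
#' held at 333 K (60 C) sustains a 3-log viability reduction in ten minutes
#' while tissue at ambient 295 K retains `N > 0.999` over 24 h. Species-level
#' overrides are accepted by every consumer of this object.
#'
#' @param delta_H Activation enthalpy (J/mol).
#' @param T_crit Compensation temperature (K).
#' @param b_comp Compensation-law intercept (J mol^-1 K^-1).
#' @param R_gas Universal gas constant (J mol^-1 K^-1).
#' @param kB_over_h Boltzmann-to-Planck constant ratio (1 / (s K)).
#' @param threshold Death threshold on viability `N` (default 0.001, a 3-log
#'   reduction).
#' @return An object of class `viability_params`.
#' @export
viability_params <- function(delta_H = 3.1e5, T_crit = 333,
                             b_comp = -282.8, R_gas = 8.31,
                             kB_over_h = 2.08e10, threshold = 0.001) {
  stopifnot(delta_H > 0, T_crit > 0, R_gas > 0, kB_over_h > 0,
            threshold > 0, threshold < 1)
  structure(list(delta_H = delta_H, T_crit = T_crit, b_comp = b_comp,
                 R_gas = R_gas, kB_over_h = kB_over_h, threshold = threshold),
            class = "viability_params")
}

#' Viability progression rate
#'
#' Temperature-dependent rate of viability decline:
#' `f(T) = (kB/h) T exp(Delta_S / R - Delta_H / (R T))` with
#' `Delta_S = Delta_H / T_crit + b_comp`. Strictly increasing in `T`.
#'
#' @param T Temperature (K); vectorized.
#' @param params A [viability_params()] object.
#' @return Rate (1/s).
#' @export
viability_rate <- function(T, params = viability_params()) {
  stopifnot(inherits(params, "viability_params"), all(T > 0))
  dS <- params$delta_H / params$T_crit + params$b_comp
  params$kB_over_h * T *
    exp(dS / params$R_gas - params$delta_H / (params$R_gas * T))
}

#' Viability after constant-temperature exposure
#'
#' Closed-form first-order decay `N = N0 exp(-f t_tot)`. At `f t_tot =
#' log(1000)` viability reaches exactly the default 0.001 death threshold
#' (a 3-log reduction).
#'
#' @param N0 Initial viability in `(0, 1]`.
#' @param f Viability rate (1/s), non-negative.
#' @param t_tot Exposure time (s).
#' @return Viability `N`.
#' @export
constant_T_viability <- function(N0, f, t_tot) {
  stopifnot(all(N0 > 0), all(N0 <= 1), all(f >= 0), all(t_tot >= 0))
  N0 * exp(-f * t_tot)
}

#' Discrete per-step viability update
#'
#' Node-wise multiplicative decay over one time step using the local
#' temperature, tracked in log space to avoid underflow:
#' `log N <- log N - f(T) dt`. Viability is monotone non-increasing; dead
#' nodes stay dead.
#'
#' @param state A `stem_state` (see [initial_state()]).
#' @param dt Time step (s).
#' @param params A [viability_params()] object.
#' @return The updated state.
#' @export
update_viability <- function(state, dt, params = viability_params()) {
  stopifnot(inherits(state, "stem_state"), dt > 0)
  state$logN <- state$logN - viability_rate(state$T, params) * dt
  state
}

#' Necrotic depth and live-area statistics
#'
#' For each wedge, the necrotic depth is the depth below the bark surface of
#' the most interior node whose viability fell below the death threshold
#' (0 if no node died); the live cross-sectional area fraction is the
#' volume-weighted fraction of nodes still at or above the threshold.
#' Intended to be evaluated after the run's cool-down has completed.
#'
#' @param state A `stem_state`.
#' @param grid The matching [build_grid()] object.
#' @param params A [viability_params()] object (supplies the threshold).
#' @return An object of class `injury_result` with `necrotic_depth` (m, per
#'   wedge), `live_area_fraction` (scalar), `time_to_max_depth` (filled by
#'   [run_simulation()], otherwise `NA`).
#' @export
necrotic_depth <- function(state, grid, params = viability_params()) {
  stopifnot(inherits(state, "stem_state"), inherits(grid, "polar_grid"))
  log_thr <- log(params$threshold)
  dead <- state$logN < log_thr
  depth <- numeric(grid$n_wedges)
  for (j in seq_len(grid$n_wedges)) {
    dj <- which(dead[, j])
    depth[j] <- if (length(dj)) grid$radius - grid$node_radii[max(dj)] else 0
  }
  live_frac <- sum(grid$cv_volumes[!dead]) / sum(grid$cv_volumes)
  structure(list(necrotic_depth = depth,
                 live_area_fraction = live_frac,
                 time_to_max_depth = rep(NA_real_, grid$n_wedges)),
            class = "injury_result")
}

#' @export
print.injury_result <- function(x, ...) {
  cat(sprintf("injury_result: depth %.2f-%.2f mm, live area %.1f%%\n",
              1000 * min(x$necrotic_depth), 1000 * max(x$necrotic_depth),
              100 * x$live_area_fraction))
  invisible(x)
}
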