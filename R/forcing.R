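#' @keywords internal
SIGMA_SB <- 5.67e-8  # Stefan-Boltzmann constant, W m^-2 K^-4

#' Time- and wedge-resolved boundary heat-flux forcing
#'
#' Holds the prescribed fire heat flux (sum of fire-driven radiant and
#' convective components) as a time series per circumferential wedge, plus the
#' ambient air temperature used for net radiant exchange. A single flux column
#' broadcasts to all wedges at simulation time.
#'
#' @param times Strictly increasing time stamps (s).
#' @param flux Numeric vector (broadcast) or matrix (`length(times)` rows,
#'   one column per wedge) of fire heat flux (W/m^2), non-negative.
#' @param T_ambient Ambient air temperature (K), scalar or one value per time.
#' @return An object of class `forcing_series`.
#' @export
forcing_series <- function(times, flux, T_ambient) {
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least two points")
  if (is.vector(flux)) flux <- matrix(flux, ncol = 1)
  if (nrow(flux) != length(times))
    stop("flux must have one row per time stamp")
  if (any(flux < 0)) stop("fire flux must be >= 0")
  if (!length(T_ambient) %in% c(1L, length(times)))
    stop("T_ambient must be scalar or one value per time stamp")
  if (any(T_ambient <= 0)) stop("T_ambient must be > 0 K")
  structure(list(times = times, flux = flux,
                 T_ambient = as.numeric(T_ambient)),
            class = "forcing_series")
}

#' @export
print.forcing_series <- function(x, ...) {
  cat(sprintf("forcing_series: %d time points over [%.4g, %.4g] s, %d flux column(s), peak %.4g W/m^2\n",
              length(x$times), min(x$times), max(x$times), ncol(x$flux),
              max(x$flux)))
  invisible(x)
}

#' Evaluate forcing at a time instant
#'
#' Linear interpolation of the per-wedge flux and the ambient temperature at
#' time `t`; a single flux column is broadcast to `n_wedges`.
#'
#' @param forcing A [forcing_series()].
#' @param t Time (s); must lie within the series horizon.
#' @param n_wedges Number of wedges to broadcast to.
#' @return List with `flux` (length `n_wedges`) and `T_ambient` (scalar).
#' @export
forcing_at <- function(forcing, t, n_wedges) {
  stopifnot(inherits(forcing, "forcing_series"))
  tms <- forcing$times
  if (t < tms[1] - 1e-9 || t > tms[length(tms)] + 1e-9)
    stop(sprintf("time %g s outside the forcing horizon [%g, %g]",
                 t, tms[1], tms[length(tms)]))
  t <- min(max(t, tms[1]), tms[length(tms)])
  k <- findInterval(t, tms, all.inside = TRUE)
  w <- (t - tms[k]) / (tms[k + 1] - tms[k])
  q <- (1 - w) * forcing$flux[k, ] + w * forcing$flux[k + 1, ]
  if (length(q) == 1L) q <- rep(q, n_wedges)
  if (length(q) != n_wedges)
    stop("flux columns do not match n_wedges")
  Ta <- if (length(forcing$T_ambient) == 1L) forcing$T_ambient else
    (1 - w) * forcing$T_ambient[k] + w * forcing$T_ambient[k + 1]
  list(flux = q, T_ambient = Ta)
}

#' Net radiant exchange with ambient air
#'
#' Black-body exchange at the bark surface,
#' `q = eps * sigma * (T_o^4 - T_s^4)`: positive (gain) when the ambient air
#' is hotter than the surface, negative (net loss) when the surface is hotter.
#' `T_o` is the ambient temperature before the fire or far from it.
#'
#' @param T_s Surface temperature (K).
#' @param T_o Ambient temperature (K).
#' @param emissivity Black-body emissivity (default 1).
#' @return Net flux (W/m^2), sign convention as above.
#' @export
radiant_exchange <- function(T_s, T_o, emissivity = 1) {
  stopifnot(all(T_s > 0), all(T_o > 0))
  emissivity * SIGMA_SB * (T_o^4 - T_s^4)
}

#' Radiant fire flux from a fire air temperature
#'
#' Approximates the fire-driven radiant heat flux from the air temperature
#' directly above the fire, `q = eps * sigma * (T_f^4 - T_o^4)`, clamped to
#' zero (with a message) where `T_f < T_o`.
#'
#' @param T_f Fire air temperature (K).
#' @param T_o Pre-fire ambient temperature (K).
#' @param emissivity Black-body emissivity (default 1).
#' @return Fire heat flux (W/m^2), non-negative.
#' @export
fire_flux_from_temperature <- function(T_f, T_o, emissivity = 1) {
  stopifnot(all(T_o > 0), all(T_f > 0))
  q <- emissivity * SIGMA_SB * (T_f^4 - T_o^4)
  if (any(q < 0)) {
    message("fire_flux_from_temperature: T_f < T_o at ",
            sum(q < 0), " point(s); flux clamped to 0")
    q <- pmax(q, 0)
  }
  q
}

#' Height-interpolated fire forcing
#'
#' Scales a normalized temporal forcing shape to a given height above ground,
#' assuming an exponential decay of the peak heat flux with height:
#' `q(z, t) = q_ground_peak * exp(c * z) * s(t)` where `s(t)` is the
#' normalized series in `[0, 1]` and the ground peak flux is derived from the
#' profile's ground fire temperature via [fire_flux_from_temperature()].
#'
#' @param profile A [height_profile()].
#' @param z Height above ground (m), in `[0, z_top]`.
#' @param normalized_series List with `times` (s) and `shape` in `[0, 1]`.
#' @return A [forcing_series()] for that height.
#' @export
height_interpolated_flux <- function(profile, z, normalized_series) {
  stopifnot(inherits(profile, "height_profile"))
  if (z < 0 || z > profile$z_top)
    stop("z must lie in [0, z_top]")
  s <- normalized_series
  if (any(s$shape < 0) || any(s$shape > 1))
    stop("normalized series must lie in [0, 1]")
  q0 <- fire_flux_from_temperature(profile$T_ground, profile$T_ambient)
  forcing_series(s$times, q0 * exp(profile$c * z) * s$shape,
                 T_ambient = profile$T_ambient)
}

#' Exponential fire-temperature height profile
#'
#' Describes how fire forcing decays with height above ground: fire air
#' temperature at ground level, ambient (pre-fire) temperature, the top height
#' and the exponential shape parameter `c` (1/m) applied to the peak heat
#' flux. The default `c = -0.0155` is taken as given for the low-intensity
#' surface-fire scenario (ground fire temperature 823 K against a 285 K
#' ambient, decaying to ambient by 20 m).
#'
#' @param T_ground Fire air temperature at ground level (K).
#' @param T_ambient Pre-fire ambient temperature (K).
#' @param z_top Top height of the profile (m).
#' @param c Exponential shape parameter (1/m), typically negative.
#' @return An object of class `height_profile`.
#' @export
height_profile <- function(T_ground = 823, T_ambient = 285, z_top = 20,
                           c = -0.0155) {
  stopifnot(z_top > 0, T_ground > 0, T_ambient > 0)
  structure(list(T_ground = T_ground, T_ambient = T_ambient,
                 z_top = z_top, c = c),
            class = "height_profile")
}

#' Circumferential heat-distribution multipliers
#'
#' Per-wedge multipliers implementing the five prescribed circumferential
#' heating patterns, by quadrant (bearings clockwise from north): "front" is
#' the upper-right quadrant, "right" the lower-right, "lee" the lower-left
#' and "left" the upper-left. The shares of the total heat dose are:
#' \describe{
#'   \item{case 1}{front and lee quadrants heated (equal shares), sides zero}
#'   \item{case 2}{uniform around the stem}
#'   \item{case 3}{3/8 front, 1/8 right, 3/8 lee, 1/8 left}
#'   \item{case 4}{8/3 / 8 front, 16/3 / 8 lee, sides zero}
#'   \item{case 5}{2/8 front, 1/8 right, 4/8 lee, 1/8 left}
#' }
#' Multipliers average to exactly 1 over the wedges, so the total delivered
#' energy is identical across cases for the same base series.
#'
#' @param case_id Integer 1..5.
#' @param n_wedges Number of wedges; must be divisible by 8.
#' @return Numeric vector of length `n_wedges`.
#' @export
circumferential_distribution <- function(case_id, n_wedges) {
  n_wedges <- as.integer(n_wedges)
  if (n_wedges %% 8L != 0L) stop("n_wedges must be divisible by 8")
  if (!case_id %in% 1:5) stop("unknown circumferential case: ", case_id)
  # quadrant shares of total dose (front, right, lee, left); multiplier =
  # share / (1/4) since each quadrant covers a quarter of the circumference
  shares <- switch(case_id,
                   `1` = c(1 / 2, 0, 1 / 2, 0),
                   `2` = c(1, 1, 1, 1) / 4,
                   `3` = c(3, 1, 3, 1) / 8,
                   `4` = c(8 / 3, 0, 16 / 3, 0) / 8,
                   `5` = c(2, 1, 4, 1) / 8)
  mult_quadrant <- shares * 4
  rep(mult_quadrant, each = n_wedges / 4L)
}

#' Synthetic laboratory heating pulse
#'
#' Deterministic stand-in for a measured bench-scale heat-flux record: a
#' linear ramp to `peak_flux` over `ramp_s`, a hold of `hold_s`, then an
#' exponential decay with time constant `cool_s / 5` sampled over `cool_s`.
#' Sampled at 1 s (or `dt_sample`) and intended to be interpolated linearly.
#'
#' @param peak_flux Peak heat flux (W/m^2).
#' @param ramp_s Ramp duration (s); 0 gives a step onset.
#' @param hold_s Hold duration (s).
#' @param cool_s Decay window duration (s).
#' @param T_ambient Ambient temperature (K).
#' @param dt_sample Sampling interval (s).
#' @return A [forcing_series()] with a single flux column.
#' @export
synthetic_lab_pulse <- function(peak_flux, ramp_s, hold_s, cool_s,
                                T_ambient = 295, dt_sample = 1) {
  stopifnot(peak_flux >= 0, ramp_s >= 0, hold_s > 0, cool_s > 0)
  total <- ramp_s + hold_s + cool_s
  times <- unique(sort(c(seq(0, total, by = dt_sample), ramp_s,
                         ramp_s + hold_s, total)))
  tau <- cool_s / 5
  q <- ifelse(times <= ramp_s,
              if (ramp_s > 0) peak_flux * times / ramp_s else peak_flux,
              ifelse(times <= ramp_s + hold_s, peak_flux,
                     peak_flux * exp(-(times - ramp_s - hold_s) / tau)))
  forcing_series(times, q, T_ambient)
}

#' Read / write forcing series as CSV
#'
#' CSV layout: header `time_s`, `T_ambient_K`, then either a single `flux`
#' column (broadcast to all wedges) or `flux_1 .. flux_n` per wedge.
#' Reading validates monotone time and non-negative flux, reporting the first
#' offending row.
#'
#' @param path File path.
#' @return `read_forcing_csv`: a [forcing_series()].
#' @export
read_forcing_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("missing column time_s")
  if (!"T_ambient_K" %in% names(df)) stop("missing column T_ambient_K")
  fluxcols <- grep("^flux", names(df), value = TRUE)
  if (length(fluxcols) == 0) stop("missing flux column(s)")
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop("non-monotone time at row ", bad[1] + 1L)
  fx <- as.matrix(df[, fluxcols, drop = FALSE])
  neg <- which(rowSums(fx < 0) > 0)
  if (length(neg))
    stop("negative flux at row ", neg[1])
  Ta <- df$T_ambient_K
  if (length(unique(Ta)) == 1L) Ta <- Ta[1]
  forcing_series(df$time_s, fx, Ta)
}

#' @rdname read_forcing_csv
#' @param series A [forcing_series()] to write.
#' @export
write_forcing_csv <- function(series, path) {
  stopifnot(inherits(series, "forcing_series"))
  nfx <- ncol(series$flux)
  fxnames <- if (nfx == 1) "flux" else paste0("flux_", seq_len(nfx))
  df <- data.frame(time_s = series$times,
                   T_ambient_K = if (length(series$T_ambient) == 1)
                     rep(series$T_ambient, length(series$times)) else
                       series$T_ambient)
  df[fxnames] <- series$flux
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import a fire temperature / heat-flux sheet (CSV export)
#'
#' Reads a long-format CSV with columns `time_s`, `height_m`, and at least one
#' of `T_fire_K` or `flux_W_m2`, and emits one [forcing_series()] per height.
#' Missing fluxes are derived from the fire temperature via
#' [fire_flux_from_temperature()] against `T_ambient`.
#'
#' @param path CSV path (export the spreadsheet sheet to CSV first; no XLSX
#'   reader is assumed).
#' @param T_ambient Pre-fire ambient temperature (K).
#' @return Named list of [forcing_series()], names are heights in m.
#' @export
import_fire_series_csv <- function(path, T_ambient = 285) {
  if (!file.exists(path))
    stop("fire series file not found: ", path,
         " (export the supplementary spreadsheet sheet to CSV with columns ",
         "time_s, height_m, T_fire_K and/or flux_W_m2)")
  df <- utils::read.csv(path)
  need <- c("time_s", "height_m")
  if (!all(need %in% names(df)))
    stop("fire series CSV must contain columns time_s and height_m")
  out <- list()
  for (z in sort(unique(df$height_m))) {
    sub <- df[df$height_m == z, , drop = FALSE]
    sub <- sub[order(sub$time_s), , drop = FALSE]
    q <- if ("flux_W_m2" %in% names(sub) && !all(is.na(sub$flux_W_m2)))
      pmax(sub$flux_W_m2, 0)
    else fire_flux_from_temperature(sub$T_fire_K, T_ambient)
    out[[as.character(z)]] <- forcing_series(sub$time_s, q, T_ambient)
  }
  out
}
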