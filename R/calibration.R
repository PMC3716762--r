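#' Reference observation for species calibration
#'
#' One lab-style stem section: a probe temperature series at a known depth,
#' the observed necrotic depth, and the section metadata needed to simulate
#' it.
#'
#' @param times,T_K Probe temperature series (s, K), time-sorted.
#' @param probe_depth_mm Probe depth below the bark surface (mm).
#' @param necrotic_depth_mm Observed necrotic depth (mm).
#' @param geometry A [stem_geometry()] for the section.
#' @param params A [species_params()] for the section (its `water_loss_rate`
#'   is ignored during fitting).
#' @param forcing The [forcing_series()] that heated the section.
#' @return An object of class `reference_observation`.
#' @export
reference_observation <- function(times, T_K, probe_depth_mm,
                                  necrotic_depth_mm, geometry, params,
                                  forcing) {
  stopifnot(length(times) == length(T_K), all(diff(times) > 0),
            necrotic_depth_mm >= 0, probe_depth_mm >= 0)
  structure(list(times = as.numeric(times), T_K = as.numeric(T_K),
                 probe_depth_mm = probe_depth_mm,
                 necrotic_depth_mm = necrotic_depth_mm,
                 geometry = geometry, params = params, forcing = forcing),
            class = "reference_observation")
}

# Simulated probe series at an observation's probe depth, resampled onto a
# fixed grid (every `resample_s` seconds).
sim_probe_series <- function(run, probe_depth_mm, times_out) {
  grid <- run$grid
  i_probe <- 1L + as.integer(round(probe_depth_mm / 1000 / grid$dr))
  i_probe <- min(max(i_probe, 1L), grid$n_radial)
  # wedge 1 (uniform lab-style forcing makes wedges identical); depths beyond
  # the sub-surface probe map onto the cambium probe, the lab placement
  series <- if (i_probe == 1L) run$probes$surface[, 1]
  else if (i_probe == 2L) run$probes$subsurface[, 1]
  else run$probes$cambium[, 1]
  stats::approx(run$probes$time, series, xout = times_out, rule = 2)$y
}

#' Species-level calibration error
#'
#' Combines, over all sections of a species, a temperature term (mean squared
#' probe error on series resampled every 200 s) and a necrotic-depth term
#' (squared error in mm):
#' `E_s = sum_is [ mean_t (T_sim - T_lab)^2 + (N_sim - N_lab)^2 ]`.
#'
#' @param simulations List of [run_simulation()] results, one per
#'   observation, simulated with probes at the observed depths.
#' @param observations List of [reference_observation()] objects.
#' @param resample_s Temperature resampling interval (s).
#' @return Scalar error (K^2 + mm^2 units, as combined by the objective).
#' @export
species_error <- function(simulations, observations, resample_s = 200) {
  if (length(simulations) != length(observations))
    stop("need one simulation per observation")
  total <- 0
  for (k in seq_along(observations)) {
    obs <- observations[[k]]
    run <- simulations[[k]]
    t_grid <- seq(min(obs$times), max(obs$times), by = resample_s)
    T_lab <- stats::approx(obs$times, obs$T_K, xout = t_grid, rule = 2)$y
    T_sim <- sim_probe_series(run, obs$probe_depth_mm, t_grid)
    N_sim <- 1000 * max(run$injury$necrotic_depth)
    total <- total + mean((T_sim - T_lab)^2) + (N_sim - obs$necrotic_depth_mm)^2
  }
  total
}

#' Fit the species water-loss-rate parameter W_m
#'
#' Deterministic bounded scalar search over `W_m` in `[0.01, 1]`: an
#' exhaustive grid (default step 0.05, plus the 0.01 lower bound) optionally
#' followed by golden-section refinement around the grid minimum. Each
#' candidate re-simulates every observation with the shared species
#' parameters and scores them with [species_error()].
#'
#' @param observations List of [reference_observation()] objects (>= 1).
#' @param config A [run_config()] used for all candidate simulations.
#' @param grid_step Grid search step.
#' @param refine Logical: run golden-section refinement after the grid.
#' @param refine_tol Bracket width at which refinement stops.
#' @param vparams A [viability_params()] object.
#' @return List with `W_m` (argmin), `error` (minimum), `profile`
#'   (data.frame `W_m`, `error` over the search grid).
#' @export
fit_wm <- function(observations, config, grid_step = 0.05, refine = FALSE,
                   refine_tol = 0.01, vparams = viability_params()) {
  if (length(observations) == 0) stop("need at least one observation")
  evaluate <- function(wm) {
    sims <- lapply(observations, function(obs) {
      p <- obs$params
      p$water_loss_rate <- wm
      run_simulation(build_grid(obs$geometry), p, config, obs$forcing,
                     vparams = vparams)
    })
    species_error(sims, observations)
  }
  cand <- sort(unique(c(0.01, seq(grid_step, 1, by = grid_step))))
  errs <- vapply(cand, function(w) {
    e <- tryCatch(evaluate(w), error = function(e) NA_real_)
    e
  }, 0)
  if (all(is.na(errs))) stop("all candidate simulations failed")
  best <- which.min(errs)
  wm_best <- cand[best]; e_best <- errs[best]
  if (refine) {
    lo <- cand[max(best - 1L, 1L)]; hi <- cand[min(best + 1L, length(cand))]
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- evaluate(x1); f2 <- evaluate(x2)
    while (b - a > refine_tol) {
      if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- evaluate(x1)
      } else { a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- evaluate(x2) }
    }
    wm_ref <- (a + b) / 2; e_ref <- evaluate(wm_ref)
    if (e_ref < e_best) { wm_best <- wm_ref; e_best <- e_ref }
  }
  list(W_m = wm_best, error = e_best,
       profile = data.frame(W_m = cand, error = errs))
}
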