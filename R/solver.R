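#' Simulation run configuration
#'
#' Numerical controls for the Crank-Nicolson time integration. The scheme is
#' unconditionally stable, but the explicit-in-step coupling of the
#' desiccation/charring sinks and viability motivates the default `dt` caps
#' (1 s for mm-scale grids, 0.1 s for 0.1 mm grids).
#'
#' @param dt Time step (s).
#' @param total_time Simulation horizon (s).
#' @param theta Time-weighting of the new level: 0.5 = Crank-Nicolson,
#'   1 = implicit Euler. Must lie in `[0.5, 1]`.
#' @param initial_temperature Uniform initial stem temperature (K).
#' @param output_every Probe recording cadence (s); defaults to `10 * dt`.
#' @param sinks Enable desiccation/charring energy sinks and water tracking.
#' @param viability Enable tissue-viability integration.
#' @param picard Number of Picard iterations re-evaluating properties at the
#'   new time level (0 = linearized scheme, properties at the old level).
#' @param boundary `"flux"` (prescribed fire flux + net radiant exchange) or
#'   `"dirichlet"` (pinned surface temperature; solver-verification mode).
#' @param dirichlet_surface_T,dirichlet_inner_T Pinned temperatures (K) for
#'   the surface node ring and (optionally) the innermost ring, used only
#'   with `boundary = "dirichlet"`.
#' @param latent_heat Latent heat of vaporization (J/kg).
#' @param heat_of_pyrolysis Endothermic charring heat (J/kg).
#' @param char_conductivity,char_heat_capacity Thermal properties of charred
#'   nodes (W/m/K; J/kg/K).
#' @param override_properties Optional list `list(k =, rho =, cp =)` of
#'   constant properties (SI units; `cp` in J/kg/K) replacing the empirical
#'   wood/bark relations — used by the analytic solver benchmarks.
#' @return An object of class `run_config`.
#' @export
run_config <- function(dt = 1, total_time, theta = 0.5,
                       initial_temperature = 295,
                       output_every = 10 * dt,
                       sinks = TRUE, viability = TRUE, picard = 0L,
                       boundary = c("flux", "dirichlet"),
                       dirichlet_surface_T = NA_real_,
                       dirichlet_inner_T = NA_real_,
                       latent_heat = LATENT_HEAT_VAP,
                       heat_of_pyrolysis = HEAT_OF_PYROLYSIS,
                       char_conductivity = 0.1,
                       char_heat_capacity = 1000,
                       override_properties = NULL) {
  boundary <- match.arg(boundary)
  stopifnot(dt > 0, total_time >= 0, theta >= 0.5, theta <= 1,
            initial_temperature > 0)
  if (boundary == "dirichlet" && !is.finite(dirichlet_surface_T))
    stop("dirichlet boundary requires dirichlet_surface_T")
  structure(list(dt = dt, total_time = total_time, theta = theta,
                 initial_temperature = initial_temperature,
                 output_every = output_every,
                 sinks = sinks, viability = viability,
                 picard = as.integer(picard),
                 boundary = boundary,
                 dirichlet_surface_T = dirichlet_surface_T,
                 dirichlet_inner_T = dirichlet_inner_T,
                 latent_heat = latent_heat,
                 heat_of_pyrolysis = heat_of_pyrolysis,
                 char_conductivity = char_conductivity,
                 char_heat_capacity = char_heat_capacity,
                 override_properties = override_properties),
            class = "run_config")
}

#' Initial simulation state
#'
#' Uniform initial temperature; per-node water mass from the radial wood
#' moisture profile (bark layers take the species inner/outer bark moisture
#' directly); no char; full viability.
#'
#' @param grid A [build_grid()] object.
#' @param params A [species_params()] object.
#' @param config A [run_config()] object.
#' @return An object of class `stem_state` with matrices `T` (K), `M`
#'   (dry-basis moisture), `water` (kg), `logN` (log viability), a
#'   [char_state()], per-node dry density/mass, and `time` (s).
#' @export
initial_state <- function(grid, params, config) {
  stopifnot(inherits(grid, "polar_grid"), inherits(params, "species_params"))
  n <- grid$n_radial; nw <- grid$n_wedges
  zone <- grid$zone
  rho_dry <- ifelse(zone == "wood", params$dry_wood_density,
                    params$dry_bark_density)
  r_d <- grid$radius - (grid$n_outer_bark + grid$n_inner_bark) * grid$dr
  if (r_d <= 0) r_d <- grid$node_radii[cambium_index(grid)]
  M0 <- numeric(n)
  wood <- zone == "wood"
  M0[wood] <- initial_moisture_profile(pmin(grid$node_radii[wood], r_d),
                                       r_d, params)
  M0[zone == "inner_bark"] <- params$inner_bark_moisture
  M0[zone == "outer_bark"] <- params$outer_bark_moisture

  rho_dry_m <- matrix(rho_dry, n, nw)
  dry_mass <- rho_dry_m * grid$cv_volumes
  M <- matrix(M0, n, nw)
  structure(list(time = 0,
                 T = matrix(config$initial_temperature, n, nw),
                 M = M,
                 water = M * dry_mass,
                 logN = matrix(0, n, nw),
                 char = char_state(n, nw, (1 - CF_CHAR) * dry_mass),
                 rho_dry = rho_dry_m,
                 dry_mass = dry_mass),
            class = "stem_state")
}

# Node-wise thermophysical properties at the current state.
# Returns k (W/m/K), cp (J/kg/K) and moist density rho (kg/m^3) matrices.
node_properties <- function(grid, params, config, state) {
  ov <- config$override_properties
  n <- grid$n_radial; nw <- grid$n_wedges
  if (!is.null(ov)) {
    return(list(k = matrix(ov$k, n, nw),
                cp = matrix(ov$cp, n, nw),
                rho = matrix(ov$rho, n, nw)))
  }
  zone <- matrix(as.integer(grid$zone), n, nw)  # 1 ob, 2 ib, 3 wood
  Tm <- state$T; M <- state$M
  if (any(!is.finite(Tm)) || any(!is.finite(M)) || any(Tm <= 0)) {
    bad <- which(!is.finite(Tm) | !is.finite(M) | Tm <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite state at node (i=%d, j=%d)", bad[1], bad[2]))
  }
  rho <- state$rho_dry * (1 + M)
  k <- matrix(0, n, nw); cp <- matrix(0, n, nw)
  wood <- zone == 3L
  if (any(wood)) {
    # G_M is the standard specific gravity: node dry density over water density
    k[wood] <- wood_conductivity(state$rho_dry[wood], 1000, M[wood])
    cp[wood] <- 1000 * wood_heat_capacity(Tm[wood], M[wood])
  }
  bark <- !wood
  if (any(bark)) {
    k[bark] <- bark_conductivity(state$rho_dry[bark], M[bark], Tm[bark])
    cp[bark] <- 1000 * bark_heat_capacity(Tm[bark], M[bark])
  }
  ch <- state$char$charred
  if (any(ch)) {
    k[ch] <- config$char_conductivity
    cp[ch] <- config$char_heat_capacity
    rho[ch] <- CF_CHAR * state$rho_dry[ch]
  }
  if (any(!is.finite(k)) || any(!is.finite(cp)) || any(k <= 0) || any(cp <= 0)) {
    bad <- which(!is.finite(k) | !is.finite(cp) | k <= 0 | cp <= 0,
                 arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite/non-positive property at node (i=%d, j=%d)",
                 bad[1], bad[2]))
  }
  list(k = k, cp = cp, rho = rho)
}

# Assemble the theta-weighted finite-volume system for one conduction step.
# Returns list(A, b). Unknown ordering: p = (j-1)*n_radial + i.
assemble_system <- function(grid, props, state, config, q_fire, T_ambient) {
  n <- grid$n_radial; nw <- grid$n_wedges; N <- n * nw
  dt <- config$dt; th <- config$theta
  Fr <- grid$face_radii; dr <- grid$dr; dth <- grid$dtheta
  k <- props$k
  C <- props$rho * props$cp * grid$cv_volumes / dt   # J/K per step

  # radial conductance between node i and i+1: harmonic-mean conductivity
  # (flux continuity across bark/wood/char interfaces) with the exact
  # cylindrical-annulus geometry factor dtheta / ln(r_i / r_{i+1}), which
  # reproduces the steady logarithmic profile exactly
  kf_r <- 2 * k[-n, , drop = FALSE] * k[-1, , drop = FALSE] /
    (k[-n, , drop = FALSE] + k[-1, , drop = FALSE])
  rr <- grid$node_radii
  G_r <- kf_r * dth / log(rr[1:(n - 1)] / rr[2:n])   # (n-1) x nw, W/K

  # circumferential conductance between wedge j and j+1 (wrap)
  jn <- c(2:nw, 1L)
  kf_t <- 2 * k * k[, jn, drop = FALSE] / (k + k[, jn, drop = FALSE])
  h_i <- Fr[1:n] - Fr[2:(n + 1)]                     # radial extent of cell
  G_t <- kf_t * h_i / (grid$node_radii * dth)        # n x nw, W/K

  idx <- matrix(seq_len(N), n, nw)
  # explicit part of the conduction operator applied to T_old
  Told <- state$T
  L_old <- matrix(0, n, nw)
  d_r <- G_r * (Told[-1, , drop = FALSE] - Told[-n, , drop = FALSE])
  L_old[-n, ] <- L_old[-n, ] + d_r
  L_old[-1, ] <- L_old[-1, ] - d_r
  d_t <- G_t * (Told[, jn, drop = FALSE] - Told)
  L_old <- L_old + d_t
  L_old <- L_old - d_t[, c(nw, 1:(nw - 1)), drop = FALSE]

  diag_v <- as.vector(C) +
    th * (as.vector(rbind(G_r, 0)) + as.vector(rbind(0, G_r)) +
            as.vector(G_t) + as.vector(G_t[, c(nw, 1:(nw - 1)), drop = FALSE]))

  ii <- c(seq_len(N),
          as.vector(idx[-n, , drop = FALSE]), as.vector(idx[-1, , drop = FALSE]),
          as.vector(idx), as.vector(idx[, jn, drop = FALSE]))
  jj <- c(seq_len(N),
          as.vector(idx[-1, , drop = FALSE]), as.vector(idx[-n, , drop = FALSE]),
          as.vector(idx[, jn, drop = FALSE]), as.vector(idx))
  xx <- c(diag_v,
          rep(-th * as.vector(G_r), 2),
          rep(-th * as.vector(G_t), 2))

  b <- as.vector(C * Told + (1 - th) * L_old)

  surface <- idx[1, ]
  A_s <- grid$radius * dth   # outer face area per unit height, per wedge
  rad_info <- NULL
  if (config$boundary == "flux") {
    Ts <- Told[1, ]
    q_rad0 <- SIGMA_SB * (T_ambient^4 - Ts^4)
    beta <- 4 * SIGMA_SB * Ts^3        # implicit radiant linearization
    b[surface] <- b[surface] + A_s * (q_fire + q_rad0 + beta * Ts)
    ii <- c(ii, surface); jj <- c(jj, surface); xx <- c(xx, A_s * beta)
    rad_info <- list(q_rad0 = q_rad0, beta = beta, A_s = A_s)
  }

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))

  if (config$boundary == "dirichlet") {
    pin <- surface
    pin_T <- rep(config$dirichlet_surface_T, nw)
    if (is.finite(config$dirichlet_inner_T)) {
      pin <- c(pin, idx[n, ])
      pin_T <- c(pin_T, rep(config$dirichlet_inner_T, nw))
    }
    A[pin, ] <- 0
    A[cbind(pin, pin)] <- 1
    b[pin] <- pin_T
  }
  list(A = A, b = b, rad = rad_info, surface = surface, A_s = A_s)
}

# One full time step: implicit conduction, then water loss + desiccation,
# charring, viability. Returns list(state, audit) with per-step energies (J).
step_state <- function(state, grid, params, config, forcing, vparams) {
  dt <- config$dt
  t0 <- state$time
  props <- node_properties(grid, params, config, state)

  q_fire <- rep(0, grid$n_wedges); Ta <- config$initial_temperature
  if (config$boundary == "flux") {
    f0 <- forcing_at(forcing, t0, grid$n_wedges)
    f1 <- forcing_at(forcing, t0 + dt, grid$n_wedges)
    q_fire <- 0.5 * (f0$flux + f1$flux)   # midpoint value for the CN step
    Ta <- 0.5 * (f0$T_ambient + f1$T_ambient)
  }

  sys <- assemble_system(grid, props, state, config, q_fire, Ta)
  Tnew_v <- as.numeric(Matrix::solve(sys$A, sys$b))
  if (config$picard > 0L) {
    st2 <- state
    for (it in seq_len(config$picard)) {
      st2$T <- matrix(Tnew_v, grid$n_radial, grid$n_wedges)
      props2 <- node_properties(grid, params, config, st2)
      sys <- assemble_system(grid, props2, state, config, q_fire, Ta)
      Tnew_v <- as.numeric(Matrix::solve(sys$A, sys$b))
    }
  }
  resid <- max(abs(sys$A %*% Tnew_v - sys$b)) / max(abs(sys$b), 1)
  if (!is.finite(resid) || resid > 1e-8)
    stop(sprintf("linear solve failed: relative residual %.3g", resid))
  Tnew <- matrix(Tnew_v, grid$n_radial, grid$n_wedges)

  CpV <- props$rho * props$cp * grid$cv_volumes     # J/K
  E_stored <- sum(CpV * (Tnew - state$T))
  E_in <- 0
  if (config$boundary == "flux") {
    q_rad_applied <- sys$rad$q_rad0 - sys$rad$beta * (Tnew[1, ] - state$T[1, ])
    E_in <- dt * sum(sys$A_s * (q_fire + q_rad_applied))
  }

  E_sink <- 0
  if (config$sinks) {
    rho_moist <- state$rho_dry * (1 + state$M)
    rate <- water_loss_rate(state$M, Tnew, rho_moist, grid$cv_volumes,
                            params$water_loss_rate)
    rate <- pmin(rate, state$water / dt)       # water mass cannot go negative
    dm <- rate * dt
    state$water <- state$water - dm
    state$M <- state$water / state$dry_mass
    E_des <- config$latent_heat * sum(dm)
    Tnew <- Tnew - config$latent_heat * dm / CpV
    E_sink <- E_des

    if (params$pyrolysis_multiplier > 0) {
      rates <- charring_rate(state$rho_dry * (1 + state$M), Tnew,
                             params$pyrolysis_multiplier,
                             rho_dry = state$rho_dry, V = grid$cv_volumes)
      rates[state$M >= 0.01] <- 0   # charring only once essentially desiccated
      cand <- pmin(state$char$front + 1L, grid$n_radial)
      adv <- advance_char_front(state$char, rates, dt)
      state$char <- adv$state
      if (any(adv$mass_charred > 0)) {
        for (j in which(adv$mass_charred > 0)) {
          Tnew[cand[j], j] <- Tnew[cand[j], j] -
            config$heat_of_pyrolysis * adv$mass_charred[j] / CpV[cand[j], j]
        }
        E_sink <- E_sink + config$heat_of_pyrolysis * sum(adv$mass_charred)
      }
    }
  }

  state$T <- Tnew
  if (config$viability)
    state$logN <- state$logN - viability_rate(Tnew, vparams) * dt
  state$time <- t0 + dt
  list(state = state,
       audit = c(E_in = E_in, E_sink = E_sink, E_stored = E_stored - E_sink))
}

#' Run a stem-heating simulation
#'
#' Time-integrates the 2-D cylindrical heat-conduction equation on the polar
#' grid with the configured boundary condition, energy sinks and tissue
#' viability, recording probe temperatures (surface, just beneath the
#' surface, and at the cambium) at the output cadence and deriving the
#' necrotic depth around the circumference at the end of the run (which
#' should include the cool-down).
#'
#' @param grid A [build_grid()] object.
#' @param params A [species_params()] object.
#' @param config A [run_config()] object.
#' @param forcing A [forcing_series()] covering `[0, total_time]` (not needed
#'   for Dirichlet verification runs).
#' @param vparams A [viability_params()] object.
#' @return An object of class `stem_run` with elements `state` (final
#'   [initial_state()]-shaped state), `probes` (list of `time`, and
#'   `surface` / `subsurface` / `cambium` matrices, time x wedge), `injury`
#'   (an `injury_result`, see [necrotic_depth()]), and `energy` (audit:
#'   `E_in`, `E_sink`, `E_stored`, `residual`, `residual_frac`).
#' @export
run_simulation <- function(grid, params, config, forcing = NULL,
                           vparams = viability_params()) {
  stopifnot(inherits(config, "run_config"))
  if (config$boundary == "flux" && is.null(forcing))
    stop("flux boundary requires a forcing_series")
  state <- initial_state(grid, params, config)
  n_steps <- as.integer(round(config$total_time / config$dt))
  sub_i <- min(2L, grid$n_radial)
  cam_i <- cambium_index(grid)
  every <- max(1L, as.integer(round(config$output_every / config$dt)))
  out_steps <- unique(c(0L, seq_len(n_steps)[seq_len(n_steps) %% every == 0L],
                        n_steps))
  n_out <- length(out_steps)
  probes <- list(time = numeric(n_out),
                 surface = matrix(NA_real_, n_out, grid$n_wedges),
                 subsurface = matrix(NA_real_, n_out, grid$n_wedges),
                 cambium = matrix(NA_real_, n_out, grid$n_wedges))
  record <- function(kk, st) {
    probes$time[kk] <<- st$time
    probes$surface[kk, ] <<- st$T[1, ]
    probes$subsurface[kk, ] <<- st$T[sub_i, ]
    probes$cambium[kk, ] <<- st$T[cam_i, ]
  }
  record(1L, state)
  audit <- c(E_in = 0, E_sink = 0, E_stored = 0)
  deepest <- integer(grid$n_wedges)
  t_deepest <- rep(NA_real_, grid$n_wedges)
  kk <- 1L
  log_thr <- log(vparams$threshold)
  for (s in seq_len(n_steps)) {
    res <- step_state(state, grid, params, config, forcing, vparams)
    state <- res$state
    audit <- audit + res$audit
    if (s %in% out_steps) {
      kk <- kk + 1L
      record(kk, state)
      if (config$viability) {
        for (j in seq_len(grid$n_wedges)) {
          dead <- which(state$logN[, j] < log_thr)
          d <- if (length(dead)) max(dead) else 0L
          if (d > deepest[j]) { deepest[j] <- d; t_deepest[j] <- state$time }
        }
      }
    }
  }
  # E_stored is the net stored-energy change (conduction minus sinks), so the
  # discrete budget to close is E_stored = E_in - E_sink
  residual <- audit[["E_stored"]] - (audit[["E_in"]] - audit[["E_sink"]])
  scale <- max(abs(audit[["E_in"]]), abs(audit[["E_stored"]]), 1e-12)
  injury <- necrotic_depth(state, grid, vparams)
  injury$time_to_max_depth <- t_deepest
  structure(list(state = state, probes = probes, injury = injury,
                 energy = list(E_in = audit[["E_in"]],
                               E_sink = audit[["E_sink"]],
                               E_stored = audit[["E_stored"]],
                               residual = residual,
                               residual_frac = residual / scale),
                 grid = grid, config = config),
            class = "stem_run")
}

#' @export
print.stem_run <- function(x, ...) {
  cat(sprintf("stem_run: t = %.4g s, %d x %d nodes\n", x$state$time,
              x$grid$n_radial, x$grid$n_wedges))
  cat(sprintf("  max T %.2f K; energy residual %.3g%%\n",
              max(x$state$T), 100 * x$energy$residual_frac))
  cat(sprintf("  necrotic depth: max %.2f mm; live area %.1f%%\n",
              1000 * max(x$injury$necrotic_depth),
              100 * x$injury$live_area_fraction))
  invisible(x)
}

#' Export a run trajectory and injury summary as CSV
#'
#' Writes the probe series (`time_s`, wedge, probe, `T_K`) and the per-wedge
#' injury summary (wedge, bearing, necrotic depth, live flag counts).
#'
#' @param run A [run_simulation()] result.
#' @param probe_path,injury_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_run_csv <- function(run, probe_path, injury_path) {
  stopifnot(inherits(run, "stem_run"))
  nw <- run$grid$n_wedges
  nt <- length(run$probes$time)
  long <- do.call(rbind, lapply(c("surface", "subsurface", "cambium"),
    function(p) data.frame(time_s = rep(run$probes$time, nw),
                           wedge = rep(seq_len(nw), each = nt),
                           probe = p,
                           T_K = as.vector(run$probes[[p]]))))
  utils::write.csv(long, probe_path, row.names = FALSE)
  inj <- data.frame(wedge = seq_len(nw),
                    bearing_deg = run$grid$wedge_angles * 180 / pi,
                    necrotic_depth_mm = 1000 * run$injury$necrotic_depth,
                    time_to_max_depth_s = run$injury$time_to_max_depth)
  utils::write.csv(inj, injury_path, row.names = FALSE)
  invisible(c(probe_path, injury_path))
}
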