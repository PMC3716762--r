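# Independent explicit-Euler (FTCS) conduction solver used as the oracle for
# the Crank-Nicolson scheme. Deliberately written with the naive
# midpoint-face geometry factor (F * dtheta / dr) and its own flux loop so it
# shares no discretization code with the package solver; it reuses only the
# scalar property functions, which are tested separately.
explicit_oracle <- function(grid, params, T0, forcing, total_time, dt) {
  n <- grid$n_radial; nw <- grid$n_wedges
  Tm <- matrix(T0, n, nw)
  zone <- as.integer(grid$zone)
  rho_dry <- ifelse(zone == 3L, params$dry_wood_density,
                    params$dry_bark_density)
  r_d <- grid$radius - (grid$n_outer_bark + grid$n_inner_bark) * grid$dr
  M0 <- numeric(n)
  wood <- zone == 3L
  M0[wood] <- initial_moisture_profile(pmin(grid$node_radii[wood], r_d),
                                       r_d, params)
  M0[zone == 2L] <- params$inner_bark_moisture
  M0[zone == 1L] <- params$outer_bark_moisture
  M <- matrix(M0, n, nw)
  V <- grid$cv_volumes
  Fr <- grid$face_radii; dth <- grid$dtheta; dr <- grid$dr
  rr <- grid$node_radii
  A_s <- grid$radius * dth
  jn <- c(2:nw, 1); jp <- c(nw, 1:(nw - 1))
  for (s in seq_len(round(total_time / dt))) {
    t <- (s - 1) * dt
    kk <- matrix(0, n, nw); cp <- matrix(0, n, nw)
    kk[wood, ] <- wood_conductivity(rho_dry[wood], 1000, M[wood, ])
    cp[wood, ] <- 1000 * wood_heat_capacity(Tm[wood, ], M[wood, ])
    kk[!wood, ] <- bark_conductivity(rho_dry[!wood], M[!wood, ], Tm[!wood, ])
    cp[!wood, ] <- 1000 * bark_heat_capacity(Tm[!wood, ], M[!wood, ])
    C <- rho_dry * (1 + M) * cp * V
    kf <- 2 * kk[-n, ] * kk[-1, ] / (kk[-n, ] + kk[-1, ])
    q_r <- kf * (Fr[2:n] * dth) / dr * (Tm[-1, ] - Tm[-n, ])
    kt <- 2 * kk * kk[, jn] / (kk + kk[, jn])
    h <- Fr[1:n] - Fr[2:(n + 1)]
    q_t <- kt * h / (rr * dth) * (Tm[, jn] - Tm)
    dT <- matrix(0, n, nw)
    dT[-n, ] <- dT[-n, ] + q_r
    dT[-1, ] <- dT[-1, ] - q_r
    dT <- dT + q_t - q_t[, jp]
    fr <- forcing_at(forcing, t, nw)
    dT[1, ] <- dT[1, ] + A_s * (fr$flux + radiant_exchange(Tm[1, ], fr$T_ambient))
    Tm <- Tm + dt * dT / C
  }
  Tm
}

# first 20 positive roots of the Bessel function J0, for the transient
# constant-property cylinder benchmark
J0_ROOTS <- c(2.404825557695773, 5.520078110286311, 8.653727912911012,
              11.791534439014282, 14.930917708487786, 18.071063967910923,
              21.21163662987926, 24.352471530749302, 27.493479132040255,
              30.634606468431975, 33.77582021357357, 36.917098353664045,
              40.05842576462824, 43.19979171317673, 46.341188371661815,
              49.482609897397815, 52.624051841115, 55.76551075501998,
              58.90698392608094, 62.048469190227166)

# series solution for a cylinder initially at T0 with surface stepped to Ts
bessel_step_profile <- function(r, R, Fo, T0, Ts) {
  frac <- vapply(r, function(ri)
    sum(2 / (J0_ROOTS * besselJ(J0_ROOTS, 1)) *
          besselJ(J0_ROOTS * ri / R, 0) * exp(-J0_ROOTS^2 * Fo)), 0)
  Ts + (T0 - Ts) * frac
}
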