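#' Solver configuration
#'
#' Time-integration controls for the coupled conservation laws. The outer
#' loop advances mechanics, energy and liquid transport explicitly with an
#' adaptive step bounded by the conduction stability limit and a volumetric
#' strain cap; fast gas physics (Darcy flow, gas diffusion, venting,
#' phase change) is subcycled inside each outer step, with the stiff
#' phase-change source handled by an exponential relaxation integrator
#' (unconditionally stable at the closed-pore rate of 10 1/s).
#'
#' @param dt_init initial outer step, s.
#' @param dt_max largest outer step, s.
#' @param rtol relative tolerance used for the per-step change guard.
#' @param max_subcycles cap on gas subcycles per outer step.
#' @param flux_limiter advective scheme; `"upwind"` (donor-cell) is the
#'   monotone choice for sharp evaporation/condensation fronts.
#' @param gas_mode gas momentum closure, `"darcy"` (dominant-balance
#'   reduction) or `"brinkman"` (retains vertical viscous shear).
#' @param t_end end time, s.
#' @param cadence diagnostics output interval, s.
#' @param convention phase-change sign convention (see
#'   [phase_change_source()]).
#' @return object of class `solver_config`.
#' @export
solver_config <- function(dt_init = 0.1, dt_max = 0.5, rtol = 1e-3,
                          max_subcycles = 200,
                          flux_limiter = "upwind",
                          gas_mode = c("darcy", "brinkman"),
                          t_end = 1800, cadence = 10,
                          convention = c("budget", "printed")) {
  gas_mode <- match.arg(gas_mode)
  convention <- match.arg(convention)
  flux_limiter <- match.arg(flux_limiter, "upwind")
  if (dt_init <= 0 || dt_max <= 0 || t_end <= 0 || rtol <= 0)
    stop("time steps, end time and tolerance must be positive")
  structure(list(dt_init = dt_init, dt_max = dt_max, rtol = rtol,
                 max_subcycles = max_subcycles, flux_limiter = flux_limiter,
                 gas_mode = gas_mode, t_end = t_end, cadence = cadence,
                 convention = convention),
            class = "solver_config")
}

# harmonic mean of two face-adjacent coefficient fields (0 if either is 0)
.hmean <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)

# divergence helpers: face arrays -> per-cell net gain.
# Fz is nr x (nz-1), positive = flow from layer k to k+1.
.gain_z <- function(Fz, nr, nz) {
  z <- matrix(0, nr, 1)
  cbind(z, Fz) - cbind(Fz, z)
}
# Fr is (nr-1) x nz, positive = flow from column i to i+1.
.gain_r <- function(Fr, nr, nz) {
  z <- matrix(0, 1, nz)
  rbind(z, Fr) - rbind(Fr, z)
}

#' Gas velocity from the pore momentum closure
#'
#' Darcy mode: `u = -(kappa_g/mu_g) grad P_g` at interior faces (the
#' dominant-balance reduction of the pore gas momentum equation at
#' permeabilities ~1e-11 m^2 and millimetre-per-second velocities).
#' Brinkman mode additionally retains the vertical viscous shear term,
#' solved per column as a steady tridiagonal problem; when the matrix is
#' fully closed (`kappa = 0` everywhere) it falls back to the stagnant
#' solution with a warning. Velocity is identically zero wherever pores
#' are closed (`alpha = 0` makes `kappa = 0`).
#'
#' @param state a `field_state`.
#' @param grid the matching `bake_grid`.
#' @param params a [material_params()].
#' @param mode `"darcy"` or `"brinkman"`.
#' @param derived optional precomputed [derived_fields()].
#' @return list with face arrays `u_z` (`nr x (nz-1)`, positive upward) and
#'   `u_r` (`(nr-1) x nz`, positive outward), m/s (superficial).
#' @export
gas_velocity <- function(state, grid, params = material_params(),
                         mode = c("darcy", "brinkman"), derived = NULL) {
  mode <- match.arg(mode)
  d <- if (is.null(derived)) derived_fields(state, grid, params) else derived
  nr <- grid$nr; nz <- grid$nz
  dzf <- vertical_spacing(grid)
  kz <- .hmean(d$kappa[, -nz, drop = FALSE], d$kappa[, -1, drop = FALSE])
  u_z <- -kz / params$mu_g * (d$P_g[, -1, drop = FALSE] - d$P_g[, -nz, drop = FALSE]) / dzf
  u_r <- if (nr > 1L) {
    kr <- .hmean(d$kappa[-nr, , drop = FALSE], d$kappa[-1, , drop = FALSE])
    -kr / params$mu_g * (d$P_g[-1, , drop = FALSE] - d$P_g[-nr, , drop = FALSE]) / grid$dr
  } else matrix(0, 0, nz)
  if (mode == "brinkman") {
    if (all(d$kappa == 0)) {
      warning("fully closed matrix: Brinkman solve singular, using u = 0")
      u_z[] <- 0
    } else {
      # steady mu_g u'' - (mu_g/kappa) u = dP/dz per column, u = 0 at ends
      for (i in seq_len(nr)) {
        kf <- kz[i, ]
        if (all(kf == 0)) { u_z[i, ] <- 0; next }
        m <- nz - 1L
        rhs <- (d$P_g[i, -1] - d$P_g[i, -nz]) / dzf[i, ]
        dz2 <- dzf[i, ]^2
        main <- 2 / dz2 + 1 / pmax(kf, 1e-16)
        A <- diag(main, m)
        if (m > 1) {
          idx <- seq_len(m - 1)
          A[cbind(idx, idx + 1)] <- -1 / dz2[idx]
          A[cbind(idx + 1, idx)] <- -1 / dz2[idx + 1]
        }
        u_z[i, ] <- solve(A, -rhs / params$mu_g)
        u_z[i, kf == 0] <- 0
      }
    }
  }
  list(u_z = u_z, u_r = u_r)
}

# Exponential flux limiter: scales a donor-draining rate so that over a
# substep the donor loses at most the exponential-relaxation amount (exact
# for a single-cell drain, monotone and unconditionally stable otherwise).
.expfac <- function(x) ifelse(x > 1e-8, (1 - exp(-pmin(x, 50))) / x, 1)

# Vectorized Thomas solve for independent tridiagonal systems per grid row.
# lower/diag/upper are nr x nz (lower[,1] and upper[,nz] unused); rhs nr x nz.
.thomas <- function(lower, diag, upper, rhs) {
  nz <- ncol(diag)
  cp <- diag; rp <- rhs
  for (k in 2:nz) {
    m <- lower[, k] / cp[, k - 1]
    cp[, k] <- cp[, k] - m * upper[, k - 1]
    rp[, k] <- rp[, k] - m * rp[, k - 1]
  }
  x <- rp
  x[, nz] <- rp[, nz] / cp[, nz]
  for (k in (nz - 1):1) x[, k] <- (rp[, k] - upper[, k] * x[, k + 1]) / cp[, k]
  x
}

# One gas subcycle. The vertical Darcy system is solved implicitly in
# pressure (backward Euler, tridiagonal per column) so that venting and
# pressure equilibration propagate through a whole column within a substep;
# species masses then move along the implicit fluxes with donor-cell
# composition. Radial Darcy flow, gas diffusion and boundary exchange are
# explicit with exponential limiters; positivity is enforced by scaling a
# cell's total outgoing fluxes to at most 95% of its content. Phase change
# is a linearized saturation adjustment (latent heat coupled to T), applied
# at the nonequilibrium rate k_MPC.
.gas_substep <- function(env, grid, params, oven, control, dt_g) {
  nr <- grid$nr; nz <- grid$nz; top <- nz
  V_g <- env$V_g
  RT <- params$R * env$T
  n_v <- env$M_v / params$M_h2o
  n_c <- env$M_c / params$M_co2
  n_a <- env$M_a / params$M_air
  n_tot <- n_v + n_c + n_a
  P_g <- n_tot * RT / V_g

  # --- stage A: implicit vertical pressure solve (backward Euler,
  # tridiagonal per column) + explicit radial Darcy + top venting ----------
  a <- V_g / (RT * dt_g)
  Cface <- 0.5 * (P_g[, -1, drop = FALSE] / RT[, -1, drop = FALSE] +
                    P_g[, -nz, drop = FALSE] / RT[, -nz, drop = FALSE])
  Gz <- env$kz_Az / params$mu_g / env$dzf * Cface
  Gv <- env$kappa[, top] / params$mu_g * grid$A_z / (grid$h[, top] / 2) *
    P_g[, top] / RT[, top]
  lower <- cbind(0, -Gz)
  upper <- cbind(-Gz, 0)
  diag <- a + cbind(Gz, 0) + cbind(0, Gz)
  diag[, top] <- diag[, top] + Gv
  rhs <- a * P_g
  rhs[, top] <- rhs[, top] + Gv * params$P_amb
  Pn <- .thomas(lower, diag, upper, rhs)
  Fmol <- Gz * (Pn[, -nz, drop = FALSE] - Pn[, -1, drop = FALSE]) * dt_g
  vent_mol <- Gv * (Pn[, top] - params$P_amb) * dt_g

  up <- Fmol > 0
  don <- function(X) ifelse(up, X[, -nz, drop = FALSE], X[, -1, drop = FALSE])
  xv <- n_v / n_tot; xc <- n_c / n_tot; xa <- n_a / n_tot
  Fz_v <- Fmol * don(xv) * params$M_h2o
  Fz_c <- Fmol * don(xc) * params$M_co2
  Fz_a <- Fmol * don(xa) * params$M_air

  if (nr > 1L) {
    dPr <- P_g[-1, , drop = FALSE] - P_g[-nr, , drop = FALSE]
    Qr <- -env$kr_Ar / params$mu_g * dPr / grid$dr
    upr <- Qr > 0
    Vg_dr <- ifelse(upr, V_g[-nr, , drop = FALSE], V_g[-1, , drop = FALSE])
    Qr <- Qr * .expfac(abs(Qr) / Vg_dr * dt_g)
    v_eqr <- abs(dPr) / (P_g[-1, , drop = FALSE] / V_g[-1, , drop = FALSE] +
                           P_g[-nr, , drop = FALSE] / V_g[-nr, , drop = FALSE])
    Qr <- sign(Qr) * pmin(abs(Qr), v_eqr / dt_g)
    rho_v <- env$M_v / V_g; rho_c <- env$M_c / V_g; rho_a <- env$M_a / V_g
    donr <- function(X) ifelse(upr, X[-nr, , drop = FALSE], X[-1, , drop = FALSE])
    Fr_v <- Qr * donr(rho_v) * dt_g
    Fr_c <- Qr * donr(rho_c) * dt_g
    Fr_a <- Qr * donr(rho_a) * dt_g
  } else {
    Fr_v <- Fr_c <- Fr_a <- matrix(0, 0, nz)
  }

  vout <- pmax(vent_mol, 0)
  vent_v <- vout * xv[, top] * params$M_h2o
  vent_c <- vout * xc[, top] * params$M_co2
  vent_a <- vout * xa[, top] * params$M_air

  # positivity: scale every cell's outgoing fluxes to <= 95% of its content
  scale_sp <- function(M, Fz, Fr, vent) {
    out <- cbind(pmax(Fz, 0), 0) + cbind(0, pmax(-Fz, 0))
    if (nr > 1L) out <- out + rbind(pmax(Fr, 0), 0) + rbind(0, pmax(-Fr, 0))
    if (!is.null(vent)) out[, top] <- out[, top] + vent
    s <- pmin(0.95 * M / pmax(out, 1e-300), 1)   # first arg keeps matrix dims
    fz <- Fz * ifelse(Fz > 0, s[, -nz, drop = FALSE], s[, -1, drop = FALSE])
    fr <- if (nr > 1L) Fr * ifelse(Fr > 0, s[-nr, , drop = FALSE], s[-1, , drop = FALSE]) else Fr
    list(Fz = fz, Fr = fr, vent = if (is.null(vent)) NULL else vent * s[, top])
  }
  gains <- function(x) {
    g <- .gain_z(x$Fz, nr, nz)
    if (nr > 1L) g <- g + .gain_r(x$Fr, nr, nz)
    if (!is.null(x$vent)) g[, top] <- g[, top] - x$vent
    g
  }
  # receiver warms by m cp (T_donor - T_receiver); donors are unaffected
  adv_heat <- function(Fz, Fr) {
    upm <- Fz > 0
    donT <- ifelse(upm, env$T[, -nz, drop = FALSE], env$T[, -1, drop = FALSE])
    q <- .gain_z(Fz * params$cp_g * donT, nr, nz) -
      .gain_z(Fz, nr, nz) * params$cp_g * env$T
    if (nr > 1L) {
      uprm <- Fr > 0
      donTr <- ifelse(uprm, env$T[-nr, , drop = FALSE], env$T[-1, , drop = FALSE])
      q <- q + .gain_r(Fr * params$cp_g * donTr, nr, nz) -
        .gain_r(Fr, nr, nz) * params$cp_g * env$T
    }
    q
  }
  sv <- scale_sp(env$M_v, Fz_v, Fr_v, vent_v)
  sc <- scale_sp(env$M_c, Fz_c, Fr_c, vent_c)
  sa <- scale_sp(env$M_a, Fz_a, Fr_a, vent_a)
  dQ <- adv_heat(sv$Fz + sc$Fz + sa$Fz, sv$Fr + sc$Fr + sa$Fr)

  # ambient inflow through an open top surface when below ambient pressure
  t_now <- env$t
  C_oven_air <- params$P_amb / (params$R * oven$T_air(t_now)) -
    oven$C_oven_v - oven$C_oven_co2
  C_amb_tot <- params$P_amb / (params$R * oven$T_air(t_now))
  vin_mol <- pmax(-vent_mol, 0)
  in_v <- vin_mol * oven$C_oven_v / C_amb_tot * params$M_h2o
  in_c <- vin_mol * oven$C_oven_co2 / C_amb_tot * params$M_co2
  in_a <- vin_mol * C_oven_air / C_amb_tot * params$M_air
  env$M_v <- env$M_v + gains(sv)
  env$M_c <- env$M_c + gains(sc)
  env$M_a <- env$M_a + gains(sa)
  env$M_v[, top] <- env$M_v[, top] + in_v
  env$M_c[, top] <- env$M_c[, top] + in_c
  env$M_a[, top] <- env$M_a[, top] + in_a
  dQ[, top] <- dQ[, top] + (in_v + in_c + in_a) * params$cp_g *
    (oven$T_air(t_now) - env$T[, top])
  env$water_out <- env$water_out + sum(sv$vent) - sum(in_v)
  env$co2_out <- env$co2_out + sum(sc$vent) - sum(in_c)

  # --- stage B: binary diffusion on the post-Darcy composition (total
  # pressure now equalized, so density gradients are compositional) --------
  rho_v <- env$M_v / V_g; rho_c <- env$M_c / V_g; rho_a <- env$M_a / V_g
  grad <- function(X) X[, -1, drop = FALSE] - X[, -nz, drop = FALSE]
  Gvd <- env$Gd_v * .expfac(env$rd_v * dt_g)
  Gcd <- env$Gd_c * .expfac(env$rd_c * dt_g)
  Dz_v <- -Gvd * grad(rho_v) * dt_g
  Dz_c <- -Gcd * grad(rho_c) * dt_g
  Dz_a <- -Gcd * grad(rho_a) * dt_g
  if (nr > 1L) {
    gradr <- function(X) X[-1, , drop = FALSE] - X[-nr, , drop = FALSE]
    Gvr <- env$Gr_v * .expfac(env$rr_v * dt_g)
    Gcr <- env$Gr_c * .expfac(env$rr_c * dt_g)
    Dr_v <- -Gvr * gradr(rho_v) * dt_g
    Dr_c <- -Gcr * gradr(rho_c) * dt_g
    Dr_a <- -Gcr * gradr(rho_a) * dt_g
  } else {
    Dr_v <- Dr_c <- Dr_a <- matrix(0, 0, nz)
  }
  dv <- scale_sp(env$M_v, Dz_v, Dr_v, NULL)
  dc <- scale_sp(env$M_c, Dz_c, Dr_c, NULL)
  da <- scale_sp(env$M_a, Dz_a, Dr_a, NULL)
  dQ <- dQ + adv_heat(dv$Fz + dc$Fz + da$Fz, dv$Fr + dc$Fr + da$Fr)
  env$M_v <- env$M_v + gains(dv)
  env$M_c <- env$M_c + gains(dc)
  env$M_a <- env$M_a + gains(da)

  # alpha-gated convective exchange with the oven atmosphere: exponential
  # relaxation toward the oven concentrations (cannot overdraw)
  fb <- function(h_coef) 1 - exp(-env$alpha[, top] * h_coef * grid$A_z /
                                   V_g[, top] * dt_g)
  dxv <- fb(oven$h_m) * (oven$C_oven_v * params$M_h2o * V_g[, top] - env$M_v[, top])
  dxc <- fb(oven$h_co2) * (oven$C_oven_co2 * params$M_co2 * V_g[, top] - env$M_c[, top])
  dxa <- fb(oven$h_co2) * (C_oven_air * params$M_air * V_g[, top] - env$M_a[, top])
  env$M_v[, top] <- env$M_v[, top] + dxv
  env$M_c[, top] <- env$M_c[, top] + dxc
  env$M_a[, top] <- env$M_a[, top] + dxa
  dQ[, top] <- dQ[, top] + pmax(dxv + dxc + dxa, 0) * params$cp_g *
    (oven$T_air(t_now) - env$T[, top])
  env$water_out <- env$water_out - sum(dxv)
  env$co2_out <- env$co2_out - sum(dxc)

  # --- stage C: moisture phase change: linearized saturation adjustment
  # toward the sorption equilibrium a_w(W, T) C_sat(T) at the nonequilibrium
  # rate; the latent shift of C_sat with temperature is included so
  # evaporation cools toward the wet-bulb point and condensation heats
  # toward the dew point without overshoot ---------------------------------
  Tc <- pmin(pmax(env$T, 274), 423)
  aw <- dough_water_activity(env$M_l / env$M_s, env$T)
  aw_Csat <- aw * saturation_concentration(Tc, params)
  C_v <- env$M_v / params$M_h2o / V_g
  Lv <- latent_heat(env$T, params)
  dCsat_dT <- (saturation_pressure_slope(Tc, params) -
                 saturation_pressure(Tc, params) / Tc) / (params$R * Tc)
  denom <- 1 / (params$M_h2o * V_g) + aw * pmax(dCsat_dT, 0) * Lv / env$heat_cap
  dm_eq <- (aw_Csat - C_v) / denom                # kg vapor to equilibrium
  dm <- dm_eq * (1 - exp(-env$k_mpc * dt_g))      # nonequilibrium relaxation
  if (control$convention == "printed") dm <- -dm
  dm <- pmin(dm, env$M_l)                         # cannot evaporate more than there is
  dm <- pmax(dm, -env$M_v)
  # condensation cannot flood the pore space: liquid gain is limited to the
  # gas volume above the minimum porosity (pore-saturation guard)
  dm <- pmax(dm, -env$cond_room)
  env$cond_room <- pmax(env$cond_room + pmin(dm, 0), 0)
  env$M_v <- env$M_v + dm
  env$M_l <- env$M_l - dm
  # apply latent + advected enthalpy to the temperature within the subcycle
  env$T <- pmin(pmax(env$T + (dQ - dm * Lv) / env$heat_cap, 274), 474)
  invisible(NULL)
}


#' Advance the coupled system by one outer step
#'
#' Operator-split update: (1) quasi-static mechanics and vertical-Lagrangian
#' mesh motion; (2) explicit energy conduction (effective conductivity with
#' the closed-pore ECD enhancement) with oven boundary fluxes, plus Fickian
#' and ECD liquid transport and the CO2 generation source; (3) subcycled gas
#' physics: Darcy flow, gas diffusion, venting, boundary exchange and the
#' stiff phase-change relaxation. Negative-density protection clips
#' evaporation to the liquid available in a cell per substep.
#'
#' @param state a `field_state`.
#' @param grid the matching `bake_grid`.
#' @param oven an [oven_program()].
#' @param params a [material_params()].
#' @param control a [solver_config()].
#' @param mech a [mechanics_config()].
#' @param dt requested step, s; reduced automatically if stability demands.
#' @return list with updated `state`, `grid`, the `dt` actually taken and a
#'   `budget` of cumulative boundary losses (kg).
#' @export
bake_step <- function(state, grid, oven, params = material_params(),
                      control = solver_config(), mech = mechanics_config(),
                      dt = control$dt_max) {
  if (dt <= 0) stop("dt must be positive")
  nr <- grid$nr; nz <- grid$nz
  d <- derived_fields(state, grid, params)

  # stability bounds: conduction and volumetric strain
  dzf <- vertical_spacing(grid)
  lz <- .hmean(d$lambda_eff[, -nz, drop = FALSE], d$lambda_eff[, -1, drop = FALSE])
  Gz <- lz * matrix(grid$A_z, nr, nz - 1L) / dzf
  G <- cbind(Gz, 0) + cbind(0, Gz)   # total face conductance per cell, W/K
  if (nr > 1L) {
    lr <- .hmean(d$lambda_eff[-nr, , drop = FALSE], d$lambda_eff[-1, , drop = FALSE])
    Gr <- lr * radial_face_areas(grid) / grid$dr
    G <- G + rbind(Gr, 0) + rbind(0, Gr)
  }
  G[, 1] <- G[, 1] + oven$h_e * grid$A_z
  G[, nz] <- G[, nz] + (oven$h_c + 20) * grid$A_z   # +20 ~ linearized radiation
  if (nr > 1L) G[nr, ] <- G[nr, ] + oven$h_e * side_wall_areas(grid)
  dt_cond <- 0.4 * min(d$heat_cap / G)
  m0 <- solve_mechanics(state, grid, params, mech, dt = dt, derived = d)
  e_abs <- max(abs(m0$e))
  dt_mech <- if (e_abs > 0) 0.02 / e_abs else Inf
  dt <- min(dt, dt_cond, dt_mech)

  # (1) mechanics + mesh motion
  m <- solve_mechanics(state, grid, params, mech, dt = dt, derived = d)
  grid <- move_mesh(grid, m$e, dt)
  d <- derived_fields(state, grid, params)

  # (2) energy conduction + boundaries (W per cell)
  dzf <- vertical_spacing(grid)
  lz <- .hmean(d$lambda_eff[, -nz, drop = FALSE], d$lambda_eff[, -1, drop = FALSE])
  # Fz is the upward heat flow through the face between layers k and k+1
  Fz <- -lz * (state$T[, -1, drop = FALSE] - state$T[, -nz, drop = FALSE]) / dzf *
    matrix(grid$A_z, nr, nz - 1L)
  Q <- .gain_z(Fz, nr, nz)
  if (nr > 1L) {
    lr <- .hmean(d$lambda_eff[-nr, , drop = FALSE], d$lambda_eff[-1, , drop = FALSE])
    Fr <- -lr * (state$T[-1, , drop = FALSE] - state$T[-nr, , drop = FALSE]) /
      grid$dr * radial_face_areas(grid)
    Q <- Q + .gain_r(Fr, nr, nz)
  }
  t_now <- state$t
  j_lb <- liquid_boundary_flux(state$T[, nz], d$W[, nz], d$alpha[, nz], oven, params)
  j_lb <- pmin(j_lb, state$M_l[, nz] / grid$A_z / dt)   # clip to available liquid
  q_top <- heat_boundary_flux(state$T[, nz], oven, "top_air", t_now, j_lb, params)
  q_bot <- heat_boundary_flux(state$T[, 1], oven, "bottom_mold", t_now, 0, params)
  Q[, nz] <- Q[, nz] + q_top * grid$A_z
  Q[, 1] <- Q[, 1] + q_bot * grid$A_z
  if (nr > 1L) {
    q_side <- heat_boundary_flux(state$T[nr, ], oven, "side_mold", t_now, 0, params)
    Q[nr, ] <- Q[nr, ] + q_side * side_wall_areas(grid)
  }

  # liquid transport: Fickian diffusion + closed-pore ECD (kg/s at faces)
  coef_f <- d$rho_s_bar * liquid_diffusivity(pmax(d$W, 0), pmin(d$f_vg, 1))
  cf <- .hmean(coef_f[, -nz, drop = FALSE], coef_f[, -1, drop = FALSE])
  Jl <- -cf * (d$W[, -1, drop = FALSE] - d$W[, -nz, drop = FALSE]) / dzf *
    matrix(grid$A_z, nr, nz - 1L)
  coef_e <- (1 - d$alpha) * pmin(d$f_vg, 1) *
    gas_effective_diffusivity(params$D_v_ref, pmin(d$f_vg, 1)) * d$a_w /
    (params$R * state$T) * saturation_pressure_slope(state$T, params)
  ce <- .hmean(coef_e[, -nz, drop = FALSE], coef_e[, -1, drop = FALSE])
  Jl <- Jl - ce * (state$T[, -1, drop = FALSE] - state$T[, -nz, drop = FALSE]) / dzf *
    matrix(grid$A_z, nr, nz - 1L)
  Fz_l <- Jl * dt
  Fr_l <- if (nr > 1L) {
    cfr <- .hmean(coef_f[-nr, , drop = FALSE], coef_f[-1, , drop = FALSE])
    cer <- .hmean(coef_e[-nr, , drop = FALSE], coef_e[-1, , drop = FALSE])
    (-cfr * (d$W[-1, , drop = FALSE] - d$W[-nr, , drop = FALSE]) -
       cer * (state$T[-1, , drop = FALSE] - state$T[-nr, , drop = FALSE])) /
      grid$dr * radial_face_areas(grid) * dt
  } else matrix(0, 0, nz)
  # donor scaling: a cell cannot lose more than 95% of its liquid ...
  outl <- cbind(pmax(Fz_l, 0), 0) + cbind(0, pmax(-Fz_l, 0))
  if (nr > 1L) outl <- outl + rbind(pmax(Fr_l, 0), 0) + rbind(0, pmax(-Fr_l, 0))
  sdon <- pmin(0.95 * state$M_l / pmax(outl, 1e-300), 1)
  Fz_l <- Fz_l * ifelse(Fz_l > 0, sdon[, -nz, drop = FALSE], sdon[, -1, drop = FALSE])
  if (nr > 1L)
    Fr_l <- Fr_l * ifelse(Fr_l > 0, sdon[-nr, , drop = FALSE], sdon[-1, , drop = FALSE])
  # ... and receiver scaling: inflow may not fill pores below porosity 0.02
  room <- pmax(d$f_vg - 0.02, 0) * d$V * params$rho_l
  inl <- cbind(0, pmax(Fz_l, 0)) + cbind(pmax(-Fz_l, 0), 0)
  if (nr > 1L) inl <- inl + rbind(matrix(0, 1, nz), pmax(Fr_l, 0)) +
    rbind(pmax(-Fr_l, 0), matrix(0, 1, nz))
  srec <- pmin(room / pmax(inl, 1e-300), 1)
  Fz_l <- Fz_l * ifelse(Fz_l > 0, srec[, -1, drop = FALSE], srec[, -nz, drop = FALSE])
  if (nr > 1L)
    Fr_l <- Fr_l * ifelse(Fr_l > 0, srec[-1, , drop = FALSE], srec[-nr, , drop = FALSE])
  dM_l <- .gain_z(Fz_l, nr, nz)
  if (nr > 1L) dM_l <- dM_l + .gain_r(Fr_l, nr, nz)
  # incompressible liquid arriving in a cell swells it, leaving shrinks it:
  # transported liquid volume moves with the mass so pore gas is not
  # spuriously compressed by the condensation front
  grid$h <- pmax(grid$h + dM_l / params$rho_l / grid$A_z, 0.05 * grid$dz0)
  dM_l[, nz] <- dM_l[, nz] - j_lb * grid$A_z * dt
  water_out_step <- sum(j_lb * grid$A_z) * dt

  # CO2 generation (correlation value scaled by the inventory normalization)
  gen <- d$rho_s_bar * co2_generation_rate(state$T) * params$k_co2_scale *
    pmin(d$f_vg, 1) * d$V * dt
  co2_gen_step <- sum(gen)

  # (3) subcycled gas physics on frozen T and geometry
  state$M_l <- pmax(state$M_l + dM_l, 0)
  d <- derived_fields(state, grid, params)   # geometry and moisture updated
  dzf <- vertical_spacing(grid)
  env <- new.env(parent = emptyenv())
  env$M_v <- state$M_v; env$M_c <- state$M_c + gen; env$M_a <- state$M_a
  env$M_l <- state$M_l
  env$T <- state$T; env$t <- t_now
  env$V_g <- d$V_g; env$f_vg <- d$f_vg; env$alpha <- d$alpha
  env$kappa <- d$kappa; env$k_mpc <- d$k_mpc
  env$M_s <- state$M_s; env$heat_cap <- d$heat_cap
  # liquid mass that can still condense before porosity hits the 0.02 floor
  env$cond_room <- pmax(d$f_vg - 0.02, 0) * d$V * params$rho_l
  env$water_out <- 0; env$co2_out <- 0

  # precomputed face geometry / coefficient factors (frozen over the step)
  env$dzf <- dzf
  Azf <- matrix(grid$A_z, nr, nz - 1L)
  env$kz_Az <- .hmean(d$kappa[, -nz, drop = FALSE], d$kappa[, -1, drop = FALSE]) * Azf
  # cubic connectivity gate (percolation) and crust reduction, matching the
  # permeability gating: the dried crust throttles all pore-gas transport
  Dv_c <- d$alpha^3 * d$beta * gas_effective_diffusivity(params$D_v_ref, pmin(d$f_vg, 1))
  Dc_c <- d$alpha^3 * d$beta * gas_effective_diffusivity(params$D_co2_ref, pmin(d$f_vg, 1))
  env$Gd_v <- .hmean(Dv_c[, -nz, drop = FALSE], Dv_c[, -1, drop = FALSE]) / dzf * Azf
  env$Gd_c <- .hmean(Dc_c[, -nz, drop = FALSE], Dc_c[, -1, drop = FALSE]) / dzf * Azf
  pairR <- 1 / d$V_g[, -nz, drop = FALSE] + 1 / d$V_g[, -1, drop = FALSE]
  env$rd_v <- env$Gd_v * pairR
  env$rd_c <- env$Gd_c * pairR
  if (nr > 1L) {
    Ar <- radial_face_areas(grid)
    env$kr_Ar <- .hmean(d$kappa[-nr, , drop = FALSE], d$kappa[-1, , drop = FALSE]) * Ar
    env$Gr_v <- .hmean(Dv_c[-nr, , drop = FALSE], Dv_c[-1, , drop = FALSE]) / grid$dr * Ar
    env$Gr_c <- .hmean(Dc_c[-nr, , drop = FALSE], Dc_c[-1, , drop = FALSE]) / grid$dr * Ar
    pairRr <- 1 / d$V_g[-nr, , drop = FALSE] + 1 / d$V_g[-1, , drop = FALSE]
    env$rr_v <- env$Gr_v * pairRr
    env$rr_c <- env$Gr_c * pairRr
  }

  n_sub <- min(max(2L, as.integer(ceiling(dt / 0.1))), control$max_subcycles)
  dt_g <- dt / n_sub
  for (k in seq_len(n_sub)) .gas_substep(env, grid, params, oven, control, dt_g)

  state$M_l <- env$M_l
  state$M_v <- env$M_v
  state$M_c <- env$M_c
  state$M_a <- env$M_a
  # physical range clamp: bounded below by frost, above by the oven drive
  state$T <- pmin(pmax(env$T + Q * dt / d$heat_cap, 274), 474)
  state$t <- t_now + dt
  list(state = state, grid = grid, dt = dt,
       budget = list(water_out = water_out_step + env$water_out,
                     co2_out = env$co2_out, co2_gen = co2_gen_step,
                     n_sub = n_sub))
}

#' Run a full baking simulation
#'
#' Integrates the coupled system to `control$t_end` with adaptive outer
#' steps, recording a diagnostics row every `control$cadence` seconds and
#' full derived-field snapshots at `snapshot_times`. Boundary water and CO2
#' losses are tallied every step so the global budgets can be audited:
#' `initial water = final water + cumulative boundary loss`.
#'
#' @inheritParams bake_step
#' @param state initial `field_state` (from [initialize_state()]).
#' @param probes probe table, see [default_probes()].
#' @param snapshot_times times (s) at which to store derived-field snapshots.
#' @param progress print a line every 300 s of simulated time.
#' @return object of class `bake_run`: list with `diagnostics` (data.frame),
#'   final `state` and `grid`, `snapshots`, and the cumulative `budget`.
#' @export
run_bake <- function(grid, state, oven, params = material_params(),
                     control = solver_config(), mech = mechanics_config(),
                     probes = default_probes(),
                     snapshot_times = c(300, 600, 900, 1200),
                     progress = FALSE) {
  diag <- list(state_diagnostics(state, grid, params, probes))
  snaps <- list()
  budget <- list(water_out = 0, co2_out = 0, co2_gen = 0)
  next_rec <- control$cadence
  next_snap <- if (length(snapshot_times)) sort(snapshot_times) else numeric(0)
  water0 <- sum(state$M_l) + sum(state$M_v)
  while (state$t < control$t_end - 1e-9) {
    dt_req <- min(control$dt_max, control$t_end - state$t, next_rec - state$t)
    if (length(next_snap)) dt_req <- min(dt_req, next_snap[1] - state$t)
    stp <- bake_step(state, grid, oven, params, control, mech, dt = dt_req)
    state <- stp$state; grid <- stp$grid
    budget$water_out <- budget$water_out + stp$budget$water_out
    budget$co2_out <- budget$co2_out + stp$budget$co2_out
    budget$co2_gen <- budget$co2_gen + stp$budget$co2_gen
    if (any(!is.finite(state$T)))
      stop("non-finite temperature at t = ", state$t, "; aborting run")
    if (state$t >= next_rec - 1e-9) {
      diag[[length(diag) + 1L]] <- state_diagnostics(state, grid, params, probes)
      next_rec <- next_rec + control$cadence
      if (progress && (state$t %% 300) < control$cadence)
        message(sprintf("t = %.0f s  axis %.1f mm  liquid %.1f g",
                        state$t, 1000 * column_heights(grid)[1],
                        1000 * sum(state$M_l)))
    }
    if (length(next_snap) && state$t >= next_snap[1] - 1e-9) {
      snaps[[as.character(next_snap[1])]] <-
        c(list(t = state$t, h = grid$h), derived_fields(state, grid, params),
          list(T = state$T))
      next_snap <- next_snap[-1]
    }
  }
  diag <- do.call(rbind, diag)
  budget$water_balance_error <-
    abs(water0 - (sum(state$M_l) + sum(state$M_v)) - budget$water_out) /
    max(water0, 1e-12)
  structure(list(diagnostics = diag, state = state, grid = grid,
                 snapshots = snaps, budget = budget),
            class = "bake_run")
}

#' @export
print.bake_run <- function(x, ...) {
  n <- nrow(x$diagnostics)
  cat(sprintf("<bake_run> %d diagnostic rows to t = %.0f s; axis height %.1f mm, liquid %.1f g\n",
              n, x$diagnostics$t[n], 1000 * x$diagnostics$axis_height[n],
              1000 * x$diagnostics$liquid_mass[n]))
  invisible(x)
}
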