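#' Initialize the field state for a baking scenario
#'
#' Uniform initial fields from the dough's measured bulk properties. The
#' solid and liquid apparent densities follow from the effective density and
#' dry-basis moisture: `rho_s_bar = rho_eff0 / (1 + W0)`,
#' `rho_l_bar = W0 rho_s_bar`. Pore gas closes the ambient pressure: the
#' vapor partial pressure sits at the sorption equilibrium
#' `a_w(W0, T0) P_sat(T0)` and fermentation CO2 carries the balance to
#' `P_amb` (the pore gas of a proofed dough). An inert-air species is
#' tracked as well (zero initially) to represent oven air drawn in through
#' the open crust late in the bake.
#'
#' The state stores extensive per-cell masses (kg) of solid, liquid, vapor,
#' CO2 and air plus temperature; apparent densities and all derived fields
#' are obtained with [derived_fields()].
#'
#' @param grid a [make_grid()] object.
#' @param params a [material_params()] object.
#' @param T0 initial temperature, K.
#' @param W0 initial dry-basis moisture ratio, > 0.
#' @param rho_eff0 initial dough density, kg/m^3.
#' @param P_co2_0 initial CO2 partial pressure, Pa; the default `NULL`
#'   assigns the full non-vapor balance `P_amb - P_v` to CO2.
#' @return object of class `field_state`.
#' @export
initialize_state <- function(grid, params = material_params(),
                             T0 = 301.15, W0 = 0.82, rho_eff0 = 1069,
                             P_co2_0 = NULL) {
  if (!is.finite(W0) || W0 <= 0) stop("W0 must be positive")
  if (rho_eff0 <= 0) stop("rho_eff0 must be positive")
  rho_s_bar <- rho_eff0 / (1 + W0)
  rho_l_bar <- W0 * rho_s_bar
  f_vs <- rho_s_bar / params$rho_s
  f_vl <- rho_l_bar / params$rho_l
  f_vg <- 1 - f_vs - f_vl
  if (f_vg <= 0 || f_vg >= 1)
    stop("inconsistent scenario: derived gas fraction ", signif(f_vg, 4),
         " outside (0, 1)")
  aw <- water_activity(W0, T0)
  P_v <- aw * saturation_pressure(T0, params)
  if (is.null(P_co2_0)) P_co2_0 <- params$P_amb - P_v
  P_air <- params$P_amb - P_v - P_co2_0
  if (P_air < 0) stop("inconsistent scenario: initial partial pressures exceed P_amb")
  V <- cell_volumes(grid)
  RT <- params$R * T0
  st <- list(
    t = 0,
    T   = matrix(T0, grid$nr, grid$nz),
    M_s = rho_s_bar * V,
    M_l = rho_l_bar * V,
    M_v = f_vg * P_v   * params$M_h2o / RT * V,
    M_c = f_vg * P_co2_0 * params$M_co2 / RT * V,
    M_a = f_vg * P_air * params$M_air / RT * V
  )
  structure(st, class = "field_state")
}

#' Derived fields on the grid
#'
#' Elementwise assembly of every secondary quantity the solver and the
#' diagnostics consume: apparent densities, phase volume fractions (closing
#' exactly to 1), dry-basis moisture, partial pressures and molar
#' concentrations from the ideal-gas law, water activity, the pore-opening /
#' crust / viscosity state functions, phase-change rate, permeability,
#' effective conductivity with its ECD share, and the volumetric heat
#' capacity.
#'
#' @param state a [initialize_state()] object (or one advanced by the solver).
#' @param grid the matching [make_grid()] object.
#' @param params a [material_params()] object.
#' @return named list of `nr x nz` matrices (plus `V`, the cell volumes).
#' @export
derived_fields <- function(state, grid, params = material_params()) {
  V <- cell_volumes(grid)
  if (any(!is.finite(state$T)) || any(!is.finite(state$M_l)))
    stop("state corruption: non-finite field at cell ",
         paste(which(!is.finite(state$T) | !is.finite(state$M_l))[1]))
  rho_s_bar <- state$M_s / V
  rho_l_bar <- state$M_l / V
  W <- rho_l_bar / rho_s_bar
  f_vs <- rho_s_bar / params$rho_s
  f_vl <- rho_l_bar / params$rho_l
  f_vg <- 1 - f_vs - f_vl
  f_vg <- pmax(f_vg, 1e-6)           # guard against full liquid saturation
  V_g <- f_vg * V
  RT <- params$R * state$T
  P_v   <- state$M_v / params$M_h2o * RT / V_g
  P_co2 <- state$M_c / params$M_co2 * RT / V_g
  P_air <- state$M_a / params$M_air * RT / V_g
  P_g <- P_v + P_co2 + P_air
  C_v <- P_v / RT
  C_co2 <- P_co2 / RT
  Tc <- pmin(pmax(state$T, 274), 460)   # constitutive validity clamp
  aw <- dough_water_activity(W, Tc)
  alpha <- pore_open_fraction(Tc, params)
  beta <- crust_function(Tc, params)
  mu_eff <- dough_viscosity(Tc, params)
  k_mpc <- mpc_rate(alpha, params)
  lam <- effective_conductivity(f_vs, f_vl, 1 - f_vs - f_vl, Tc, aw, alpha, params)
  kappa <- permeability(pmin(f_vg, 1), alpha, beta, params)
  heat_cap <- state$M_s * params$cp_s + state$M_l * params$cp_l +
    (state$M_v + state$M_c + state$M_a) * params$cp_g      # J/K per cell
  list(V = V, rho_s_bar = rho_s_bar, rho_l_bar = rho_l_bar, W = W,
       f_vs = f_vs, f_vl = f_vl, f_vg = f_vg, V_g = V_g,
       P_v = P_v, P_co2 = P_co2, P_air = P_air, P_g = P_g,
       C_v = C_v, C_co2 = C_co2, a_w = aw,
       alpha = alpha, beta = beta, mu_eff = mu_eff, k_mpc = k_mpc,
       lambda_eff = lam$lambda_eff, edc_share = lam$edc_share,
       kappa = kappa, heat_cap = heat_cap)
}

#' Default probe set
#'
#' Lagrangian material probes matching the thermocouple and pressure-tap
#' layout: initial coordinates (r, z) in metres. Probes move with the dough.
#' @return data.frame with columns `name`, `r`, `z`.
#' @export
default_probes <- function() {
  data.frame(name = c("T1", "T2", "T3", "P1"),
             r = c(0, 0, 0.025, 0),
             z = c(0.005, 0.010, 0.015, 0.010))
}

# Interpolate a cell-centred field at a material probe. Vertical position is
# material: the slab initially at z0 stays at fixed fractional cell index
# because mesh motion is vertical-Lagrangian.
probe_interp <- function(field, grid, r0, z0) {
  i <- which.min(abs(grid$r - r0))
  idx <- z0 / grid$dz0 + 0.5        # continuous cell index, 1-based centres
  k0 <- floor(idx); w <- idx - k0
  k0 <- min(max(k0, 1L), grid$nz)
  k1 <- min(k0 + 1L, grid$nz)
  if (z0 < 0 || z0 > grid$height0) stop("probe outside initial domain")
  (1 - w) * field[i, k0] + w * field[i, k1]
}

# Current laboratory height of a material probe (m).
probe_height <- function(grid, r0, z0) {
  i <- which.min(abs(grid$r - r0))
  idx <- z0 / grid$dz0
  k0 <- floor(idx); w <- idx - k0
  cs <- cumsum(grid$h[i, ])
  base <- if (k0 >= 1) cs[min(k0, grid$nz)] else 0
  base + w * grid$h[i, min(k0 + 1L, grid$nz)]
}

#' One diagnostics row for the current state
#'
#' Scalar summaries used throughout the analysis: axis and side free-surface
#' heights, total phase masses, Lagrangian probe temperatures and the P1
#' gauge pressure, the volume-averaged vapor mole fraction
#' `P_v/(P_v + P_co2)` over the closed-pore region (cells with alpha < 1),
#' the maximum ECD conductivity share in that region, domain temperature
#' extremes, the crumb moisture maximum and the volume expansion ratio.
#'
#' @inheritParams derived_fields
#' @param probes probe table as from [default_probes()].
#' @return one-row data.frame (SI units; heights m, masses kg, pressure Pa).
#' @export
state_diagnostics <- function(state, grid, params = material_params(),
                              probes = default_probes()) {
  d <- derived_fields(state, grid, params)
  V0 <- pi * grid$radius^2 * grid$height0
  closed <- d$alpha < 1
  xv <- if (any(closed)) {
    sum((d$P_v / (d$P_v + d$P_co2) * d$V)[closed]) / sum(d$V[closed])
  } else NA_real_
  Tc <- pmin(pmax(state$T, 274), 460)
  edc_max <- if (any(closed)) max(((1 - d$alpha) * lambda_edc(Tc, d$a_w, d$f_vg, params) *
                                     d$f_vg / d$lambda_eff)[closed]) else NA_real_
  crumb <- state$T < params$T_c
  out <- data.frame(
    t = state$t,
    axis_height = column_heights(grid)[1],
    side_height = column_heights(grid)[grid$nr],
    volume = sum(d$V),
    volume_ratio = sum(d$V) / V0,
    solid_mass = sum(state$M_s),
    liquid_mass = sum(state$M_l),
    vapor_mass = sum(state$M_v),
    co2_mass = sum(state$M_c),
    air_mass = sum(state$M_a),
    min_T = min(state$T), max_T = max(state$T),
    xv_closed = xv, edc_share_max = edc_max,
    max_W_crumb = if (any(crumb)) max(d$W[crumb]) else NA_real_,
    all_open = all(d$alpha >= 1)
  )
  for (j in seq_len(nrow(probes))) {
    nm <- probes$name[j]
    out[[nm]] <- probe_interp(state$T, grid, probes$r[j], probes$z[j])
    if (nm == "P1")
      out[["P1_gauge"]] <- probe_interp(d$P_g, grid, probes$r[j], probes$z[j]) - params$P_amb
  }
  out
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> t = %.1f s, T in [%.2f, %.2f] K, liquid %.4f kg\n",
              x$t, min(x$T), max(x$T), sum(x$M_l)))
  invisible(x)
}
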