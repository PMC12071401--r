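#' @title Constitutive closures for the baking model
#' @description Pure algebraic state functions consumed by the governing
#'   equations: sorption (water activity), saturation properties, latent heat,
#'   diffusivities, CO2 generation, the pore-opening / crusting / viscosity
#'   transition sigmoids, phase-change kinetics, the evaporation-condensation-
#'   diffusion (ECD) flux and its equivalent conductivity, the effective
#'   conductivity mixture rule, permeability and the ideal-gas mixture density.
#'   All functions are vectorized over their first arguments and use kelvin.
#' @name constitutive
NULL

# Quintic smoothstep: 0 below 0, 1 above 1, C^2-continuous with zero slope at
# both band edges (hard saturation outside the band).
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  pmin(pmax(x * x * x * (x * (x * 6 - 15) + 10), 0), 1)  # guard FP overshoot
}

#' Water activity of dough from the Oswin-type sorption isotherm
#'
#' Closed-form inversion of `100 W = A (a_w/(1-a_w))^B` with
#' `A = 15.64 - 0.1 (T - 273.15)` and `B = 0.38 + 1.69e-3 (T - 273.15)`:
#' `x = (100 W / A)^(1/B)`, `a_w = x/(1+x)`.
#'
#' @param W dry-basis moisture ratio (kg water / kg dry solid), > 0.
#' @param T temperature, K, within 273.15..423.15 (A changes sign near 156 degC).
#' @return water activity strictly in (0, 1), increasing in W at fixed T.
#' @export
water_activity <- function(W, T) {
  if (any(!is.finite(W)) || any(W <= 0)) stop("W must be positive")
  if (any(T < 273.15 | T > 423.15)) stop("T outside supported range [273.15, 423.15] K")
  TC <- T - 273.15
  A <- 15.64 - 0.1 * TC
  B <- 0.38 + 1.69e-3 * TC
  x <- (100 * W / A)^(1 / B)
  x / (1 + x)
}


# Water activity for solver use: W floored, T clamped to the sorption
# correlation's validity range (the Oswin A(T) coefficient vanishes near
# 156 degC; beyond complete solidification at 110 degC the isotherm is
# extrapolated isothermally).
dough_water_activity <- function(W, T) {
  water_activity(pmax(W, 1e-6), pmin(pmax(T, 274), 383.15))
}

#' Saturation pressure of water vapor (Magnus form)
#'
#' `P_sat = a exp(b (T - 273.15)/(T - c))`; with the default coefficients
#' this gives 1 atm within 1% at 100 degC.
#'
#' @param T temperature, K, > 273.15.
#' @param params [material_params()] carrying the coefficients.
#' @return saturation pressure, Pa.
#' @export
saturation_pressure <- function(T, params = material_params()) {
  if (any(T <= 273.15)) stop("T must exceed 273.15 K")
  params$psat_a * exp(params$psat_b * (T - 273.15) / (T - params$psat_c))
}

# dP_sat/dT, analytic; used by the ECD conductivity.
saturation_pressure_slope <- function(T, params = material_params()) {
  b <- params$psat_b; cc <- params$psat_c
  saturation_pressure(T, params) * b * (273.15 - cc) / (T - cc)^2
}

#' Saturation molar concentration of water vapor
#'
#' `C_sat = P_sat / (R T)` (ideal gas).
#'
#' @inheritParams saturation_pressure
#' @return mol/m^3.
#' @export
saturation_concentration <- function(T, params = material_params()) {
  saturation_pressure(T, params) / (params$R * T)
}

#' Latent heat of vaporization
#'
#' Linear Watson-type correction `L_v = L_v,ref + (c_p,g - c_p,l)(T - T0)`;
#' decreasing in T since the gas heat capacity is below the liquid one.
#'
#' @inheritParams saturation_pressure
#' @return J/kg.
#' @export
latent_heat <- function(T, params = material_params()) {
  params$Lv_ref + (params$cp_g - params$cp_l) * (T - params$T0)
}

#' Liquid water diffusivity in the matrix
#'
#' `D_l = 1e-9 eps_g exp(-10 + 10 W)`, increasing in both moisture and
#' porosity.
#'
#' @param W dry-basis moisture ratio, >= 0.
#' @param eps_g gas volume fraction (porosity) in \[0, 1\].
#' @return m^2/s.
#' @export
liquid_diffusivity <- function(W, eps_g) {
  if (any(eps_g < 0 | eps_g > 1)) stop("eps_g must lie in [0, 1]")
  if (any(W < 0)) stop("W must be nonnegative")
  1e-9 * eps_g * exp(-10 + 10 * W)
}

#' Effective gas diffusivity (Bruggeman-type)
#'
#' `D_eff = D_ref eps_g^(4/3)`.
#'
#' @param D_ref binary gas diffusivity, m^2/s, > 0.
#' @param eps_g gas volume fraction in \[0, 1\].
#' @return m^2/s.
#' @export
gas_effective_diffusivity <- function(D_ref, eps_g) {
  if (any(D_ref <= 0)) stop("D_ref must be positive")
  if (any(eps_g < 0 | eps_g > 1)) stop("eps_g must lie in [0, 1]")
  D_ref * eps_g^(4 / 3)
}

#' CO2 generation rate of yeast per unit dry mass
#'
#' Piecewise correlation in Celsius: linear `5e-6 T - 9.98e-5` up to 40 degC
#' (clamped at zero where negative), Gaussian decay
#' `1e-4 exp(-((T-40)/10)^2)` above. The two branches differ by 0.2% at the
#' 40 degC seam; the right branch value is adopted there. This function
#' returns the raw correlation value; the Eq.-14-style source term applies
#' the inventory normalization `k_co2_scale` from [material_params()]
#' (see that help page for the rationale).
#'
#' @param T temperature, K (converted to Celsius internally).
#' @return correlation value (kg CO2 per kg dry solid per correlation time
#'   unit), always >= 0, decaying to 0 at high temperature.
#' @export
co2_generation_rate <- function(T) {
  TC <- T - 273.15
  out <- ifelse(TC >= 40,   # the Gaussian branch value is adopted at the seam
                1e-4 * exp(-((TC - 40) / 10)^2),
                pmax(5e-6 * TC - 9.98e-5, 0))
  out
}

#' Pore-opening function
#'
#' Quintic smoothstep in temperature: exactly 0 below `T_open - dT_open/2`
#' (closed pores), exactly 1 above `T_open + dT_open/2` (fully open),
#' 0.5 at the midpoint.
#'
#' @param T temperature, K.
#' @param params [material_params()] supplying `T_open`, `dT_open`.
#' @return opening fraction alpha in \[0, 1\], nondecreasing in T.
#' @export
pore_open_fraction <- function(T, params = material_params()) {
  smoothstep((T - (params$T_open - params$dT_open / 2)) / params$dT_open)
}

#' Crusting function
#'
#' Permeability reduction factor: 1 in the crumb well below the crust
#' temperature `T_c`, 0.1 in the crust well above it, with a smoothstep
#' transition of width `dT_c` centred on `T_c`.
#'
#' @inheritParams pore_open_fraction
#' @return beta in \[0.1, 1\], nonincreasing in T.
#' @export
crust_function <- function(T, params = material_params()) {
  1 - 0.9 * smoothstep((T - (params$T_c - params$dT_c / 2)) / params$dT_c)
}

#' Effective dough viscosity
#'
#' Sigmoid transition in log-viscosity space from the fluid-like value
#' `mu_l_dough` at `T <= T_tra - dT_tra/2` to the solid-like value
#' `mu_s_dough` at `T >= T_tra + dT_tra/2`; the midpoint is the geometric
#' mean of the two plateaus.
#'
#' @inheritParams pore_open_fraction
#' @return Pa s.
#' @export
dough_viscosity <- function(T, params = material_params()) {
  s <- smoothstep((T - (params$T_tra - params$dT_tra / 2)) / params$dT_tra)
  exp(log(params$mu_l_dough) + s * (log(params$mu_s_dough) - log(params$mu_l_dough)))
}

#' Moisture phase-change rate constant
#'
#' Linear blend between the nonequilibrium open-pore rate and the
#' equilibrium-limit closed-pore rate:
#' `k_MPC = alpha k_open + (1 - alpha) k_closed`.
#'
#' @param alpha pore-opening fraction in \[0, 1\].
#' @inheritParams pore_open_fraction
#' @return 1/s, bounded by \[k_open, k_closed\].
#' @export
mpc_rate <- function(alpha, params = material_params()) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  alpha * params$k_mpc_open + (1 - alpha) * params$k_mpc_closed
}

#' Moisture phase-change source term
#'
#' Mass source of the liquid phase per unit bread volume. With the default
#' `"budget"` convention the source is positive for condensation (vapor
#' excess over the sorption equilibrium `C_v > a_w C_sat` produces liquid)
#' and negative for evaporation, which closes the global water budget and
#' reproduces the evaporation/condensation front phenomenology; the vapor
#' phase receives the opposite sign and the energy equation the latent
#' term `+ m_l L_v`. The `"printed"` convention flips the sign.
#'
#' @param T temperature, K.
#' @param W dry-basis moisture ratio.
#' @param C_v vapor molar concentration in the pore gas, mol/m^3, >= 0.
#' @param f_vg gas volume fraction in (0, 1\].
#' @param alpha pore-opening fraction in \[0, 1\].
#' @param params [material_params()].
#' @param convention `"budget"` (default) or `"printed"`.
#' @return liquid mass source, kg/(m^3 s); exactly zero at equilibrium.
#' @export
phase_change_source <- function(T, W, C_v, f_vg, alpha,
                                params = material_params(),
                                convention = c("budget", "printed")) {
  convention <- match.arg(convention)
  if (any(C_v < 0)) stop("C_v must be nonnegative")
  if (any(f_vg <= 0 | f_vg > 1)) stop("f_vg must lie in (0, 1]")
  k <- mpc_rate(alpha, params)
  aw <- water_activity(W, T)
  Cs <- saturation_concentration(T, params)
  m <- k * f_vg * (aw * Cs - C_v) * params$M_h2o
  if (convention == "budget") -m else m
}

#' ECD liquid-water flux through closed pores
#'
#' Evaporation-condensation-diffusion transport: vapor evaporates from the
#' hot pore wall, diffuses across the pore and condenses on the cold wall,
#' carrying water down the saturation-pressure (hence temperature) gradient.
#' The pathway is gated by `(1 - alpha)`: it is active in closed pores and
#' becomes ineffective once the pores open (the open-pore vapor diffusion
#' term of the vapor equation takes over).
#'
#' @param T temperature, K.
#' @param W dry-basis moisture ratio.
#' @param f_vg gas volume fraction in (0, 1\].
#' @param alpha pore-opening fraction in \[0, 1\].
#' @param grad_T temperature gradient component, K/m.
#' @param params [material_params()].
#' @return flux component, kg/(m^2 s); zero in an isothermal field and in
#'   fully open pores.
#' @export
ecd_flux <- function(T, W, f_vg, alpha, grad_T, params = material_params()) {
  if (any(f_vg <= 0 | f_vg > 1)) stop("f_vg must lie in (0, 1]")
  aw <- water_activity(W, T)
  dpdT <- saturation_pressure_slope(T, params)
  D_eff <- gas_effective_diffusivity(params$D_v_ref, f_vg)
  -(1 - alpha) * f_vg * D_eff * aw / (params$R * T) * dpdT * grad_T
}

#' Equivalent thermal conductivity of the ECD mechanism
#'
#' `lambda_EDC = f_vg D_v,eff a_w L_v / (R T) dP_sat/dT`, with the Bruggeman
#' effective vapor diffusivity `D_v,eff = D_v f_vg^(4/3)` (pore vapor
#' diffuses through the tortuous gas network), defined so that
#' `lambda_EDC grad T = - j_l,ECD L_v` for fully closed pores.
#'
#' @param T temperature, K, > 273.15.
#' @param a_w water activity in \[0, 1\].
#' @param f_vg gas volume fraction in \[0, 1\].
#' @param params [material_params()].
#' @return W/(m K), increasing in T over the baking range.
#' @export
lambda_edc <- function(T, a_w, f_vg, params = material_params()) {
  D_eff <- ifelse(f_vg > 0, gas_effective_diffusivity(params$D_v_ref, pmin(f_vg, 1)), 0)
  f_vg * D_eff * a_w * latent_heat(T, params) /
    (params$R * T) * saturation_pressure_slope(T, params)
}

#' Effective thermal conductivity and ECD share
#'
#' Parallel mixture rule `lambda_c = f_vs lambda_s + f_vl lambda_l +
#' f_vg lambda_g` plus the closed-pore ECD enhancement
#' `(1 - alpha) lambda_EDC f_vg`.
#'
#' @param f_vs,f_vl,f_vg phase volume fractions summing to 1 (within 1e-9).
#' @param T temperature, K.
#' @param a_w water activity.
#' @param alpha pore-opening fraction.
#' @param params [material_params()].
#' @return list with `lambda_eff` (W/(m K)) and `edc_share` (fraction of
#'   `lambda_eff` contributed by the ECD term).
#' @export
effective_conductivity <- function(f_vs, f_vl, f_vg, T, a_w, alpha,
                                   params = material_params()) {
  if (any(abs(f_vs + f_vl + f_vg - 1) > 1e-9))
    stop("phase volume fractions must sum to 1")
  lam_c <- f_vs * params$lambda_s + f_vl * params$lambda_l + f_vg * params$lambda_g
  lam_e <- (1 - alpha) * lambda_edc(T, a_w, f_vg, params) * f_vg
  lam <- lam_c + lam_e
  list(lambda_eff = lam, edc_share = lam_e / lam)
}

#' Gas permeability of the matrix
#'
#' `kappa_g = kappa0 alpha^3 beta phi^1.34` with porosity `phi = f_vg`;
#' zero while pores are closed, reduced an order of magnitude in the crust.
#' The cubic power of the opening fraction reflects percolation: bulk gas
#' conduction requires a system-spanning cluster of ruptured pores, so
#' conductivity vanishes superlinearly near the opening threshold while the
#' fully open and fully closed limits are unchanged.
#'
#' @param f_vg porosity in \[0, 1\].
#' @param alpha pore-opening fraction in \[0, 1\].
#' @param beta crusting factor in \[0.1, 1\].
#' @param params [material_params()].
#' @return m^2.
#' @export
permeability <- function(f_vg, alpha, beta, params = material_params()) {
  if (any(f_vg < 0 | f_vg > 1 | alpha < 0 | alpha > 1 | beta < 0 | beta > 1))
    stop("permeability arguments must lie in [0, 1]")
  params$kappa0 * alpha^3 * beta * f_vg^1.34
}

#' Ideal-gas mixture density and molar mass
#'
#' Three-species pore-gas mixture (water vapor, CO2, inert air):
#' `rho_g = (P_v M_v + P_co2 M_co2 + P_air M_air) / (R T)` with the
#' mole-fraction-weighted mixture molar mass.
#'
#' @param P_v,P_co2 partial pressures, Pa, >= 0 and not all zero.
#' @param T temperature, K, > 0.
#' @param P_air inert-air partial pressure, Pa (default 0 recovers the
#'   two-species vapor + CO2 mixture).
#' @param params [material_params()].
#' @return list with `rho_g` (kg/m^3) and `M_g` (kg/mol).
#' @export
gas_density <- function(P_v, P_co2, T, P_air = 0, params = material_params()) {
  if (any(P_v < 0 | P_co2 < 0 | P_air < 0)) stop("partial pressures must be nonnegative")
  P <- P_v + P_co2 + P_air
  if (any(P <= 0)) stop("degenerate gas mixture: all partial pressures zero")
  if (any(T <= 0)) stop("T must be positive")
  M_g <- (P_v * params$M_h2o + P_co2 * params$M_co2 + P_air * params$M_air) / P
  list(rho_g = P * M_g / (params$R * T), M_g = M_g)
}
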