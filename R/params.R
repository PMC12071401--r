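#' Material parameter set for the baking model
#'
#' Assembles every constitutive constant the governing equations consume:
#' intrinsic phase densities, specific heats, the reference latent heat,
#' dough viscosities and the fluid-to-solid transition sigmoid, reference
#' permeability, phase-change rate constants for closed (equilibrium) and
#' open (nonequilibrium) pores, the pore-opening and crusting transitions,
#' phase conductivities, gas diffusivities and molar masses. Each value
#' carries a provenance tag (`"paper"`, `"fitted"` or `"literature"`)
#' retrievable with `attr(p, "provenance")`.
#'
#' Temperatures are kelvin throughout; correlations written against Celsius
#' (water-activity coefficients, CO2 generation) convert internally.
#'
#' @param ... named overrides of any default, e.g. `material_params(T_open = 349.15)`.
#' @return An object of class `material_params` (a named list).
#' @examples
#' p <- material_params()
#' p$T_open - 273.15   # pore-opening midpoint, degC
#' @export
material_params <- function(...) {
  defaults <- list(
    rho_s      = 1500,      # solid intrinsic density, kg/m^3
    rho_l      = 1000,      # liquid water density, kg/m^3
    cp_g       = 2030,      # gas specific heat, J/(kg K)
    cp_l       = 4180,      # liquid specific heat, J/(kg K)
    cp_s       = 1800,      # solid specific heat, J/(kg K) (literature fill)
    Lv_ref     = 2.454e6,   # latent heat at T0, J/kg
    T0         = 301.15,    # reference/initial temperature, K (28 degC)
    mu_l_dough = 1e4,       # fluid-like dough viscosity, Pa s
    mu_s_dough = 4.5e6,     # solid-like dough viscosity, Pa s
    mu_g       = 1.8e-5,    # gas viscosity, Pa s
    kappa0     = 8.77e-11,  # reference permeability, m^2
    T_open     = 349.15,    # pore-opening midpoint, K (76 degC, fitted)
    dT_open    = 10,        # pore-opening band width, K (fitted)
    T_tra      = 353.15,    # viscosity transition midpoint, K (80 degC, fitted)
    dT_tra     = 60,        # viscosity transition band width, K (fitted)
    T_c        = 373.15,    # crust temperature, K (100 degC)
    dT_c       = 5,         # crust transition band width, K (design default)
    k_mpc_open   = 0.8,     # nonequilibrium phase-change rate, 1/s (fitted)
    k_mpc_closed = 10,      # equilibrium-limit phase-change rate, 1/s
    emissivity = 0.9,       # surface emissivity (Table 1 eta_eff)
    lambda_s   = 0.20,      # W/(m K) (literature fill)
    lambda_l   = 0.60,      # W/(m K) (literature fill)
    lambda_g   = 0.026,     # W/(m K) (literature fill)
    D_v_ref    = 2.6e-5,    # vapor-air binary diffusivity, m^2/s (literature fill)
    D_co2_ref  = 1.6e-5,    # CO2-air binary diffusivity, m^2/s (literature fill)
    M_h2o      = 0.018,     # kg/mol
    M_co2      = 0.044,     # kg/mol
    M_air      = 0.029,     # kg/mol (inert background species)
    R          = 8.314,     # J/(mol K)
    P_amb      = 101325,    # Pa
    g          = 9.8,       # m/s^2
    # Saturation-pressure Magnus form coefficients (configurable so the
    # literal printed prefactor variant can be selected).
    psat_a     = 610.78,    # Pa
    psat_b     = 17.2694,
    psat_c     = 35.86,     # K offset in the denominator T - psat_c
    # Scale applied to the printed CO2-generation correlation in the source
    # term. The correlation's time/mass base is not stated; at face value
    # (kg/(kg s)) it integrates to ~3.5 kg CO2 per m^3 of dough over the
    # pre-opening bake, several times the total gas inventory a loaf can
    # hold. The scale normalizes the integral to the desorbable dissolved
    # CO2 of fermentation-saturated dough (Henry's law, ~0.65 kg/m^3 at
    # ~30 degC in the 48% liquid fraction): 0.65/3.5 ~= 0.2.
    k_co2_scale = 0.2
  )
  prov <- c(
    rho_s = "paper", rho_l = "paper", cp_g = "paper", cp_l = "paper",
    cp_s = "literature", Lv_ref = "paper", T0 = "paper",
    mu_l_dough = "paper", mu_s_dough = "paper", mu_g = "paper",
    kappa0 = "paper", T_open = "fitted", dT_open = "fitted",
    T_tra = "fitted", dT_tra = "fitted", T_c = "paper", dT_c = "literature",
    k_mpc_open = "fitted", k_mpc_closed = "paper", emissivity = "paper",
    lambda_s = "literature", lambda_l = "literature", lambda_g = "literature",
    D_v_ref = "literature", D_co2_ref = "literature",
    M_h2o = "paper", M_co2 = "paper", M_air = "literature", R = "paper",
    P_amb = "paper", g = "paper", psat_a = "literature", psat_b = "literature",
    psat_c = "paper", k_co2_scale = "literature"
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) stop("unknown material parameter(s): ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
  }
  p <- structure(defaults, class = "material_params", provenance = prov)
  validate_material_params(p)
  p
}

validate_material_params <- function(p) {
  pos <- c("rho_s", "rho_l", "cp_g", "cp_l", "cp_s", "Lv_ref", "mu_l_dough",
           "mu_s_dough", "mu_g", "kappa0", "dT_open", "dT_tra", "dT_c",
           "lambda_s", "lambda_l", "lambda_g", "D_v_ref", "D_co2_ref",
           "M_h2o", "M_co2", "M_air", "R", "P_amb")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("material parameter '", nm, "' must be a positive finite scalar")
  }
  if (p$emissivity <= 0 || p$emissivity > 1) stop("emissivity must lie in (0, 1]")
  if (p$k_mpc_open >= p$k_mpc_closed)
    stop("k_mpc_open must be smaller than k_mpc_closed")
  invisible(p)
}

#' @export
print.material_params <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<material_params>", length(x), "parameters\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %-12g [%s]\n", nm, x[[nm]],
                if (nm %in% names(prov)) prov[[nm]] else "computed"))
  }
  invisible(x)
}
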