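#' Oven environment program
#'
#' Time-dependent boundary environment: oven air temperature, mold wall
#' temperature, effective radiation density, oven vapor/CO2 concentrations
#' and the surface transfer coefficients. `T_air` and `T_wall` may be given
#' as constants or as functions of time (s); [synth_oven_program()] builds
#' the oscillating variant emulating intermittent oven heating.
#'
#' @param T_air oven air temperature, K, or function(t) -> K.
#' @param T_wall mold wall temperature, K, or function(t) -> K. The default
#'   `NULL` uses a first-order lag of `T_air` with time constant `tau_wall`
#'   starting from `T_wall0` (a mold inserted at dough temperature warming
#'   toward the oven setpoint).
#' @param tau_wall mold wall thermal lag, s.
#' @param T_wall0 initial mold wall temperature, K.
#' @param Phi effective radiation density, W/m^2.
#' @param C_oven_v oven water-vapor concentration, mol/m^3.
#' @param C_oven_co2 oven CO2 concentration, mol/m^3 (negligible).
#' @param h_c top-surface convective heat transfer coefficient, W/(m^2 K).
#' @param h_e mold contact heat transfer coefficient, W/(m^2 K).
#' @param coefficients `"analogy"` derives `h_m`, `h_co2` from `h_c` via the
#'   heat-mass analogy; `"constant"` uses the overrides `h_m`, `h_co2`.
#' @param h_m,h_co2 mass transfer coefficient overrides, m/s.
#' @return object of class `oven_program`.
#' @export
oven_program <- function(T_air = 453.15, T_wall = NULL, tau_wall = 250,
                         T_wall0 = 301.15, Phi = 1000,
                         C_oven_v = 0.5, C_oven_co2 = 0,
                         h_c = 10, h_e = 100,
                         coefficients = c("analogy", "constant"),
                         h_m = NULL, h_co2 = NULL) {
  coefficients <- match.arg(coefficients)
  T_air_fun <- if (is.function(T_air)) T_air else {
    stopifnot(T_air > 273.15); local({ Ta <- T_air; function(t) rep(Ta, length(t)) })
  }
  T_wall_fun <- if (is.function(T_wall)) T_wall else if (!is.null(T_wall)) {
    local({ Tw <- T_wall; function(t) rep(Tw, length(t)) })
  } else {
    # first-order response toward the (possibly varying) air temperature;
    # for a constant program this is the exact exponential approach
    local({
      f <- T_air_fun; tw0 <- T_wall0; tau <- tau_wall
      function(t) f(t) + (tw0 - f(t)) * exp(-t / tau)
    })
  }
  if (Phi < 0) stop("Phi must be nonnegative")
  tc <- transfer_coefficients(h_c = h_c, mode = coefficients,
                              h_m = h_m, h_co2 = h_co2)
  structure(list(T_air = T_air_fun, T_wall = T_wall_fun, Phi = Phi,
                 C_oven_v = C_oven_v, C_oven_co2 = C_oven_co2,
                 h_c = tc$h_c, h_m = tc$h_m, h_co2 = tc$h_co2, h_e = h_e),
            class = "oven_program")
}

#' Surface transfer coefficients from the heat-mass analogy
#'
#' Mass transfer coefficients are derived from the natural-convection heat
#' transfer coefficient via the Chilton-Colburn analogy
#' `h_m = h_c / (rho_air c_p,air Le^(2/3))` with species Lewis numbers
#' (vapor ~ 1.05, CO2 ~ 1.5 in hot air). `mode = "constant"` returns the
#' supplied overrides unchanged.
#'
#' @param h_c heat transfer coefficient, W/(m^2 K).
#' @param mode `"analogy"` or `"constant"`.
#' @param h_m,h_co2 overrides used in constant mode, m/s.
#' @param rho_air,cp_air hot-air properties used by the analogy.
#' @param Le_v,Le_co2 species Lewis numbers.
#' @return list with `h_c`, `h_m`, `h_co2`.
#' @export
transfer_coefficients <- function(h_c = 10, mode = c("analogy", "constant"),
                                  h_m = NULL, h_co2 = NULL,
                                  rho_air = 0.78, cp_air = 1009,
                                  Le_v = 1.05, Le_co2 = 1.5) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    if (is.null(h_m) || is.null(h_co2))
      stop("constant mode requires h_m and h_co2 overrides")
    return(list(h_c = h_c, h_m = h_m, h_co2 = h_co2))
  }
  base <- h_c / (rho_air * cp_air)
  list(h_c = h_c, h_m = base / Le_v^(2 / 3), h_co2 = base / Le_co2^(2 / 3))
}

#' Synthetic oscillating oven program
#'
#' Deterministic-for-seed stand-in for measured intermittent-heating traces:
#' a mean-zero triangular oscillation of given amplitude and period about
#' the setpoint (the seed sets the oscillation phase), optionally preceded
#' by a first-order warm-up, with the mold-wall trace generated as the
#' lagged low-pass of the air trace. Zero amplitude reproduces a constant
#' program.
#'
#' @param setpoint oven setpoint, K.
#' @param amplitude oscillation amplitude, K, >= 0.
#' @param period oscillation period, s.
#' @param seed integer seed fixing the oscillation phase.
#' @param warmup_tau first-order warm-up time constant, s (0 = preheated).
#' @param T_start air temperature before warm-up, K.
#' @param ... further arguments passed to [oven_program()] (e.g. `tau_wall`).
#' @return an `oven_program`.
#' @export
synth_oven_program <- function(setpoint = 453.15, amplitude = 5, period = 120,
                               seed = 0, warmup_tau = 0, T_start = 301.15, ...) {
  if (amplitude < 0) stop("amplitude must be nonnegative")
  if (period <= 0) stop("period must be positive")
  phase <- if (amplitude > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    ph <- stats::runif(1)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    ph
  } else 0
  T_air_fun <- local({
    sp <- setpoint; A <- amplitude; P <- period; ph <- phase
    wt <- warmup_tau; ts <- T_start
    function(t) {
      x <- (t / P + ph) %% 1
      tri <- ifelse(x < 0.5, 4 * x - 1, 3 - 4 * x)   # mean-zero triangle in [-1, 1]
      base <- if (wt > 0) sp + (ts - sp) * exp(-t / wt) else rep(sp, length(t))
      base + A * tri
    }
  })
  oven_program(T_air = T_air_fun, ...)
}

#' Liquid-water boundary flux at the bread/air interface
#'
#' Evaporative loss through natural convection while surface pores are
#' closed, `j_l,b = (1 - alpha) h_m M_H2O (a_w C_sat - C_oven,v)`; gated off
#' once the surface opens (vapor convection takes over).
#'
#' @param T,W surface-cell temperature (K) and dry-basis moisture.
#' @param alpha surface pore-opening fraction.
#' @param oven an [oven_program()].
#' @param params a [material_params()].
#' @return outward-positive mass flux, kg/(m^2 s).
#' @export
liquid_boundary_flux <- function(T, W, alpha, oven, params = material_params()) {
  Tc <- pmin(pmax(T, 274), 423)
  aw <- dough_water_activity(W, T)
  (1 - alpha) * oven$h_m * params$M_h2o *
    (aw * saturation_concentration(Tc, params) - oven$C_oven_v)
}

#' Vapor boundary flux at the bread/air interface
#'
#' `j_v,b = alpha h_m M_H2O (C_v - C_oven,v)`: convective vapor exchange
#' through open surface pores.
#'
#' @param C_v surface-cell vapor concentration, mol/m^3.
#' @param alpha surface pore-opening fraction.
#' @inheritParams liquid_boundary_flux
#' @return outward-positive mass flux, kg/(m^2 s).
#' @export
vapor_boundary_flux <- function(C_v, alpha, oven, params = material_params()) {
  alpha * oven$h_m * params$M_h2o * (C_v - oven$C_oven_v)
}

#' CO2 boundary flux at the bread/air interface
#'
#' `j_CO2,b = alpha h_CO2 M_CO2 (C_CO2 - C_oven,CO2)`.
#'
#' @param C_co2 surface-cell CO2 concentration, mol/m^3.
#' @inheritParams vapor_boundary_flux
#' @return outward-positive mass flux, kg/(m^2 s).
#' @export
co2_boundary_flux <- function(C_co2, alpha, oven, params = material_params()) {
  alpha * oven$h_co2 * params$M_co2 * (C_co2 - oven$C_oven_co2)
}

# Inert-air exchange with the oven atmosphere (same convective pathway as
# CO2). The oven air concentration closes the ambient pressure at the oven
# air temperature.
air_boundary_flux <- function(C_air, alpha, oven, t, params = material_params()) {
  C_oven_air <- params$P_amb / (params$R * oven$T_air(t)) -
    oven$C_oven_v - oven$C_oven_co2
  alpha * oven$h_co2 * params$M_air * (C_air - C_oven_air)
}

#' Heat flux into the bread surface
#'
#' Top (bread/air) face: convection + net gray-surface radiation
#' `epsilon (Phi - sigma T^4)` minus evaporative cooling of the liquid
#' boundary flux. Mold faces (`bottom_mold`, `side_mold`): contact
#' conduction `h_e (T_w - T)`.
#'
#' @param T surface temperature, K.
#' @param oven an [oven_program()].
#' @param tag `"top_air"`, `"bottom_mold"` or `"side_mold"`.
#' @param t time, s (for the programmed oven trace).
#' @param j_l_b evaporative liquid boundary flux, kg/(m^2 s) (top face only).
#' @param params a [material_params()].
#' @return inward-positive heat flux, W/m^2.
#' @export
heat_boundary_flux <- function(T, oven, tag, t = 0, j_l_b = 0,
                               params = material_params()) {
  sigma <- 5.670374419e-8
  switch(tag,
    top_air = oven$h_c * (oven$T_air(t) - T) +
      params$emissivity * (oven$Phi - sigma * T^4) -
      j_l_b * latent_heat(T, params),
    bottom_mold = ,
    side_mold = oven$h_e * (oven$T_wall(t) - T),
    stop("unknown boundary tag: ", tag)
  )
}
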