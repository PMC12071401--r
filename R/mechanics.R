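#' Mechanics configuration
#'
#' Settings for the dough momentum / mesh-motion solve. Inertia is dropped
#' by default (creeping flow: at viscosities of 1e4 Pa s and above and
#' centimetre scales the inertial terms are ~10 orders below the viscous
#' ones); the flag is retained for fidelity to the full momentum balance
#' but only scales the quasi-static solution's applicability check.
#'
#' @param mode volumetric closure: `"pressure_driven"` (closed-pore gauge
#'   pressure drives viscous volumetric creep; gas obeys the ideal-gas law
#'   locally) or `"prescribed_divergence"` (the divergence is imposed from
#'   the local ideal-gas volume balance at ambient pressure).
#' @param gravity include the overburden weight (enables the slight
#'   post-opening collapse).
#' @param inertia retained for interface completeness; must be FALSE.
#' @param e_max expansion strain-rate cap, 1/s (mesh-quality guard).
#' @param e_min compression strain-rate cap, 1/s (positive number). The
#'   cell-wall network resists buckling, so pores are not crushed at the
#'   shear-viscosity rate; the observed gravitational settling of a baked
#'   loaf is a fraction of a millimetre (strain rates ~2e-5 1/s), which
#'   this cap respects with a factor-of-five margin.
#' @param bulk_factor ratio of the volumetric viscous resistance to
#'   `mu_eff`; 4/3 is the uniaxial-extension value of the compressible
#'   Newtonian stress with free lateral confinement released vertically.
#' @return object of class `mechanics_config`.
#' @export
mechanics_config <- function(mode = c("pressure_driven", "prescribed_divergence"),
                             gravity = TRUE, inertia = FALSE,
                             e_max = 0.3, e_min = 1e-4, bulk_factor = 4 / 3) {
  mode <- match.arg(mode)
  if (inertia) stop("inertial mechanics is not implemented (creeping flow only)")
  if (e_max <= 0 || e_min <= 0 || bulk_factor <= 0)
    stop("e_max, e_min and bulk_factor must be positive")
  structure(list(mode = mode, gravity = gravity, inertia = inertia,
                 e_max = e_max, e_min = e_min, bulk_factor = bulk_factor),
            class = "mechanics_config")
}

# Overburden normal stress at each cell centre (Pa): weight per unit area of
# the material above, plus half the cell's own slab.
overburden_stress <- function(state, grid, params) {
  Mtot <- state$M_s + state$M_l + state$M_v + state$M_c + state$M_a
  w <- Mtot / grid$A_z * params$g            # slab weights, Pa
  above <- t(apply(w, 1, function(x) rev(cumsum(rev(x))))) - 0.5 * w
  if (grid$nr == 1L) above <- matrix(above, 1L)  # apply() drops dims for nr = 1
  above
}

#' Quasi-static dough mechanics on the column grid
#'
#' Creeping compressible viscous flow in the slender-column reduction:
#' the dough is confined laterally by the mold (no-slip bottom, slip side
#' walls, free top surface), so deformation is vertical and the volumetric
#' strain rate is the vertical stretching rate. In `pressure_driven` mode
#' each cell creeps at
#' `e = (P_g - P_amb - overburden) / (bulk_factor mu_eff + P_g dt)`,
#' the extensional viscous balance of the deviatoric Newtonian stress with
#' the gas gauge-pressure body force; the `P_g dt` term is a semi-implicit
#' stabilization of the gas stiffness (exact in the dt -> 0 limit). In
#' `prescribed_divergence` mode the divergence is imposed by relaxing the
#' gas volume toward its ideal-gas value at ambient pressure.
#'
#' Velocity is zero whenever the gauge forcing vanishes (and gravity is
#' off), halves when `mu_eff` doubles, is zero at the no-slip bottom and
#' maximal at the free surface.
#'
#' @param state a `field_state`.
#' @param grid the matching `bake_grid`.
#' @param params a [material_params()].
#' @param config a [mechanics_config()].
#' @param dt time-step used for the semi-implicit stabilization, s.
#' @param derived optional precomputed [derived_fields()] result.
#' @return list with `e` (volumetric strain rate, 1/s, `nr x nz`), `v_top`
#'   (vertical velocity at each cell's upper face, m/s) and `p` (the
#'   mechanical pressure field, taken up by the gauge forcing).
#' @export
solve_mechanics <- function(state, grid, params = material_params(),
                            config = mechanics_config(), dt = 0,
                            derived = NULL) {
  d <- if (is.null(derived)) derived_fields(state, grid, params) else derived
  if (any(d$mu_eff <= 0)) stop("mu_eff must be positive")
  load <- if (config$gravity) overburden_stress(state, grid, params) else 0
  if (config$mode == "pressure_driven") {
    gauge <- d$P_g - params$P_amb - load
    # the P_g dt / f_vg term is the linearized gas stiffness (compressing the
    # cell compresses only its gas), a semi-implicit damping exact as dt -> 0
    e <- gauge / (config$bulk_factor * d$mu_eff + d$P_g / pmax(d$f_vg, 1e-3) * dt)
  } else {
    # imposed divergence: gas volume relaxes to n R T / P_amb
    V_star <- (state$M_v / params$M_h2o + state$M_c / params$M_co2 +
                 state$M_a / params$M_air) * params$R * state$T / params$P_amb
    rate <- 0.2                               # 1/s, relaxation of the volume defect
    e <- (V_star - d$V_g) / d$V * rate
    if (config$gravity) e <- e - load / (config$bulk_factor * d$mu_eff)
  }
  # only closed-pore gauge pressure pushes the matrix: once pores open and
  # interconnect, gas vents through the network instead of straining the
  # walls, and expansion ceases (gate positive strain by 1 - alpha)
  e <- ifelse(e > 0, e * (1 - d$alpha), e)
  e <- pmin(pmax(e, -config$e_min), config$e_max)
  # dried matrix is solid (moisture loss completes solidification): no creep
  e[d$W < 0.05] <- 0
  # mesh-quality guard: a single cell may not stretch beyond 4x its initial
  # spacing (absent neighbor shear coupling, expansion must stay distributed)
  e[grid$h > 4 * grid$dz0 & e > 0] <- 0
  # matrix rigidity floor: pores cannot be squeezed shut mechanically
  e[d$f_vg < 0.05 & e < 0] <- 0
  # columns may not outgrow the mold
  over <- column_heights(grid) >= grid$mold_height
  if (any(over)) e[over, ] <- pmin(e[over, ], 0)
  v_top <- t(apply(e * grid$h, 1, cumsum))
  if (grid$nr == 1L) v_top <- matrix(v_top, 1L)
  list(e = e, v_top = v_top, p = d$P_g - params$P_amb)
}

#' Move the mesh under a volumetric strain-rate field
#'
#' Vertical-Lagrangian update `h <- h exp(e dt)` per cell: boundary nodes
#' advect with the flow, masses are untouched so every extensive quantity
#' is conserved identically under pure mesh motion; apparent densities
#' rescale by the inverse volume change. Cell heights are floored at 5% of
#' the initial spacing (tangling guard).
#'
#' @param grid a `bake_grid`.
#' @param e volumetric strain-rate field, 1/s (`nr x nz`).
#' @param dt time step, s, > 0.
#' @return the updated grid.
#' @export
move_mesh <- function(grid, e, dt) {
  if (dt <= 0) stop("dt must be positive")
  h_new <- grid$h * exp(e * dt)
  if (any(!is.finite(h_new)) || any(h_new <= 0)) stop("mesh motion produced invalid cell heights")
  grid$h <- pmax(h_new, 0.05 * grid$dz0)
  grid
}
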