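#' Default baking scenario
#'
#' The calibrated reference scenario: a 100 mm diameter, 20 mm tall dough
#' cylinder at 28 degC, dry-basis moisture 0.82 and density 1069 kg/m^3,
#' baked for 1800 s in a 180 degC oven with mold-wall lag, effective
#' radiation density 1000 W/m^2 and dry oven air. Every entry can be
#' overridden from YAML via [load_scenario()] or programmatically by
#' modifying the returned list.
#'
#' @return nested named list of class `bake_scenario`.
#' @export
default_scenario <- function() {
  structure(list(
    geometry = list(radius = 0.05, height = 0.020, mold_height = 0.100),
    initial = list(T0 = 301.15, W0 = 0.82, rho_eff0 = 1069, P_co2_0 = NULL),
    material = list(),                      # material_params() overrides
    oven = list(T_air = 453.15, tau_wall = 250, T_wall0 = 301.15,
                Phi = 1000, C_oven_v = 0.5, C_oven_co2 = 0,
                h_c = 10, h_e = 100, amplitude = 0, period = 120, seed = 0),
    solver = list(dt_max = 0.5, t_end = 1800, cadence = 10,
                  gas_mode = "darcy", convention = "budget"),
    mechanics = list(mode = "pressure_driven", gravity = TRUE),
    mesh = list(mode = "axisym2d", nr = 10, nz = 20),
    output = list(snapshot_times = c(300, 600, 900, 1200))
  ), class = "bake_scenario")
}

# strict recursive merge: every key in `user` must exist in `defaults`
# (material overrides are checked against material_params() instead).
.merge_scenario <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- paste0(path, nm)
    if (!nm %in% names(defaults))
      stop("unknown scenario key: '", here, "'")
    if (is.list(defaults[[nm]]) && nm != "material") {
      if (!is.list(user[[nm]]))
        stop("scenario key '", here, "' must be a mapping")
      defaults[[nm]] <- .merge_scenario(defaults[[nm]], user[[nm]],
                                        paste0(here, "$"))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a scenario from a YAML file
#'
#' Reads a (possibly empty) YAML file and resolves it against
#' [default_scenario()]. Unknown keys are an error (no silent typos);
#' material overrides are validated by [material_params()].
#'
#' @param path YAML file path.
#' @return resolved `bake_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  sc <- .merge_scenario(unclass(default_scenario()), user)
  if (sc$geometry$radius <= 0 || sc$geometry$height <= 0)
    stop("scenario geometry must be positive")
  # validate material overrides early
  do.call(material_params, sc$material)
  structure(sc, class = "bake_scenario")
}

# Build the runtime objects (grid, state, params, oven, control, mech) from
# a scenario; shared by run_scenario and the sweep.
.assemble <- function(scenario, mode = NULL, mesh_level = NULL) {
  sc <- scenario
  if (!is.null(mode)) sc$mesh$mode <- mode
  if (!is.null(mesh_level)) {
    sc$mesh$nr <- 2L + 4L * mesh_level
    sc$mesh$nz <- 8L + 6L * mesh_level
  }
  params <- do.call(material_params, sc$material)
  grid <- make_grid(sc$mesh$mode, sc$mesh$nr, sc$mesh$nz,
                    radius = sc$geometry$radius, height = sc$geometry$height,
                    mold_height = sc$geometry$mold_height)
  state <- initialize_state(grid, params, T0 = sc$initial$T0,
                            W0 = sc$initial$W0, rho_eff0 = sc$initial$rho_eff0,
                            P_co2_0 = sc$initial$P_co2_0)
  ov <- sc$oven
  oven <- if (ov$amplitude > 0) {
    synth_oven_program(setpoint = ov$T_air, amplitude = ov$amplitude,
                       period = ov$period, seed = ov$seed,
                       tau_wall = ov$tau_wall, T_wall0 = ov$T_wall0,
                       Phi = ov$Phi, C_oven_v = ov$C_oven_v,
                       C_oven_co2 = ov$C_oven_co2, h_c = ov$h_c, h_e = ov$h_e)
  } else {
    oven_program(T_air = ov$T_air, tau_wall = ov$tau_wall, T_wall0 = ov$T_wall0,
                 Phi = ov$Phi, C_oven_v = ov$C_oven_v,
                 C_oven_co2 = ov$C_oven_co2, h_c = ov$h_c, h_e = ov$h_e)
  }
  control <- solver_config(dt_max = sc$solver$dt_max, t_end = sc$solver$t_end,
                           cadence = sc$solver$cadence,
                           gas_mode = sc$solver$gas_mode,
                           convention = sc$solver$convention)
  mech <- mechanics_config(mode = sc$mechanics$mode,
                           gravity = sc$mechanics$gravity)
  list(scenario = sc, params = params, grid = grid, state = state,
       oven = oven, control = control, mech = mech)
}

#' Run a scenario end to end
#'
#' @param scenario a `bake_scenario` (see [default_scenario()],
#'   [load_scenario()]).
#' @param mode optional mesh-mode override (`"axial1d"`, `"axisym2d"`).
#' @param mesh_level optional resolution level (1 = coarse, 2 = default
#'   working resolution, 3 = fine); sets `nr = 2 + 4 level`,
#'   `nz = 8 + 6 level`.
#' @param progress print progress lines.
#' @return a `bake_run` with the resolved scenario attached as attribute
#'   `"scenario"`.
#' @export
run_scenario <- function(scenario = default_scenario(), mode = NULL,
                         mesh_level = NULL, progress = FALSE) {
  a <- .assemble(scenario, mode, mesh_level)
  run <- run_bake(a$grid, a$state, a$oven, a$params, a$control, a$mech,
                  snapshot_times = a$scenario$output$snapshot_times,
                  progress = progress)
  attr(run, "scenario") <- a$scenario
  run
}

#' Summarize a baking run
#'
#' Headline diagnostics of a completed run: liquid-water loss, height and
#' volume extrema, the P1 gauge-pressure peak, the doneness time (minimum
#' domain temperature crossing 93 degC), the closed-pore vapor mole
#' fraction statistics, the ECD conductivity share maximum and the crumb
#' moisture peak.
#'
#' @param run a `bake_run`.
#' @return named list of scalars (heights mm, masses g, pressure Pa,
#'   times s, shares as fractions).
#' @export
summarize_run <- function(run) {
  dg <- run$diagnostics
  n <- nrow(dg)
  first_cross <- function(x, thr) {
    i <- which(x >= thr)[1]
    if (is.na(i)) NA_real_ else dg$t[i]
  }
  open_i <- which(dg$all_open)[1]
  pre <- if (is.na(open_i)) seq_len(n) else seq_len(max(open_i - 1L, 1L))
  peak_i <- which.max(dg$P1_gauge)
  late <- dg$t > 900
  list(
    final_liquid_loss_g = 1000 * (dg$liquid_mass[1] - dg$liquid_mass[n]),
    initial_liquid_g = 1000 * dg$liquid_mass[1],
    max_axis_height_mm = 1000 * max(dg$axis_height),
    side_height_plateau_mm = 1000 *
      (if (any(late)) mean(dg$side_height[late]) else dg$side_height[n]),
    peak_P1_gauge_Pa = dg$P1_gauge[peak_i],
    peak_P1_time_s = dg$t[peak_i],
    t_doneness_93C_s = first_cross(dg$min_T, 366.15),
    mean_xv_closed = mean(dg$xv_closed[pre], na.rm = TRUE),
    t_xv_80pct_s = first_cross(ifelse(is.na(dg$xv_closed), -Inf, dg$xv_closed), 0.8),
    max_edc_share = max(dg$edc_share_max, na.rm = TRUE),
    final_volume_ratio = dg$volume_ratio[n],
    max_crumb_W = max(dg$max_W_crumb, na.rm = TRUE),
    t_all_open_s = if (is.na(open_i)) NA_real_ else dg$t[open_i],
    water_balance_error = run$budget$water_balance_error
  )
}

#' Run the reference baking scenario and emit a report
#'
#' Convenience wrapper: runs [default_scenario()] (or an override) in the
#' requested mode/resolution and writes, when `out_dir` is given, the
#' diagnostics CSV, VTK snapshots (2-D mode), the scenario echo and a
#' summary JSON.
#'
#' @inheritParams run_scenario
#' @param out_dir optional output directory.
#' @return list with `run` (the `bake_run`) and `summary`
#'   (see [summarize_run()]).
#' @export
run_paper_scenario <- function(mode = c("axisym2d", "axial1d"), mesh_level = 2,
                               scenario = default_scenario(), out_dir = NULL,
                               progress = FALSE) {
  mode <- match.arg(mode)
  run <- run_scenario(scenario, mode = mode, mesh_level = mesh_level,
                      progress = progress)
  summ <- summarize_run(run)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_diagnostics_csv(run, file.path(out_dir, "diagnostics.csv"))
    yaml::write_yaml(unclass(attr(run, "scenario")),
                     file.path(out_dir, "scenario.yaml"))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (mode == "axisym2d") {
      for (nm in names(run$snapshots))
        write_vtk_snapshot(run$snapshots[[nm]], run$grid,
                           file.path(out_dir, paste0("snapshot_", nm, "s.vtk")))
    }
  }
  list(run = run, summary = summ)
}

#' Sweep a scalar parameter across a set of values
#'
#' Runs one simulation per value (overriding the named material parameter
#' or scenario scalar) and tabulates the summary metrics, for sensitivity
#' studies such as the pore-opening temperature or the open-pore
#' phase-change rate constant.
#'
#' @param parameter name of a [material_params()] entry (e.g. `"T_open"`,
#'   `"k_mpc_open"`, `"dT_tra"`).
#' @param values numeric vector of values (kelvin for temperatures).
#' @param scenario base scenario.
#' @param mode mesh mode for the sweep runs (1-D axial by default: the
#'   radial structure is secondary for tall-rise diagnostics and the sweep
#'   stays fast).
#' @param mesh_level resolution level.
#' @return data.frame: one row per value with the [summarize_run()] metrics.
#' @export
sweep_parameter <- function(parameter, values, scenario = default_scenario(),
                            mode = "axial1d", mesh_level = 1) {
  stopifnot(is.character(parameter), length(parameter) == 1L)
  if (!parameter %in% names(material_params()))
    stop("'", parameter, "' is not a registered material parameter")
  rows <- lapply(values, function(v) {
    sc <- scenario
    sc$material[[parameter]] <- v
    s <- summarize_run(run_scenario(sc, mode = mode, mesh_level = mesh_level))
    cbind(data.frame(value = v), as.data.frame(s))
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- parameter
  out
}
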