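p <- material_params()

# an oven in full equilibrium with the initial dough (no driving force)
matched_oven <- function(T0 = 301.15, W0 = 0.82) {
  aw <- water_activity(W0, T0)
  oven_program(T_air = T0, T_wall = T0, Phi = 5.670374419e-8 * T0^4,
               C_oven_v = aw * saturation_concentration(T0, material_params()),
               h_c = 1e-9, h_e = 0)
}

test_that("boundary fluxes vanish simultaneously at full equilibrium", {
  ov <- matched_oven()
  aw <- water_activity(0.82, 301.15)
  Cv <- aw * saturation_concentration(301.15, p)
  expect_equal(liquid_boundary_flux(301.15, 0.82, 0, ov, p), 0, tolerance = 1e-15)
  expect_equal(vapor_boundary_flux(Cv, 1, ov, p), 0, tolerance = 1e-15)
  expect_equal(co2_boundary_flux(0, 1, ov, p), 0, tolerance = 1e-15)
  expect_equal(heat_boundary_flux(301.15, ov, "top_air", 0, 0, p), 0,
               tolerance = 1e-9)
  expect_equal(heat_boundary_flux(301.15, ov, "bottom_mold", 0, 0, p), 0)
})

test_that("boundary fluxes follow the printed forms and gates", {
  ov <- oven_program()
  # alpha gates: open surface has no liquid flux, closed surface no gas flux
  expect_identical(liquid_boundary_flux(350, 0.8, 1, ov, p), 0)
  expect_identical(vapor_boundary_flux(10, 0, ov, p), 0)
  expect_identical(co2_boundary_flux(5, 0, ov, p), 0)
  expect_gt(co2_boundary_flux(5, 1, ov, p), 0)   # outward for interior excess
  # evaporative flux magnitude at a boiling wet surface
  j <- liquid_boundary_flux(373.15, 3, 0, ov, p)   # W large -> a_w ~ 1
  aw <- water_activity(3, 373.15)
  expect_equal(j, ov$h_m * p$M_h2o * (aw * saturation_concentration(373.15, p) - 0.5),
               tolerance = 1e-12)
  # net radiation at 100 degC under the measured radiation density
  q <- heat_boundary_flux(373.15, oven_program(h_c = 0, Phi = 1000), "top_air", 0, 0, p)
  expect_equal(q, 0.9 * (1000 - 5.670374419e-8 * 373.15^4), tolerance = 1e-6)
  expect_equal(q, -89.5, tolerance = 1e-2)
  # mold contact conduction with the stated coefficient
  ovw <- oven_program(T_wall = 373.15, h_e = 100)
  expect_equal(heat_boundary_flux(323.15, ovw, "side_mold", 0, 0, p), 5000)
  expect_error(heat_boundary_flux(300, ov, "left_wall"), "tag")
})

test_that("transfer coefficients follow the heat-mass analogy", {
  tc <- transfer_coefficients(h_c = 10, mode = "constant", h_m = 0.02, h_co2 = 0.01)
  expect_identical(tc$h_m, 0.02)
  a1 <- transfer_coefficients(h_c = 10)
  a2 <- transfer_coefficients(h_c = 20)
  expect_equal(a2$h_m / a1$h_m, 2)           # linear in h_c
  le1 <- transfer_coefficients(h_c = 10, Le_v = 1, rho_air = 1, cp_air = 1000)
  expect_equal(le1$h_m, 10 / 1000)           # Le = 1 analogy limit
})

test_that("the synthetic oven program is deterministic and mean-preserving", {
  ovc <- synth_oven_program(setpoint = 453.15, amplitude = 0)
  expect_equal(ovc$T_air(c(0, 100, 500)), rep(453.15, 3))
  ov1 <- synth_oven_program(amplitude = 8, period = 120, seed = 7)
  ov2 <- synth_oven_program(amplitude = 8, period = 120, seed = 7)
  tt <- seq(0, 600, by = 1)
  expect_identical(ov1$T_air(tt), ov2$T_air(tt))
  ov3 <- synth_oven_program(amplitude = 8, period = 120, seed = 8)
  expect_false(identical(ov1$T_air(tt), ov3$T_air(tt)))
  # mean over one period stays at the setpoint (quadrature)
  tp <- seq(0, 120, length.out = 2401)
  expect_equal(mean(ov1$T_air(tp)), 453.15, tolerance = 0.01 * 453.15)
  expect_lt(abs(mean(ov1$T_air(tp)) - 453.15), 0.5)
  # mold wall is a lagged first-order trace rising from the dough temperature
  expect_equal(ov1$T_wall(0), 301.15, tolerance = 1e-6)
  expect_gt(ov1$T_wall(500), ov1$T_wall(100))
  expect_lt(ov1$T_wall(250), 453.15)
  expect_error(synth_oven_program(amplitude = -1), "amplitude")
})
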