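test_that("Carreau-Yasuda viscosity matches its closed form and limits", {
  cy <- carreau_yasuda_params()
  expect_equal(cy_viscosity(0, cy), 56e-3)
  expect_lt(abs(cy_viscosity(1e6, cy) - 3.45e-3) / 3.45e-3, 0.01)
  # direct evaluation at gamma = 1/lambda
  g <- 1 / cy$lambda
  mu_ref <- 3.45e-3 + (56e-3 - 3.45e-3) * 2^((cy$n - 1) / 2)
  expect_equal(cy_viscosity(g, cy), mu_ref, tolerance = 1e-12)
  expect_equal(mu_ref, 45.5e-3, tolerance = 1e-3)
  expect_error(cy_viscosity(-1, cy), "non-negative")
})

test_that("viscosity is continuous, decreasing, bounded on a log grid", {
  cy <- carreau_yasuda_params()
  g <- 10^seq(-3, 6, length.out = 200)
  mu <- cy_viscosity(g, cy)
  expect_true(all(diff(mu) < 0))
  expect_true(all(mu >= cy$mu_inf & mu <= cy$mu_0))
  props <- fluid_props(rheology = "newtonian")
  expect_equal(effective_viscosity(g, props), rep(3.5e-3, length(g)))
})

test_that("inlet waveform reproduces the printed piecewise form", {
  w <- inlet_waveform(smoothing_window = 0)
  expect_equal(inlet_velocity(0.5, w), 0.1)
  expect_equal(inlet_velocity(0, w), 0.5 * sin(0.0160236))
  tt <- seq(0, 1, by = 1e-4)
  u <- inlet_velocity(tt, w)
  expect_equal(max(u), 0.5, tolerance = 1e-6)
  expect_equal(tt[which.max(u)], (pi / 2 - 0.0160236) / (4 * pi),
               tolerance = 1e-3)
  expect_true(all(u >= 0))
  # periodicity
  expect_equal(inlet_velocity(tt + 3, w), u)
  # discontinuity magnitude at end of systole
  jump <- 0.5 * sin(4 * pi * 0.218 + 0.0160236) - 0.1
  expect_equal(jump, 0.088, tolerance = 5e-3)
  expect_equal(inlet_velocity(0.218 - 1e-9, w) - inlet_velocity(0.218 + 1e-9, w),
               jump, tolerance = 1e-6)
})

test_that("smoothed waveform is continuous and preserves the cycle integral", {
  ws <- inlet_waveform()            # 10 ms blend
  w0 <- inlet_waveform(smoothing_window = 0)
  tt <- seq(0, 1, by = 1e-5)
  us <- inlet_velocity(tt, ws)
  expect_lt(max(abs(diff(us))), 0.01)   # no jumps at 10 us resolution
  expect_lt(abs(waveform_mean(ws) - waveform_mean(w0)) / waveform_mean(w0),
            0.01)
  # peak-rescaling helper
  w7 <- scale_waveform_peak(ws, 0.7)
  expect_equal(max(inlet_velocity(tt, w7)), 0.7, tolerance = 1e-3)
})

test_that("dimensionless numbers match independent hand evaluation", {
  p38 <- fluid_props(mu = 3.8e-3)
  expect_equal(womersley_number(6.35e-3, 1, p38),
               (6.35e-3 / 2) * sqrt(2 * pi * 1060 / 3.8e-3),
               tolerance = 1e-12)
  expect_equal(womersley_number(6.35e-3, 1, p38), 4.2, tolerance = 0.01)
  expect_equal(womersley_number(6.35e-3, 1, fluid_props(mu = 3e-3)), 4.73,
               tolerance = 1e-2)
  expect_lt(womersley_number(6.35e-3, 1,
                             fluid_props(mu = 1e3, validate = FALSE)), 1e-2)
  expect_equal(reynolds_number(0.5, 6.35e-3, fluid_props()), 961.57,
               tolerance = 1e-4)
  expect_equal(reynolds_number(0, 6.35e-3, fluid_props()), 0)
  expect_equal(reynolds_number(0.5, 6.35e-3, fluid_props(mu = 3e-3)),
               1121.83, tolerance = 1e-4)
  expect_equal(dean_number(500, 1e-3, 5e-3), 500 * sqrt(0.1))
  expect_equal(dean_number(1000, 1e-3, 5e-3) / dean_number(500, 1e-3, 5e-3), 2)
  expect_lt(dean_number(500, 1e-3, 1e8), 1e-2)
})

test_that("vortex formation time matches the closed-form cycle integral", {
  w <- inlet_waveform(smoothing_window = 0)
  # independent closed form: systolic sine integral + plateau
  sys_int <- (0.5 / (4 * pi)) * (cos(0.0160236) - cos(4 * pi * 0.218 + 0.0160236))
  plat_int <- 0.1 * (1 - 0.218)
  vft_ref <- (sys_int + plat_int) / 6.35e-3
  expect_equal(vortex_formation_time(w, 6.35e-3), vft_ref, tolerance = 1e-3)
  expect_equal(vft_ref, 24.4, tolerance = 1e-2)
  expect_equal(vortex_formation_time(w, 2 * 6.35e-3) * 2,
               vortex_formation_time(w, 6.35e-3))
})

test_that("fluid property validation enforces the physiological band", {
  expect_error(fluid_props(mu = 5e-3), "physiological")
  expect_silent(fluid_props(mu = 5e-3, validate = FALSE))
  expect_error(carreau_yasuda_params(mu_inf = 0.06, mu_0 = 0.056))
})
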