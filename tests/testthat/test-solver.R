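test_that("steady channel flow reproduces plane Poiseuille", {
  st <- channel_steady()
  m <- channel_mesh()
  # centerline velocity = 1.5 x mean, measured as the vertex of a
  # quadratic fit through the nodal mid-channel profile
  sel <- abs(m$nodes[, 1] - 10e-3) < 1e-9
  yy <- m$nodes[sel, 2]; uu <- st$ux[sel, 1]
  fit <- stats::lm(uu ~ yy + I(yy^2))
  ctr <- unname(fit$coefficients[1] - fit$coefficients[2]^2 /
                  (4 * fit$coefficients[3]))
  expect_equal(ctr, 0.15, tolerance = 0.01)
  # wall shear stress 6 mu u / h within 2% away from the ends
  w <- wall_shear_stress(st)
  wp <- w$probes
  interior <- wp$x > 5e-3 & wp$x < 15e-3
  tau_ref <- 6 * 3.5e-3 * 0.1 / 2e-3
  expect_equal(abs(w$wss[interior, 1]), rep(tau_ref, sum(interior)),
               tolerance = 0.02)
  # global mass balance to solver precision
  expect_lt(max(st$diagnostics$mass_defect), 1e-10)
})

test_that("mirror-symmetric bifurcation splits the flow 50/50", {
  cf <- bifurcation_config(d_ica_distal = 3.5e-3, d_eca_distal = 3.5e-3,
                           L_ica = 20e-3, L_eca = 20e-3,
                           angle_split = 0.5, bulb_diameter_factor = 1)
  m <- generate_mesh(build_outline(cf), 8e-4)
  st <- solve_steady(m, 0.15, fluid_props(), solver_settings())
  fs <- flow_split(st)
  expect_equal(fs$ica_fraction, 0.5, tolerance = 0.01)
  # cross-axis velocity is mirror-antisymmetric: uy ~ 0 on the axis
  axis_pts <- seq(2e-3, 30e-3, length.out = 15)
  uy <- interpolate_field(m, st$uy[, 1], axis_pts, rep(0, 15))
  expect_lt(max(abs(uy)), 0.01 * max(abs(st$ux)))
})

test_that("pulsatile channel flow matches the Womersley series solution", {
  bench <- womersley_bench()
  expect_lt(womersley_rms(bench), 0.03)
  expect_lt(max(bench$field$diagnostics$mass_defect), 1e-3)
})

test_that("zero inflow produces a zero field", {
  mc <- channel_mesh()
  still <- solver_settings(dt = 5e-3, n_cycles = 1,
                           inlet_profile_fun = function(y, t) rep(0, length(y)))
  fl <- solve_pulsatile(mc, inlet_waveform(), newtonian(), still,
                        outlet_pressure = 0)
  expect_lt(max(abs(fl$ux)), 1e-12)
  expect_lt(max(abs(fl$uy)), 1e-12)
})

test_that("no-slip holds on wall nodes and the solve is deterministic", {
  fl <- bif_pulsatile_coarse()
  m <- bif_mesh_coarse()
  wall <- unique(c(m$boundary_edges$n1[m$boundary_edges$tag == "WALL"],
                   m$boundary_edges$n2[m$boundary_edges$tag == "WALL"]))
  expect_lt(max(abs(fl$ux[wall, ])), 1e-10)
  expect_lt(max(abs(fl$uy[wall, ])), 1e-10)
  expect_lt(max(fl$diagnostics$mass_defect), 1e-3)
  # determinism on a cheap rerun
  mc <- channel_mesh()
  s <- solver_settings(dt = 5e-3, n_cycles = 1)
  f1 <- solve_pulsatile(mc, inlet_waveform(), newtonian(), s)
  f2 <- solve_pulsatile(mc, inlet_waveform(), newtonian(), s)
  expect_lt(max(abs(f1$ux - f2$ux)), 1e-10)
})

test_that("Carreau-Yasuda solve keeps effective viscosity within bounds", {
  m <- bif_mesh_coarse()
  st <- solve_steady(m, 0.155, fluid_props(), solver_settings())
  el <- carotidflow:::.element_data(m)
  est <- carotidflow:::.element_state(el, st$ux[, 1], st$uy[, 1])
  mu <- effective_viscosity(est$shear, fluid_props())
  cy <- carreau_yasuda_params()
  expect_true(all(mu >= cy$mu_inf & mu <= cy$mu_0))
  expect_gt(max(mu), 2 * cy$mu_inf)   # shear-thinning active somewhere
})

test_that("inlet Reynolds above the laminar bound raises a warning", {
  mc <- channel_mesh()
  expect_warning(
    solve_steady(mc, 2.2, fluid_props(), solver_settings()),
    "laminar")
})
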