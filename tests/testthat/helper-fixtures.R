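# Shared fixtures, memoized so expensive solves run once per test session.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(key, fun) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, fun(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

newtonian <- function() fluid_props(rheology = "newtonian")

# small straight channel (20 mm x 2 mm) and its steady Poiseuille solve
channel_mesh <- function() .memo("channel_mesh", function() {
  generate_mesh(build_channel_outline(20e-3, 2e-3), 2e-4)
})

channel_steady <- function() .memo("channel_steady", function() {
  solve_steady(channel_mesh(), 0.1, newtonian(), solver_settings())
})

# coarse baseline bifurcation mesh and a short pulsatile solve used by
# several metric tests
bif_mesh_coarse <- function() .memo("bif_mesh_coarse", function() {
  generate_mesh(build_outline(bifurcation_config()), 8e-4)
})

bif_pulsatile_coarse <- function() .memo("bif_pulsatile_coarse", function() {
  solve_pulsatile(bif_mesh_coarse(), inlet_waveform(), fluid_props(),
                  solver_settings(dt = 2.5e-3, n_cycles = 2,
                                  store_per_cycle = 80))
})

# pulsatile channel benchmark at Womersley number ~4.2: solve + analytic
womersley_bench <- function() .memo("womersley_bench", function() {
  props <- newtonian()
  nu <- props$mu_newtonian / props$rho
  a <- 4.2 * sqrt(nu / (2 * pi))
  omega <- 2 * pi
  prof <- function(y, t) womersley_channel_solution(y, t, a, nu,
                                                    u0 = 0.1, u1 = 0.08,
                                                    omega = omega)
  mesh <- generate_mesh(build_channel_outline(12e-3, 2 * a), 4e-4)
  field <- solve_pulsatile(mesh, inlet_waveform(), props,
                           solver_settings(dt = 2e-3, n_cycles = 3,
                                           inlet_profile_fun = prof),
                           outlet_pressure = 0)
  list(mesh = mesh, field = field, prof = prof, a = a)
})

# RMS error of the Womersley benchmark against the analytic series
womersley_rms <- function(bench) {
  yy <- seq(-0.95 * bench$a, 0.95 * bench$a, length.out = 33)
  err2 <- 0; ref2 <- 0
  for (k in seq(4, length(bench$field$times), by = 7)) {
    num <- interpolate_field(bench$mesh, bench$field$ux[, k],
                             rep(6e-3, 33), yy)
    ana <- bench$prof(yy, bench$field$times[k])
    err2 <- err2 + sum((num - ana)^2); ref2 <- ref2 + sum(ana^2)
  }
  sqrt(err2 / ref2)
}

# synthetic uniform-velocity field on a channel mesh (for particle controls)
uniform_channel_field <- function(u = 0.1) .memo("uniform_field", function() {
  mesh <- channel_mesh()
  n <- nrow(mesh$nodes)
  structure(list(mesh = mesh, times = 0,
                 ux = matrix(u, n, 1), uy = matrix(0, n, 1),
                 p = matrix(0, n, 1), period = NA_real_,
                 props = newtonian(), kind = "steady",
                 settings = solver_settings()),
            class = "flow_field")
})
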