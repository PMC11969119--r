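test_that("seeding is reproducible, inside the lumen, and flux-weighted", {
  m <- channel_mesh()
  p10 <- particle_params(n_particles = 10, seed = 3)
  s1 <- seed_particles(p10, m)
  s2 <- seed_particles(p10, m)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 10)
  expect_true(all(s1$y > m$inlet$y_lo & s1$y < m$inlet$y_hi))
  expect_true(all(s1$release_time >= 0 & s1$release_time <= 1))
  # parabolic flux weighting: central half holds 11/16 of the particles
  pbig <- particle_params(n_particles = 10000, seed = 5)
  sb <- seed_particles(pbig, m)
  R <- (m$inlet$y_hi - m$inlet$y_lo) / 2
  frac <- mean(abs(sb$y) < R / 2)
  expect_equal(frac, 11 / 16, tolerance = 0.03)
})

test_that("tracers in a uniform channel flow transit in L/u", {
  fld <- uniform_channel_field(0.1)
  par <- particle_params(n_particles = 50, seed = 2, max_transit_cycles = 3)
  seeds <- seed_particles(par, fld$mesh, profile = "plug")
  seeds$release_time <- 0
  ens <- advect(seeds, fld, par)
  rs <- residence_statistics(ens)
  expect_equal(rs$retained_fraction, 0)
  expect_equal(sum(rs$exit_fractions), 1)
  # PRT = L / u for every tracer (1%), and never below the kinematic bound
  L <- 20e-3 - seeds$x[1]
  expect_equal(ens$particles$residence_time, rep(L / 0.1, 50),
               tolerance = 0.01)
  expect_true(all(ens$particles$residence_time >= L / 0.1 - ens$dt))
})

test_that("Stokes-drag platelets behave as tracers at 3 um", {
  expect_equal(stokes_response_time(particle_params(), 3.5e-3), 1.51e-7,
               tolerance = 1e-2)
  fld <- uniform_channel_field(0.1)
  par_t <- particle_params(n_particles = 30, seed = 9, mode = "TRACER")
  par_s <- particle_params(n_particles = 30, seed = 9, mode = "STOKES_DRAG")
  seeds <- seed_particles(par_t, fld$mesh)
  seeds$release_time <- 0
  e_t <- advect(seeds, fld, par_t)
  e_s <- advect(seeds, fld, par_s)
  expect_equal(e_s$particles$residence_time, e_t$particles$residence_time,
               tolerance = 0.005)
  expect_identical(e_s$particles$exit, e_t$particles$exit)
})

test_that("bifurcation transport favors the internal branch", {
  fl <- bif_pulsatile_coarse()
  par <- particle_params(n_particles = 300, seed = 4, max_transit_cycles = 3)
  seeds <- seed_particles(par, fl$mesh, fl$waveform)
  ens <- advect(seeds, fl, par)
  rs <- residence_statistics(ens)
  # accounting: every particle is exactly one of the outcomes
  p <- ens$particles
  expect_equal(nrow(p), 300)
  expect_true(all(p$exit %in% c("ICA", "ECA", "RETAINED", "FLAGGED")))
  expect_equal(sum(rs$exit_fractions), 1, tolerance = 1e-12)
  # more platelets enter the ICA than the ECA
  expect_gt(rs$exit_fractions["ICA"], rs$exit_fractions["ECA"])
  # censored particles carry the censoring horizon
  if (any(p$exit == "RETAINED"))
    expect_equal(unique(p$residence_time[p$exit == "RETAINED"]), 3 * 1)
  # reproducibility
  ens2 <- advect(seed_particles(par, fl$mesh, fl$waveform), fl, par)
  expect_identical(residence_statistics(ens2)$exit_fractions,
                   rs$exit_fractions)
})

test_that("stagnation mass concentrates at below-average-shear walls", {
  fl <- bif_pulsatile_coarse()
  par <- particle_params(n_particles = 250, seed = 8, max_transit_cycles = 3)
  seeds <- seed_particles(par, fl$mesh, fl$waveform)
  ens <- advect(seeds, fl, par)
  stag <- ens$stagnation
  total <- sum(stag$hist)
  expect_gt(total, 0)
  # cross-tabulate stagnation mass against wall TAWSS: stagnation sits on
  # the slow outer walls, below the top decile of wall shear, and the
  # high-shear divider flanks collect almost none of it
  wm <- compute_wall_metrics(fl)
  xmid <- (stag$breaks[-1] + stag$breaks[-length(stag$breaks)]) / 2
  wsum <- 0
  for (wid in colnames(stag$hist)) {
    wall <- wm[wm$wall_id == wid, ]
    if (!nrow(wall)) next
    for (b in which(stag$hist[, wid] > 0)) {
      tw <- wall$tawss[which.min(abs(wall$x - xmid[b]))]
      wsum <- wsum + tw * stag$hist[b, wid]
    }
  }
  expect_lt(wsum / total, stats::quantile(wm$tawss, 0.9))
  ridge_mass <- sum(stag$hist[, c("ridge_hi", "ridge_lo")])
  expect_lt(ridge_mass / total, 0.2)
})
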