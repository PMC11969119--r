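test_that("cycle metrics match closed-form oracles", {
  tt <- (seq_len(400) - 0.5) / 400
  # constant unidirectional shear
  r1 <- tawss_osi_ecap(rep(2, 400), tt)
  expect_equal(r1$tawss, 2)
  expect_equal(r1$osi, 0)
  expect_equal(r1$ecap, 0)
  # zero-mean oscillation: tawss = 2/pi, osi = 1/2, ecap = pi/4
  r2 <- tawss_osi_ecap(sin(2 * pi * tt), tt)
  expect_equal(r2$tawss, 2 / pi, tolerance = 1e-4)
  expect_equal(r2$osi, 0.5, tolerance = 1e-4)
  expect_equal(r2$ecap, pi / 4, tolerance = 1e-3)
  # non-reversing oscillation
  r3 <- tawss_osi_ecap(1 + 0.5 * sin(2 * pi * tt), tt)
  expect_equal(r3$tawss, 1, tolerance = 1e-6)
  expect_equal(r3$osi, 0, tolerance = 1e-6)
  expect_equal(r3$ecap, 0, tolerance = 1e-6)
  # degenerate no-flow wall
  r4 <- tawss_osi_ecap(rep(0, 400), tt)
  expect_equal(unlist(r4), c(tawss = 0, osi = 0, ecap = 0))
})

test_that("OSI stays in [0, 0.5], is 0 for steady flow, and ECAP*TAWSS = OSI", {
  fl <- bif_pulsatile_coarse()
  w <- wall_shear_stress(fl)
  mm <- tawss_osi_ecap(w$wss, w$times)
  expect_true(all(mm$osi >= 0 & mm$osi <= 0.5))
  expect_true(all(mm$tawss >= abs(rowMeans(w$wss)) - 1e-12))
  nz <- mm$tawss > 0
  expect_equal(mm$ecap[nz] * mm$tawss[nz], mm$osi[nz], tolerance = 1e-12)
  st <- channel_steady()
  ws <- wall_shear_stress(st)
  ms <- tawss_osi_ecap(ws$wss, ws$times)
  expect_true(all(ms$osi == 0))
})

test_that("risk classifier reproduces the worked tiers", {
  expect_equal(as.character(classify_risk(0.4, 0.35, 0.875)$tier), "HIGH")
  expect_equal(as.character(classify_risk(1.0, 0.2, 0.2)$tier), "MEDIUM")
  expect_equal(as.character(classify_risk(2.0, 0.05, 0.025)$tier), "LOW")
  # ECAP alone can force HIGH; gaps fall through to UNCLASSIFIED
  expect_equal(as.character(classify_risk(0.3, 0.45, 1.6)$tier), "HIGH")
  expect_equal(as.character(classify_risk(0.4, 0.05, 0.125)$tier),
               "UNCLASSIFIED")
  v <- classify_risk(c(0.4, 1.0, 2.0), c(0.35, 0.2, 0.05),
                     c(0.875, 0.2, 0.025))
  expect_equal(as.character(v$tier), c("HIGH", "MEDIUM", "LOW"))
  expect_error(classify_risk(1, 0.7, 0.1))
})

test_that("section profiles recover the Poiseuille shape", {
  st <- channel_steady()
  pr <- section_profile(st, "B_B")
  expect_gt(nrow(pr), 50)
  expect_equal(max(pr$speed) / mean(pr$speed), 1.5, tolerance = 0.02)
  # symmetric about the centerline
  mid <- pr$coordinate[which.max(pr$speed)]
  expect_lt(abs(mid), 1e-4)
})

test_that("plateau-phase sections are steady", {
  fl <- bif_pulsatile_coarse()
  k1 <- which.min(abs(fl$times - 0.6))
  k2 <- which.min(abs(fl$times - 0.9))
  p1 <- section_profile(fl, "B_B", instant = k1)
  p2 <- section_profile(fl, "B_B", instant = k2)
  expect_equal(p1$speed, p2$speed, tolerance = 0.01)
})

test_that("site summaries aggregate labeled windows", {
  fl <- bif_pulsatile_coarse()
  wm <- compute_wall_metrics(fl)
  ss <- site_summary(wm)
  expect_setequal(ss$site, c("M", "N", "O", "P"))
  expect_true(all(ss$n > 0))
  expect_true(all(ss$tawss_mean >= 0))
  expect_error(site_summary(wm, sites = "Z"), "no wall nodes")
  # synthetic uniform metric: mean equals the constant, SD 0
  fake <- wm
  fake$tawss <- 1
  sf <- site_summary(fake)
  expect_equal(sf$tawss_mean, rep(1, 4))
  expect_equal(sf$tawss_sd, rep(0, 4))
})

test_that("wall pressure peaks at the bifurcation ridge", {
  fl <- bif_pulsatile_coarse()
  wm <- compute_wall_metrics(fl)
  k <- which.max(wm$mean_pressure)
  expect_true(wm$wall_id[k] %in% c("ridge_hi", "ridge_lo", "tip"))
})
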