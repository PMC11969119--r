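test_that("plaque model configurations map to the documented sites", {
  sites <- function(m) sort(vapply(apply_plaque_model(m),
                                   function(p) p$site, ""))
  expect_equal(sites("A1"), sort(c("RIDGE", "OUTER_ICA", "OUTER_ECA")))
  expect_equal(sites("A2"), sort(c("RIDGE", "OUTER_ICA")))
  expect_equal(sites("A3"), sort(c("OUTER_ICA", "OUTER_ECA")))
  expect_equal(sites("A4"), sort(c("RIDGE", "OUTER_ECA")))
  expect_equal(sites("A5"), "RIDGE")
  expect_length(apply_plaque_model("NONE"), 0)
  expect_error(apply_plaque_model("A9"))
})

test_that("default outline carries the nominal vessel widths", {
  ol <- build_outline(bifurcation_config())
  g <- ol$geom
  # CCA channel width
  expect_equal(ol$funs$top(1e-3) - ol$funs$bot(1e-3), 6.35e-3)
  # distal ICA perpendicular width
  xe <- g$x_end_i
  w_ica <- (ol$funs$top(xe) - ol$funs$ridge_hi(xe)) * cos(g$th_i)
  # the bulb has decayed by the branch end; only the taper remains
  expect_equal(w_ica, 4.5e-3, tolerance = 1e-6)
  w_eca <- (ol$funs$ridge_lo(g$x_end_e) - ol$funs$bot(g$x_end_e)) * cos(g$th_e)
  expect_equal(w_eca, 3.0e-3, tolerance = 1e-6)
})

test_that("zero-thickness plaque reproduces the plaque-free outline", {
  ol0 <- build_outline(bifurcation_config())
  olz <- build_outline(bifurcation_config(
    plaque_specs = list(plaque_spec("OUTER_ICA", mean_thickness = 0))))
  for (wall in names(ol0$walls)) {
    expect_equal(olz$walls[[wall]]$y, ol0$walls[[wall]]$y, tolerance = 1e-12)
  }
})

test_that("plaque apex reduces the lumen width by its apex thickness", {
  # apex protrusion = 2 x mean thickness for an outer-wall plaque
  cf0 <- bifurcation_config(bulb_diameter_factor = 1)
  cfp <- bifurcation_config(
    bulb_diameter_factor = 1,
    plaque_specs = list(plaque_spec("OUTER_ICA", mean_thickness = 1e-3)))
  ol0 <- build_outline(cf0); olp <- build_outline(cfp)
  # probe the plaque window by brute-force normal-ray casting
  g <- olp$geom
  xc <- g$x_b + (23.09e-3 / 6) * g$ci
  xr <- xc + c(-1e-3, 1e-3)
  w0 <- min_lumen_width(ol0, "ica", x_range = xr)
  wp <- min_lumen_width(olp, "ica", x_range = xr)
  expect_equal(w0 - wp, 2e-3, tolerance = 0.02)
})

test_that("mirror-symmetric configuration yields a mirror-symmetric outline", {
  cf <- bifurcation_config(d_ica_distal = 3.5e-3, d_eca_distal = 3.5e-3,
                           L_ica = 20e-3, L_eca = 20e-3,
                           angle_split = 0.5, bulb_diameter_factor = 1)
  ol <- build_outline(cf)
  xs <- seq(0, ol$geom$x_end_i - 1e-9, length.out = 400)
  expect_equal(ol$funs$top(xs), -ol$funs$bot(xs), tolerance = 1e-12)
  expect_equal(ol$funs$ridge_hi(xs[xs >= ol$geom$x_b]),
               -ol$funs$ridge_lo(xs[xs >= ol$geom$x_b]), tolerance = 1e-12)
  expect_equal(ol$geom$y_apex, 0, tolerance = 1e-15)
})

test_that("adding a plaque shrinks the enclosed area by about its bump area", {
  a0 <- outline_area(build_outline(bifurcation_config()))
  for (m in c("A5", "A3", "A1")) {
    am <- outline_area(build_outline(bifurcation_config(plaque_model = m)))
    expect_lt(am, a0)
  }
  # single (uncapped) outer-ICA plaque: bump area = mean thickness x length
  sp <- plaque_spec("OUTER_ICA", mean_thickness = 1e-3)
  ap <- outline_area(build_outline(bifurcation_config(
    plaque_specs = list(sp))))
  expect_equal(a0 - ap, sp$mean_thickness * sp$length, tolerance = 0.02)
  # nominal thicknesses wider than the planar lumen allows are capped
  olc <- build_outline(bifurcation_config(plaque_model = "A3"))
  expect_true("OUTER_ECA" %in% names(olc$geom$plaque_caps))
})

test_that("infeasible plaques raise a geometry error naming the site", {
  expect_error(
    build_outline(bifurcation_config(
      plaque_obstruction_cap = Inf,
      plaque_specs = list(plaque_spec("OUTER_ECA", mean_thickness = 1.6e-3)))),
    "OUTER_ECA")
  expect_error(
    build_outline(bifurcation_config(
      plaque_obstruction_cap = Inf,
      plaque_specs = list(plaque_spec("OUTER_ICA", mean_thickness = 3.2e-3)))),
    "ICA")
})

test_that("outline polygon is closed, tagged and positively oriented", {
  ol <- build_outline(bifurcation_config(plaque_model = "A2"))
  p <- ol$polygon
  expect_equal(length(p$edge_tag), nrow(p$xy))
  expect_setequal(unique(p$edge_tag),
                  c("WALL", "INLET", "OUTLET_ICA", "OUTLET_ECA"))
  expect_equal(sum(p$edge_tag == "INLET"), 1)
  expect_equal(sum(p$edge_tag == "OUTLET_ICA"), 1)
  expect_equal(sum(p$edge_tag == "OUTLET_ECA"), 1)
  # shoelace signed area positive (counter-clockwise)
  xy <- p$xy; n <- nrow(xy); i2 <- c(2:n, 1)
  signed <- 0.5 * sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])
  expect_gt(signed, 0)
})

test_that("outline generation is deterministic", {
  o1 <- build_outline(bifurcation_config(plaque_model = "A4"))
  o2 <- build_outline(bifurcation_config(plaque_model = "A4"))
  expect_identical(o1$walls, o2$walls)
  expect_identical(o1$polygon$xy, o2$polygon$xy)
})
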