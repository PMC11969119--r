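test_that("channel mesh area matches the rectangle", {
  ol <- build_channel_outline(32e-3, 6.35e-3)
  m <- generate_mesh(ol, 0.5e-3)
  expect_equal(mesh_area(m), 203.2e-6, tolerance = 0.005)
  expect_equal(m$n_boundary_layers, 5L)
})

test_that("triangulation is conforming with a manifold tagged boundary", {
  m <- generate_mesh(build_outline(bifurcation_config(plaque_model = "A2")),
                     8e-4)
  ar <- carotidflow:::.tri_areas(m)
  expect_true(all(ar > 0))
  # every boundary edge belongs to exactly one triangle
  tri <- m$triangles
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  all_edges <- c(ekey(tri[, 1], tri[, 2]), ekey(tri[, 2], tri[, 3]),
                 ekey(tri[, 3], tri[, 1]))
  cnt <- table(all_edges)
  be <- ekey(m$boundary_edges$n1, m$boundary_edges$n2)
  expect_true(all(cnt[be] == 1))
  # interior edges are shared by exactly two triangles
  expect_true(all(cnt[!(names(cnt) %in% be)] == 2))
  # boundary covers: counts of each tag present
  expect_setequal(unique(m$boundary_edges$tag),
                  c("WALL", "INLET", "OUTLET_ICA", "OUTLET_ECA"))
  # all site labels present on a plaque-bearing model, walls only
  wp <- m$wall_probes
  expect_setequal(setdiff(unique(wp$site), NA), c("M", "N", "O", "P"))
})

test_that("node count grows under refinement and refine() rescales size", {
  ol <- build_outline(bifurcation_config())
  m1 <- generate_mesh(ol, 1.2e-3)
  m2 <- generate_mesh(ol, 0.6e-3)
  expect_gt(nrow(m2$nodes), nrow(m1$nodes))
  r1 <- refine(m1, 1)
  expect_equal(r1$characteristic_size, m1$characteristic_size)
  expect_equal(nrow(r1$nodes), nrow(m1$nodes))
  r2 <- refine(m1, 2)
  expect_equal(r2$characteristic_size, m1$characteristic_size / 2)
  expect_equal(mesh_area(r2), mesh_area(m1), tolerance = 0.005)
})

test_that("meshing is deterministic", {
  ol <- build_outline(bifurcation_config(plaque_model = "A5"))
  m1 <- generate_mesh(ol, 8e-4)
  m2 <- generate_mesh(ol, 8e-4)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$triangles, m2$triangles)
})

test_that("interpolation reproduces nodal fields on the blocks", {
  m <- bif_mesh_coarse()
  # a linear field is reproduced exactly by bilinear block interpolation
  f <- 2 * m$nodes[, 1] - 3 * m$nodes[, 2] + 1e-3
  pts <- cbind(c(5e-3, 20e-3, 35e-3, 40e-3),
               c(1e-3, -2e-3, 3.5e-3, -4e-3))
  v <- interpolate_field(m, f, pts[, 1], pts[, 2])
  expect_equal(v, 2 * pts[, 1] - 3 * pts[, 2] + 1e-3, tolerance = 1e-10)
  # a point inside the divider wedge is outside the lumen
  g <- m$outline$geom
  xw <- g$x_b + 0.6 * (g$x_end_e - g$x_b)
  yw <- (m$outline$funs$ridge_hi(xw) + m$outline$funs$ridge_lo(xw)) / 2
  expect_true(is.na(interpolate_field(m, f, xw, yw)))
})

test_that("mesh exports are well-formed text files", {
  m <- channel_mesh()
  msh <- tempfile(fileext = ".msh")
  vtk <- tempfile(fileext = ".vtk")
  write_mesh_msh(m, msh)
  write_mesh_vtk(m, vtk, point_data = list(speed = m$nodes[, 2]))
  ml <- readLines(msh)
  expect_equal(ml[1], "$MeshFormat")
  expect_equal(as.integer(ml[5]), nrow(m$nodes))
  vl <- readLines(vtk)
  expect_true(any(grepl("^CELLS", vl)))
  expect_true(any(grepl("SCALARS speed", vl)))
})
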