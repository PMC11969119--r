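# Structured transfinite triangulation of the planar lumen.
#
# Each lumen is meshed as mapped blocks of quadrilaterals split into
# triangles: the CCA trunk as one block whose cross distribution is the
# union of the two branch distributions (plus the blunt-tip strip), and one
# block per branch sharing the junction column, so the triangulation is
# conforming by construction. Cross distributions carry geometrically
# graded boundary layers at every wall.

# normalized cross-channel node fractions with two-sided boundary layers
.graded_fractions <- function(width, h, nbl, growth = 1.3) {
  stopifnot(width > 0, h > 0, nbl >= 1)
  # first-layer thickness: h/3 but never let the two BLs fill the channel
  d1 <- min(h / 3, 0.25 * width * (growth - 1) / (growth^nbl - 1))
  bl <- d1 * growth^(seq_len(nbl) - 1)
  interior <- width - 2 * sum(bl)
  n_int <- max(2L, as.integer(round(interior / h)))
  sp <- c(bl, rep(interior / n_int, n_int), rev(bl))
  f <- cumsum(c(0, sp)) / sum(sp)
  f[length(f)] <- 1
  f
}

.quads_to_tris <- function(idx) {
  nc <- nrow(idx); nr <- ncol(idx)
  a <- idx[-nc, -nr]; b <- idx[-1, -nr]; cc <- idx[-1, -1]; d <- idx[-nc, -1]
  rbind(cbind(as.vector(a), as.vector(b), as.vector(cc)),
        cbind(as.vector(a), as.vector(cc), as.vector(d)))
}

#' Triangulate a lumen outline
#'
#' Builds a conforming triangular mesh of the outline with `n_boundary_layers`
#' geometrically graded layers of thin elements along every wall. Works for
#' both bifurcation and straight-channel outlines.
#'
#' @param outline A `carotid_outline` from [build_outline()] or
#'   [build_channel_outline()].
#' @param characteristic_size Target interior element size (m).
#' @param n_boundary_layers Number of graded wall layers (default 5).
#' @param bl_growth Geometric growth ratio of the wall layers.
#' @return A `mesh2d` object: nodes, triangles, tagged boundary edges, wall
#'   probe table (for wall-shear recovery), and the structured block maps
#'   used for fast velocity interpolation.
#' @export
generate_mesh <- function(outline, characteristic_size,
                          n_boundary_layers = 5L, bl_growth = 1.3) {
  stopifnot(inherits(outline, "carotid_outline"), characteristic_size > 0)
  h <- characteristic_size
  nbl <- as.integer(n_boundary_layers)
  if (outline$kind == "channel") {
    mesh <- .mesh_channel(outline, h, nbl, bl_growth)
  } else {
    mesh <- .mesh_bifurcation(outline, h, nbl, bl_growth)
  }
  mesh$characteristic_size <- h
  mesh$n_boundary_layers <- nbl
  mesh$bl_growth <- bl_growth
  mesh$outline <- outline
  class(mesh) <- "mesh2d"
  .check_mesh(mesh)
  mesh
}

#' Re-mesh at a finer characteristic size
#'
#' @param mesh A `mesh2d`.
#' @param factor Refinement factor (>= 1); the new characteristic size is
#'   `characteristic_size / factor`. Tags and block structure are rebuilt on
#'   the same outline.
#' @export
refine <- function(mesh, factor) {
  stopifnot(inherits(mesh, "mesh2d"), factor >= 1)
  generate_mesh(mesh$outline, mesh$characteristic_size / factor,
                mesh$n_boundary_layers, mesh$bl_growth)
}

#' Total mesh area
#' @param mesh A `mesh2d`.
#' @return Sum of triangle areas (m^2).
#' @export
mesh_area <- function(mesh) sum(.tri_areas(mesh))

.tri_areas <- function(mesh) {
  p <- mesh$nodes; t <- mesh$triangles
  0.5 * ((p[t[, 2], 1] - p[t[, 1], 1]) * (p[t[, 3], 2] - p[t[, 1], 2]) -
         (p[t[, 3], 1] - p[t[, 1], 1]) * (p[t[, 2], 2] - p[t[, 1], 2]))
}

#' @export
print.mesh2d <- function(x, ...) {
  cat("mesh2d:", nrow(x$nodes), "nodes,", nrow(x$triangles), "triangles,",
      nrow(x$boundary_edges), "boundary edges\n")
  cat("  characteristic size:", x$characteristic_size, "m;",
      x$n_boundary_layers, "boundary layers\n")
  invisible(x)
}

# ---------------------------------------------------------------------------

.mesh_channel <- function(out, h, nbl, growth) {
  L <- out$geom$L; R <- out$geom$R
  f <- .graded_fractions(2 * R, h, nbl, growth)
  nxc <- max(4L, ceiling(L / h))
  xs <- seq(0, L, length.out = nxc + 1)
  nr <- length(f)
  idx <- matrix(seq_len((nxc + 1) * nr), nrow = nxc + 1, byrow = FALSE)
  X <- matrix(rep(xs, nr), nrow = nxc + 1)
  Y <- outer(rep(1, nxc + 1), -R + f * 2 * R)
  nodes <- cbind(as.vector(X), as.vector(Y))
  tris <- .quads_to_tris(idx)

  be <- rbind(
    data.frame(n1 = idx[-(nxc + 1), 1], n2 = idx[-1, 1],
               tag = "WALL", wall_id = "bot"),
    data.frame(n1 = idx[-(nxc + 1), nr], n2 = idx[-1, nr],
               tag = "WALL", wall_id = "top"),
    data.frame(n1 = idx[1, -1], n2 = idx[1, -nr], tag = "INLET",
               wall_id = NA),
    data.frame(n1 = idx[nxc + 1, -nr], n2 = idx[nxc + 1, -1],
               tag = "OUTLET_ICA", wall_id = NA))

  wp <- rbind(
    .probe_row(idx, nodes, cols = seq_len(nxc + 1), wall_row = 1,
               p1 = 2, p2 = 3, wall_id = "bot", s0 = 0),
    .probe_row(idx, nodes, cols = seq_len(nxc + 1), wall_row = nr,
               p1 = nr - 1, p2 = nr - 2, wall_id = "top", s0 = 0))
  wp$site <- NA_character_

  blocks <- list(list(name = "channel", xcols = xs, f = f, idx = idx,
                      branch = "CCA"))
  list(nodes = nodes, triangles = tris, boundary_edges = be,
       wall_probes = wp, blocks = blocks,
       inlet = list(nodes = idx[1, ], y = nodes[idx[1, ], 2],
                    y_lo = -R, y_hi = R))
}

# probe table for one structured wall row: wall nodes at `wall_row`,
# first/second interior rows p1/p2 in the same column
.probe_row <- function(idx, nodes, cols, wall_row, p1, p2, wall_id, s0) {
  nd <- idx[cols, wall_row]
  i1 <- idx[cols, p1]; i2 <- idx[cols, p2]
  x <- nodes[nd, 1]; y <- nodes[nd, 2]
  # local wall tangent (proximal -> distal, i.e. increasing x)
  n <- length(nd)
  dx <- c(x[2] - x[1], diff(x, lag = 2) / 2, x[n] - x[n - 1])
  dy <- c(y[2] - y[1], diff(y, lag = 2) / 2, y[n] - y[n - 1])
  tl <- sqrt(dx^2 + dy^2)
  tx <- dx / tl; ty <- dy / tl
  cosphi <- tx                      # angle between vertical probe and normal
  d1 <- abs(nodes[i1, 2] - y) * abs(cosphi)
  d2 <- abs(nodes[i2, 2] - y) * abs(cosphi)
  s <- s0 + c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  data.frame(node = nd, wall_id = wall_id, x = x, y = y, s = s,
             tx = tx, ty = ty, i1 = i1, i2 = i2, d1 = d1, d2 = d2)
}

.mesh_bifurcation <- function(out, h, nbl, growth) {
  g <- out$geom; f <- out$funs
  R <- g$R; x_b <- g$x_b; yA <- g$yA; yB <- g$yB

  f_i <- .graded_fractions(R - yB, h, nbl, growth)
  f_e <- .graded_fractions(yA + R, h, nbl, growth)
  n_ri <- length(f_i); n_re <- length(f_e)
  n_rows <- n_re + n_ri                  # CCA column rows (lower + upper)

  nxc <- max(6L, ceiling(g$x_b / h))
  nxi <- max(6L, ceiling((g$x_end_i - x_b) / (h * g$ci)))
  nxe <- max(6L, ceiling((g$x_end_e - x_b) / (h * g$ce)))
  xs_c <- seq(0, x_b, length.out = nxc + 1)
  xs_i <- seq(x_b, g$x_end_i, length.out = nxi + 1)
  xs_e <- seq(x_b, g$x_end_e, length.out = nxe + 1)

  # --- node numbering ------------------------------------------------------
  idx_cca <- matrix(seq_len((nxc + 1) * n_rows), nrow = nxc + 1)
  n0 <- (nxc + 1) * n_rows
  idx_ica <- matrix(0L, nrow = nxi + 1, ncol = n_ri)
  idx_ica[1, ] <- idx_cca[nxc + 1, n_re + seq_len(n_ri)]
  idx_ica[-1, ] <- n0 + seq_len(nxi * n_ri)
  n1 <- n0 + nxi * n_ri
  idx_eca <- matrix(0L, nrow = nxe + 1, ncol = n_re)
  idx_eca[1, ] <- idx_cca[nxc + 1, seq_len(n_re)]
  idx_eca[-1, ] <- n1 + seq_len(nxe * n_re)
  n_nodes <- n1 + nxe * n_re

  nodes <- matrix(0, n_nodes, 2)
  # CCA block
  ybot_c <- f$bot(xs_c); ytop_c <- f$top(xs_c)
  Yl <- ybot_c + outer(yA - ybot_c, f_e)        # (nxc+1) x n_re
  Yu <- yB + outer(ytop_c - yB, f_i)
  nodes[as.vector(idx_cca), 1] <- rep(xs_c, n_rows)
  nodes[as.vector(idx_cca), 2] <- as.vector(cbind(Yl, Yu))
  # ICA block
  ylo_i <- f$ridge_hi(xs_i); yhi_i <- f$top(xs_i)
  Yi <- ylo_i + outer(yhi_i - ylo_i, f_i)
  nodes[as.vector(idx_ica), 1] <- rep(xs_i, n_ri)
  nodes[as.vector(idx_ica), 2] <- as.vector(Yi)
  # ECA block
  ylo_e <- f$bot(xs_e); yhi_e <- f$ridge_lo(xs_e)
  Ye <- ylo_e + outer(yhi_e - ylo_e, f_e)
  nodes[as.vector(idx_eca), 1] <- rep(xs_e, n_re)
  nodes[as.vector(idx_eca), 2] <- as.vector(Ye)

  tris <- rbind(.quads_to_tris(idx_cca),
                .quads_to_tris(idx_ica),
                .quads_to_tris(idx_eca))

  # --- boundary edges ------------------------------------------------------
  be <- rbind(
    data.frame(n1 = idx_cca[-(nxc + 1), 1], n2 = idx_cca[-1, 1],
               tag = "WALL", wall_id = "bot"),
    data.frame(n1 = idx_eca[-(nxe + 1), 1], n2 = idx_eca[-1, 1],
               tag = "WALL", wall_id = "bot"),
    data.frame(n1 = idx_cca[-(nxc + 1), n_rows], n2 = idx_cca[-1, n_rows],
               tag = "WALL", wall_id = "top"),
    data.frame(n1 = idx_ica[-(nxi + 1), n_ri], n2 = idx_ica[-1, n_ri],
               tag = "WALL", wall_id = "top"),
    data.frame(n1 = idx_ica[-(nxi + 1), 1], n2 = idx_ica[-1, 1],
               tag = "WALL", wall_id = "ridge_hi"),
    data.frame(n1 = idx_eca[-(nxe + 1), n_re], n2 = idx_eca[-1, n_re],
               tag = "WALL", wall_id = "ridge_lo"),
    data.frame(n1 = idx_cca[nxc + 1, n_re], n2 = idx_cca[nxc + 1, n_re + 1],
               tag = "WALL", wall_id = "tip"),
    data.frame(n1 = idx_cca[1, -1], n2 = idx_cca[1, -n_rows],
               tag = "INLET", wall_id = NA),
    data.frame(n1 = idx_ica[nxi + 1, -n_ri], n2 = idx_ica[nxi + 1, -1],
               tag = "OUTLET_ICA", wall_id = NA),
    data.frame(n1 = idx_eca[nxe + 1, -n_re], n2 = idx_eca[nxe + 1, -1],
               tag = "OUTLET_ECA", wall_id = NA))

  # --- wall probe table ----------------------------------------------------
  wp <- rbind(
    .probe_row(idx_cca, nodes, seq_len(nxc + 1), 1, 2, 3, "bot", 0),
    .probe_row(idx_eca, nodes, 1 + seq_len(nxe), 1, 2, 3, "bot",
               s0 = x_b),   # continued arclength, corrected below
    .probe_row(idx_cca, nodes, seq_len(nxc + 1), n_rows,
               n_rows - 1, n_rows - 2, "top", 0),
    .probe_row(idx_ica, nodes, 1 + seq_len(nxi), n_ri,
               n_ri - 1, n_ri - 2, "top", s0 = x_b),
    .probe_row(idx_ica, nodes, seq_len(nxi + 1), 1, 2, 3, "ridge_hi", 0),
    .probe_row(idx_eca, nodes, seq_len(nxe + 1), n_re,
               n_re - 1, n_re - 2, "ridge_lo", 0))
  # fix continued arclengths for the branch parts of the outer walls
  for (wid in c("bot", "top")) {
    k <- wp$wall_id == wid
    ss <- wp$s[k]; xx <- wp$x[k]; yy <- wp$y[k]
    o <- order(xx)
    s_cont <- c(0, cumsum(sqrt(diff(xx[o])^2 + diff(yy[o])^2)))
    ss[o] <- s_cont
    wp$s[k] <- ss
  }

  # --- site labels ---------------------------------------------------------
  wp$site <- NA_character_
  st <- out$sites
  lab <- function(wid, xr) wp$wall_id == wid & wp$x >= xr[1] & wp$x <= xr[2]
  wp$site[lab("bot", st$M$x_range)] <- "M"
  wp$site[lab("bot", st$P$x_range)] <- "P"
  wp$site[lab("top", st$N$x_range)] <- "N"
  o_hi <- wp$wall_id == "ridge_hi" &
    (wp$x - x_b) / g$ci >= st$O$s_range[1] &
    (wp$x - x_b) / g$ci <= st$O$s_range[2]
  o_lo <- wp$wall_id == "ridge_lo" &
    (wp$x - x_b) / g$ce >= st$O$s_range[1] &
    (wp$x - x_b) / g$ce <= st$O$s_range[2]
  wp$site[o_hi | o_lo] <- "O"

  blocks <- list(
    list(name = "cca_lo", xcols = xs_c, f = f_e,
         idx = idx_cca[, seq_len(n_re)], branch = "CCA"),
    list(name = "cca_hi", xcols = xs_c, f = f_i,
         idx = idx_cca[, n_re + seq_len(n_ri)], branch = "CCA"),
    list(name = "cca_gap", xcols = xs_c, f = c(0, 1),
         idx = idx_cca[, c(n_re, n_re + 1)], branch = "CCA"),
    list(name = "ica", xcols = xs_i, f = f_i, idx = idx_ica, branch = "ICA"),
    list(name = "eca", xcols = xs_e, f = f_e, idx = idx_eca, branch = "ECA"))

  list(nodes = nodes, triangles = tris, boundary_edges = be,
       wall_probes = wp, blocks = blocks,
       inlet = list(nodes = idx_cca[1, ], y = nodes[idx_cca[1, ], 2],
                    y_lo = -R, y_hi = R))
}

.check_mesh <- function(mesh) {
  ar <- .tri_areas(mesh)
  if (any(ar <= 0)) {
    stop("mesh generation failed: ", sum(ar <= 0), " inverted triangles; ",
         "try a coarser characteristic size (>= ",
         signif(mesh$characteristic_size * 1.5, 3), " m)")
  }
  invisible(TRUE)
}

#' Minimum interior angle of the mesh (degrees)
#' @param mesh A `mesh2d`.
#' @export
mesh_min_angle <- function(mesh) {
  p <- mesh$nodes; t <- mesh$triangles
  ang <- function(a, b, cc) {
    u <- p[b, ] - p[a, ]; v <- p[cc, ] - p[a, ]
    acos(pmin(1, pmax(-1, rowSums(u * v) /
                        sqrt(rowSums(u^2) * rowSums(v^2)))))
  }
  min(c(ang(t[, 1], t[, 2], t[, 3]), ang(t[, 2], t[, 3], t[, 1]),
        ang(t[, 3], t[, 1], t[, 2]))) * 180 / pi
}
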