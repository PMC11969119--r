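# Parametric 2D planar carotid bifurcation lumens.
#
# The lumen is represented by x-monotone wall curves: a common carotid (CCA)
# trunk along +x that splits at a blunt flow divider into an internal branch
# (ICA, deflected upward, carrying the carotid bulb) and an external branch
# (ECA, deflected downward). Plaques are smooth inward protrusions of the
# walls. All coordinates are SI meters; the CCA inlet is at x = 0 centered
# on y = 0.

PLAQUE_SITES <- c("RIDGE", "OUTER_ICA", "OUTER_ECA", "OUTER_CCA")

# Table of default plaque dimensions per host vessel (m)
.plaque_defaults <- list(
  RIDGE     = list(length = 7e-3,    mean_thickness = 1e-3),
  OUTER_CCA = list(length = 7e-3,    mean_thickness = 1e-3),
  OUTER_ICA = list(length = 5.12e-3, mean_thickness = 2e-3),
  OUTER_ECA = list(length = 4e-3,    mean_thickness = 2e-3)
)

#' Specify a single plaque
#'
#' A plaque is a smooth inward wall protrusion with a squared-sine profile:
#' zero thickness and zero slope at both shoulders, apex thickness equal to
#' twice the mean thickness (so the along-length average matches the
#' specified mean).
#'
#' @param site One of `"RIDGE"`, `"OUTER_ICA"`, `"OUTER_ECA"`, `"OUTER_CCA"`.
#' @param length Plaque length along the wall (m). Defaults per site:
#'   7 mm at the ridge/CCA, 5.12 mm on the ICA, 4 mm on the ECA.
#' @param mean_thickness Average protrusion thickness (m). Defaults: 1 mm at
#'   the ridge/CCA, 2 mm on the branch outer walls.
#' @param profile Bump profile; only `"COSINE_SQUARED"` (the squared-sine
#'   window above) is implemented.
#' @return A `plaque_spec` object.
#' @export
plaque_spec <- function(site, length = NULL, mean_thickness = NULL,
                        profile = "COSINE_SQUARED") {
  site <- match.arg(site, PLAQUE_SITES)
  profile <- match.arg(profile, "COSINE_SQUARED")
  d <- .plaque_defaults[[site]]
  if (is.null(length)) length <- d$length
  if (is.null(mean_thickness)) mean_thickness <- d$mean_thickness
  stopifnot(length > 0, mean_thickness >= 0)
  structure(list(site = site, length = length,
                 mean_thickness = mean_thickness, profile = profile),
            class = "plaque_spec")
}

#' Plaque sites for the named plaque configuration models
#'
#' The five configuration models place plaques at: A1 ridge + outer ICA +
#' outer ECA; A2 ridge + outer ICA; A3 outer ICA + outer ECA; A4 ridge +
#' outer ECA; A5 ridge only. `NONE` has no plaque.
#'
#' @param model `"NONE"` or `"A1"` ... `"A5"`.
#' @return List of [plaque_spec()] objects (empty for `NONE`).
#' @export
apply_plaque_model <- function(model) {
  model <- match.arg(model, c("NONE", "A1", "A2", "A3", "A4", "A5"))
  sites <- switch(model,
    NONE = character(0),
    A1 = c("RIDGE", "OUTER_ICA", "OUTER_ECA"),
    A2 = c("RIDGE", "OUTER_ICA"),
    A3 = c("OUTER_ICA", "OUTER_ECA"),
    A4 = c("RIDGE", "OUTER_ECA"),
    A5 = "RIDGE")
  lapply(sites, plaque_spec)
}

#' Parametric bifurcation geometry configuration
#'
#' Dimensions default to the vascular model parameters used throughout:
#' CCA diameter 6.35 mm and length 32 mm, ICA distal diameter 4.5 mm and
#' length 23.09 mm, ECA distal diameter 3 mm and length 19.35 mm.
#'
#' @param d_cca CCA diameter (m).
#' @param d_ica_distal,d_eca_distal Distal branch diameters (m), measured
#'   perpendicular to the branch centerline; branch widths taper linearly
#'   from their share of the junction section to these values.
#' @param L_cca,L_ica,L_eca Vessel lengths (m); branch lengths are along the
#'   branch centerline.
#' @param bifurcation_angle Total ICA-ECA angle in degrees, in (0, 90).
#' @param angle_split Fraction of the total angle taken by the ICA (the ICA
#'   deflects more than the ECA); `0.5` gives symmetric deflection.
#' @param plaque_model Named configuration (`"NONE"`, `"A1"` ... `"A5"`);
#'   ignored when `plaque_specs` is given explicitly.
#' @param plaque_specs List of [plaque_spec()]; defaults to
#'   `apply_plaque_model(plaque_model)`.
#' @param bulb_diameter_factor Carotid bulb widening as a multiple of the
#'   proximal ICA width, blended smoothly over the first third of the ICA.
#'   Set to 1 to disable the bulb.
#' @param ridge_tip_width Bluntness (m) of the flow-divider tip: the wedge
#'   between the branches starts from a flat face of this width rather than
#'   a mathematically sharp corner, as in real flow dividers.
#' @param plaque_obstruction_cap Outer-wall plaque thickness is capped at
#'   this fraction of the local plaque-free lumen half-width, so that
#'   nominal plaque dimensions taken from thicker 3D vessels remain
#'   meaningful in the planar analog. Set `Inf` to impose stated
#'   thicknesses verbatim (which may make the lumen close and error).
#' @param fillet_length Half-width (m) of the C1 smoothing window applied to
#'   the outer walls at the branch take-off kinks.
#' @return A `bifurcation_config` object.
#' @export
bifurcation_config <- function(d_cca = 6.35e-3,
                               d_ica_distal = 4.5e-3,
                               d_eca_distal = 3.0e-3,
                               L_cca = 32e-3,
                               L_ica = 23.09e-3,
                               L_eca = 19.35e-3,
                               bifurcation_angle = 25,
                               angle_split = 2 / 3,
                               plaque_model = "NONE",
                               plaque_specs = NULL,
                               bulb_diameter_factor = 1.3,
                               ridge_tip_width = 0.3e-3,
                               fillet_length = 2e-3,
                               plaque_obstruction_cap = 0.6) {
  plaque_model <- match.arg(plaque_model, c("NONE", "A1", "A2", "A3", "A4", "A5"))
  if (is.null(plaque_specs)) plaque_specs <- apply_plaque_model(plaque_model)
  stopifnot(d_cca > 0, d_ica_distal > 0, d_eca_distal > 0,
            L_cca > 0, L_ica > 0, L_eca > 0,
            bifurcation_angle > 0, bifurcation_angle < 90,
            angle_split > 0, angle_split < 1,
            bulb_diameter_factor >= 1,
            ridge_tip_width > 0, ridge_tip_width < d_cca / 4,
            fillet_length > 0, fillet_length < L_cca / 4,
            plaque_obstruction_cap > 0)
  if (!all(vapply(plaque_specs, inherits, TRUE, "plaque_spec")))
    stop("plaque_specs must be a list of plaque_spec objects")
  structure(list(d_cca = d_cca, d_ica_distal = d_ica_distal,
                 d_eca_distal = d_eca_distal, L_cca = L_cca, L_ica = L_ica,
                 L_eca = L_eca, bifurcation_angle = bifurcation_angle,
                 angle_split = angle_split, plaque_model = plaque_model,
                 plaque_specs = plaque_specs,
                 bulb_diameter_factor = bulb_diameter_factor,
                 ridge_tip_width = ridge_tip_width,
                 fillet_length = fillet_length,
                 plaque_obstruction_cap = plaque_obstruction_cap),
            class = "bifurcation_config")
}

# squared-sine bump window: 0 at both ends with zero slope, 1 at center
.bump <- function(s, s0, len) {
  xi <- (s - s0) / len
  ifelse(xi > 0 & xi < 1, sin(pi * xi)^2, 0)
}

# C1 cubic Hermite blend of a piecewise function over [xa, xb]
.hermite_blend <- function(x, xa, xb, ya, yb, dya, dyb) {
  t <- (x - xa) / (xb - xa)
  h <- xb - xa
  ya * (2 * t^3 - 3 * t^2 + 1) + dya * h * (t^3 - 2 * t^2 + t) +
    yb * (-2 * t^3 + 3 * t^2) + dyb * h * (t^3 - t^2)
}

#' Build the lumen outline for a bifurcation configuration
#'
#' Constructs the four wall curves (outer/top wall carrying the ICA outer
#' side, outer/bottom wall carrying the ECA outer side, and the two flow
#' divider walls), inserts the carotid bulb and any plaque bumps, tags the
#' M/N/O/P wall site windows, and assembles a closed, positively oriented
#' polygon with per-edge tags.
#'
#' @param config A [bifurcation_config()].
#' @param ds Sampling step along x for the wall polylines (m).
#' @return A `carotid_outline` object with components `walls` (dense
#'   polylines), `geom` (derived junction geometry), `sites` (site windows),
#'   and `polygon` (closed tagged polyline).
#' @export
build_outline <- function(config, ds = 5e-5) {
  cf <- config
  R <- cf$d_cca / 2
  th_i <- cf$bifurcation_angle * cf$angle_split * pi / 180
  th_e <- cf$bifurcation_angle * (1 - cf$angle_split) * pi / 180
  ci <- cos(th_i); ce <- cos(th_e)
  x_b <- cf$L_cca
  delta <- cf$ridge_tip_width
  r <- cf$d_ica_distal / cf$d_eca_distal
  y_apex <- (R - delta / 2) * (ci - r * ce) / (ci + r * ce)
  yA <- y_apex - delta / 2   # top of ECA share at the junction
  yB <- y_apex + delta / 2   # bottom of ICA share
  wi0 <- (R - yB) * ci       # proximal perpendicular widths
  we0 <- (yA + R) * ce
  x_end_i <- x_b + cf$L_ica * ci
  x_end_e <- x_b + cf$L_eca * ce

  # vertical extents of the branch channels, tapering linearly to the
  # distal diameters (converted to vertical extents)
  Vi <- function(x) (R - yB) + (cf$d_ica_distal / ci - (R - yB)) *
    (x - x_b) / (x_end_i - x_b)
  Ve <- function(x) (yA + R) + (cf$d_eca_distal / ce - (yA + R)) *
    (x - x_b) / (x_end_e - x_b)
  yc_i <- function(x) (yB + R) / 2 + (x - x_b) * tan(th_i)
  yc_e <- function(x) -(R - yA) / 2 - (x - x_b) * tan(th_e)

  ica_top_raw  <- function(x) yc_i(x) + Vi(x) / 2
  ica_ridge    <- function(x) yc_i(x) - Vi(x) / 2
  eca_bot_raw  <- function(x) yc_e(x) - Ve(x) / 2
  eca_ridge    <- function(x) yc_e(x) + Ve(x) / 2

  # ---- top (outer) wall: CCA top + fillet + ICA outer, with bulb/plaque
  fl <- cf$fillet_length
  slope_top <- (ica_top_raw(x_b + 1e-6) - ica_top_raw(x_b)) / 1e-6
  top_fun_raw <- function(x) {
    y <- ifelse(x <= x_b, R, ica_top_raw(pmax(x, x_b)))
    inb <- x > x_b - fl & x < x_b + fl
    if (any(inb)) {
      y[inb] <- .hermite_blend(x[inb], x_b - fl, x_b + fl,
                               R, ica_top_raw(x_b + fl), 0, slope_top)
    }
    y
  }
  slope_bot <- (eca_bot_raw(x_b + 1e-6) - eca_bot_raw(x_b)) / 1e-6
  bot_fun_raw <- function(x) {
    y <- ifelse(x <= x_b, -R, eca_bot_raw(pmax(x, x_b)))
    inb <- x > x_b - fl & x < x_b + fl
    if (any(inb)) {
      y[inb] <- .hermite_blend(x[inb], x_b - fl, x_b + fl,
                               -R, eca_bot_raw(x_b + fl), 0, slope_bot)
    }
    y
  }

  # ---- bumps on walls -----------------------------------------------------
  # arclength proxies along each wall: branch walls use centerline arclength
  s_ica <- function(x) (x - x_b) / ci
  s_eca <- function(x) (x - x_b) / ce

  bulb_amp <- (cf$bulb_diameter_factor - 1) * wi0
  bulb_fun <- function(x) {
    if (bulb_amp <= 0) return(0 * x)
    (bulb_amp / ci) * .bump(s_ica(x), 0, cf$L_ica / 3)
  }

  specs <- cf$plaque_specs
  get_spec <- function(site) {
    k <- vapply(specs, function(p) p$site == site, TRUE)
    if (any(k)) specs[[which(k)[1]]] else NULL
  }
  sp_ica  <- get_spec("OUTER_ICA")
  sp_eca  <- get_spec("OUTER_ECA")
  sp_rdg  <- get_spec("RIDGE")
  sp_cca  <- get_spec("OUTER_CCA")

  # plaque window centers (arclength along host wall): the ICA plaque sits
  # in the bulb/carotid sinus (the anatomical predilection site), the ECA
  # plaque at mid-branch
  c_ica <- if (!is.null(sp_ica)) cf$L_ica / 6 else NA
  c_eca <- if (!is.null(sp_eca)) 0.50 * cf$L_eca else NA

  # A ridge plaque is one plaque draped over the flow-divider wedge: each
  # face carries half the stated mean thickness (apex protrusion per face
  # equals the mean thickness).
  ridge_hi_fun <- function(x) {
    y <- ica_ridge(x)
    if (!is.null(sp_rdg)) {
      y <- y + (sp_rdg$mean_thickness / ci) *
        .bump(s_ica(x), 0, min(sp_rdg$length, cf$L_ica * 0.8))
    }
    y
  }
  ridge_lo_fun <- function(x) {
    y <- eca_ridge(x)
    if (!is.null(sp_rdg)) {
      y <- y - (sp_rdg$mean_thickness / ce) *
        .bump(s_eca(x), 0, min(sp_rdg$length, cf$L_eca * 0.8))
    }
    y
  }

  # outer-wall plaque thicknesses, capped at a fraction of the local
  # plaque-free half-width so nominal 3D plaque dimensions stay meaningful
  # in the planar lumen
  cap <- cf$plaque_obstruction_cap
  plaque_caps <- list()
  eff_ica <- if (!is.null(sp_ica)) {
    xc <- x_b + ci * c_ica
    w_loc <- (top_fun_raw(xc) + bulb_fun(xc) - ridge_hi_fun(xc)) * ci
    e <- min(sp_ica$mean_thickness, cap * w_loc / 2)
    if (e < sp_ica$mean_thickness)
      plaque_caps$OUTER_ICA <- c(stated = sp_ica$mean_thickness, used = e)
    e
  } else 0
  eff_eca <- if (!is.null(sp_eca)) {
    xc <- x_b + ce * c_eca
    w_loc <- (ridge_lo_fun(xc) - bot_fun_raw(xc)) * ce
    e <- min(sp_eca$mean_thickness, cap * w_loc / 2)
    if (e < sp_eca$mean_thickness)
      plaque_caps$OUTER_ECA <- c(stated = sp_eca$mean_thickness, used = e)
    e
  } else 0
  eff_cca <- if (!is.null(sp_cca)) {
    e <- min(sp_cca$mean_thickness, cap * R)
    if (e < sp_cca$mean_thickness)
      plaque_caps$OUTER_CCA <- c(stated = sp_cca$mean_thickness, used = e)
    e
  } else 0

  top_fun <- function(x) {
    y <- top_fun_raw(x) + bulb_fun(x)
    if (!is.null(sp_ica)) {
      y <- y - (2 * eff_ica / ci) *
        .bump(s_ica(x), c_ica - sp_ica$length / 2, sp_ica$length)
    }
    y
  }
  bot_fun <- function(x) {
    y <- bot_fun_raw(x)
    if (!is.null(sp_eca)) {
      y <- y + (2 * eff_eca / ce) *
        .bump(s_eca(x), c_eca - sp_eca$length / 2, sp_eca$length)
    }
    if (!is.null(sp_cca)) {
      # outer CCA plaque just proximal to the branch take-off
      x0 <- x_b - fl - sp_cca$length
      y <- y + 2 * eff_cca * .bump(x, x0, sp_cca$length)
    }
    y
  }

  # ---- feasibility: channels must stay open -------------------------------
  xs_i <- seq(x_b, x_end_i, by = ds)
  xs_e <- seq(x_b, x_end_e, by = ds)
  xs_c <- seq(0, x_b, by = ds)
  gap_i <- top_fun(xs_i) - ridge_hi_fun(xs_i)
  gap_e <- ridge_lo_fun(xs_e) - bot_fun(xs_e)
  gap_c <- top_fun(xs_c) - bot_fun(xs_c)
  min_gap <- 0.05 * min(wi0, we0)
  if (min(gap_c) <= min_gap)
    stop("geometry infeasible: CCA lumen closed (OUTER_CCA plaque too thick)")
  if (min(gap_i) <= min_gap)
    stop("geometry infeasible: ICA lumen closed (plaque at ",
         if (!is.null(sp_ica)) "OUTER_ICA" else "RIDGE", " too thick)")
  if (min(gap_e) <= min_gap)
    stop("geometry infeasible: ECA lumen closed (plaque at ",
         if (!is.null(sp_eca)) "OUTER_ECA" else "RIDGE", " too thick)")

  geom <- list(R = R, x_b = x_b, y_apex = y_apex, yA = yA, yB = yB,
               th_i = th_i, th_e = th_e, ci = ci, ce = ce,
               wi0 = wi0, we0 = we0, x_end_i = x_end_i, x_end_e = x_end_e,
               delta = delta, fillet = fl,
               bulb_apex_s = cf$L_ica / 6,
               plaque_centers = list(OUTER_ICA = c_ica, OUTER_ECA = c_eca),
               plaque_caps = plaque_caps)

  # ---- site windows (arclength ranges per wall) ---------------------------
  wbar <- (wi0 + we0) / 2
  n_center <- if (!is.null(sp_ica)) c_ica - sp_ica$length / 2 else cf$L_ica / 6
  sites <- list(
    M = list(wall = "bot", x_range = c(x_b - fl - 1.5 * cf$d_cca, x_b - fl)),
    N = list(wall = "top",
             x_range = x_b + ci * (n_center + c(-0.75, 0.75) * wi0)),
    O = list(wall = "ridge",
             s_range = c(0, 0.75 * wbar)),
    P = list(wall = "bot",
             x_range = x_b + ce * c(0.25 * we0, 0.25 * we0 + 1.5 * we0))
  )

  walls <- list(
    top = data.frame(x = c(xs_c, xs_i[-1]), y = top_fun(c(xs_c, xs_i[-1]))),
    bot = data.frame(x = c(xs_c, xs_e[-1]), y = bot_fun(c(xs_c, xs_e[-1]))),
    ridge_hi = data.frame(x = xs_i, y = ridge_hi_fun(xs_i)),
    ridge_lo = data.frame(x = xs_e, y = ridge_lo_fun(xs_e))
  )

  out <- structure(list(kind = "bifurcation", config = cf, geom = geom,
                        sites = sites, walls = walls,
                        funs = list(top = top_fun, bot = bot_fun,
                                    ridge_hi = ridge_hi_fun,
                                    ridge_lo = ridge_lo_fun)),
                   class = "carotid_outline")
  out$polygon <- .outline_polygon(out, ds)
  out
}

# closed, positively oriented tagged polygon for an outline
.outline_polygon <- function(out, ds) {
  g <- out$geom
  w <- out$walls
  # bottom wall left->right, ECA outlet up, ridge_lo right->left, tip face,
  # ridge_hi left->right, ICA outlet up, top wall right->left, inlet down
  pts <- rbind(
    cbind(w$bot$x, w$bot$y),
    cbind(rev(w$ridge_lo$x), rev(w$ridge_lo$y)),
    cbind(w$ridge_hi$x, w$ridge_hi$y),
    cbind(rev(w$top$x), rev(w$top$y))
  )
  # tags[i] labels edge from pts[i,] to pts[i+1,] (cyclically)
  tags <- c(rep("WALL", nrow(w$bot) - 1),
            "OUTLET_ECA",
            rep("WALL", nrow(w$ridge_lo) - 1),
            "WALL",                          # blunt tip face
            rep("WALL", nrow(w$ridge_hi) - 1),
            "OUTLET_ICA",
            rep("WALL", nrow(w$top) - 1),
            "INLET")
  list(xy = pts, edge_tag = tags)
}

#' Enclosed lumen area of an outline
#'
#' Shoelace area of the closed outline polygon (m^2).
#' @param outline A `carotid_outline` (or channel outline).
#' @export
outline_area <- function(outline) {
  p <- outline$polygon$xy
  n <- nrow(p)
  i2 <- c(2:n, 1)
  0.5 * abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]))
}

#' Rectangular channel outline
#'
#' A straight 2D channel of the given length and height, inlet at x = 0,
#' outlet at x = length, used for analytic validation (plane Poiseuille and
#' oscillatory channel flow).
#'
#' @param length,height Channel dimensions (m).
#' @export
build_channel_outline <- function(length = 32e-3, height = 6.35e-3) {
  stopifnot(length > 0, height > 0)
  R <- height / 2
  top_fun <- function(x) rep(R, base::length(x))
  bot_fun <- function(x) rep(-R, base::length(x))
  xs <- seq(0, length, length.out = 201)
  out <- structure(list(kind = "channel",
                        config = list(length = length, height = height),
                        geom = list(R = R, L = length),
                        sites = list(),
                        walls = list(top = data.frame(x = xs, y = R),
                                     bot = data.frame(x = xs, y = -R)),
                        funs = list(top = top_fun, bot = bot_fun)),
                   class = "carotid_outline")
  pts <- rbind(cbind(xs, -R), cbind(rev(xs), R))
  tags <- c(rep("WALL", 200), "OUTLET_ICA", rep("WALL", 200), "INLET")
  out$polygon <- list(xy = pts, edge_tag = tags)
  out
}

#' Minimum lumen width of a branch channel by normal-ray casting
#'
#' Brute-force measurement used in tests and geometry reports: for each
#' sample point on one wall, cast the inward normal ray and find the nearest
#' intersection with the opposite wall polyline; returns the minimum such
#' distance over the probed x-range.
#'
#' @param outline A `carotid_outline`.
#' @param channel `"ica"`, `"eca"` or `"cca"`.
#' @param x_range Range of x to probe (defaults to the full channel).
#' @param n Number of probe rays.
#' @export
min_lumen_width <- function(outline, channel = c("ica", "eca", "cca"),
                            x_range = NULL, n = 400) {
  channel <- match.arg(channel)
  g <- outline$geom
  f <- outline$funs
  pick <- switch(channel,
    ica = list(lo = f$ridge_hi, hi = f$top, xr = c(g$x_b, g$x_end_i)),
    eca = list(lo = f$bot, hi = f$ridge_lo, xr = c(g$x_b, g$x_end_e)),
    cca = list(lo = f$bot, hi = f$top, xr = c(0, g$x_b)))
  xr <- if (is.null(x_range)) pick$xr else x_range
  xr[1] <- max(xr[1], pick$xr[1]); xr[2] <- min(xr[2], pick$xr[2])
  xs <- seq(xr[1] + 1e-9, xr[2] - 1e-9, length.out = n)
  # opposite wall as dense polyline over the whole channel
  xd <- seq(pick$xr[1], pick$xr[2], length.out = 4000)
  hi <- cbind(xd, pick$hi(xd))
  eps <- 1e-6
  widths <- vapply(xs, function(x0) {
    y0 <- pick$lo(x0)
    # local tangent of the lower wall -> inward normal
    ty <- (pick$lo(min(x0 + eps, xr[2])) - pick$lo(max(x0 - eps, xr[1]))) /
      (min(x0 + eps, xr[2]) - max(x0 - eps, xr[1]))
    tv <- c(1, ty) / sqrt(1 + ty^2)
    nv <- c(-tv[2], tv[1])          # points into the lumen (upward-ish)
    # intersect ray (x0,y0) + t*nv with polyline hi
    p <- c(x0, y0)
    d1 <- hi[, 1] - p[1]; d2 <- hi[, 2] - p[2]
    # signed perpendicular distance of polyline points from the ray
    s <- d1 * nv[2] - d2 * nv[1]
    idx <- which(s[-length(s)] * s[-1] <= 0)
    if (!length(idx)) return(NA_real_)
    tt <- vapply(idx, function(i) {
      a <- hi[i, ]; bb <- hi[i + 1, ]
      den <- (bb[1] - a[1]) * nv[2] - (bb[2] - a[2]) * nv[1]
      if (abs(den) < 1e-18) return(NA_real_)
      u <- ((p[1] - a[1]) * nv[2] - (p[2] - a[2]) * nv[1]) / den
      q <- a + u * (bb - a)
      (q[1] - p[1]) * nv[1] + (q[2] - p[2]) * nv[2]
    }, numeric(1))
    tt <- tt[is.finite(tt) & tt > 0]
    if (!length(tt)) NA_real_ else min(tt)
  }, numeric(1))
  min(widths, na.rm = TRUE)
}
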