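# Lagrangian platelet-surrogate tracking through a stored flow field.
#
# Particles are released across the inlet with flux-proportional spatial
# and temporal density, advected through the cyclically replayed velocity
# frames (RK2, with an exponential Stokes-drag update in STOKES_DRAG mode),
# clamped reflectively at walls, and terminated at an outlet or at the
# censoring horizon.

#' Particle tracking parameters
#'
#' @param n_particles Number of released particles (default 10,000).
#' @param diameter Particle diameter (m); platelets are about 3 um.
#' @param density Particle density (kg/m^3); defaults to blood density,
#'   i.e. a neutrally buoyant surrogate.
#' @param mode `"TRACER"` (follow the fluid exactly) or `"STOKES_DRAG"`
#'   (linear drag with response time rho_p d^2 / (18 mu)).
#' @param seed RNG seed for reproducible seeding.
#' @param max_transit_cycles Censoring horizon in cardiac cycles; particles
#'   still inside at the horizon are RETAINED.
#' @export
particle_params <- function(n_particles = 10000L, diameter = 3e-6,
                            density = 1060, mode = c("TRACER", "STOKES_DRAG"),
                            seed = 1L, max_transit_cycles = 10L) {
  mode <- match.arg(mode)
  stopifnot(n_particles > 0, diameter > 0, density > 0,
            max_transit_cycles >= 1)
  structure(list(n_particles = as.integer(n_particles), diameter = diameter,
                 density = density, mode = mode, seed = as.integer(seed),
                 max_transit_cycles = as.integer(max_transit_cycles)),
            class = "particle_params")
}

#' Stokes response time of a particle
#'
#' \eqn{\tau_p = \rho_p d^2 / (18\mu)}; about 1.5e-7 s for a 3 um platelet
#' surrogate in blood, i.e. effectively a tracer.
#'
#' @param params A [particle_params()].
#' @param mu Fluid dynamic viscosity (Pa.s).
#' @export
stokes_response_time <- function(params, mu = 3.5e-3) {
  params$density * params$diameter^2 / (18 * mu)
}

#' Seed particles across the inlet
#'
#' Spatial positions are drawn with density proportional to the inlet axial
#' velocity profile (flux-proportional seeding) and release times are drawn
#' over one cardiac cycle with density proportional to the instantaneous
#' inlet flow rate. Reproducible for a fixed seed.
#'
#' @param params A [particle_params()].
#' @param mesh A `mesh2d` (its inlet segment is used).
#' @param waveform An [inlet_waveform()].
#' @param profile Inlet profile assumed for the flux weighting
#'   (`"parabolic"` or `"plug"`).
#' @return data.frame with columns `x`, `y`, `release_time`.
#' @export
seed_particles <- function(params, mesh, waveform = inlet_waveform(),
                           profile = c("parabolic", "plug")) {
  profile <- match.arg(profile)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)
  n <- params$n_particles
  ylo <- mesh$inlet$y_lo; yhi <- mesh$inlet$y_hi
  R <- (yhi - ylo) / 2; y0 <- (yhi + ylo) / 2
  # inverse-CDF sampling of the flux-weighted cross position
  yy <- seq(ylo + 1e-4 * R, yhi - 1e-4 * R, length.out = 2001)
  wgt <- if (profile == "plug") rep(1, length(yy)) else
    pmax(1 - ((yy - y0) / R)^2, 0)
  cdf <- cumsum(wgt); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  y <- stats::approx(cdf, yy, runif(n), ties = "ordered")$y
  # flux-weighted release times over one period
  tt <- seq(0, waveform$period, length.out = 2001)
  q <- pmax(inlet_velocity(tt, waveform), 0)
  cq <- cumsum(q); cq <- (cq - cq[1]) / (cq[length(cq)] - cq[1])
  rt <- stats::approx(cq, tt, runif(n), ties = "ordered")$y
  data.frame(x = rep(1e-6 * R, n), y = y, release_time = rt)
}

# nearest wall ids per block side (NA = interior pseudo-boundary)
.block_walls <- function(name) {
  switch(name,
         channel = c(lo = "bot", hi = "top"),
         cca_lo = c(lo = "bot", hi = NA),
         cca_hi = c(lo = NA, hi = "top"),
         cca_gap = c(lo = NA, hi = NA),
         ica = c(lo = "ridge_hi", hi = "top"),
         eca = c(lo = "bot", hi = "ridge_lo"),
         c(lo = NA, hi = NA))
}

# blended nodal velocity at cycle phase
.frame_blend <- function(field, phase) {
  nt <- length(field$times)
  if (nt == 1L) return(cbind(field$ux[, 1], field$uy[, 1]))
  Tp <- field$period
  ft <- field$times
  k <- findInterval(phase, ft)
  if (k == 0 || k == nt) {
    t0 <- ft[nt] - Tp; t1 <- ft[1]
    a <- (phase - if (k == 0) t0 else ft[nt]) / (t1 - t0)
    a <- min(max(a, 0), 1)
    cbind((1 - a) * field$ux[, nt] + a * field$ux[, 1],
          (1 - a) * field$uy[, nt] + a * field$uy[, 1])
  } else {
    a <- (phase - ft[k]) / (ft[k + 1] - ft[k])
    cbind((1 - a) * field$ux[, k] + a * field$ux[, k + 1],
          (1 - a) * field$uy[, k] + a * field$uy[, k + 1])
  }
}

#' Advect a seeded particle ensemble through a flow field
#'
#' The stored (periodic) flow field is replayed cyclically. Integration is
#' explicit RK2 with a global step bounded by the mesh size and peak speed.
#' Particles never cross walls: positions are clamped reflectively into the
#' lumen and the near-wall residence is logged. Each particle terminates at
#' an outlet or at the censoring horizon.
#'
#' @param ensemble Seed table from [seed_particles()].
#' @param field A `flow_field` (pulsatile or steady).
#' @param params A [particle_params()].
#' @param dt Integration step (s); default auto from mesh size and peak
#'   speed.
#' @param near_wall_band Near-wall band as a fraction of the local
#'   half-width (default 0.1).
#' @param stagnation_speed_frac Speed threshold of the stagnation map as a
#'   fraction of the cycle-mean inlet speed (default 0.05).
#' @return A `particle_ensemble` object.
#' @export
advect <- function(ensemble, field, params = particle_params(),
                   dt = NULL, near_wall_band = 0.1,
                   stagnation_speed_frac = 0.05, record_paths = FALSE) {
  mesh <- field$mesh
  n <- nrow(ensemble)
  Tp <- if (is.na(field$period)) 1 else field$period
  umax <- 0
  for (k in seq_along(field$times))
    umax <- max(umax, max(abs(field$ux[, k])), max(abs(field$uy[, k])))
  if (is.null(dt)) {
    dt <- 0.5 * mesh$characteristic_size / max(umax, 1e-6)
    if (length(field$times) > 1)
      dt <- min(dt, diff(field$times[1:2]))
  }
  u_ref <- if (field$kind == "pulsatile")
    waveform_mean(field$waveform) else
      max(abs(field$ux[, 1])) / 1.5
  stag_thresh <- stagnation_speed_frac * u_ref
  eta_band <- near_wall_band / 2       # band as fraction of full width

  horizon <- params$max_transit_cycles * Tp
  tau_p <- stokes_response_time(params, field$props$mu_newtonian)

  x <- ensemble$x; y <- ensemble$y
  rel <- ensemble$release_time
  cur_blk <- rep(NA_integer_, n)  # block each particle currently travels in
  state <- rep("PENDING", n)     # PENDING/ACTIVE/ICA/ECA/OUT/RETAINED/FLAGGED
  res_time <- rep(NA_real_, n)
  t_nw <- numeric(n)             # near-wall time
  vpx <- numeric(n); vpy <- numeric(n)   # particle velocity (STOKES_DRAG)

  # stagnation histogram: x-bins per wall id
  wall_ids <- c("bot", "top", "ridge_hi", "ridge_lo")
  xr <- range(mesh$nodes[, 1])
  nbin <- 60L
  brk <- seq(xr[1], xr[2], length.out = nbin + 1)
  stag <- matrix(0, nbin, length(wall_ids),
                 dimnames = list(NULL, wall_ids))

  # outlet stations per block
  block_xmax <- vapply(mesh$blocks, function(b) max(b$xcols), numeric(1))
  block_has_outlet <- vapply(mesh$blocks, function(b)
    b$name %in% c("channel", "ica", "eca"), logical(1))
  block_exit <- vapply(mesh$blocks, function(b)
    switch(b$name, ica = "ICA", eca = "ECA", channel = "OUT", NA_character_),
    character(1))

  clock <- 0
  drag <- params$mode == "STOKES_DRAG"
  paths <- if (record_paths) vector("list", 4096) else NULL
  np_rec <- 0L
  while (any(state %in% c("PENDING", "ACTIVE")) && clock < Tp + horizon) {
    state[state == "PENDING" & rel <= clock] <- "ACTIVE"
    act <- which(state == "ACTIVE")
    if (length(act)) {
      ph <- clock %% Tp
      U1 <- .frame_blend(field, ph)
      u1 <- matrix(interpolate_field(mesh, U1, x[act], y[act]), ncol = 2)
      u1[!is.finite(u1)] <- 0
      if (drag) {
        a <- exp(-dt / tau_p)
        vx <- u1[, 1] + (vpx[act] - u1[, 1]) * a
        vy <- u1[, 2] + (vpy[act] - u1[, 2]) * a
      } else { vx <- u1[, 1]; vy <- u1[, 2] }
      xm <- x[act] + dt * vx; ym <- y[act] + dt * vy
      U2 <- .frame_blend(field, (clock + dt) %% Tp)
      u2 <- matrix(interpolate_field(mesh, U2, xm, ym), ncol = 2)
      bad2 <- !is.finite(u2[, 1])
      u2[bad2, ] <- u1[bad2, ]
      if (drag) {
        vx2 <- u2[, 1] + (vx - u2[, 1]) * exp(-dt / tau_p)
        vy2 <- u2[, 2] + (vy - u2[, 2]) * exp(-dt / tau_p)
      } else { vx2 <- u2[, 1]; vy2 <- u2[, 2] }
      xn <- x[act] + dt * 0.5 * (vx + vx2)
      yn <- y[act] + dt * 0.5 * (vy + vy2)
      if (drag) { vpx[act] <- 0.5 * (vx + vx2); vpy[act] <- 0.5 * (vy + vy2) }

      loc <- .locate_points(mesh, xn, yn, nearest = TRUE)
      spd <- sqrt((0.5 * (vx + vx2))^2 + (0.5 * (vy + vy2))^2)
      for (ii in seq_along(act)) {
        p <- act[ii]
        # outlet crossing of the block the particle was traveling in
        pb <- cur_blk[p]
        if (!is.na(pb) && block_has_outlet[pb] &&
            xn[ii] >= block_xmax[pb] - 1e-12) {
          state[p] <- block_exit[pb]
          res_time[p] <- clock + dt - rel[p]
          next
        }
        bi <- loc$block[ii]
        if (is.na(bi)) {
          # beyond an outlet? otherwise flag
          past <- which(block_has_outlet & xn[ii] >= block_xmax - 1e-12)
          if (length(past)) {
            state[p] <- block_exit[past[1]]
            res_time[p] <- clock + dt - rel[p]
          } else state[p] <- "FLAGGED"
          next
        }
        b <- mesh$blocks[[bi]]
        eta <- loc$eta[ii]
        # reflective clamp into the lumen
        if (loc$eta[ii] < 0.002 || loc$eta[ii] > 0.998) {
          eta <- min(max(eta, 0.002), 0.998)
          k <- loc$k[ii]; t_ <- loc$xi[ii]
          nr <- ncol(b$idx)
          ylo_ <- (1 - t_) * mesh$nodes[b$idx[k, 1], 2] +
            t_ * mesh$nodes[b$idx[k + 1, 1], 2]
          yhi_ <- (1 - t_) * mesh$nodes[b$idx[k, nr], 2] +
            t_ * mesh$nodes[b$idx[k + 1, nr], 2]
          yn[ii] <- ylo_ + eta * (yhi_ - ylo_)
        }
        # outlet crossing of the newly entered block
        if (block_has_outlet[bi] && xn[ii] >= block_xmax[bi] - 1e-12) {
          state[p] <- block_exit[bi]
          res_time[p] <- clock + dt - rel[p]
          next
        }
        cur_blk[p] <- bi
        # near-wall logging
        wd <- .block_walls(b$name)
        side <- if (eta < eta_band) "lo" else if (eta > 1 - eta_band) "hi"
                else NA
        if (!is.na(side) && !is.na(wd[[side]])) {
          t_nw[p] <- t_nw[p] + dt
          if (spd[ii] < stag_thresh) {
            bn <- min(max(findInterval(xn[ii], brk), 1L), nbin)
            stag[bn, wd[[side]]] <- stag[bn, wd[[side]]] + dt
          }
        }
        x[p] <- xn[ii]; y[p] <- yn[ii]
      }
      if (record_paths) {
        np_rec <- np_rec + 1L
        paths[[np_rec]] <- data.frame(id = act, t = clock + dt,
                                      x = x[act], y = y[act])
      }
    }
    clock <- clock + dt
  }
  retained <- state %in% c("ACTIVE", "PENDING")
  state[retained] <- "RETAINED"
  res_time[state == "RETAINED"] <- horizon
  nwf <- ifelse(is.na(res_time) | res_time <= 0, 0, t_nw / res_time)

  structure(list(
    particles = data.frame(x0 = ensemble$x, y0 = ensemble$y,
                           release_time = rel, exit = state,
                           residence_time = res_time,
                           near_wall_fraction = nwf),
    stagnation = list(breaks = brk, hist = stag),
    trajectories = if (record_paths)
      do.call(rbind, paths[seq_len(np_rec)]) else NULL,
    dt = dt, params = params),
    class = "particle_ensemble")
}

#' Residence-time and branch-split statistics
#'
#' @param ensemble A `particle_ensemble` from [advect()].
#' @return List with per-branch PRT summaries, exit fractions, retained
#'   fraction and the near-wall stagnation histogram.
#' @export
residence_statistics <- function(ensemble) {
  p <- ensemble$particles
  if (!nrow(p)) stop("empty particle ensemble")
  ok <- p$exit != "FLAGGED"
  n_ok <- sum(ok)
  tab <- table(factor(p$exit[ok],
                      levels = unique(c("ICA", "ECA", "OUT", "RETAINED",
                                        unique(p$exit[ok])))))
  frac <- as.numeric(tab) / n_ok
  names(frac) <- names(tab)
  per_branch <- do.call(rbind, lapply(names(tab)[tab > 0], function(br) {
    rt <- p$residence_time[ok & p$exit == br]
    data.frame(branch = br, n = length(rt), prt_mean = mean(rt),
               prt_median = stats::median(rt))
  }))
  list(exit_fractions = frac[frac > 0 | names(frac) %in%
                               c("ICA", "ECA", "RETAINED")],
       retained_fraction = unname(frac["RETAINED"]),
       flagged = sum(!ok),
       per_branch = per_branch,
       stagnation = ensemble$stagnation)
}
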