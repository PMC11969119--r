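# Unsteady incompressible Navier-Stokes on the triangulated lumen.
#
# Discretization: equal-order P1-P1 finite elements with SUPG/PSPG
# stabilization, stress-divergence viscous form (variable Carreau-Yasuda
# viscosity), backward-Euler time stepping. The momentum advection velocity,
# the effective viscosity and the stabilization parameters are Picard-lagged
# and refreshed every few steps, so the sparse LU factorization is reused
# between refreshes. Summing the (unconstrained) continuity rows shows that
# the discrete solution balances inlet and outlet fluxes exactly up to
# linear-solver precision: PSPG terms telescope out for a constant pressure
# test function.

#' Solver settings
#'
#' @param dt Time step (s).
#' @param n_cycles Maximum number of cardiac cycles to march.
#' @param store_per_cycle Number of uniformly spaced instants stored per
#'   cycle for post-processing.
#' @param refresh_every Steps between refreshes of the lagged advection
#'   velocity / viscosity / stabilization (and the LU factorization).
#' @param picard_tolerance Relative update tolerance of the steady Picard
#'   iteration.
#' @param max_picard Iteration cap of the steady Picard loop.
#' @param relax Under-relaxation factor of the steady Picard update.
#' @param divergence_tolerance Admissible instantaneous relative mass defect.
#' @param cycle_convergence_tol Relative L2 change between consecutive
#'   cycles below which the pulsatile march stops.
#' @param inlet_profile `"parabolic"` (the waveform is the cross-section
#'   mean of a Poiseuille profile) or `"plug"`.
#' @param inlet_profile_fun Optional `function(y, t)` overriding the inlet
#'   axial velocity profile entirely (used for analytic benchmarks).
#' @export
solver_settings <- function(dt = 1e-3, n_cycles = 3L, store_per_cycle = 100L,
                            refresh_every = 5L, picard_tolerance = 1e-4,
                            max_picard = 40L, relax = 0.7,
                            divergence_tolerance = 1e-3,
                            cycle_convergence_tol = 1e-2,
                            inlet_profile = c("parabolic", "plug"),
                            inlet_profile_fun = NULL) {
  inlet_profile <- match.arg(inlet_profile)
  stopifnot(dt > 0, n_cycles >= 1, picard_tolerance > 0,
            divergence_tolerance > 0, cycle_convergence_tol > 0)
  structure(list(dt = dt, n_cycles = as.integer(n_cycles),
                 store_per_cycle = as.integer(store_per_cycle),
                 refresh_every = as.integer(refresh_every),
                 picard_tolerance = picard_tolerance,
                 max_picard = as.integer(max_picard), relax = relax,
                 divergence_tolerance = divergence_tolerance,
                 cycle_convergence_tol = cycle_convergence_tol,
                 inlet_profile = inlet_profile,
                 inlet_profile_fun = inlet_profile_fun),
            class = "solver_settings")
}

# ---- element precomputation -----------------------------------------------

.element_data <- function(mesh) {
  p <- mesh$nodes; t <- mesh$triangles
  x1 <- p[t[, 1], 1]; y1 <- p[t[, 1], 2]
  x2 <- p[t[, 2], 1]; y2 <- p[t[, 2], 2]
  x3 <- p[t[, 3], 1]; y3 <- p[t[, 3], 2]
  A2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  A <- A2 / 2
  B <- cbind(y2 - y3, y3 - y1, y1 - y2) / A2      # dN/dx
  C <- cbind(x3 - x2, x1 - x3, x2 - x1) / A2      # dN/dy
  list(tri = t, A = A, B = B, C = C, n = nrow(p), m = nrow(t))
}

# element-mean velocity and shear rate from nodal fields
.element_state <- function(el, ux, uy) {
  t <- el$tri
  wx <- (ux[t[, 1]] + ux[t[, 2]] + ux[t[, 3]]) / 3
  wy <- (uy[t[, 1]] + uy[t[, 2]] + uy[t[, 3]]) / 3
  dudx <- rowSums(el$B * cbind(ux[t[, 1]], ux[t[, 2]], ux[t[, 3]]))
  dudy <- rowSums(el$C * cbind(ux[t[, 1]], ux[t[, 2]], ux[t[, 3]]))
  dvdx <- rowSums(el$B * cbind(uy[t[, 1]], uy[t[, 2]], uy[t[, 3]]))
  dvdy <- rowSums(el$C * cbind(uy[t[, 1]], uy[t[, 2]], uy[t[, 3]]))
  gam <- sqrt(2 * dudx^2 + 2 * dvdy^2 + (dudy + dvdx)^2)
  list(wx = wx, wy = wy, shear = gam)
}

# stabilization parameter per element (tau in seconds)
.tau_e <- function(el, wx, wy, mu_e, rho, dt = NULL) {
  speed <- sqrt(wx^2 + wy^2)
  h_geo <- sqrt(2 * abs(el$A))
  # streamline element length
  wgx <- wx / pmax(speed, 1e-12); wgy <- wy / pmax(speed, 1e-12)
  den <- abs(wgx * el$B[, 1] + wgy * el$C[, 1]) +
    abs(wgx * el$B[, 2] + wgy * el$C[, 2]) +
    abs(wgx * el$B[, 3] + wgy * el$C[, 3])
  h_adv <- ifelse(den > 1e-12, 2 / den, h_geo)
  nu <- mu_e / rho
  inv2 <- (2 * speed / h_adv)^2 + 9 * (4 * nu / h_geo^2)^2
  if (!is.null(dt)) inv2 <- inv2 + (2 / dt)^2
  1 / sqrt(inv2)
}

# Assemble the coupled system. Returns list(A, B_rhs) as dgCMatrix; rows of
# constrained dofs replaced by identity. When dt is NULL (steady) B_rhs is
# absent.
.assemble_system <- function(el, wx, wy, mu_e, tau, rho, dt, constrained) {
  m <- el$m; n <- el$n
  A_ <- el$A; B <- el$B; C <- el$C
  T <- el$tri
  WG <- cbind(wx * B[, 1] + wy * C[, 1],
              wx * B[, 2] + wy * C[, 2],
              wx * B[, 3] + wy * C[, 3])
  rows <- vector("list", 32); cols <- vector("list", 32)
  vals <- vector("list", 32); nt <- 0L
  add <- function(r, cc, v) {
    nt <<- nt + 1L
    rows[[nt]] <<- r; cols[[nt]] <<- cc; vals[[nt]] <<- v
  }
  rrows <- list(); rcols <- list(); rvals <- list(); rt <- 0L
  addr <- function(r, cc, v) {
    rt <<- rt + 1L
    rrows[[rt]] <<- r; rcols[[rt]] <<- cc; rvals[[rt]] <<- v
  }
  transient <- !is.null(dt)
  for (i in 1:3) {
    ni <- T[, i]; bi <- B[, i]; ci <- C[, i]; wgi <- WG[, i]
    for (j in 1:3) {
      nj <- T[, j]; bj <- B[, j]; cj <- C[, j]; wgj <- WG[, j]
      mass <- A_ * (1 + (i == j)) / 12
      adv <- rho * A_ / 3 * wgj
      supg_adv <- rho * tau * A_ * wgi * wgj
      kxx <- mu_e * A_ * (2 * bi * bj + ci * cj)
      kyy <- mu_e * A_ * (bi * bj + 2 * ci * cj)
      kxy <- mu_e * A_ * ci * bj
      kyx <- mu_e * A_ * bi * cj
      diag_uu <- adv + supg_adv
      if (transient) diag_uu <- diag_uu + rho * mass / dt +
          rho * tau / dt * wgi * A_ / 3
      # momentum x row
      add(ni, nj, kxx + diag_uu)
      add(ni, nj + n, kxy)
      add(ni, nj + 2 * n, -A_ / 3 * bi + tau * A_ * wgi * bj)
      # momentum y row
      add(ni + n, nj + n, kyy + diag_uu)
      add(ni + n, nj, kyx)
      add(ni + n, nj + 2 * n, -A_ / 3 * ci + tau * A_ * wgi * cj)
      # continuity row
      add(ni + 2 * n, nj, A_ / 3 * bj + tau * A_ * bi * wgj +
            if (transient) tau / dt * A_ / 3 * bi else 0)
      add(ni + 2 * n, nj + n, A_ / 3 * cj + tau * A_ * ci * wgj +
            if (transient) tau / dt * A_ / 3 * ci else 0)
      add(ni + 2 * n, nj + 2 * n, tau / rho * A_ * (bi * bj + ci * cj))
      if (transient) {
        addr(ni, nj, rho * mass / dt + rho * tau / dt * wgi * A_ / 3)
        addr(ni + n, nj + n, rho * mass / dt + rho * tau / dt * wgi * A_ / 3)
        addr(ni + 2 * n, nj, tau / dt * A_ / 3 * bi)
        addr(ni + 2 * n, nj + n, tau / dt * A_ / 3 * ci)
      }
    }
  }
  ri <- unlist(rows); cj_ <- unlist(cols); vv <- unlist(vals)
  keep <- !(ri %in% constrained)
  ri <- c(ri[keep], constrained)
  cj_ <- c(cj_[keep], constrained)
  vv <- c(vv[keep], rep(1, length(constrained)))
  Amat <- Matrix::sparseMatrix(i = ri, j = cj_, x = vv,
                               dims = c(3 * n, 3 * n))
  out <- list(A = Amat)
  if (transient) {
    out$B_rhs <- Matrix::sparseMatrix(i = unlist(rrows), j = unlist(rcols),
                                      x = unlist(rvals),
                                      dims = c(3 * n, 3 * n))
  }
  out
}

# ---- boundary conditions --------------------------------------------------

.dirichlet_sets <- function(mesh) {
  wall_nodes <- unique(c(mesh$boundary_edges$n1[mesh$boundary_edges$tag == "WALL"],
                         mesh$boundary_edges$n2[mesh$boundary_edges$tag == "WALL"]))
  inlet_nodes <- setdiff(mesh$inlet$nodes, wall_nodes)
  n <- nrow(mesh$nodes)
  list(wall = wall_nodes, inlet = inlet_nodes,
       constrained = c(wall_nodes, wall_nodes + n,
                       inlet_nodes, inlet_nodes + n))
}

# inlet axial profile with cross-section mean u_mean
.inlet_profile_values <- function(mesh, u_mean, profile) {
  y <- mesh$nodes[, 2]
  R <- (mesh$inlet$y_hi - mesh$inlet$y_lo) / 2
  y0 <- (mesh$inlet$y_hi + mesh$inlet$y_lo) / 2
  if (profile == "plug") rep(u_mean, nrow(mesh$nodes))
  else 1.5 * u_mean * (1 - ((y - y0) / R)^2)
}

# boundary flux through a tag (positive in +x; inlet and outlets are
# vertical sections)
.tag_flux <- function(mesh, ux, tag) {
  be <- mesh$boundary_edges
  k <- be$tag == tag
  if (!any(k)) return(0)
  n1 <- be$n1[k]; n2 <- be$n2[k]
  dy <- abs(mesh$nodes[n2, 2] - mesh$nodes[n1, 2])
  sum(dy / 2 * (ux[n1] + ux[n2]))
}

#' Instantaneous mass defect of a flow field
#'
#' Relative imbalance between inlet and total outlet fluxes per stored
#' instant.
#' @param field A `flow_field`.
#' @return Numeric vector (one per stored instant).
#' @export
mass_defect <- function(field) {
  vapply(seq_along(field$times), function(k) {
    qin <- .tag_flux(field$mesh, field$ux[, k], "INLET")
    qica <- .tag_flux(field$mesh, field$ux[, k], "OUTLET_ICA")
    qeca <- .tag_flux(field$mesh, field$ux[, k], "OUTLET_ECA")
    abs(qin - qica - qeca) / max(abs(qin), 1e-12)
  }, numeric(1))
}

#' Flow split between the branches
#'
#' @param field A `flow_field`.
#' @return Data frame with cycle-mean outlet flux per branch and the ICA
#'   fraction.
#' @export
flow_split <- function(field) {
  qica <- mean(vapply(seq_along(field$times), function(k)
    .tag_flux(field$mesh, field$ux[, k], "OUTLET_ICA"), numeric(1)))
  qeca <- mean(vapply(seq_along(field$times), function(k)
    .tag_flux(field$mesh, field$ux[, k], "OUTLET_ECA"), numeric(1)))
  data.frame(q_ica = qica, q_eca = qeca,
             ica_fraction = qica / (qica + qeca))
}

# ---- steady solver --------------------------------------------------------

#' Steady flow solve
#'
#' Picard iteration on the stabilized steady Navier-Stokes system with
#' under-relaxation and lagged viscosity; continuation in the inflow
#' magnitude is applied automatically at higher Reynolds numbers.
#'
#' @param mesh A `mesh2d`.
#' @param inflow_mean Cross-section mean inlet velocity (m/s).
#' @param props A [fluid_props()].
#' @param settings A [solver_settings()].
#' @return A `flow_field` with a single stored instant.
#' @export
solve_steady <- function(mesh, inflow_mean, props = fluid_props(),
                         settings = solver_settings()) {
  el <- .element_data(mesh)
  ds <- .dirichlet_sets(mesh)
  n <- el$n
  d_in <- mesh$inlet$y_hi - mesh$inlet$y_lo
  re <- reynolds_number(inflow_mean, d_in, props)
  if (re >= 1200)
    warning("inlet Reynolds number ", round(re), " >= 1200: laminar ",
            "assumption questionable")
  stages <- if (re > 400) c(0.4, 0.7, 1) else 1
  U <- numeric(3 * n)
  hist <- numeric(0)
  for (stg in stages) {
    prof <- .inlet_profile_values(mesh, stg * inflow_mean,
                                  settings$inlet_profile)
    bcval <- numeric(3 * n)
    bcval[ds$inlet] <- prof[ds$inlet]
    converged <- FALSE
    for (it in seq_len(settings$max_picard)) {
      st <- .element_state(el, U[1:n], U[n + 1:n])
      mu_e <- effective_viscosity(st$shear, props)
      tau <- .tau_e(el, st$wx, st$wy, mu_e, props$rho)
      sys <- .assemble_system(el, st$wx, st$wy, mu_e, tau, props$rho,
                              dt = NULL, constrained = ds$constrained)
      rhs <- numeric(3 * n)
      rhs[ds$constrained] <- bcval[ds$constrained]
      Unew <- as.numeric(Matrix::solve(sys$A, rhs))
      if (any(!is.finite(Unew))) stop("steady solve diverged (non-finite)")
      w <- settings$relax
      Uup <- w * Unew + (1 - w) * U
      rel <- sqrt(sum((Uup[1:(2 * n)] - U[1:(2 * n)])^2)) /
        max(sqrt(sum(Uup[1:(2 * n)]^2)), 1e-14)
      U <- Uup
      hist <- c(hist, rel)
      if (rel < settings$picard_tolerance) { converged <- TRUE; break }
    }
    if (!converged && stg == 1 &&
        hist[length(hist)] > 100 * settings$picard_tolerance) {
      stop("steady Picard iteration failed to converge; residual history: ",
           paste(signif(utils::tail(hist, 5), 3), collapse = ", "))
    }
  }
  field <- structure(list(mesh = mesh, times = 0,
                          ux = matrix(U[1:n], ncol = 1),
                          uy = matrix(U[n + 1:n], ncol = 1),
                          p = matrix(U[2 * n + 1:n], ncol = 1),
                          period = NA_real_, props = props,
                          settings = settings, kind = "steady",
                          diagnostics = list(picard_history = hist)),
                     class = "flow_field")
  field$diagnostics$mass_defect <- mass_defect(field)
  field
}

# ---- pulsatile solver -----------------------------------------------------

#' Pulsatile flow solve
#'
#' Marches the stabilized system with backward-Euler steps from rest until
#' consecutive cardiac cycles agree to `cycle_convergence_tol` (or
#' `n_cycles` is reached) and returns the final cycle. The outlet boundary
#' condition is traction-free, equivalent to the equal fixed pressure
#' applied at both outlets (the uniform 13,332 Pa outlet load only shifts
#' the pressure gauge).
#'
#' @param mesh A `mesh2d`.
#' @param waveform An [inlet_waveform()] giving the mean inlet velocity.
#' @param props A [fluid_props()].
#' @param settings A [solver_settings()].
#' @param outlet_pressure Reference outlet pressure (Pa) added to the
#'   reported pressure field.
#' @param verbose Print cycle-level progress.
#' @return A `flow_field` with `store_per_cycle` instants over the final
#'   cycle.
#' @export
solve_pulsatile <- function(mesh, waveform = inlet_waveform(),
                            props = fluid_props(),
                            settings = solver_settings(),
                            outlet_pressure = 13332, verbose = FALSE) {
  el <- .element_data(mesh)
  ds <- .dirichlet_sets(mesh)
  n <- el$n
  dt <- settings$dt
  Tp <- waveform$period
  steps_per_cycle <- round(Tp / dt)
  stopifnot(steps_per_cycle >= 20)
  store_every <- max(1L, round(steps_per_cycle / settings$store_per_cycle))
  store_idx <- seq(store_every, steps_per_cycle, by = store_every)
  nstore <- length(store_idx)

  prof_fun <- settings$inlet_profile_fun
  base_prof <- .inlet_profile_values(mesh, 1, settings$inlet_profile)
  yin <- mesh$nodes[, 2]

  U <- numeric(3 * n)
  prev_frames <- NULL
  frames_ux <- matrix(0, n, nstore); frames_uy <- matrix(0, n, nstore)
  frames_p <- matrix(0, n, nstore); frame_t <- numeric(nstore)
  cycle_change <- numeric(0)
  max_speed <- 0
  luA <- NULL; Brhs <- NULL
  d_in <- mesh$inlet$y_hi - mesh$inlet$y_lo

  for (cyc in seq_len(settings$n_cycles)) {
    ks <- 0L
    for (s in seq_len(steps_per_cycle)) {
      t_new <- (cyc - 1) * Tp + s * dt
      if (is.null(luA) || (s - 1) %% settings$refresh_every == 0) {
        st <- .element_state(el, U[1:n], U[n + 1:n])
        mu_e <- effective_viscosity(st$shear, props)
        tau <- .tau_e(el, st$wx, st$wy, mu_e, props$rho, dt)
        sys <- .assemble_system(el, st$wx, st$wy, mu_e, tau, props$rho,
                                dt = dt, constrained = ds$constrained)
        luA <- Matrix::lu(sys$A)
        Brhs <- sys$B_rhs
      }
      rhs <- as.numeric(Brhs %*% U)
      if (is.null(prof_fun)) {
        um <- inlet_velocity(t_new, waveform)
        vals <- um * base_prof
      } else {
        vals <- prof_fun(yin, t_new)
      }
      rhs[ds$constrained] <- 0
      rhs[ds$inlet] <- vals[ds$inlet]
      U <- as.numeric(Matrix::solve(luA, rhs))
      if (any(!is.finite(U)))
        stop("pulsatile solve diverged at t = ", signif(t_new, 4), " s")
      if (s %in% store_idx) {
        ks <- ks + 1L
        frames_ux[, ks] <- U[1:n]
        frames_uy[, ks] <- U[n + 1:n]
        frames_p[, ks] <- U[2 * n + 1:n]
        frame_t[ks] <- s * dt
        sp <- max(sqrt(U[1:n]^2 + U[n + 1:n]^2))
        if (sp > max_speed) max_speed <- sp
      }
    }
    if (!is.null(prev_frames)) {
      num <- sqrt(sum((frames_ux - prev_frames$ux)^2 +
                        (frames_uy - prev_frames$uy)^2))
      den <- max(sqrt(sum(frames_ux^2 + frames_uy^2)), 1e-14)
      cycle_change <- c(cycle_change, num / den)
      if (verbose) message("cycle ", cyc, ": relative change ",
                           signif(num / den, 3))
      if (num / den < settings$cycle_convergence_tol && cyc >= 2) break
    }
    prev_frames <- list(ux = frames_ux, uy = frames_uy)
  }

  hx <- mean(diff(mesh$blocks[[1]]$xcols))
  field <- structure(list(mesh = mesh, times = frame_t,
                          ux = frames_ux, uy = frames_uy,
                          p = frames_p + outlet_pressure,
                          period = Tp, waveform = waveform, props = props,
                          settings = settings, kind = "pulsatile",
                          diagnostics = list(
                            cycles_run = cyc,
                            cycle_change = cycle_change,
                            cfl = max_speed * dt / hx)),
                     class = "flow_field")
  field$diagnostics$mass_defect <- mass_defect(field)
  md <- max(field$diagnostics$mass_defect)
  if (md > settings$divergence_tolerance)
    warning("instantaneous mass defect ", signif(md, 3),
            " exceeds tolerance ", settings$divergence_tolerance)
  field
}

#' @export
print.flow_field <- function(x, ...) {
  cat("flow_field (", x$kind, "): ", nrow(x$ux), " nodes, ",
      length(x$times), " stored instants\n", sep = "")
  if (!is.null(x$diagnostics$mass_defect))
    cat("  max mass defect:", signif(max(x$diagnostics$mass_defect), 3), "\n")
  invisible(x)
}

# ---- mesh independence ----------------------------------------------------

#' Mesh refinement study with grid convergence index
#'
#' Runs steady solves of a configuration at a descending sequence of mesh
#' sizes, monitors the peak wall shear stress magnitude on the flanks of
#' the bifurcation ridge, and computes the fine-grid grid convergence index
#' (GCI, safety factor 1.25) by Richardson extrapolation.
#'
#' @param config A [bifurcation_config()].
#' @param sizes Characteristic mesh sizes (m), strictly decreasing, at
#'   least 3.
#' @param inflow_mean Mean inlet velocity for the steady solves; defaults
#'   to the cycle mean of the standard waveform.
#' @param props,settings Solver inputs.
#' @return A data.frame (one row per size) plus attributes `gci_percent`,
#'   `order`, and `reliable`.
#' @export
mesh_independence_study <- function(config, sizes,
                                    inflow_mean = NULL,
                                    props = fluid_props(),
                                    settings = solver_settings()) {
  stopifnot(length(sizes) >= 3, all(diff(sizes) < 0))
  if (is.null(inflow_mean)) inflow_mean <- waveform_mean(inlet_waveform())
  outline <- build_outline(config)
  vals <- numeric(length(sizes)); nnodes <- integer(length(sizes))
  for (k in seq_along(sizes)) {
    mesh <- generate_mesh(outline, sizes[k])
    fld <- solve_steady(mesh, inflow_mean, props, settings)
    vals[k] <- ridge_flank_peak_wss(fld, method = "field",
                                    window = c(0.5, 1.5))
    nnodes[k] <- nrow(mesh$nodes)
  }
  nk <- length(sizes)
  relchg <- c(NA, abs(diff(vals)) / abs(vals[-1]) * 100)
  # Richardson extrapolation on the three finest levels
  f1 <- vals[nk]; f2 <- vals[nk - 1]; f3 <- vals[nk - 2]
  r <- sizes[nk - 1] / sizes[nk]
  ratio <- (f3 - f2) / (f2 - f1)
  reliable <- is.finite(ratio) && ratio > 0
  p <- if (reliable) log(ratio) / log(r) else 2
  gci <- 1.25 * abs((f2 - f1) / f1) / (r^p - 1) * 100
  out <- data.frame(size = sizes, n_nodes = nnodes, peak_ridge_wss = vals,
                    rel_change_pct = relchg)
  attr(out, "gci_percent") <- gci
  attr(out, "order") <- p
  attr(out, "reliable") <- reliable
  out
}

# ---- analytic benchmark ---------------------------------------------------

#' Oscillatory channel-flow solution
#'
#' Exact velocity profile of plane pulsatile (Womersley-type) flow in a 2D
#' channel driven so that the cross-section mean velocity is
#' `u0 + u1*cos(omega t)`: the steady part is the Poiseuille parabola and
#' the oscillatory part is the cosh-profile series solution.
#'
#' @param y Cross-channel coordinates (m), relative to the centerline.
#' @param t Time (s), scalar.
#' @param half_width Channel half-width (m).
#' @param nu Kinematic viscosity (m^2/s).
#' @param u0 Steady mean velocity (m/s).
#' @param u1 Oscillatory mean-velocity amplitude (m/s).
#' @param omega Angular frequency (rad/s).
#' @return Axial velocity at (y, t).
#' @export
womersley_channel_solution <- function(y, t, half_width, nu, u0, u1, omega) {
  a <- half_width
  steady <- 1.5 * u0 * (1 - (y / a)^2)
  if (u1 == 0) return(steady)
  beta <- sqrt(complex(imaginary = omega / nu))
  shape <- 1 - cosh(beta * y) / cosh(beta * a)
  mean_shape <- 1 - tanh(beta * a) / (beta * a)
  steady + Re(u1 / mean_shape * shape * exp(complex(imaginary = omega * t)))
}
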