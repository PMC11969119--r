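# Constitutive model, boundary conditions and dimensionless numbers for
# pulsatile carotid flow.

#' Blood fluid properties
#'
#' Container for the bulk fluid properties used throughout the solver and the
#' dimensionless-number calculators. Blood density defaults to 1060 kg/m^3.
#' The Newtonian viscosity is used directly when `rheology = "newtonian"` and
#' as the reference viscosity for Reynolds/Womersley numbers otherwise.
#'
#' @param rho Density in kg/m^3 (> 0).
#' @param mu Newtonian dynamic viscosity in Pa.s. Physiological whole-blood
#'   values lie in 3e-3 to 4e-3 Pa.s; values outside that band are rejected
#'   unless `validate = FALSE`.
#' @param rheology `"carreau_yasuda"` (shear-thinning, the default) or
#'   `"newtonian"`.
#' @param cy Carreau-Yasuda parameter set, see [carreau_yasuda_params()].
#' @param validate Set `FALSE` to allow viscosities outside the
#'   physiological band (e.g. for sensitivity studies).
#' @return An object of class `fluid_props`.
#' @export
fluid_props <- function(rho = 1060, mu = 3.5e-3,
                        rheology = c("carreau_yasuda", "newtonian"),
                        cy = carreau_yasuda_params(), validate = TRUE) {
  rheology <- match.arg(rheology)
  stopifnot(is.numeric(rho), length(rho) == 1L, rho > 0,
            is.numeric(mu), length(mu) == 1L, mu > 0)
  if (validate && (mu < 3e-3 || mu > 4e-3)) {
    stop("Newtonian viscosity ", mu, " Pa.s outside the physiological band ",
         "[3e-3, 4e-3]; pass validate = FALSE to override.")
  }
  structure(list(rho = rho, mu_newtonian = mu, rheology = rheology, cy = cy),
            class = "fluid_props")
}

#' Carreau-Yasuda parameters for blood
#'
#' Shear-thinning viscosity law
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)\,
#'   [1 + (\lambda\dot\gamma)^a]^{(n-1)/a}.}
#' Zero-shear and infinite-shear plateaus default to 56 mPa.s and 3.45 mPa.s
#' with time constant 3.313 s. The power index `n` and Yasuda exponent `a`
#' default to the standard blood values 0.3568 and 2 (with `a = 2` the law
#' reduces to the Carreau model).
#'
#' @param mu_inf,mu_0 Infinite- and zero-shear viscosities (Pa.s),
#'   `0 < mu_inf < mu_0`.
#' @param lambda Relaxation time constant (s).
#' @param n Power-law index in (0, 1).
#' @param a Yasuda exponent (> 0).
#' @export
carreau_yasuda_params <- function(mu_inf = 3.45e-3, mu_0 = 56e-3,
                                  lambda = 3.313, n = 0.3568, a = 2) {
  stopifnot(mu_inf > 0, mu_0 > mu_inf, lambda > 0, n > 0, n < 1, a > 0)
  structure(list(mu_inf = mu_inf, mu_0 = mu_0, lambda = lambda, n = n, a = a),
            class = "carreau_yasuda_params")
}

#' Carreau-Yasuda viscosity
#'
#' @param shear_rate Scalar shear rate(s) in 1/s, >= 0.
#' @param params A [carreau_yasuda_params()] object.
#' @return Dynamic viscosity in Pa.s, bounded in `[mu_inf, mu_0]` and
#'   non-increasing in the shear rate.
#' @export
cy_viscosity <- function(shear_rate, params = carreau_yasuda_params()) {
  if (any(shear_rate < 0)) stop("shear_rate must be non-negative")
  with(params,
       mu_inf + (mu_0 - mu_inf) * (1 + (lambda * shear_rate)^a)^((n - 1) / a))
}

#' Effective viscosity under the configured rheology
#'
#' @param shear_rate Shear rate(s) in 1/s.
#' @param props A [fluid_props()] object.
#' @return Pa.s; constant for Newtonian rheology.
#' @export
effective_viscosity <- function(shear_rate, props) {
  if (props$rheology == "newtonian") {
    rep(props$mu_newtonian, length(shear_rate))
  } else {
    cy_viscosity(shear_rate, props$cy)
  }
}

#' Pulsatile inlet waveform
#'
#' Piecewise cardiac-cycle waveform for the CCA inlet mean velocity (m/s):
#' a systolic half-sine `amplitude * sin(4*pi*t + phase)` on
#' `[0, t_systole]` followed by a diastolic plateau, repeated with the given
#' period. The raw waveform is discontinuous where the systolic branch meets
#' the plateau; a cosine blend over `smoothing_window` seconds (default
#' 10 ms) removes the jumps for solver stability while preserving the cycle
#' integral. Set `smoothing_window = 0` for the exact piecewise form.
#'
#' @param amplitude Systolic amplitude (m/s).
#' @param phase Phase offset of the systolic sine (rad).
#' @param t_systole End of the systolic branch (s).
#' @param plateau Diastolic plateau velocity (m/s).
#' @param period Cardiac period (s).
#' @param smoothing_window Width of the cosine blend at the branch joints (s).
#' @param scale Dimensionless multiplier applied to the whole waveform
#'   (used for the 0.3--0.7 m/s inlet-velocity sweep, which rescales the
#'   waveform so its peak equals the requested value).
#' @export
inlet_waveform <- function(amplitude = 0.5, phase = 0.0160236,
                           t_systole = 0.218, plateau = 0.1, period = 1,
                           smoothing_window = 0.01, scale = 1) {
  stopifnot(t_systole > 0, t_systole < period, plateau > 0,
            smoothing_window >= 0, smoothing_window < t_systole, scale > 0)
  structure(list(amplitude = amplitude, phase = phase, t_systole = t_systole,
                 plateau = plateau, period = period,
                 smoothing_window = smoothing_window, scale = scale),
            class = "inlet_waveform")
}

#' Scale a waveform so its systolic peak equals a target velocity
#'
#' @param w An [inlet_waveform()].
#' @param peak Requested peak velocity (m/s).
#' @export
scale_waveform_peak <- function(w, peak) {
  stopifnot(peak > 0)
  tt <- seq(0, w$period, length.out = 4001)
  w$scale <- 1
  w$scale <- peak / max(inlet_velocity(tt, w))
  w
}

# cosine smoothstep on [0, 1]
.smoothstep <- function(x) 0.5 * (1 - cos(pi * pmin(pmax(x, 0), 1)))

#' Evaluate the inlet waveform
#'
#' Total function of time: the argument is reduced modulo the period. With a
#' positive `smoothing_window` the two branch joints (end of systole and the
#' cycle wrap) are blended smoothly.
#'
#' @param t Time(s) in seconds, any length.
#' @param w An [inlet_waveform()].
#' @return Mean inlet velocity in m/s (vectorized).
#' @export
inlet_velocity <- function(t, w = inlet_waveform()) {
  tm <- t %% w$period
  sine <- function(tt) w$amplitude * sin(4 * pi * tt + w$phase)
  u <- ifelse(tm <= w$t_systole, sine(tm), w$plateau)
  h <- w$smoothing_window
  if (h > 0) {
    # blend sine -> plateau across t_systole
    j1 <- abs(tm - w$t_systole) < h / 2
    if (any(j1)) {
      s <- .smoothstep((tm[j1] - w$t_systole + h / 2) / h)
      u[j1] <- (1 - s) * sine(tm[j1]) + s * w$plateau
    }
    # blend plateau -> sine across the cycle wrap (t = 0 == period)
    d <- pmin(tm, w$period - tm)          # signed distance to the wrap
    j2 <- d < h / 2 & !j1
    if (any(j2)) {
      x <- ifelse(tm[j2] < h / 2, tm[j2] + h / 2, tm[j2] - w$period + h / 2)
      s <- .smoothstep(x / h)
      u[j2] <- (1 - s) * w$plateau + s * sine(ifelse(tm[j2] < h / 2,
                                                     tm[j2], tm[j2] - w$period))
    }
  }
  w$scale * u
}

#' Cycle-mean of the inlet waveform
#'
#' @param w An [inlet_waveform()].
#' @param n Number of quadrature points.
#' @return Time-averaged velocity over one period (m/s).
#' @export
waveform_mean <- function(w, n = 8192) {
  tt <- (seq_len(n) - 0.5) / n * w$period
  mean(inlet_velocity(tt, w))
}

#' Womersley number
#'
#' \eqn{\alpha = (d/2)\sqrt{2\pi\rho/(T\mu)}}: ratio of pulsatile inertia to
#' viscous diffusion. For the carotid inlet (d = 6.35 mm, T = 1 s,
#' mu = 3.8 mPa.s) this evaluates to about 4.2.
#'
#' @param diameter Vessel diameter (m).
#' @param period Cardiac period (s).
#' @param props [fluid_props()]; the Newtonian reference viscosity is used.
#' @export
womersley_number <- function(diameter, period = 1, props = fluid_props()) {
  stopifnot(diameter > 0, period > 0)
  (diameter / 2) * sqrt(2 * pi * props$rho / (period * props$mu_newtonian))
}

#' Reynolds number
#'
#' \eqn{Re = \rho u d / \mu} with the Newtonian reference viscosity.
#'
#' @param speed Characteristic velocity (m/s), >= 0.
#' @param diameter Vessel diameter (m).
#' @param props [fluid_props()].
#' @export
reynolds_number <- function(speed, diameter, props = fluid_props()) {
  stopifnot(all(speed >= 0), diameter > 0)
  props$rho * speed * diameter / props$mu_newtonian
}

#' Dean number
#'
#' \eqn{De = Re\sqrt{d/(2R_c)}}: secondary-flow strength of a curved vessel
#' segment with curvature radius `curvature_radius`.
#'
#' @param re Reynolds number.
#' @param diameter Vessel diameter (m).
#' @param curvature_radius Centerline curvature radius (m), > 0.
#' @export
dean_number <- function(re, diameter, curvature_radius) {
  stopifnot(curvature_radius > 0, diameter > 0)
  re * sqrt(diameter / (2 * curvature_radius))
}

#' Vortex formation time
#'
#' Dimensionless stroke length \eqn{VFT = (1/d)\int_0^T u_m(t)\,dt}: how many
#' inlet diameters of fluid column pass per cardiac cycle. For the default
#' waveform and d = 6.35 mm this is about 24.4.
#'
#' @param w An [inlet_waveform()].
#' @param diameter Inlet diameter (m).
#' @param n Quadrature points over one period.
#' @export
vortex_formation_time <- function(w, diameter, n = 8192) {
  stopifnot(diameter > 0)
  waveform_mean(w, n) * w$period / diameter
}
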