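# Closed-form acousto-mechanics of an entrained donor particle.
# All computation in SI units (m, s, kg, Pa, Pa*s); unit conversion lives
# at the I/O boundary (see load_config / report writers).

.check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict && x <= 0)
    stop(sprintf("'%s' must be > 0 (got %g)", name, x), call. = FALSE)
  if (!strict && x < 0)
    stop(sprintf("'%s' must be >= 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}

#' Carrier-fluid properties
#'
#' Bundles the three fluid constants the acoustic entrainment model needs.
#' The dynamic viscosity `mu_f` is the estimand of the inverse problem.
#'
#' @param rho_f Mass density \[kg/m^3\].
#' @param c_f Speed of sound in the fluid \[m/s\].
#' @param mu_f Dynamic viscosity \[Pa s\] (water ~ 0.89e-3, blood ~ 3e-3 to 4e-3).
#' @return An object of class `vfret_fluid`.
#' @export
fluid_medium <- function(rho_f = 1000, c_f = 1543, mu_f = 0.89e-3) {
  .check_positive(rho_f, "rho_f")
  .check_positive(c_f, "c_f")
  .check_positive(mu_f, "mu_f")
  structure(list(rho_f = rho_f, c_f = c_f, mu_f = mu_f), class = "vfret_fluid")
}

#' Acoustic excitation
#'
#' @param P_f Acoustic pressure amplitude \[Pa\].
#' @param f0 Excitation frequency \[Hz\]; angular frequency `omega0 = 2*pi*f0`
#'   is derived.
#' @return An object of class `vfret_drive`.
#' @export
acoustic_drive <- function(P_f = 20, f0 = 50) {
  .check_positive(P_f, "P_f", strict = FALSE)
  .check_positive(f0, "f0")
  structure(list(P_f = P_f, f0 = f0, omega0 = 2 * pi * f0),
            class = "vfret_drive")
}

#' Lumped spherical donor particle
#'
#' The donor fluorophores are assumed lumped into a sphere of diameter `d_p`.
#' Mass may be given directly or derived from a particle density via
#' [sphere_mass()]. The FRET pairing constants (Forster distance `R0`,
#' acceptors per donor `kA`) travel with the particle.
#'
#' @param d_p Particle diameter \[m\].
#' @param m_p Particle mass \[kg\]; if `NULL`, derived as
#'   `rho_p * pi * d_p^3 / 6`.
#' @param rho_p Particle density \[kg/m^3\], used only when `m_p` is `NULL`.
#'   Default 1000 (neutrally buoyant in water).
#' @param R0 Forster distance \[m\] (50% transfer efficiency at `d = R0` for
#'   a single acceptor).
#' @param kA Acceptors per donor (>= 1).
#' @return An object of class `vfret_particle`.
#' @export
donor_particle <- function(d_p = 500e-6, m_p = NULL, rho_p = 1000,
                           R0 = 10e-9, kA = 1) {
  .check_positive(d_p, "d_p")
  .check_positive(R0, "R0")
  if (!is.numeric(kA) || length(kA) != 1L || kA < 1)
    stop("'kA' must be >= 1", call. = FALSE)
  if (is.null(m_p)) {
    .check_positive(rho_p, "rho_p")
    m_p <- sphere_mass(d_p, rho_p)
  }
  .check_positive(m_p, "m_p")
  structure(list(d_p = d_p, m_p = m_p, R0 = R0, kA = kA),
            class = "vfret_particle")
}

#' Peak fluid displacement amplitude under acoustic excitation
#'
#' `U_f,max = P_f / (2 pi rho_f f0 c_f)`: the displacement amplitude of the
#' bulk fluid oscillation, independent of any particle property, linear in
#' pressure and hyperbolic in frequency.
#'
#' @param drive A [acoustic_drive()].
#' @param fluid A [fluid_medium()].
#' @return Displacement amplitude \[m\].
#' @export
fluid_displacement_amplitude <- function(drive, fluid) {
  stopifnot(inherits(drive, "vfret_drive"), inherits(fluid, "vfret_fluid"))
  drive$P_f / (2 * pi * fluid$rho_f * drive$f0 * fluid$c_f)
}

#' Mass of a homogeneous sphere
#'
#' @param d_p Diameter \[m\].
#' @param rho_p Density \[kg/m^3\].
#' @return Mass \[kg\], `rho_p * pi * d_p^3 / 6`.
#' @export
sphere_mass <- function(d_p, rho_p) {
  .check_positive(d_p, "d_p")
  .check_positive(rho_p, "rho_p")
  rho_p * pi * d_p^3 / 6
}

#' Stokes-drag particle time scale
#'
#' `tau_p = m_p / (3 pi mu_f d_p)`, the viscous relaxation time that governs
#' how faithfully the particle follows the oscillating fluid. Strictly
#' decreasing in viscosity: a more viscous fluid couples the particle more
#' tightly.
#'
#' @param particle A [donor_particle()].
#' @param fluid A [fluid_medium()].
#' @return Time scale \[s\].
#' @export
particle_time_scale <- function(particle, fluid) {
  stopifnot(inherits(particle, "vfret_particle"), inherits(fluid, "vfret_fluid"))
  particle$m_p / (3 * pi * fluid$mu_f * particle$d_p)
}

#' Entrainment coefficient and phase lag
#'
#' For a particle with time scale `tau_p` driven at angular frequency
#' `omega0`, the fraction of the fluid's oscillation amplitude transmitted to
#' the particle is `eta_p = 1 / sqrt(1 + (omega0 tau_p)^2)` and the particle
#' lags the fluid by `phi_p = atan(omega0 tau_p)`. `eta_p -> 1` (full
#' entrainment) for light particles or viscous fluids; `eta_p -> 0` for heavy
#' particles or high frequency.
#'
#' @param drive A [acoustic_drive()].
#' @param tau_p Particle time scale \[s\], >= 0.
#' @return List with `eta_p` (in (0, 1\]) and `phi_p` \[rad, in \[0, pi/2)\].
#' @export
entrainment <- function(drive, tau_p) {
  stopifnot(inherits(drive, "vfret_drive"))
  if (!is.numeric(tau_p) || any(tau_p < 0))
    stop("'tau_p' must be >= 0", call. = FALSE)
  x <- drive$omega0 * tau_p
  list(eta_p = 1 / sqrt(1 + x^2), phi_p = atan(x))
}

#' Full vibration state of an entrained particle
#'
#' Convenience composition: fluid amplitude, particle time scale, entrainment
#' and the resulting particle amplitude `Up_max = eta_p * Uf_max`.
#' Warns when the particle diameter exceeds a tenth of the acoustic
#' wavelength `c_f / f0`, outside the small-particle regime the entrainment
#' model assumes.
#'
#' @inheritParams fluid_displacement_amplitude
#' @param particle A [donor_particle()].
#' @return An object of class `vfret_vibration` with fields `Uf_max`,
#'   `tau_p`, `eta_p`, `phi_p`, `Up_max`, `omega0`.
#' @export
vibration_state <- function(drive, fluid, particle) {
  wavelength <- fluid$c_f / drive$f0
  if (particle$d_p > wavelength / 10)
    warning(sprintf(
      "particle diameter (%.3g m) exceeds 1/10 of the acoustic wavelength (%.3g m); small-particle entrainment model may be inaccurate",
      particle$d_p, wavelength), call. = FALSE)
  Uf_max <- fluid_displacement_amplitude(drive, fluid)
  tau_p <- particle_time_scale(particle, fluid)
  ent <- entrainment(drive, tau_p)
  structure(list(Uf_max = Uf_max, tau_p = tau_p,
                 eta_p = ent$eta_p, phi_p = ent$phi_p,
                 Up_max = ent$eta_p * Uf_max, omega0 = drive$omega0),
            class = "vfret_vibration")
}

#' Donor-acceptor distance trajectory
#'
#' `d(t) = d0 - Up_max * cos(omega0 t - phi_p)`: the instantaneous distance
#' between the vibrating donor sphere and the acceptor layer, oscillating
#' about the steady-state position `d0`. If `d0 <= Up_max` the donor touches
#' the acceptor layer at some phase; values are returned as-is and the result
#' carries a `touching` attribute (the estimator refuses such traces).
#'
#' @param d0 Steady-state donor position \[m\], > 0.
#' @param vib A [vibration_state()].
#' @param t Time or vector of times \[s\].
#' @return Numeric vector of distances \[m\] with attribute `touching`
#'   (logical).
#' @export
donor_acceptor_distance <- function(d0, vib, t) {
  .check_positive(d0, "d0")
  stopifnot(inherits(vib, "vfret_vibration"))
  d <- d0 - vib$Up_max * cos(vib$omega0 * t - vib$phi_p)
  attr(d, "touching") <- d0 <= vib$Up_max
  d
}

#' @export
print.vfret_vibration <- function(x, ...) {
  cat("VFRET vibration state\n")
  cat(sprintf("  Uf_max: %.4g nm   Up_max: %.4g nm\n",
              x$Uf_max * 1e9, x$Up_max * 1e9))
  cat(sprintf("  tau_p:  %.4g s    eta_p: %.4f   phi_p: %.4f rad\n",
              x$tau_p, x$eta_p, x$phi_p))
  invisible(x)
}
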