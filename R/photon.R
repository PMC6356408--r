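# FRET efficiency, photon budget, SNR-calibrated Gaussian noise, and the
# simulated photon-count time series (the forward model's observable).

# fixed physical constants
.hp <- 6.62e-34   # Planck constant [J s]
.c_light <- 3e8   # speed of light [m/s]
.sigma_per_ext <- 3.825e-25  # absorption cross-section per unit extinction [m^2 / (M^-1 cm^-1)]

#' FRET efficiency at a given donor-acceptor distance
#'
#' `E = kA R0^6 / (d^6 + kA R0^6)`: the sixth-power distance law with `kA`
#' acceptors per donor. Equals 1/2 at `d = R0` for a single acceptor,
#' approaches 1 as `d -> 0` and 0 as `d -> Inf`.
#'
#' @param d Donor-acceptor distance(s) \[m\], > 0.
#' @param R0 Forster distance \[m\].
#' @param kA Acceptors per donor, >= 1.
#' @return Efficiency in (0, 1), same length as `d`.
#' @export
fret_efficiency <- function(d, R0, kA = 1) {
  if (any(d <= 0)) stop("'d' must be > 0", call. = FALSE)
  .check_positive(R0, "R0")
  if (kA < 1) stop("'kA' must be >= 1", call. = FALSE)
  r6 <- kA * R0^6
  r6 / (d^6 + r6)
}

#' Photon budget of the acceptor emission channel
#'
#' Collects the optical constants that set `alpha`, the expected acceptor
#' photon count per counting bin at unit FRET efficiency:
#' `alpha = delta_t * I_D * D_B * sigma_D * Phi_A * N_D * lambda_Da / (hp c)`
#' with absorption cross-section `sigma_D = D_ext * 3.825e-25` m^2.
#' Warns when the counting bin is not much longer than the photon-emission
#' cycle time `t_p` (donor excitation + transfer + acceptor emission,
#' nanoseconds), where the per-bin rate picture breaks down.
#'
#' @param delta_t Photon-counting bin \[s\].
#' @param I_D Donor excitation intensity \[W/m^2/nm\].
#' @param D_B Donor excitation bandwidth \[nm\].
#' @param D_ext Donor extinction coefficient \[M^-1 cm^-1\].
#' @param Phi_A Acceptor quantum yield, in (0, 1\].
#' @param N_D Number of donors (default 1).
#' @param lambda_Da Donor excitation wavelength \[m\].
#' @param t_p Photon-emission cycle time \[s\] used only for the
#'   `delta_t >> t_p` validity warning (default 10 ns).
#' @return An object of class `vfret_budget` including the derived `alpha`
#'   \[photons per bin\].
#' @export
photon_budget <- function(delta_t = 20e-6, I_D = 1, D_B = 25, D_ext = 7e4,
                          Phi_A = 0.68, N_D = 1, lambda_Da = 500e-9,
                          t_p = 10e-9) {
  for (nm in c("delta_t", "I_D", "D_B", "D_ext", "Phi_A", "N_D", "lambda_Da"))
    .check_positive(get(nm), nm)
  if (Phi_A > 1) stop("'Phi_A' must be in (0, 1]", call. = FALSE)
  if (delta_t < 100 * t_p)
    warning("counting bin delta_t is not >> photon cycle time t_p; per-bin rate model may be invalid",
            call. = FALSE)
  b <- structure(list(delta_t = delta_t, I_D = I_D, D_B = D_B, D_ext = D_ext,
                      Phi_A = Phi_A, N_D = N_D, lambda_Da = lambda_Da,
                      t_p = t_p),
                 class = "vfret_budget")
  b$alpha <- photon_budget_alpha(b)
  b
}

#' Photon-count scale alpha from a photon budget
#'
#' @param budget A [photon_budget()].
#' @return `alpha` \[photons per bin\], linear in every budget factor.
#' @export
photon_budget_alpha <- function(budget) {
  stopifnot(inherits(budget, "vfret_budget"))
  sigma_D <- budget$D_ext * .sigma_per_ext
  budget$delta_t * budget$I_D * budget$D_B * sigma_D * budget$Phi_A *
    budget$N_D * budget$lambda_Da / (.hp * .c_light)
}

#' Noise standard deviation from a signal-to-noise ratio
#'
#' SNR is defined against the worst case of a fully efficient transfer:
#' `SNR = alpha^2 / sigma_n^2`, so `sigma_n = alpha * 10^(-snr_db/20)`.
#'
#' @param alpha Photon-count scale \[photons per bin\], > 0.
#' @param snr_db Signal-to-noise ratio \[dB\]; `Inf` gives `sigma_n = 0`.
#' @return `sigma_n` \[photons per bin\].
#' @export
noise_sigma_from_snr <- function(alpha, snr_db) {
  .check_positive(alpha, "alpha")
  if (is.infinite(snr_db)) return(0)
  alpha * 10^(-snr_db / 20)
}

#' Simulate a noisy photon-count measurement series
#'
#' The forward model: the entrained donor oscillates about `d0`, the FRET
#' efficiency follows the sixth-power law along that trajectory, and the
#' photodetector records `alpha * E(t) + n(t)` per bin with additive white
#' Gaussian noise of variance `sigma_n^2` set by the SNR. Counts are
#' real-valued (the continuous Gaussian model is implemented as stated, with
#' no Poissonization or clamping).
#'
#' The time grid uses `S = round(T / delta_t)` samples per period with the
#' bin width adjusted to `T / S` so periods fold exactly; `S >= 12` is
#' enforced. When `d0 <= Up_max` the trajectory touches the acceptor layer:
#' distances are clamped at a small floor before the efficiency is evaluated
#' and the series is flagged `touching = TRUE`.
#'
#' @param fluid A [fluid_medium()] (its `mu_f` is the ground truth).
#' @param drive A [acoustic_drive()].
#' @param particle A [donor_particle()].
#' @param d0 Steady-state donor position \[m\].
#' @param n_periods Number of acoustic periods to simulate, >= 1.
#' @param delta_t Requested counting bin \[s\] (default 20 us).
#' @param alpha Photon-count scale; default 1 (efficiency units). Supplying
#'   `budget` overrides it.
#' @param budget Optional [photon_budget()]; its `alpha` is used if given.
#' @param snr_db SNR \[dB\]; `Inf` (default) simulates noiselessly.
#' @param seed Integer RNG seed for the noise draws.
#' @param distance_floor Clamp floor for touching trajectories \[m\]
#'   (default 0.1 nm).
#' @return An object of class `vfret_series`: fields `t`, `counts`, `S`,
#'   `delta_t` (adjusted), `f0`, `alpha`, `sigma_n`, `snr_db`, `seed`,
#'   `touching`, and a `truth` snapshot of all generating parameters.
#' @export
simulate_series <- function(fluid, drive, particle, d0, n_periods,
                            delta_t = 20e-6, alpha = 1, budget = NULL,
                            snr_db = Inf, seed = 1L,
                            distance_floor = 0.1e-9) {
  stopifnot(inherits(fluid, "vfret_fluid"), inherits(drive, "vfret_drive"),
            inherits(particle, "vfret_particle"))
  .check_positive(d0, "d0")
  if (n_periods < 1) stop("'n_periods' must be >= 1", call. = FALSE)
  if (!is.null(budget)) alpha <- photon_budget_alpha(budget)
  .check_positive(alpha, "alpha")

  T0 <- 1 / drive$f0
  S <- as.integer(round(T0 / delta_t))
  if (S < 12)
    stop(sprintf("samples per period S = %d < 12; decrease delta_t or f0", S),
         call. = FALSE)
  dt <- T0 / S  # exact-period grid

  vib <- vibration_state(drive, fluid, particle)
  n <- as.integer(n_periods) * S
  t <- (seq_len(n) - 1L) * dt
  d <- donor_acceptor_distance(d0, vib, t)
  touching <- attr(d, "touching")
  d <- as.vector(d)
  if (touching) d <- pmax(d, distance_floor)
  eff <- fret_efficiency(d, particle$R0, particle$kA)
  sigma_n <- noise_sigma_from_snr(alpha, snr_db)
  counts <- alpha * eff
  if (sigma_n > 0) {
    set.seed(as.integer(seed))
    counts <- counts + stats::rnorm(n, 0, sigma_n)
  }
  structure(list(
    t = t, counts = counts, S = S, delta_t = dt, f0 = drive$f0,
    alpha = alpha, sigma_n = sigma_n, snr_db = snr_db,
    seed = as.integer(seed), touching = touching,
    truth = list(d0 = d0, mu_f = fluid$mu_f, rho_f = fluid$rho_f,
                 c_f = fluid$c_f, P_f = drive$P_f, f0 = drive$f0,
                 d_p = particle$d_p, m_p = particle$m_p,
                 R0 = particle$R0, kA = particle$kA,
                 Up_max = vib$Up_max)),
    class = "vfret_series")
}

#' @export
print.vfret_series <- function(x, ...) {
  cat(sprintf("VFRET measurement series: %d samples (%d periods x S=%d), f0=%g Hz\n",
              length(x$counts), length(x$counts) %/% x$S, x$S, x$f0))
  cat(sprintf("  alpha=%g, SNR=%g dB, sigma_n=%g, touching=%s, seed=%d\n",
              x$alpha, x$snr_db, x$sigma_n, x$touching, x$seed))
  cat(sprintf("  truth: d0=%.4g nm, mu_f=%.4g mPa*s\n",
              x$truth$d0 * 1e9, x$truth$mu_f * 1e3))
  invisible(x)
}
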