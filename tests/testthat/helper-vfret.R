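# Shared fixtures: baseline simulation conditions and the independent
# single-expression oracle for the composed noiseless forward model.

baseline_fluid <- function(mu_f = 0.89e-3) fluid_medium(1000, 1543, mu_f)
baseline_drive <- function(P_f = 20, f0 = 50) acoustic_drive(P_f, f0)
baseline_particle <- function(d_p = 500e-6, ...)
  donor_particle(d_p = d_p, rho_p = 1000, R0 = 10e-9, kA = 1, ...)

known_params <- function(fluid, drive, particle, alpha = 1) {
  list(rho_f = fluid$rho_f, c_f = fluid$c_f, P_f = drive$P_f, f0 = drive$f0,
       d_p = particle$d_p, m_p = particle$m_p, R0 = particle$R0,
       kA = particle$kA, alpha = alpha)
}

# Independent transcription of the composed noiseless observable as ONE
# expression, with the entrainment coefficient rewritten algebraically as
# 3*mu*dp / sqrt(9*mu^2*dp^2 + 4*f0^2*mp^2) and the phase as
# atan(2*f0*mp / (3*mu*dp)). Used only as an oracle; the package composes
# the same physics from its modular parts.
oracle_counts <- function(t, d0, mu, dp, mp, R0, kA, Pf, rho, cf, f0, alpha = 1) {
  alpha / (1 + (1 / kA) * (1 / R0^6) *
    (d0 - (3 * mu * dp / sqrt(9 * mu^2 * dp^2 + 4 * f0^2 * mp^2)) *
       (Pf / (2 * pi * rho * f0 * cf)) *
       cos(2 * pi * f0 * t - atan(2 * f0 * mp / (3 * mu * dp))))^6)
}

# random draws from the baseline parameter ranges (f0 10-300 Hz, Pf 1-20 Pa,
# dp 1-500 um, mu 0.5-5 mPa s), with d0 placed above the vibration amplitude
random_draw <- function() {
  f0 <- runif(1, 10, 300)
  Pf <- runif(1, 1, 20)
  dp <- runif(1, 1e-6, 500e-6)
  mu <- runif(1, 0.5e-3, 5e-3)
  fl <- fluid_medium(1000, 1543, mu)
  dr <- acoustic_drive(Pf, f0)
  pt <- donor_particle(d_p = dp, rho_p = 1000, R0 = 10e-9, kA = 1)
  vib <- suppressWarnings(vibration_state(dr, fl, pt))
  d0 <- vib$Up_max + runif(1, 1e-9, 20e-9)
  list(fluid = fl, drive = dr, particle = pt, vib = vib, d0 = d0)
}

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.xmin)
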