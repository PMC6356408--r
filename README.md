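# vfret — vibrating-FRET microfluidic viscometry

`vfret` models a microfluidic viscometer that reads out fluid viscosity
optically, with no electronics in the fluid. A micrometre-scale sphere of
donor fluorophores suspended in the fluid is shaken by a low-frequency
acoustic field. How faithfully the particle follows the oscillating fluid
depends on the fluid's dynamic viscosity, so the particle's vibration
amplitude — and therefore its oscillating distance to a nearby acceptor
layer — encodes the viscosity. Förster resonance energy transfer (FRET)
converts that distance into a periodic photon-emission signal collected by
an ordinary photodetector. The package provides both directions:

* a **forward simulator** — entrainment physics, FRET efficiency,
  photon-budget scaling, and SNR-calibrated additive Gaussian noise — that
  generates the photon-count time series such a device would record, and
* an **inverse estimator** that recovers the viscosity and the donor's
  steady-state position from those series by period fold-averaging, sample
  filtering, and Levenberg–Marquardt nonlinear least squares, plus a
  Monte Carlo harness for studying estimator performance versus SNR.

It is aimed at sensor modellers and biophysicists evaluating this kind of
acousto-optical point-of-care design (blood viscosity, water monitoring)
before building hardware.

## The model

Acoustic pressure of amplitude $P_f$ at frequency $f_0$ vibrates the fluid
with peak displacement

$$U_{f,\max} = \frac{P_f}{2\pi \rho_f f_0 c_f},$$

where $\rho_f$ is the fluid density and $c_f$ its sound speed. A spherical
particle of mass $m_p$ and diameter $d_p$ has Stokes-drag time scale
$\tau_p = m_p / (3\pi \mu_f d_p)$, and follows the fluid with entrainment
coefficient and phase lag

$$\eta_p = \frac{1}{\sqrt{1 + (\omega_0 \tau_p)^2}}, \qquad
  \phi_p = \tan^{-1}(\omega_0 \tau_p), \qquad \omega_0 = 2\pi f_0 .$$

The viscosity $\mu_f$ enters through $\tau_p$: more viscous fluids entrain
the particle more strongly ($\eta_p \to 1$). The donor–acceptor distance
oscillates as $d(t) = d_0 - \eta_p U_{f,\max}\cos(\omega_0 t - \phi_p)$
about the steady-state position $d_0$, and the FRET efficiency follows the
sixth-power law with Förster distance $R_0$ and $k_A$ acceptors per donor:

$$E_{\mathrm{FRET}}(t) = \frac{k_A R_0^6}{d(t)^6 + k_A R_0^6}.$$

The detector records $N(t) = \alpha E_{\mathrm{FRET}}(t) + n(t)$ photon
counts per bin $\Delta t$, where $\alpha$ is the photon budget (set by
excitation intensity, absorption cross-section, quantum yield, and bin
width) and $n(t)$ is white Gaussian noise with variance fixed by
$\mathrm{SNR} = \alpha^2/\sigma_n^2$.

The estimator folds $N_T$ periods into one mean waveform, discards phase
bins with measured efficiency below $E_{\min}$, rejects measurement sets
that are saturated (donor touching the acceptor layer) or too sparse, fits
$(d_0, \mu_f)$ per measurement by Levenberg–Marquardt with all other
parameters known, and averages the estimates over the $N_m$ measurements.

## Worked example

Estimate a blood-like viscosity (3.5 mPa·s) from five noisy measurement
sets at 20 dB SNR:

```r
library(vfret)

fluid  <- fluid_medium(rho_f = 1000, c_f = 1543, mu_f = 3.5e-3)  # truth
drive  <- acoustic_drive(P_f = 20, f0 = 50)
donor  <- donor_particle(d_p = 500e-6, R0 = 10e-9, kA = 1)

vib <- vibration_state(drive, fluid, donor)
vib
#> VFRET vibration state
#>   Uf_max: 41.26 nm   Up_max: 25.82 nm
#>   tau_p:  0.003968 s    eta_p: 0.6257   phi_p: 0.8948 rad

protocol <- estimation_protocol(NT = 200, Nm = 5)
d0s <- sample_positions(protocol$Nm, vib$Up_max, protocol, seed = 1)
series <- lapply(seq_along(d0s), function(i)
  simulate_series(fluid, drive, donor, d0 = d0s[i],
                  n_periods = protocol$NT, snr_db = 20, seed = i))

known <- list(rho_f = 1000, c_f = 1543, P_f = 20, f0 = 50,
              d_p = donor$d_p, m_p = donor$m_p,
              R0 = donor$R0, kA = donor$kA, alpha = 1)
estimate_viscosity(series, known, protocol)
#> VFRET estimate report
#>   mu_f: 3.425 mPa*s   d0: 36.48 nm  (means over 4 measurements; 1 rejected)
```

The fluid oscillates with a 41 nm amplitude of which the 500 µm particle
picks up 63% (26 nm) at this viscosity. One of the five measurement sets
happened to bring the donor within the saturation zone of the acceptor
layer and was rejected; the remaining four recover the true 3.5 mPa·s to
about 2% at this SNR. With noiseless data the recovery is exact to
machine precision.

The Monte Carlo harness sweeps viscosity and SNR:

```r
cfg <- experiment_config(mu_list = c(0.89e-3, 3.5e-3),
                         snr_list = c(10, 20, 30, 40), master_seed = 1)
error_metrics(run_estimation_study(cfg))
```

A thin command-line wrapper around the same functions is installed at
`inst/scripts/vfret.R` with subcommands `simulate`, `estimate`,
`montecarlo`, and `sweep`; tabular outputs are CSV (`t_s`, `counts` for
series; one row per measurement for reports) with JSON sidecars for truth
snapshots and seeds, and configuration is a YAML file with an explicit
`units:` block (see `?load_config`).

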