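---
title: "Methods: vibrating-FRET viscometry, forward model and inverse estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vibrating-FRET viscometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfret)
```

## The physical model and its assumptions

The device this package models couples three pieces of physics.

**Acoustic entrainment.** A pressure wave of amplitude $P_f$ and frequency
$f_0$ makes the fluid oscillate with peak displacement
$U_{f,\max} = P_f / (2\pi \rho_f f_0 c_f)$. A suspended sphere of diameter
$d_p$ and mass $m_p$ follows this oscillation imperfectly: with Stokes-drag
time scale $\tau_p = m_p/(3\pi \mu_f d_p)$, the particle amplitude is
$\eta_p U_{f,\max}$ with $\eta_p = (1 + (\omega_0\tau_p)^2)^{-1/2}$ and
phase lag $\phi_p = \tan^{-1}(\omega_0\tau_p)$. This assumes the particle
is much smaller than the acoustic wavelength $c_f/f_0$ (the package warns
when $d_p > c_f/(10 f_0)$), and neglects acoustic radiation forces,
standing waves, Basset history forces, gravity/buoyancy dynamics, and
non-Newtonian rheology. The viscosity dependence that makes the device a
viscometer enters only through $\tau_p$: a more viscous fluid couples the
particle more tightly ($\eta_p$ rises toward 1, $\phi_p$ falls toward 0).

**FRET transduction.** The donor sphere sits a steady-state distance $d_0$
from an acceptor layer, so the donor–acceptor distance oscillates as
$d(t) = d_0 - \eta_p U_{f,\max}\cos(\omega_0 t - \phi_p)$, and the transfer
efficiency follows the sixth-power law
$E(t) = k_A R_0^6 / (d(t)^6 + k_A R_0^6)$. Photophysics kinetics
(excited-state dynamics, photobleaching, self-quenching) are outside the
model; the fluorophore constants enter only through $R_0$, $k_A$, and the
photon budget.

**Photon counting.** Each bin of width $\Delta t$ records
$N(t) = \alpha E(t) + n(t)$, where $\alpha$ is the expected count at unit
efficiency and $n(t)$ is zero-mean white Gaussian noise with
$\sigma_n = \alpha\,10^{-\mathrm{SNR_{dB}}/20}$ (SNR defined against the
worst case $E = 1$). The Gaussian model is implemented exactly as stated:
counts are real-valued and not clamped to non-negative integers. Noise is
assumed i.i.d. per bin after $\Delta t$ binning. Since the SNR definition
makes the absolute scale of $\alpha$ irrelevant to estimator behaviour,
simulations default to $\alpha = 1$ (efficiency units); a
`photon_budget()` can supply a physical $\alpha$, and the number of donors
`N_D` it contains defaults to 1.

## The inverse algorithm

For each of $N_m$ measurement sets, taken at positions $d_0$ drawn
uniformly on $[U_{p,\max} + 1\,\mathrm{nm},\; U_{p,\max} + 20\,\mathrm{nm}]$:

1. **Fold-average** $N_T$ periods at fixed phase into one mean waveform of
   $S = \mathrm{round}(T/\Delta t)$ bins, cutting the noise variance by
   $1/N_T$.
2. **Filter** phase bins whose *measured* normalized count
   $\bar N/\alpha$ falls below $E_{\min}$ (default 0.01). The filter uses
   the measured quantity, not the true efficiency, because only measured
   quantities are available to an estimator. Filtering happens after
   folding — the folded waveform is the estimator's input, so that is
   where a per-sample efficiency is first well defined.
3. **Reject** the whole set when fewer than
   $\mathrm{round}(S/12)$ bins qualify (too little of the period carries
   signal) or when the waveform saturates
   ($\max \bar N/\alpha \ge 0.99$) — the signature of the donor touching
   the acceptor layer, where the efficiency pins at 1 and carries no
   viscosity information. The count threshold is boundary-inclusive:
   exactly $S/12$ qualifying bins is accepted.
4. **Fit** $(d_0, \mu_f)$ on the kept bins by Levenberg–Marquardt
   (`minpack.lm::nls.lm`) against the noiseless forward model with all
   other parameters known.
5. **Aggregate**: the final estimates are unweighted means over the
   accepted, converged measurements.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `rho_f`, `c_f` | 1000, 1543 | kg/m³, m/s | water-like carrier fluid |
| `mu_f` | 0.89e-3 (water), 3.5e-3 (blood) | Pa·s | estimand; sweep range 0.5–5 mPa·s |
| `P_f` | 20 | Pa | acoustic pressure; range 1–20 |
| `f0` | 50 | Hz | excitation; range 10–300 (low, so wavelength ≫ particle) |
| `d_p` | 500e-6 | m | donor lump diameter; range 1–500 µm |
| `rho_p` | 1000 | kg/m³ | particle density for the mass (see below) |
| `R0` | 10e-9 | m | Förster distance (worst-case analysis value; the fluorescein–TAMRA preset carries 5.5 nm) |
| `kA` | 1 | — | acceptors per donor (worst case) |
| `delta_t` | 20e-6 | s | counting bin → S = 1000 at 50 Hz |
| `E_min` | 0.01 | — | per-bin efficiency floor |
| `Nmin_fraction` | 1/12 | — | minimum qualifying fraction of a period |
| `NT`, `Nm`, `NMC` | 1000, 20, 20 (full); 200, 5, 5 (scaled) | — | study sizes |

Two documentation notes on these defaults. First, the protocol literature
this design follows states the minimum-sample rule both as $T/(12\Delta t)$
and as $T/(6\Delta t)$ in different places; the package defaults to 1/12
and exposes `Nmin_fraction`. Second, the particle mass is nowhere
specified by the design; the package assumes a neutrally buoyant lump
(`rho_p` = 1000 kg/m³, $m_p = \rho_p \pi d_p^3/6$), exposes both `m_p` and
`rho_p`, and makes no attempt to tune them: under this default, a 300 µm
particle at 200 Hz has $U_{p,\max}$ below 10 nm, so the "touching" regime
sometimes illustrated for that geometry is not reachable without a
different mass assumption.

## Numerical choices

* **Units.** All computation is SI; nm/µm/mPa·s appear only at the I/O
  boundary (`load_config`, printed reports). "mPa·s" is the natural
  display unit since water is 0.89 and blood 3–4 on that scale.
* **Exact period folding.** The bin width is adjusted to $\Delta t' = T/S$
  so that every period covers exactly $S$ bins and folding needs no
  interpolation. At the default $f_0 = 50$ Hz, $\Delta t = 20$ µs gives
  $S = 1000$ exactly.
* **Fit parameterization and bounds.** The fit runs in (nm, mPa·s) so both
  parameters are O(1–100). Box bounds default to $d_0 \in [0.5\,\mathrm{nm},
  1\,\mu\mathrm{m}]$ and $\mu_f \in [0.1, 10]$ mPa·s, keeping the model
  evaluable. A fit that terminates on a bound is marked non-converged:
  boundary solutions signal misspecification, not estimates. Non-converged
  fits are excluded from the final averages (the aggregation rule had to
  be decided here; exclusion keeps the averages meaningful).
* **Initial guesses.** Defaults are deterministic and unbiased within the
  configured prior ranges: $\mu_{f,\mathrm{init}}$ is the midpoint of the
  viscosity search range (2.75 mPa·s for 0.5–5), and $d_{0,\mathrm{init}} =
  U_{p,\max}(\mu_{f,\mathrm{init}}) + 10.5$ nm, the midpoint of the
  position prior.
* **Identifiability.** A numerically static donor ($U_{p,\max} \approx 0$)
  makes $\mu_f$ unidentifiable; the fit detects this through the singular
  values of the Jacobian at the solution and flags `ill_conditioned`.
* **Touching trajectories.** The forward model stays total: when
  $d_0 \le U_{p,\max}$ the distance is clamped at a 0.1 nm floor (so the
  efficiency stays finite) and the series is flagged; the estimator
  refuses flagged series outright, and catches unflagged near-touching
  sets through the 0.99 saturation rejection.
* **Seeding.** One master seed; each (sweep point, replicate, measurement)
  derives a child seed from it arithmetically, so runs are exactly
  reproducible and adding sweep points does not perturb existing
  replicates.

## What the generator emulates — and what it does not

The synthetic series reproduce the periodic efficiency waveform, its
viscosity-dependent amplitude and phase, and SNR-calibrated white Gaussian
detector noise. They do **not** contain Poisson shot-noise discreteness,
detector dark counts or afterpulsing, photobleaching, particle drift or
flow, or non-Newtonian shear-rate effects. Passing tests therefore
demonstrate the estimator's correctness and noise behaviour *under the
stated model*, not robustness to real-detector artifacts; the monotone
error-versus-SNR trend is the claim most likely to transfer to hardware,
the absolute error values the least.

## Study sizes

The scaled study (`scaled = TRUE`, the default) uses $N_T = 200$ periods,
$N_m = 5$ measurements, $N_{MC} = 5$ replicates — sizes chosen so a full
viscosity × SNR sweep completes in seconds while the error-versus-SNR
trend remains clearly resolved. The full protocol (1000/20/20) is
available via `scaled = FALSE` or the CLI `--full` flag. Noiseless checks
use $N_T = 5$: folding noiseless data is idempotent, so extra periods add
nothing.

```{r example, eval = FALSE}
cfg <- experiment_config(mu_list = c(0.89e-3, 3.5e-3),
                         snr_list = c(10, 20, 30, 40), master_seed = 1)
met <- error_metrics(run_estimation_study(cfg))
met[, c("mu_true", "snr_db", "mean_estimate", "mean_rel_err", "rejection_rate")]
```

## Known limitations

* The estimator assumes every parameter except $(d_0, \mu_f)$ is known
  exactly; errors in $P_f$, $m_p$, or $\alpha$ propagate directly into the
  viscosity estimate and are not modelled.
* Rejection rates rise at low SNR because folded noise can push the
  waveform maximum over the 0.99 saturation threshold; with few
  measurements per set a replicate can occasionally lose all of them, and
  the harness records such replicates as explicit failure rows rather than
  estimates.
* The uniform $d_0$ sampling abstracts the physical search motion of the
  acceptor layer; choosing measurement sets with $d_0 > U_{p,\max}$ in a
  real device is an open signal-processing problem, and only the
  saturation proxy above stands in for it here.
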