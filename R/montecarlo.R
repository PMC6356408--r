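# Monte Carlo orchestration: displacement-amplitude sweeps and the
# estimator-performance study versus SNR and viscosity.

#' Experiment configuration
#'
#' Holds the physics, protocol, and sweep settings for a simulation study.
#' Defaults are the baseline simulation conditions: water-like medium
#' (rho_f = 1000 kg/m^3, c_f = 1543 m/s), R0 = 10 nm, kA = 1 (worst case),
#' Pf = 20 Pa, f0 = 50 Hz, dp = 500 um, delta_t = 20 us, with viscosities
#' covering water (0.89 mPa s) and blood (3.5 mPa s) and SNR from 10 to
#' 40 dB. The full protocol is NT = 1000 periods, Nm = 20 measurements,
#' NMC = 20 replicates; `scaled = TRUE` (default) runs the reduced
#' NT = 200, Nm = 5, NMC = 5 study whose trends match the full one at a
#' fraction of the cost.
#'
#' @param rho_f,c_f Fluid density \[kg/m^3\] and sound speed \[m/s\].
#' @param P_f,f0 Acoustic pressure \[Pa\] and frequency \[Hz\].
#' @param d_p Particle diameter \[m\]; `m_p` optional explicit mass \[kg\];
#'   `rho_p` particle density \[kg/m^3\] used when `m_p` is `NULL`.
#' @param m_p,rho_p See `d_p`.
#' @param R0,kA Forster distance \[m\] and acceptors per donor.
#' @param delta_t Photon-counting bin \[s\].
#' @param alpha Photon-count scale (efficiency units by default).
#' @param mu_list True viscosities to sweep \[Pa s\].
#' @param snr_list SNR sweep \[dB\].
#' @param f0_list,Pf_list,dp_list Grids for the displacement sweeps.
#' @param NMC Monte Carlo replicates per sweep point.
#' @param protocol An [estimation_protocol()]; `NT`/`Nm` inside it are
#'   overridden by the scaled/full choice unless you pass your own.
#' @param master_seed Master RNG seed; every replicate derives a child seed
#'   from it and its (point, replicate, measurement) indices, so adding
#'   sweep points does not perturb existing replicates.
#' @param scaled Use the scaled-down study sizes (NT=200, Nm=5, NMC=5).
#' @return An object of class `vfret_config`.
#' @export
experiment_config <- function(rho_f = 1000, c_f = 1543,
                              P_f = 20, f0 = 50,
                              d_p = 500e-6, m_p = NULL, rho_p = 1000,
                              R0 = 10e-9, kA = 1,
                              delta_t = 20e-6, alpha = 1,
                              mu_list = c(0.89e-3, 3.5e-3),
                              snr_list = c(10, 20, 30, 40),
                              f0_list = c(10, 20, 50, 100, 200, 300),
                              Pf_list = c(1, 5, 10, 20),
                              dp_list = c(1e-6, 10e-6, 100e-6, 300e-6, 500e-6),
                              NMC = NULL, protocol = NULL,
                              master_seed = 1L, scaled = TRUE) {
  if (length(mu_list) == 0 || length(snr_list) == 0 ||
      length(f0_list) == 0 || length(Pf_list) == 0 || length(dp_list) == 0)
    stop("sweep lists must be non-empty", call. = FALSE)
  if (any(mu_list <= 0))
    stop("'mu_list': viscosities mu_f must be > 0", call. = FALSE)
  if (any(f0_list <= 0) || f0 <= 0)
    stop("'f0' must be > 0", call. = FALSE)
  if (any(dp_list <= 0) || d_p <= 0)
    stop("'d_p' must be > 0", call. = FALSE)
  if (is.null(protocol)) {
    protocol <- if (scaled) estimation_protocol(NT = 200, Nm = 5)
                else estimation_protocol(NT = 1000, Nm = 20)
  }
  if (is.null(NMC)) NMC <- if (scaled) 5L else 20L
  structure(list(rho_f = rho_f, c_f = c_f, P_f = P_f, f0 = f0,
                 d_p = d_p, m_p = m_p, rho_p = rho_p, R0 = R0, kA = kA,
                 delta_t = delta_t, alpha = alpha,
                 mu_list = mu_list, snr_list = snr_list,
                 f0_list = f0_list, Pf_list = Pf_list, dp_list = dp_list,
                 NMC = as.integer(NMC), protocol = protocol,
                 master_seed = as.integer(master_seed), scaled = scaled),
            class = "vfret_config")
}

# Deterministic child seed from (master, point, replicate, measurement),
# kept inside 32-bit integer range.
.child_seed <- function(master, point, replicate = 0L, measurement = 0L) {
  s <- (as.double(master) * 2654435761 + point * 97003 +
          replicate * 7919 + measurement * 131) %% 2147483647
  as.integer(s)
}

.config_particle <- function(config) {
  donor_particle(d_p = config$d_p, m_p = config$m_p, rho_p = config$rho_p,
                 R0 = config$R0, kA = config$kA)
}

#' Displacement-amplitude sweeps
#'
#' Deterministic grids of the fluid amplitude `Uf_max(f0, Pf)` and the
#' particle amplitude `Up_max(f0, dp, mu_f)` over the configured ranges;
#' the numerical counterpart of the amplitude maps used to choose operating
#' points (fluid amplitude reaches hundreds of nm at low frequency; particle
#' amplitude grows with viscosity and shrinks with particle size and
#' frequency).
#'
#' @param config An [experiment_config()].
#' @return List of two data frames: `fluid` (f0, P_f, Uf_max) and
#'   `particle` (f0, d_p, mu_f, eta_p, Up_max). Amplitudes in metres.
#' @export
sweep_displacement <- function(config) {
  stopifnot(inherits(config, "vfret_config"))
  fl_grid <- expand.grid(f0 = config$f0_list, P_f = config$Pf_list,
                         KEEP.OUT.ATTRS = FALSE)
  fl_grid$Uf_max <- mapply(function(f0, P_f) {
    fluid_displacement_amplitude(acoustic_drive(P_f, f0),
                                 fluid_medium(config$rho_f, config$c_f, 1e-3))
  }, fl_grid$f0, fl_grid$P_f)

  pt_grid <- expand.grid(f0 = config$f0_list, d_p = config$dp_list,
                         mu_f = config$mu_list, KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(f0, d_p, mu_f) {
    fl <- fluid_medium(config$rho_f, config$c_f, mu_f)
    dr <- acoustic_drive(config$P_f, f0)
    pt <- donor_particle(d_p = d_p, rho_p = config$rho_p,
                         R0 = config$R0, kA = config$kA)
    vib <- suppressWarnings(vibration_state(dr, fl, pt))
    c(eta_p = vib$eta_p, Up_max = vib$Up_max)
  }, pt_grid$f0, pt_grid$d_p, pt_grid$mu_f)
  pt_grid$eta_p <- res["eta_p", ]
  pt_grid$Up_max <- res["Up_max", ]
  list(fluid = fl_grid, particle = pt_grid)
}

#' Run the Monte Carlo estimation study
#'
#' For every (viscosity, SNR) sweep point and every replicate: draw `Nm`
#' steady-state positions above the true vibration amplitude, simulate the
#' noisy photon-count series, run the full inverse pipeline (fold, filter,
#' fit, aggregate), and record the estimates against ground truth. Per-point
#' failures (e.g. every measurement rejected) are recorded as failure rows
#' and the study continues.
#'
#' @param config An [experiment_config()].
#' @return A tidy data frame (class `vfret_sweep`), one row per
#'   (sweep point, replicate): truth, estimates, absolute and relative
#'   errors, counts of used/rejected measurements, and a `failed` flag.
#' @export
run_estimation_study <- function(config) {
  stopifnot(inherits(config, "vfret_config"))
  particle <- .config_particle(config)
  drive <- acoustic_drive(config$P_f, config$f0)
  protocol <- config$protocol
  grid <- expand.grid(mu_f = config$mu_list, snr_db = config$snr_list,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid) * config$NMC)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    mu_true <- grid$mu_f[g]
    snr <- grid$snr_db[g]
    fluid <- fluid_medium(config$rho_f, config$c_f, mu_true)
    vib <- suppressWarnings(vibration_state(drive, fluid, particle))
    known <- list(rho_f = config$rho_f, c_f = config$c_f,
                  P_f = config$P_f, f0 = config$f0,
                  d_p = particle$d_p, m_p = particle$m_p,
                  R0 = particle$R0, kA = particle$kA,
                  alpha = config$alpha)
    for (r in seq_len(config$NMC)) {
      k <- k + 1L
      d0s <- sample_positions(protocol$Nm, vib$Up_max, protocol,
                              seed = .child_seed(config$master_seed, g, r))
      series <- lapply(seq_along(d0s), function(i) {
        suppressWarnings(simulate_series(
          fluid, drive, particle, d0 = d0s[i],
          n_periods = protocol$NT, delta_t = config$delta_t,
          alpha = config$alpha, snr_db = snr,
          seed = .child_seed(config$master_seed, g, r, i)))
      })
      rep_row <- tryCatch({
        rpt <- estimate_viscosity(series, known, protocol)
        usable <- rpt$per_measurement$verdict == "accept" &
          rpt$per_measurement$converged
        d0_relerr <- mean(abs(rpt$per_measurement$d0_hat[usable] -
                                d0s[usable]) / d0s[usable])
        data.frame(
          mu_true = mu_true, snr_db = snr, replicate = r,
          mu_hat = rpt$mu_hat_final,
          mu_abs_err = abs(rpt$mu_hat_final - mean(series[[1]]$truth$mu_f)),
          mu_rel_err = abs(rpt$mu_hat_final - mu_true) / mu_true,
          d0_rel_err = d0_relerr,
          n_used = rpt$n_used, n_rejected = rpt$n_rejected,
          failed = FALSE, stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(mu_true = mu_true, snr_db = snr, replicate = r,
                   mu_hat = NA_real_, mu_abs_err = NA_real_,
                   mu_rel_err = NA_real_, d0_rel_err = NA_real_,
                   n_used = 0L, n_rejected = protocol$Nm,
                   failed = TRUE, stringsAsFactors = FALSE)
      })
      rows[[k]] <- rep_row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("vfret_sweep", "data.frame")
  out
}

#' Summary error metrics of a sweep result
#'
#' Per sweep point (true viscosity x SNR): mean estimate, bias, RMSE, mean
#' relative error, and rejection rate, over the non-failed replicates.
#'
#' @param result A [run_estimation_study()] result.
#' @return Data frame with one row per sweep point.
#' @export
error_metrics <- function(result) {
  stopifnot(is.data.frame(result), nrow(result) > 0)
  key <- interaction(result$mu_true, result$snr_db, drop = TRUE)
  parts <- split(result, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    ok <- !d$failed
    est <- d$mu_hat[ok]
    truth <- d$mu_true[1]
    data.frame(
      mu_true = truth, snr_db = d$snr_db[1],
      n_replicates = nrow(d), n_failed = sum(!ok),
      mean_estimate = mean(est),
      bias = mean(est) - truth,
      rmse = sqrt(mean((est - truth)^2)),
      mean_rel_err = mean(abs(est - truth) / truth),
      rejection_rate = mean(d$n_rejected / (d$n_used + d$n_rejected)),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$mu_true, out$snr_db), , drop = FALSE]
}
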