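# Inverse algorithm: fold-average periods, filter samples and measurement
# sets, fit (d0, mu_f) per measurement by Levenberg-Marquardt nonlinear
# least squares, and aggregate across measurements.

#' Estimation protocol parameters
#'
#' Controls the folding, filtering, and fitting stages of the inverse
#' algorithm. Defaults follow the simulation protocol: 1000 periods
#' averaged, 20 measurement sets, minimum efficiency 0.01 for a sample to
#' count, and at least `S/12` qualifying samples (one twelfth of a period)
#' for a measurement set to be usable.
#'
#' @param NT Periods to fold-average.
#' @param Nm Number of measurement sets.
#' @param E_min Minimum measured efficiency for sample inclusion.
#' @param Nmin_fraction Minimum qualifying samples per period, as a fraction
#'   of the samples-per-period count `S`.
#' @param d0_min,d0_max Offsets above `Up_max` bracketing the uniform
#'   sampling of the steady-state position `d0` \[m\].
#' @param d0_initial Initial guess for `d0` \[m\], or `NULL` to use
#'   `Up_max(mu_initial) + (d0_min + d0_max)/2`.
#' @param mu_initial Initial guess for viscosity \[Pa s\]; default the
#'   midpoint of the 0.5--5 mPa s search range.
#' @param d0_bounds,mu_bounds Box constraints for the fit \[m\] and \[Pa s\].
#' @param max_iter,ftol Solver controls passed to [minpack.lm::nls.lm()].
#' @return An object of class `vfret_protocol`.
#' @export
estimation_protocol <- function(NT = 1000, Nm = 20, E_min = 0.01,
                                Nmin_fraction = 1 / 12,
                                d0_min = 1e-9, d0_max = 20e-9,
                                d0_initial = NULL, mu_initial = 2.75e-3,
                                d0_bounds = c(0.5e-9, 1e-6),
                                mu_bounds = c(0.1e-3, 10e-3),
                                max_iter = 100, ftol = 1e-12) {
  if (E_min <= 0 || E_min >= 1) stop("'E_min' must be in (0, 1)", call. = FALSE)
  if (Nmin_fraction <= 0 || Nmin_fraction > 1)
    stop("'Nmin_fraction' must be in (0, 1]", call. = FALSE)
  if (d0_min >= d0_max) stop("'d0_min' must be < 'd0_max'", call. = FALSE)
  if (mu_initial < mu_bounds[1] || mu_initial > mu_bounds[2])
    stop("'mu_initial' outside 'mu_bounds'", call. = FALSE)
  structure(list(NT = NT, Nm = Nm, E_min = E_min,
                 Nmin_fraction = Nmin_fraction,
                 d0_min = d0_min, d0_max = d0_max,
                 d0_initial = d0_initial, mu_initial = mu_initial,
                 d0_bounds = d0_bounds, mu_bounds = mu_bounds,
                 max_iter = max_iter, ftol = ftol),
            class = "vfret_protocol")
}

#' Fold-average a measurement series over periods
#'
#' Averages the photon counts across `NT` consecutive periods at fixed phase
#' offset, suppressing the Gaussian noise variance by `1/NT`. Element `j` of
#' the result is the mean of samples `j, j+S, ..., j+(NT-1)S`.
#'
#' @param series A [simulate_series()] result (or compatible list with
#'   `counts`, `S`, `delta_t`).
#' @param NT Number of periods to average; the series must contain at least
#'   `NT * S` samples.
#' @return An object of class `vfret_waveform`: `tau` (phase offsets in
#'   \[0, T)), `waveform` (S mean counts), plus `S`, `delta_t`, `f0`,
#'   `alpha`, `NT`, `touching` carried from the series.
#' @export
fold_average <- function(series, NT) {
  stopifnot(is.list(series), !is.null(series$counts), !is.null(series$S))
  S <- series$S
  if (NT < 1) stop("'NT' must be >= 1", call. = FALSE)
  if (length(series$counts) < NT * S)
    stop(sprintf("series has %d samples; %d periods of S=%d require %d",
                 length(series$counts), NT, S, NT * S), call. = FALSE)
  m <- matrix(series$counts[seq_len(NT * S)], nrow = S)
  structure(list(tau = (seq_len(S) - 1L) * series$delta_t,
                 waveform = rowMeans(m),
                 S = S, delta_t = series$delta_t, f0 = series$f0,
                 alpha = series$alpha, NT = as.integer(NT),
                 touching = isTRUE(series$touching),
                 truth = series$truth),
            class = "vfret_waveform")
}

#' Filter samples of a folded waveform and judge the measurement set
#'
#' Keeps the phase bins whose measured normalized count (`waveform / alpha`,
#' the efficiency scale available to the operator) is at least `E_min`.
#' The whole measurement set is rejected when too few samples qualify
#' (fewer than `round(Nmin_fraction * S)`, boundary inclusive) or when the
#' waveform saturates (max normalized count >= 0.99), the signature of a
#' donor touching the acceptor layer, which carries no viscosity
#' information.
#'
#' @param waveform A [fold_average()] result.
#' @param protocol An [estimation_protocol()].
#' @return List with `kept` (integer indices into the waveform), `verdict`
#'   (`"accept"` or `"reject"`), and `reason` (`NA`, `"touching"`, or
#'   `"too_few_samples"`).
#' @export
select_samples <- function(waveform, protocol) {
  stopifnot(inherits(waveform, "vfret_waveform"),
            inherits(protocol, "vfret_protocol"))
  eff <- waveform$waveform / waveform$alpha
  kept <- which(eff >= protocol$E_min)
  if (max(eff) >= 0.99)
    return(list(kept = integer(0), verdict = "reject", reason = "touching"))
  n_min <- round(protocol$Nmin_fraction * waveform$S)
  if (length(kept) < n_min)
    return(list(kept = integer(0), verdict = "reject",
                reason = "too_few_samples"))
  list(kept = kept, verdict = "accept", reason = NA_character_)
}

#' Draw steady-state donor positions for a measurement campaign
#'
#' Positions are uniform on `[Up_max + d0_min, Up_max + d0_max]`, i.e. the
#' acceptor-layer search always lands above the particle's vibration
#' amplitude so the donor does not touch the layer.
#'
#' @param Nm Number of positions.
#' @param Up_max Particle vibration amplitude at the true viscosity \[m\].
#' @param protocol An [estimation_protocol()] (supplies `d0_min`, `d0_max`).
#' @param seed Integer RNG seed.
#' @return Numeric vector of `Nm` positions \[m\], all > `Up_max`.
#' @export
sample_positions <- function(Nm, Up_max, protocol, seed = 1L) {
  stopifnot(inherits(protocol, "vfret_protocol"))
  set.seed(as.integer(seed))
  stats::runif(Nm, Up_max + protocol$d0_min, Up_max + protocol$d0_max)
}

# Model waveform on the efficiency scale at phase offsets tau, with all
# physics known except (d0, mu_f). Parameters in fit units: d0 [nm],
# mu_f [mPa s] for conditioning.
.model_waveform <- function(par_nm_mPas, tau, known) {
  d0 <- par_nm_mPas[1] * 1e-9
  mu <- par_nm_mPas[2] * 1e-3
  fl <- fluid_medium(known$rho_f, known$c_f, mu)
  dr <- acoustic_drive(known$P_f, known$f0)
  Uf <- fluid_displacement_amplitude(dr, fl)
  tau_p <- known$m_p / (3 * pi * mu * known$d_p)
  x <- dr$omega0 * tau_p
  eta <- 1 / sqrt(1 + x^2)
  phi <- atan(x)
  d <- d0 - eta * Uf * cos(dr$omega0 * tau - phi)
  d <- pmax(d, 0.1e-9)
  fret_efficiency(d, known$R0, known$kA)
}

#' Fit one measurement: estimate (d0, mu_f) by Levenberg-Marquardt
#'
#' Minimizes the sum of squared deviations between the folded, filtered
#' waveform (normalized by `alpha`) and the noiseless forward model over the
#' kept phase bins, with all other physical parameters known. The fit runs
#' in (nm, mPa s) units for conditioning, under box bounds. A fit that
#' terminates on a bound is marked non-converged (boundary solutions signal
#' misspecification, not estimates); a near-singular Jacobian at the
#' solution (e.g. a numerically static donor, for which viscosity is
#' unidentifiable) sets `ill_conditioned`.
#'
#' @param waveform A [fold_average()] result.
#' @param kept Integer indices from [select_samples()].
#' @param known Named list of known parameters: `rho_f`, `c_f`, `P_f`, `f0`,
#'   `d_p`, `m_p`, `R0`, `kA`, `alpha`.
#' @param protocol An [estimation_protocol()].
#' @return List with `d0_hat` \[m\], `mu_hat` \[Pa s\], `converged`,
#'   `ill_conditioned`, `residual_norm`, `n_samples_used`, `n_iter`.
#' @export
fit_measurement <- function(waveform, kept, known, protocol) {
  stopifnot(inherits(waveform, "vfret_waveform"),
            inherits(protocol, "vfret_protocol"))
  if (length(kept) < 2) stop("need at least 2 kept samples to fit", call. = FALSE)
  tau <- waveform$tau[kept]
  y <- waveform$waveform[kept] / waveform$alpha

  mu_init <- protocol$mu_initial
  d0_init <- protocol$d0_initial
  if (is.null(d0_init)) {
    fl <- fluid_medium(known$rho_f, known$c_f, mu_init)
    dr <- acoustic_drive(known$P_f, known$f0)
    pt <- donor_particle(d_p = known$d_p, m_p = known$m_p,
                         R0 = known$R0, kA = known$kA)
    Up0 <- suppressWarnings(vibration_state(dr, fl, pt))$Up_max
    d0_init <- Up0 + (protocol$d0_min + protocol$d0_max) / 2
  }
  lower <- c(protocol$d0_bounds[1] * 1e9, protocol$mu_bounds[1] * 1e3)
  upper <- c(protocol$d0_bounds[2] * 1e9, protocol$mu_bounds[2] * 1e3)
  start <- pmin(pmax(c(d0_init * 1e9, mu_init * 1e3), lower), upper)

  resid_fn <- function(p) y - .model_waveform(p, tau, known)
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = protocol$max_iter, ftol = protocol$ftol,
      ptol = protocol$ftol))

  p_hat <- fit$par
  # relative distance to a bound, in fit units
  at_bound <- any(pmin(p_hat - lower, upper - p_hat) <
                    1e-8 * pmax(abs(p_hat), 1))
  # conditioning of the 2-column Jacobian at the solution
  J <- tryCatch({
    eps <- 1e-6 * pmax(abs(p_hat), 1)
    cbind(
      (.model_waveform(p_hat + c(eps[1], 0), tau, known) -
         .model_waveform(p_hat - c(eps[1], 0), tau, known)) / (2 * eps[1]),
      (.model_waveform(p_hat + c(0, eps[2]), tau, known) -
         .model_waveform(p_hat - c(0, eps[2]), tau, known)) / (2 * eps[2]))
  }, error = function(e) NULL)
  ill <- TRUE
  if (!is.null(J) && all(is.finite(J))) {
    sv <- svd(J, nu = 0, nv = 0)$d
    ill <- sv[2] <= 1e-10 * max(sv[1], .Machine$double.eps)
  }
  converged <- fit$info %in% 1:4 && !at_bound && !ill

  list(d0_hat = p_hat[1] * 1e-9, mu_hat = p_hat[2] * 1e-3,
       converged = converged, ill_conditioned = ill, at_bound = at_bound,
       residual_norm = sqrt(sum(fit$fvec^2)),
       n_samples_used = length(kept), n_iter = fit$niter,
       solver_info = fit$info)
}

#' Aggregate per-measurement fits into a final estimate report
#'
#' The final `(d0, mu_f)` estimates are unweighted arithmetic means over the
#' accepted, converged measurements. Rejected or non-converged measurements
#' are excluded from the averages but fully accounted for in the rejection
#' ledger.
#'
#' @param fits List of per-measurement records, each a list with at least
#'   `verdict`, and for accepted ones the [fit_measurement()] fields.
#' @return An object of class `vfret_report`: `per_measurement` (data frame),
#'   `d0_hat_final`, `mu_hat_final` \[SI\], `n_used`, `n_rejected`,
#'   `rejection_reasons`.
#' @export
aggregate_estimates <- function(fits) {
  n <- length(fits)
  if (n == 0) stop("no measurements to aggregate", call. = FALSE)
  rows <- lapply(seq_len(n), function(i) {
    f <- fits[[i]]
    data.frame(
      measurement = i,
      verdict = f$verdict %||% "accept",
      reason = f$reason %||% NA_character_,
      d0_hat = f$d0_hat %||% NA_real_,
      mu_hat = f$mu_hat %||% NA_real_,
      converged = isTRUE(f$converged),
      residual_norm = f$residual_norm %||% NA_real_,
      n_samples_used = f$n_samples_used %||% 0L,
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  usable <- per$verdict == "accept" & per$converged
  if (!any(usable)) {
    reasons <- ifelse(per$verdict == "reject", per$reason, "non_converged")
    stop(paste0("no usable measurements: ",
                paste(sprintf("#%d:%s", per$measurement, reasons),
                      collapse = ", ")), call. = FALSE)
  }
  structure(list(
    per_measurement = per,
    d0_hat_final = mean(per$d0_hat[usable]),
    mu_hat_final = mean(per$mu_hat[usable]),
    n_used = sum(usable),
    n_rejected = sum(!usable),
    rejection_reasons = table(ifelse(per$verdict == "reject", per$reason,
                                     ifelse(per$converged, "used",
                                            "non_converged")))),
    class = "vfret_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full inverse pipeline on a set of measurement series
#'
#' Convenience wrapper: fold each series over `NT` periods, filter, fit the
#' accepted ones, and aggregate.
#'
#' @param series_list List of [simulate_series()] results.
#' @param known Named list of known physics parameters (see
#'   [fit_measurement()]).
#' @param protocol An [estimation_protocol()].
#' @return A `vfret_report` (see [aggregate_estimates()]).
#' @export
estimate_viscosity <- function(series_list, known, protocol) {
  fits <- lapply(series_list, function(s) {
    if (isTRUE(s$touching))
      return(list(verdict = "reject", reason = "touching"))
    w <- fold_average(s, protocol$NT)
    sel <- select_samples(w, protocol)
    if (sel$verdict == "reject")
      return(list(verdict = "reject", reason = sel$reason))
    c(list(verdict = "accept", reason = NA_character_),
      fit_measurement(w, sel$kept, known, protocol))
  })
  aggregate_estimates(fits)
}

#' @export
print.vfret_report <- function(x, ...) {
  cat("VFRET estimate report\n")
  cat(sprintf("  mu_f: %.4g mPa*s   d0: %.4g nm  (means over %d measurements; %d rejected)\n",
              x$mu_hat_final * 1e3, x$d0_hat_final * 1e9,
              x$n_used, x$n_rejected))
  invisible(x)
}
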