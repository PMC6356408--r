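# Fold averaging, sample filtering, position sampling, LM fitting,
# and aggregation.

make_waveform <- function(values, alpha = 1, delta_t = 20e-6) {
  structure(list(tau = (seq_along(values) - 1) * delta_t,
                 waveform = values, S = length(values), delta_t = delta_t,
                 f0 = 1 / (length(values) * delta_t), alpha = alpha,
                 NT = 1L, touching = FALSE, truth = NULL),
            class = "vfret_waveform")
}

test_that("fold averaging reduces to identity for NT = 1 and preserves constants", {
  fl <- baseline_fluid()
  dr <- baseline_drive()
  pt <- baseline_particle()
  s <- simulate_series(fl, dr, pt, 20e-9, n_periods = 3)
  w1 <- fold_average(s, 1)
  expect_identical(w1$waveform, s$counts[seq_len(s$S)])
  # constant input -> constant output
  s_const <- s
  s_const$counts <- rep(0.37, length(s$counts))
  expect_true(all(fold_average(s_const, 3)$waveform == 0.37))
  # noiseless periodic input folds to any single period
  w3 <- fold_average(s, 3)
  expect_equal(w3$waveform, s$counts[seq_len(s$S)], tolerance = 1e-14)
  expect_error(fold_average(s, 4), "periods")
})

test_that("sample selection applies the efficiency floor and set-level rules", {
  prot <- estimation_protocol(NT = 1, Nm = 1, E_min = 0.01,
                              Nmin_fraction = 1 / 12)
  # all samples below E_min -> too few
  w_low <- make_waveform(rep(0.001, 120))
  expect_equal(select_samples(w_low, prot)$reason, "too_few_samples")
  # saturated waveform -> touching
  w_sat <- make_waveform(c(rep(0.5, 119), 1.0))
  expect_equal(select_samples(w_sat, prot)$reason, "touching")
  # boundary: exactly round(S/12) qualifying samples is accepted
  w_edge <- make_waveform(c(rep(0.5, 10), rep(0.001, 110)))  # S=120, Nmin=10
  sel <- select_samples(w_edge, prot)
  expect_equal(sel$verdict, "accept")
  expect_identical(sel$kept, 1:10)
  # one fewer is rejected
  w_9 <- make_waveform(c(rep(0.5, 9), rep(0.001, 111)))
  expect_equal(select_samples(w_9, prot)$reason, "too_few_samples")
})

test_that("position sampling is uniform above the vibration amplitude", {
  prot <- estimation_protocol(NT = 1, Nm = 1)
  Up <- 8e-9
  # degenerate uniform
  prot_d <- estimation_protocol(NT = 1, Nm = 1, d0_min = 5e-9,
                                d0_max = 5e-9 + 1e-15)
  expect_equal(sample_positions(5, Up, prot_d, seed = 1),
               rep(Up + 5e-9, 5), tolerance = 1e-6)
  # empirical mean within 3 standard errors of Up + (min+max)/2
  x <- sample_positions(1e5, Up, prot, seed = 4)
  expect_true(all(x > Up))
  half_width <- (prot$d0_max - prot$d0_min) / 2
  se <- (prot$d0_max - prot$d0_min) / sqrt(12 * 1e5)
  expect_lt(abs(mean(x) - (Up + prot$d0_min + half_width)), 3 * se)
  # determinism
  expect_identical(sample_positions(10, Up, prot, seed = 8),
                   sample_positions(10, Up, prot, seed = 8))
})

test_that("noiseless fit recovers the generating parameters to 1e-6", {
  fl <- baseline_fluid(3.5e-3)
  dr <- baseline_drive()
  pt <- baseline_particle()
  vib <- suppressWarnings(vibration_state(dr, fl, pt))
  d0 <- vib$Up_max + 8e-9
  s <- simulate_series(fl, dr, pt, d0, n_periods = 2)
  prot <- estimation_protocol(NT = 2, Nm = 1)
  w <- fold_average(s, 2)
  sel <- select_samples(w, prot)
  expect_equal(sel$verdict, "accept")
  fit <- fit_measurement(w, sel$kept, known_params(fl, dr, pt), prot)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$mu_hat, 3.5e-3), 1e-6)
  expect_lt(rel_err(fit$d0_hat, d0), 1e-6)
  expect_lt(fit$residual_norm, 1e-8)
})

test_that("fit recovers truth from initial guesses off by +/-50%", {
  fl <- baseline_fluid(2e-3)
  dr <- baseline_drive()
  pt <- baseline_particle()
  vib <- suppressWarnings(vibration_state(dr, fl, pt))
  d0 <- vib$Up_max + 10e-9
  s <- simulate_series(fl, dr, pt, d0, n_periods = 1)
  prot_lo <- estimation_protocol(NT = 1, Nm = 1, mu_initial = 1e-3,
                                 d0_initial = d0 * 0.5)
  prot_hi <- estimation_protocol(NT = 1, Nm = 1, mu_initial = 3e-3,
                                 d0_initial = d0 * 1.5)
  w <- fold_average(s, 1)
  for (prot in list(prot_lo, prot_hi)) {
    sel <- select_samples(w, prot)
    fit <- fit_measurement(w, sel$kept, known_params(fl, dr, pt), prot)
    expect_true(fit$converged)
    expect_lt(rel_err(fit$mu_hat, 2e-3), 1e-6)
    expect_lt(rel_err(fit$d0_hat, d0), 1e-6)
  }
})

test_that("a static donor leaves viscosity unidentifiable and is flagged", {
  fl <- baseline_fluid()
  dr <- acoustic_drive(0, 50)   # no drive -> Up_max = 0
  pt <- baseline_particle()
  s <- simulate_series(fl, dr, pt, 12e-9, n_periods = 1)
  prot <- estimation_protocol(NT = 1, Nm = 1)
  w <- fold_average(s, 1)
  sel <- select_samples(w, prot)
  fit <- fit_measurement(w, sel$kept, known_params(fl, dr, pt), prot)
  expect_true(fit$ill_conditioned)
  expect_false(fit$converged)
})

test_that("fitting the fold of NT periods matches fitting one period when noiseless", {
  fl <- baseline_fluid(1.5e-3)
  dr <- baseline_drive()
  pt <- baseline_particle()
  vib <- suppressWarnings(vibration_state(dr, fl, pt))
  d0 <- vib$Up_max + 6e-9
  known <- known_params(fl, dr, pt)
  fits <- lapply(c(1, 7), function(NT) {
    s <- simulate_series(fl, dr, pt, d0, n_periods = NT)
    prot <- estimation_protocol(NT = NT, Nm = 1)
    w <- fold_average(s, NT)
    sel <- select_samples(w, prot)
    fit_measurement(w, sel$kept, known, prot)
  })
  expect_equal(fits[[1]]$mu_hat, fits[[2]]$mu_hat, tolerance = 1e-9)
  expect_equal(fits[[1]]$d0_hat, fits[[2]]$d0_hat, tolerance = 1e-9)
})

test_that("aggregation averages usable fits and ledgers the rest", {
  ok <- function(mu, d0) list(verdict = "accept", reason = NA_character_,
                              d0_hat = d0, mu_hat = mu, converged = TRUE,
                              residual_norm = 0, n_samples_used = 100L)
  rej <- list(verdict = "reject", reason = "touching")
  # identical estimates -> that value
  r1 <- aggregate_estimates(list(ok(2e-3, 1e-8), ok(2e-3, 1e-8)))
  expect_equal(r1$mu_hat_final, 2e-3)
  # one accepted + one rejected
  r2 <- aggregate_estimates(list(ok(3e-3, 1e-8), rej))
  expect_equal(r2$mu_hat_final, 3e-3)
  expect_equal(r2$n_rejected, 1)
  expect_equal(r2$n_used, 1)
  # {1, 2, 3} mPa s -> 2 mPa s, permutation invariant
  fits <- list(ok(1e-3, 1e-8), ok(2e-3, 2e-8), ok(3e-3, 3e-8))
  r3 <- aggregate_estimates(fits)
  expect_equal(r3$mu_hat_final, 2e-3)
  r3p <- aggregate_estimates(fits[c(3, 1, 2)])
  expect_equal(r3p$mu_hat_final, r3$mu_hat_final)
  expect_equal(r3p$d0_hat_final, r3$d0_hat_final)
  # non-converged fits are excluded from the averages
  nc <- ok(9e-3, 9e-8); nc$converged <- FALSE
  r4 <- aggregate_estimates(list(ok(2e-3, 1e-8), nc))
  expect_equal(r4$mu_hat_final, 2e-3)
  # zero usable measurements is an explicit error with reasons
  expect_error(aggregate_estimates(list(rej, rej)), "no usable")
})

test_that("end-to-end noiseless pipeline recovers parameters across the ranges", {
  set.seed(31)
  for (mu in c(0.7e-3, 2e-3, 4.5e-3)) {
    fl <- baseline_fluid(mu)
    dr <- baseline_drive()
    pt <- baseline_particle()
    vib <- suppressWarnings(vibration_state(dr, fl, pt))
    prot <- estimation_protocol(NT = 3, Nm = 3)
    d0s <- sample_positions(3, vib$Up_max, prot, seed = round(mu * 1e6))
    series <- lapply(seq_along(d0s), function(i)
      simulate_series(fl, dr, pt, d0s[i], n_periods = 3, seed = i))
    rpt <- estimate_viscosity(series, known_params(fl, dr, pt), prot)
    expect_lt(rel_err(rpt$mu_hat_final, mu), 1e-4)
    usable <- rpt$per_measurement$verdict == "accept" &
      rpt$per_measurement$converged
    expect_lt(max(rel_err(rpt$per_measurement$d0_hat[usable], d0s[usable])),
              1e-4)
  }
})

test_that("estimates respect the box bounds", {
  fl <- baseline_fluid(3.5e-3)
  dr <- baseline_drive()
  pt <- baseline_particle()
  vib <- suppressWarnings(vibration_state(dr, fl, pt))
  d0 <- vib$Up_max + 8e-9
  s <- simulate_series(fl, dr, pt, d0, n_periods = 50, snr_db = 10, seed = 5)
  prot <- estimation_protocol(NT = 50, Nm = 1)
  w <- fold_average(s, 50)
  sel <- select_samples(w, prot)
  expect_equal(sel$verdict, "accept")
  fit <- fit_measurement(w, sel$kept, known_params(fl, dr, pt), prot)
  expect_gte(fit$d0_hat, prot$d0_bounds[1])
  expect_lte(fit$d0_hat, prot$d0_bounds[2])
  expect_gte(fit$mu_hat, prot$mu_bounds[1])
  expect_lte(fit$mu_hat, prot$mu_bounds[2])
})
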