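test_that("normalization maps baseline to ~0 and plateau to ~1", {
  tr <- tibble::tibble(time_min = 0:100, signal = 10 + 0:100)
  out <- normalize_trace(tr)
  expect_lt(abs(out$signal[1]), 0.05)
  expect_lt(abs(out$signal[101] - 1), 0.05)
  expect_true(all(out$normalized))
})

test_that("re-normalizing a normalized trace is the identity", {
  raw <- sim_tht_traces(raw = TRUE, baseline = 500, gain = 2000, seed = 5,
                        n_replicates = 1)
  once <- normalize_trace(raw)
  again <- normalize_trace(dplyr::mutate(once, normalized = FALSE))
  expect_equal(again$signal, once$signal, tolerance = 1e-12)
  expect_error(normalize_trace(once), class = "oligoflux_input_error")
})

test_that("raw generator output normalizes back onto the noiseless curve", {
  t <- seq(0, 2000, 1)
  raw <- sim_tht_traces(t, raw = TRUE, baseline = 500, gain = 2000, seed = 5,
                        noise_sd = 0.02, n_replicates = 1)
  out <- normalize_trace(raw)
  rms <- sqrt(mean((out$signal - gl_mass(t, 50, 0.02, 0.3))^2))
  expect_lt(rms, 1.5 * 0.02)
})

test_that("a trace without growth is a degenerate-trace error", {
  flat <- tibble::tibble(time_min = 0:20, signal = rep(5, 21))
  expect_error(normalize_trace(flat), class = "oligoflux_degenerate_error")
})

test_that("elongation fit is exact on a noiseless line and zero on a flat trace", {
  tr <- tibble::tibble(time_min = 0:10, signal = 0.003 * (0:10))
  fit <- fit_elongation(tr)
  expect_equal(fit$slope, 0.003, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_points_used, 6)
  flat <- tibble::tibble(time_min = 0:10, signal = rep(0.2, 11))
  expect_equal(fit_elongation(flat)$slope, 0)
  expect_error(fit_elongation(tr, n_points = 1), class = "oligoflux_input_error")
  expect_error(fit_elongation(head(tr, 3), n_points = 6),
               class = "oligoflux_input_error")
})

test_that("relative elongation divides by the control mean", {
  fits <- tibble::tibble(condition = c("A", "control"), slope = c(0.001, 0.002))
  out <- relative_elongation(fits)
  expect_equal(out$slope_rel, c(0.5, 1.0))
  # several control replicates: their relative values average exactly 1
  fits3 <- tibble::tibble(condition = rep("control", 3),
                          slope = c(0.0018, 0.0022, 0.0020))
  expect_identical(mean(relative_elongation(fits3)$slope_rel), 1)
  bad <- tibble::tibble(condition = "control", slope = -0.001)
  expect_error(relative_elongation(bad), class = "oligoflux_degenerate_error")
  expect_error(relative_elongation(fits, control = "missing"),
               class = "oligoflux_input_error")
})

test_that("the logistic fit recovers exact-model data to optimizer precision", {
  tr <- sim_tht_traces(seq(0, 2000, 2), a = 50, kappa = 0.02, noise_sd = 0,
                       n_replicates = 1)
  fit <- fit_logistic(tr)
  expect_true(fit$converged)
  expect_lt(abs(fit$a / 50 - 1), 1e-6)
  expect_lt(abs(fit$kappa / 0.02 - 1), 1e-6)
  expect_equal(fit$t_half, gl_half_time(50, 0.02), tolerance = 1e-6)
})

test_that("replicates are pooled into a single joint fit", {
  tr <- sim_tht_traces(seq(0, 2000, 2), noise_sd = 0.02, n_replicates = 3,
                       seed = 4)
  fit <- fit_logistic(tr)
  expect_true(fit$converged)
  expect_equal(fit$n_obs, 3 * length(seq(0, 2000, 2)))
  expect_lt(abs(fit$kappa / 0.02 - 1), 0.05)
})

test_that("a trace that never grows past 20% is a fit-failure value, not a crash", {
  tr <- tibble::tibble(time_min = seq(0, 100, 5),
                       signal = 0.15 * (1 - exp(-seq(0, 100, 5) / 30)))
  fit <- fit_logistic(tr)
  expect_false(fit$converged)
  expect_match(fit$message, "does not converge")
  expect_true(is.na(fit$t_half))
})

test_that("half-time root-solving matches the symmetric-logistic midpoint at c = 1", {
  fit <- make_gl_fit(a = 50, kappa = 0.02, c = 1)
  expect_equal(half_time(fit), log(50) / 0.02, tolerance = 1e-8)
})

test_that("half-time decreases strictly with kappa", {
  ths <- vapply(c(0.01, 0.02, 0.04, 0.08),
                function(k) half_time(make_gl_fit(50, k)), numeric(1))
  expect_true(all(diff(ths) < 0))
})

test_that("half-time agrees with a dense-grid 0.5 crossing", {
  fit <- make_gl_fit(50, 0.02)
  tg <- seq(260, 280, 0.01)
  cross <- tg[which(gl_mass(tg, 50, 0.02) >= 0.5)[1]]
  expect_lt(abs(half_time(fit) - cross), 0.011)
})

test_that("amplification rate matches finite-difference dP/dt at the half-time", {
  pars <- draw_params(20, seed = 303)
  for (i in seq_len(nrow(pars))) {
    fit <- make_gl_fit(pars$a[i], pars$kappa[i])
    th <- fit$t_half
    num <- num_flux(th, pars$a[i], pars$kappa[i], 0.3, r_plus = 1,
                    h = th / 2000)
    expect_lt(abs(amplification_rate(fit) / num - 1), 0.005)
  }
})

test_that("amplification rate vanishes in the frozen-kinetics limit", {
  expect_lt(amplification_rate(make_gl_fit(50, 1e-6)), 1e-10)
})
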