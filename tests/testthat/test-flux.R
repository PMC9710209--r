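test_that("the flux vanishes in the frozen-kinetics limit", {
  fit <- make_gl_fit(50, 1e-6)
  fp <- compute_flux(fit, r_plus = 0.002,
                     t_grid = seq(0, 2000, 1))
  expect_lt(max(fp$phi), 1e-9)
})

test_that("the flux is a non-negative unimodal bell", {
  pars <- draw_params(20, seed = 401)
  for (i in seq_len(nrow(pars))) {
    fit <- make_gl_fit(pars$a[i], pars$kappa[i])
    fp <- compute_flux(fit, r_plus = 0.002)
    expect_true(all(fp$phi >= 0))
    sign_changes <- sum(diff(sign(diff(fp$phi))) != 0)
    expect_equal(sign_changes, 1)
  }
})

test_that("the closed-form flux matches the finite-difference construction", {
  pars <- draw_params(10, seed = 402)
  for (i in seq_len(nrow(pars))) {
    a <- pars$a[i]; k <- pars$kappa[i]
    fit <- make_gl_fit(a, k)
    th <- fit$t_half
    tg <- seq(th / 50, 4 * th, length.out = 300)
    fp <- phi_vals <- compute_flux(fit, r_plus = 0.002, t_grid = tg)$phi
    num <- num_flux(tg, a, k, 0.3, r_plus = 0.002, h = th / 5000)
    keep <- phi_vals > 1e-3 * max(phi_vals)
    expect_lt(max(abs(num[keep] / phi_vals[keep] - 1)), 1e-3)
  }
})

test_that("the closed-form area agrees with trapezoidal quadrature", {
  pars <- draw_params(20, seed = 403)
  for (i in seq_len(nrow(pars))) {
    fit <- make_gl_fit(pars$a[i], pars$kappa[i])
    fp <- compute_flux(fit, r_plus = 0.002)
    quad <- sum(diff(fp$t) * (head(fp$phi, -1) + tail(fp$phi, -1)) / 2)
    expect_lt(abs(flux_area(fit, 0.002) / quad - 1), 1e-3)
  }
})

test_that("the area scales inversely with the elongation rate", {
  fit <- make_gl_fit(50, 0.02)
  expect_equal(flux_area(fit, 0.004), flux_area(fit, 0.002) / 2,
               tolerance = 1e-12)
  # and the scaling is what quadrature sees too
  fp <- compute_flux(fit, r_plus = 0.004)
  quad <- sum(diff(fp$t) * (head(fp$phi, -1) + tail(fp$phi, -1)) / 2)
  expect_lt(abs(flux_area(fit, 0.004) / quad - 1), 1e-3)
})

test_that("the peak time matches the grid argmax and moves with kinetics", {
  pars <- draw_params(20, seed = 404)
  for (i in seq_len(nrow(pars))) {
    fit <- make_gl_fit(pars$a[i], pars$kappa[i])
    fp <- compute_flux(fit, r_plus = 0.002)
    tp <- flux_peak_time(fit, 0.002)
    expect_lt(abs(tp - fp$t[which.max(fp$phi)]), fit$t_half / 1000 + 1e-9)
  }
  tps <- vapply(c(0.01, 0.02, 0.04),
                function(k) flux_peak_time(make_gl_fit(50, k), 0.002),
                numeric(1))
  expect_true(all(diff(tps) < 0))
})

test_that("the peak time rescales with the time unit", {
  tp_min <- flux_peak_time(make_gl_fit(50, 0.02), 0.002)
  tp_hr <- flux_peak_time(make_gl_fit(50, 0.02 * 60), 0.002 * 60)
  expect_equal(tp_hr, tp_min / 60, tolerance = 1e-8)
})

test_that("the peak height is the flux at the peak time and the grid max", {
  pars <- draw_params(20, seed = 405)
  for (i in seq_len(nrow(pars))) {
    fit <- make_gl_fit(pars$a[i], pars$kappa[i])
    hp <- flux_peak_height(fit, 0.002)
    tp <- flux_peak_time(fit, 0.002)
    expect_identical(hp, phi_closed(tp, pars$a[i], pars$kappa[i], 0.3, 0.002))
    fp <- compute_flux(fit, r_plus = 0.002)
    expect_lt(abs(max(fp$phi) / hp - 1), 1e-4)
  }
})

test_that("flux metrics normalize to a control mean of exactly 1", {
  m <- tibble::tibble(
    condition = c(rep("control", 3), "aS46"),
    replicate = c(1:3, 1),
    phi_peak = c(0.9, 1.0, 1.1, 0.5),
    phi_area = c(9, 10, 11, 6),
    phi_time = c(190, 200, 210, 320))
  out <- normalize_flux_metrics(m)
  ctrl <- dplyr::filter(out, condition == "control")
  expect_identical(mean(ctrl$phi_peak_rel), 1)
  expect_identical(mean(ctrl$phi_area_rel), 1)
  expect_identical(mean(ctrl$phi_time_rel), 1)
  expect_equal(dplyr::filter(out, condition == "aS46")$phi_peak_rel, 0.5)
  zero <- dplyr::mutate(m, phi_peak = 0)
  expect_error(normalize_flux_metrics(zero),
               class = "oligoflux_degenerate_error")
})

test_that("slowing amplification lowers the flux peak and delays it", {
  rp <- 0.002
  ctrl <- make_gl_fit(50, 0.02)
  ctrl_peak <- flux_peak_height(ctrl, rp)
  ctrl_time <- flux_peak_time(ctrl, rp)
  ctrl_area <- flux_area(ctrl, rp)
  for (k in seq(0.004, 0.018, by = 0.002)) {
    inh <- make_gl_fit(50, k)
    expect_lt(flux_peak_height(inh, rp) / ctrl_peak, 1)
    expect_lt(flux_area(inh, rp) / ctrl_area, 1)
    expect_gt(flux_peak_time(inh, rp) / ctrl_time, 1)
  }
})

test_that("invalid elongation rates are rejected", {
  fit <- make_gl_fit(50, 0.02)
  expect_error(compute_flux(fit, r_plus = 0), class = "oligoflux_input_error")
  expect_error(flux_area(fit, -1), class = "oligoflux_input_error")
})

test_that("the pipeline wrapper reproduces per-replicate metrics end to end", {
  t <- seq(0, 2000, 4)
  traces <- dplyr::bind_rows(
    sim_tht_traces(t, kappa = 0.02, noise_sd = 0.01, seed = 1,
                   condition = "control"),
    sim_tht_traces(t, kappa = 0.01, noise_sd = 0.01, seed = 10,
                   condition = "inhibitor"))
  out <- flux_metrics_table(traces, r_plus = 0.002)
  expect_equal(nrow(out), 6)
  expect_true(all(out$converged))
  ctrl <- dplyr::filter(out, condition == "control")
  expect_equal(mean(ctrl$phi_peak_rel), 1, tolerance = 1e-12)
  inh <- dplyr::filter(out, condition == "inhibitor")
  expect_true(all(inh$phi_peak_rel < 1))
  expect_true(all(inh$phi_time_rel > 1))
})
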