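# Closed-form oligomer flux of the generalized logistic model.
#
# With M' = (kappa/c) M (1 - M^c) and P = M'/(r_+ (1 - M)), the flux of
# reactive oligomers phi = dP/dt reduces to a function of M alone:
#   phi = (kappa^2 / (c^2 r_+)) * M (1 - M^c) h(M) / (1 - M)^2,
#   h(M) = 1 - (1 + c) M^c + c M^(1+c),
# which is non-negative on [0, 1] (h decreases from 1 to 0) and vanishes at
# both ends, giving the characteristic bell shape. In the exponential
# parameterization u = a exp(-kappa t): M^c = 1/(1+u), 1 - M^c = u/(1+u),
# and h = (u - c (1 - M)) / (1 + u), which is what is evaluated here.
phi_closed <- function(t, a, kappa, c, r_plus) {
  u <- a * exp(-kappa * t)
  M <- exp(-log1p(u) / c)
  m <- -expm1(-log1p(u) / c)      # 1 - M, accurate for small u
  h <- (u - c * m) / (1 + u)
  out <- (kappa^2 / (c^2 * r_plus)) * M * (u / (1 + u)) * h / m^2
  out[m == 0 | u == 0] <- 0
  out
}

# d(phi)/dt, used for locating the peak. phi = A f(M), A = kappa^2/(c^2 r_+),
# f = p h / (1-M)^2 with p = M(1 - M^c); dphi/dt = A f'(M) M'(t) with
# f' = [(p' h + p h')(1 - M) + 2 p h] / (1 - M)^3,
# p' = 1 - (1+c) M^c, h' = c (1+c) M^(c-1) (M - 1).
dphi_dt <- function(t, a, kappa, c, r_plus) {
  u <- a * exp(-kappa * t)
  M <- exp(-log1p(u) / c)
  m <- -expm1(-log1p(u) / c)
  Mc <- 1 / (1 + u)
  p <- M * u / (1 + u)
  pp <- 1 - (1 + c) * Mc
  h <- (u - c * m) / (1 + u)
  hp <- -c * (1 + c) * (Mc / M) * m
  fp <- ((pp * h + p * hp) * m + 2 * p * h) / m^3
  Mdot <- (kappa / c) * M * u / (1 + u)
  out <- (kappa^2 / (c^2 * r_plus)) * fp * Mdot
  out[m == 0 | u == 0] <- 0
  out
}

#' Oligomer flux profile of a fitted aggregation reaction
#'
#' The flux of reactive oligomers, `phi(t)`, is the net rate at which new
#' aggregates are generated over time. It is driven by secondary nucleation
#' on fibril surfaces (the source) and depleted as oligomers elongate into
#' mature fibrils (the sink). For a reaction described by the generalized
#' logistic fit, `phi(t) = dP/dt` with `P = (dM/dt) / (r_+ (1 - M))`
#' evaluates in closed form and is a non-negative, unimodal bell over time.
#'
#' The profile is evaluated on `t ∈ [0, 5 t_half]` with step `t_half / 1000`
#' unless a grid is supplied. Three summary scalars are attached: the peak
#' height `phi_peak`, the area `phi_area` (total oligomers generated over the
#' reaction) and the peak time `phi_time`, computed by the closed forms of
#' [flux_peak_height()], [flux_area()] and [flux_peak_time()].
#'
#' @param fit a converged [fit_logistic()] result.
#' @param r_plus effective elongation rate `2 k_+ m_tot` (per minute, > 0),
#'   typically the slope of a highly seeded elongation fit.
#' @param t_grid optional time grid (minutes).
#' @return A tibble of class `flux_profile` with columns `t` and `phi` and
#'   attributes `phi_peak`, `phi_area`, `phi_time`, `r_plus`, `t_half` and
#'   the model parameters.
#' @examples
#' fit <- fit_logistic(sim_tht_traces(noise_sd = 0, n_replicates = 1))
#' fp <- compute_flux(fit, r_plus = 0.002)
#' flux_summary(fp)
#' @export
compute_flux <- function(fit, r_plus, t_grid = NULL) {
  check_logistic_fit(fit)
  if (!is.numeric(r_plus) || length(r_plus) != 1L || r_plus <= 0)
    stop_input("`r_plus` must be a single positive number.")
  th <- fit$t_half
  if (is.null(t_grid)) t_grid <- seq(0, 5 * th, by = th / 1000)
  phi <- phi_closed(t_grid, fit$a, fit$kappa, fit$c, r_plus)
  out <- tibble::tibble(t = t_grid, phi = phi)
  class(out) <- c("flux_profile", class(out))
  attr(out, "phi_peak") <- flux_peak_height(fit, r_plus)
  attr(out, "phi_area") <- flux_area(fit, r_plus)
  attr(out, "phi_time") <- flux_peak_time(fit, r_plus)
  attr(out, "r_plus") <- r_plus
  attr(out, "t_half") <- th
  attr(out, "params") <- c(a = fit$a, kappa = fit$kappa, c = fit$c)
  out
}

#' Summary scalars of a flux profile
#'
#' @param profile a [compute_flux()] result.
#' @return A one-row tibble with `phi_peak`, `phi_area`, `phi_time`,
#'   `r_plus` and `t_half`.
#' @export
flux_summary <- function(profile) {
  if (!inherits(profile, "flux_profile"))
    stop_input("`profile` must be a `flux_profile`.")
  tibble::tibble(
    phi_peak = attr(profile, "phi_peak"),
    phi_area = attr(profile, "phi_area"),
    phi_time = attr(profile, "phi_time"),
    r_plus = attr(profile, "r_plus"),
    t_half = attr(profile, "t_half")
  )
}

#' Area under the oligomer flux
#'
#' Because `phi = dP/dt`, the area under the flux is available in closed form
#' as `P(Inf) - P(0) = kappa / r_+ - P(0)`: the total (normalized) number of
#' oligomers generated over the full time course.
#'
#' @inheritParams compute_flux
#' @return The area (normalized concentration units).
#' @export
flux_area <- function(fit, r_plus) {
  check_logistic_fit(fit)
  if (r_plus <= 0) stop_input("`r_plus` must be > 0.")
  p0 <- gl_fibril_number(0, fit$a, fit$kappa, fit$c, r_plus)
  fit$kappa / r_plus - p0
}

#' Peak time of the oligomer flux
#'
#' Solves `d(phi)/dt = 0` by bracketed root-finding on
#' `[t_half / 100, 5 t_half]`; the flux rises through the early growth phase
#' and decays after monomer depletion, so the bracket straddles the single
#' interior maximum.
#'
#' @inheritParams compute_flux
#' @return The peak time in minutes.
#' @export
flux_peak_time <- function(fit, r_plus) {
  check_logistic_fit(fit)
  if (r_plus <= 0) stop_input("`r_plus` must be > 0.")
  th <- fit$t_half
  lo <- th / 100
  hi <- 5 * th
  flo <- dphi_dt(lo, fit$a, fit$kappa, fit$c, r_plus)
  fhi <- dphi_dt(hi, fit$a, fit$kappa, fit$c, r_plus)
  if (flo <= 0 || fhi >= 0)
    stop_degenerate("no interior flux peak in [t_half/100, 5 t_half].")
  uniroot(function(t) dphi_dt(t, fit$a, fit$kappa, fit$c, r_plus),
          c(lo, hi), tol = 1e-10)$root
}

#' Peak height of the oligomer flux
#'
#' Evaluates the closed-form flux at its peak time: the maximal rate at which
#' oligomeric species are generated.
#'
#' @inheritParams compute_flux
#' @return The peak height (normalized concentration per minute).
#' @export
flux_peak_height <- function(fit, r_plus) {
  check_logistic_fit(fit)
  phi_closed(flux_peak_time(fit, r_plus), fit$a, fit$kappa, fit$c, r_plus)
}

#' Normalize flux metrics to the control condition
#'
#' Divides each of `phi_peak`, `phi_area` and `phi_time` by its mean over the
#' control condition's replicates, yielding the dimensionless relative
#' metrics used to rank inhibitors: an ideal inhibitor reduces the relative
#' peak and area while delaying the relative peak time beyond 1.
#'
#' @param metrics a tibble with columns `condition`, `phi_peak`, `phi_area`,
#'   `phi_time` (one row per replicate), e.g. from [flux_metrics_table()].
#' @param control control condition label.
#' @return `metrics` with `phi_peak_rel`, `phi_area_rel`, `phi_time_rel`
#'   columns; control rows average exactly 1.
#' @export
normalize_flux_metrics <- function(metrics, control = "control") {
  needed <- c("phi_peak", "phi_area", "phi_time")
  if (!all(needed %in% names(metrics)))
    stop_input("`metrics` must have phi_peak, phi_area and phi_time columns.")
  relative_to_control(metrics, dplyr::all_of(needed), control = control)
}
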