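#' Normalize a raw ThT trace to the [0, 1] fibril-mass scale
#'
#' Rescales raw fluorescence counts so that the pre-growth baseline maps to 0
#' and the end-point plateau maps to 1:
#' `(signal - baseline) / (plateau - baseline)`, with the baseline estimated
#' as the mean of the first `baseline_n` samples and the plateau as the mean
#' of the last `plateau_n` samples. If the data carry a `replicate` column,
#' each replicate is normalized with its own windows.
#'
#' @param trace a tibble with columns `time_min` and `signal` (and optionally
#'   `replicate` and other metadata columns, which are preserved).
#' @param baseline_n number of leading samples averaged for the baseline.
#' @param plateau_n number of trailing samples averaged for the plateau.
#' @return The input tibble with `signal` rescaled and `normalized = TRUE`.
#' @examples
#' raw <- sim_tht_traces(raw = TRUE, baseline = 500, gain = 2000, seed = 5)
#' norm <- normalize_trace(raw)
#' @export
normalize_trace <- function(trace, baseline_n = 3, plateau_n = 5) {
  check_trace(trace)
  if ("normalized" %in% names(trace) && isTRUE(any(trace$normalized)))
    stop_input("`trace` is already normalized.")
  one <- function(df) {
    df <- dplyr::arrange(df, .data$time_min)
    if (nrow(df) < baseline_n + plateau_n)
      stop_input("trace too short for the baseline and plateau windows.")
    base <- mean(head(df$signal, baseline_n))
    plat <- mean(tail(df$signal, plateau_n))
    if (plat <= base)
      stop_degenerate("degenerate trace: plateau does not exceed baseline (no growth).")
    df$signal <- (df$signal - base) / (plat - base)
    df
  }
  keys <- intersect(c("condition", "well", "replicate"), names(trace))
  out <- if (length(keys)) {
    trace |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup() |>
      dplyr::relocate(dplyr::any_of(names(trace)))
  } else {
    one(trace)
  }
  out$normalized <- TRUE
  tibble::as_tibble(out)
}

#' Fit the initial linear elongation phase of a highly seeded trace
#'
#' In a highly seeded reaction (e.g. 15% preformed seeds) nucleation is
#' negligible and the early fibril mass grows linearly,
#' `M(t) = M(0) + 2 k_+ P(0) m(0) t`, so the slope of an ordinary
#' least-squares line through the first `n_points` samples measures the
#' unresolved elongation-rate product `2 k_+ P(0) m(0)`. By convention the
#' first six data points of the normalized trace are used.
#'
#' @param trace a normalized single-replicate trace tibble (`time_min`,
#'   `signal`).
#' @param n_points number of leading samples to fit (>= 2).
#' @return An object of class `elongation_fit` with fields `slope` (per
#'   minute), `intercept`, `n_points_used` and `r_squared`.
#' @examples
#' tr <- tibble::tibble(time_min = 0:10, signal = 0.003 * (0:10))
#' fit_elongation(tr)
#' @export
fit_elongation <- function(trace, n_points = 6) {
  check_trace(trace)
  if (n_points < 2) stop_input("`n_points` must be >= 2.")
  if ("normalized" %in% names(trace) && !all(trace$normalized))
    stop_input("`trace` must be normalized first (see normalize_trace()).")
  trace <- dplyr::arrange(trace, .data$time_min)
  if (nrow(trace) < n_points)
    stop_input("`n_points` exceeds the trace length.")
  d <- head(trace, n_points)
  fit <- lm(signal ~ time_min, data = d)
  tss <- sum((d$signal - mean(d$signal))^2)
  r2 <- if (tss > 0) 1 - sum(resid(fit)^2) / tss else NA_real_
  structure(
    list(
      slope = unname(coef(fit)[["time_min"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      n_points_used = n_points,
      r_squared = r2
    ),
    class = "elongation_fit"
  )
}

#' @export
print.elongation_fit <- function(x, ...) {
  cat(sprintf(
    "Elongation fit: slope = %.4g /min (n = %d, R^2 = %.4f)\n",
    x$slope, x$n_points_used, x$r_squared))
  invisible(x)
}

#' Express per-condition values relative to the control mean
#'
#' Divides a per-replicate column by the mean of that column over the control
#' condition, so control replicates average exactly 1. Used for relative
#' elongation rates, relative half-times, relative amplification rates and
#' the relative oligomer-flux metrics.
#'
#' @param df a tibble with a `condition` column.
#' @param cols columns to normalize (tidyselect); each gains a `_rel`
#'   companion column.
#' @param control control condition label.
#' @return `df` with one `<col>_rel` column per input column.
#' @examples
#' df <- tibble::tibble(condition = c("A", "control"), slope = c(0.001, 0.002))
#' relative_to_control(df, slope)
#' @export
relative_to_control <- function(df, cols, control = "control") {
  if (!"condition" %in% names(df)) stop_input("`df` must have a `condition` column.")
  if (!control %in% df$condition)
    stop_input("control condition '", control, "' not present.")
  ctrl <- dplyr::filter(df, .data$condition == control)
  dplyr::mutate(df, dplyr::across(
    {{ cols }},
    function(x) {
      m <- mean(ctrl[[dplyr::cur_column()]])
      if (!is.finite(m) || m <= 0)
        stop_degenerate("degenerate control: mean of '", dplyr::cur_column(),
                        "' is not positive.")
      x / m
    },
    .names = "{.col}_rel"
  ))
}

#' Relative elongation rates across conditions
#'
#' Normalizes per-replicate elongation slopes (`2 k_+ P(0) m(0)`) to the mean
#' slope of the control condition; since `P(0)` and `m(0)` are common to all
#' conditions of one experiment, the ratio isolates the effect on the
#' elongation rate `k_+`.
#'
#' @param fits a tibble with columns `condition` and `slope` (one row per
#'   replicate), e.g. built from [fit_elongation()] results.
#' @param control control condition label.
#' @return `fits` with a `slope_rel` column; control rows average exactly 1.
#' @export
relative_elongation <- function(fits, control = "control") {
  if (!"slope" %in% names(fits)) stop_input("`fits` must have a `slope` column.")
  relative_to_control(fits, "slope", control = control)
}

#' Fit the generalized logistic model to normalized aggregation data
#'
#' Estimates the amplitude `a` and amplification rate `kappa` of the
#' generalized logistic curve ([gl_mass()]) by bounded nonlinear least
#' squares, with the shape parameter `c` held fixed (default 0.3). When the
#' input carries several replicates they are fitted jointly by pooling
#' residuals. A fit that cannot be performed (optimizer failure, or a trace
#' that never reaches half of the plateau) is returned as a non-converged
#' result carrying a diagnostic message rather than an error, mirroring how
#' titration tables report "fit does not converge".
#'
#' Starting values: `kappa` from the maximum finite-difference slope divided
#' by 0.25, and `a` from the initial signal via `M(0) = (1 + a)^{-1/c}`.
#' Bounds: `a` in (0, 1e6], `kappa` in (0, 10].
#'
#' @param trace a normalized trace tibble (`time_min`, `signal`, optionally
#'   `replicate`); replicates are pooled.
#' @param c_fixed fixed shape parameter in (0, 1].
#' @return An object of class `logistic_fit`: fields `a`, `kappa`, `c`,
#'   `lambda` ([gl_lambda()]), `rss`, `r_squared`, `t_half`, `converged`,
#'   `n_obs`, `message` and the fitted `data`.
#' @examples
#' tr <- sim_tht_traces(noise_sd = 0, n_replicates = 1)
#' fit <- fit_logistic(tr)
#' @export
fit_logistic <- function(trace, c_fixed = 0.3) {
  check_trace(trace)
  if (c_fixed <= 0 || c_fixed > 1) stop_input("`c_fixed` must be in (0, 1].")
  if ("normalized" %in% names(trace) && !all(trace$normalized))
    stop_input("`trace` must be normalized first (see normalize_trace()).")
  trace <- dplyr::arrange(trace, .data$time_min)
  tt <- trace$time_min
  yy <- trace$signal
  if (length(yy) < 10)
    stop_input("need at least 10 samples spanning the sigmoid.")

  failure <- function(msg) {
    structure(
      list(a = NA_real_, kappa = NA_real_, c = c_fixed, lambda = NA_real_,
           rss = NA_real_, r_squared = NA_real_, t_half = NA_real_,
           converged = FALSE, n_obs = length(yy), message = msg,
           data = tibble::as_tibble(trace)),
      class = "logistic_fit")
  }
  if (max(yy, na.rm = TRUE) < 0.5)
    return(failure("trace never reaches half of the plateau; fit does not converge"))

  # starting values from the data
  m0 <- min(max(mean(head(yy, 3)), 1e-4), 0.99)
  a0 <- min(max(m0^(-c_fixed) - 1, 1e-6), 1e6)
  # one trace's time step for the finite-difference slope (replicates pooled)
  first_rep <- if ("replicate" %in% names(trace)) {
    dplyr::filter(trace, .data$replicate == trace$replicate[[1]])
  } else trace
  slope_max <- max(diff(first_rep$signal) / diff(first_rep$time_min))
  k0 <- min(max(slope_max / 0.25, 1e-6), 10)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ (1 + a * exp(-kappa * tt))^(-1 / c_fixed),
      start = list(a = a0, kappa = k0),
      lower = c(a = 1e-12, kappa = 1e-12),
      upper = c(a = 1e6, kappa = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error"))
    return(failure(paste0("fit does not converge: ", conditionMessage(fit))))

  est <- coef(fit)
  rss <- sum(resid(fit)^2)
  tss <- sum((yy - mean(yy))^2)
  out <- structure(
    list(a = unname(est[["a"]]), kappa = unname(est[["kappa"]]), c = c_fixed,
         lambda = gl_lambda(est[["a"]], est[["kappa"]], c_fixed),
         rss = rss, r_squared = 1 - rss / tss, t_half = NA_real_,
         converged = TRUE, n_obs = length(yy), message = NULL,
         data = tibble::as_tibble(trace)),
    class = "logistic_fit")
  out$t_half <- half_time(out)
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Generalized logistic fit: NOT CONVERGED (", x$message, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    paste0("Generalized logistic fit: a = %.4g, kappa = %.4g /min ",
           "(c fixed at %.2g)\n  t_half = %.1f min, R^2 = %.4f, n = %d\n"),
    x$a, x$kappa, x$c, x$t_half, x$r_squared, x$n_obs))
  invisible(x)
}

#' Half-time of a fitted aggregation curve
#'
#' Root-solves the fitted generalized logistic curve for `M(t) = 0.5`; the
#' solution is unique because the curve is strictly increasing.
#'
#' @param fit a converged [fit_logistic()] result.
#' @return The half-time in minutes.
#' @export
half_time <- function(fit) {
  check_logistic_fit(fit)
  f <- function(t) gl_mass(t, fit$a, fit$kappa, fit$c) - 0.5
  upper <- 1 / fit$kappa
  while (f(upper) < 0) upper <- upper * 2
  if (f(0) >= 0) return(0)
  uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Effective rate of fibril amplification
#'
#' The linear polymerization law `dM/dt = r_+ P m` turns a fitted `M(t)` into
#' the normalized fibril number concentration `P(t)` ([gl_fibril_number()]);
#' its derivative `dP/dt`, evaluated at the reaction half-time where it is
#' close to maximal, serves as an effective rate of secondary-nucleation
#' driven fibril amplification. Values are compared across conditions
#' relative to the control mean (see [relative_to_control()]).
#'
#' @param fit a converged [fit_logistic()] result.
#' @param r_plus effective elongation rate fed into the polymerization law;
#'   1 (normalized units) when only relative values are of interest.
#' @return `dP/dt` at the half-time (per minute, normalized units).
#' @export
amplification_rate <- function(fit, r_plus = 1) {
  check_logistic_fit(fit)
  phi_closed(fit$t_half, fit$a, fit$kappa, fit$c, r_plus)
}

check_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(c("time_min", "signal") %in% names(trace)))
    stop_input("`trace` must be a data frame with `time_min` and `signal` columns.")
  invisible(TRUE)
}

check_logistic_fit <- function(fit) {
  if (!inherits(fit, "logistic_fit")) stop_input("`fit` must be a `logistic_fit`.")
  if (!isTRUE(fit$converged)) stop_input("`fit` did not converge.")
  invisible(TRUE)
}
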