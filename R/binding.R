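#' Floor a binding curve at its lowest response
#'
#' Shifts the response so the lowest signal sits at zero, the conventional
#' presentation of thermophoresis binding curves before fitting the
#' two-parameter saturation equation. Idempotent.
#'
#' @param curve a tibble with columns `concentration_uM` and `response`.
#' @return The curve with `response` shifted and `zeroed = TRUE`.
#' @export
zero_floor <- function(curve) {
  check_binding_curve(curve)
  curve$response <- curve$response - min(curve$response)
  curve$zeroed <- TRUE
  tibble::as_tibble(curve)
}

#' Fit the saturation binding equation to a titration
#'
#' Least-squares fit of `Y = B_max * x / (K_d + x)` to a
#' concentration-response table, as used to extract equilibrium dissociation
#' constants from microscale thermophoresis titrations. With `offset = TRUE`
#' a third additive offset parameter is estimated instead of pre-flooring the
#' data (see [zero_floor()]). Non-convergence is reported as a value
#' (`converged = FALSE`), not an error, since titrations of weak binders
#' routinely fail to saturate.
#'
#' @param curve a tibble with columns `concentration_uM` (> 0) and
#'   `response`, at least 4 points.
#' @param offset if `TRUE`, fit `Y = B_max x / (K_d + x) + y0`.
#' @return An object of class `binding_fit` with fields `kd` (same units as
#'   the concentrations), `bmax`, `offset`, `r_squared`, `converged`,
#'   `n_points` and the `data`.
#' @examples
#' cur <- sim_binding_curve(kd = 1, bmax = 10, top_conc = 63, seed = 1)
#' fit_saturation(cur)
#' @export
fit_saturation <- function(curve, offset = FALSE) {
  check_binding_curve(curve)
  x <- curve$concentration_uM
  y <- curve$response
  # start kd at the concentration closest to half-maximal response
  bmax0 <- max(y)
  kd0 <- x[which.min(abs(y - bmax0 / 2))]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- median(x)

  failure <- function(msg) {
    structure(
      list(kd = NA_real_, bmax = NA_real_, offset = NA_real_,
           r_squared = NA_real_, converged = FALSE, n_points = length(x),
           message = msg, data = tibble::as_tibble(curve)),
      class = "binding_fit")
  }
  fit <- tryCatch(
    if (offset) {
      minpack.lm::nlsLM(
        y ~ bmax * x / (kd + x) + y0,
        start = list(kd = kd0, bmax = bmax0, y0 = min(y)),
        lower = c(kd = .Machine$double.xmin, bmax = -Inf, y0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        y ~ bmax * x / (kd + x),
        start = list(kd = kd0, bmax = bmax0),
        lower = c(kd = .Machine$double.xmin, bmax = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) e
  )
  if (inherits(fit, "error"))
    return(failure(paste0("fit does not converge: ", conditionMessage(fit))))
  est <- coef(fit)
  rss <- sum(resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(
    list(kd = unname(est[["kd"]]), bmax = unname(est[["bmax"]]),
         offset = if (offset) unname(est[["y0"]]) else 0,
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         converged = TRUE, n_points = length(x), message = NULL,
         data = tibble::as_tibble(curve)),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Saturation binding fit: fit does not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Saturation binding fit: K_d = %.4g, B_max = %.4g (R^2 = %.3f, n = %d)\n",
    x$kd, x$bmax, x$r_squared, x$n_points))
  invisible(x)
}

#' Reference subtraction for biolayer interferometry traces
#'
#' Subtracts the reference-sensor trace (no ligand immobilized, controlling
#' for non-specific binding and drift) from the sample trace, then subtracts
#' the mean of the result over the baseline window so the association phase
#' starts near zero.
#'
#' @param sample,reference tibbles with columns `time_s` and `signal_nm`
#'   (and optionally `phase`). Both must share a time grid.
#' @param baseline_window `c(t0, t1)` in seconds; defaults to the rows
#'   labelled `phase == "baseline"` if present, else the first 10% of the
#'   trace.
#' @return The corrected sample tibble.
#' @export
bli_reference_subtract <- function(sample, reference, baseline_window = NULL) {
  for (df in list(sample, reference))
    if (!is.data.frame(df) || !all(c("time_s", "signal_nm") %in% names(df)))
      stop_input("BLI traces need `time_s` and `signal_nm` columns.")
  if (nrow(sample) != nrow(reference) ||
      max(abs(sample$time_s - reference$time_s)) > 1e-9)
    stop_input("sample and reference traces must share a time grid.")
  out <- sample
  out$signal_nm <- sample$signal_nm - reference$signal_nm
  if (is.null(baseline_window)) {
    idx <- if ("phase" %in% names(out) && any(out$phase == "baseline")) {
      out$phase == "baseline"
    } else {
      out$time_s <= quantile(out$time_s, 0.1)
    }
  } else {
    idx <- out$time_s >= baseline_window[1] & out$time_s <= baseline_window[2]
  }
  if (!any(idx)) stop_input("baseline window contains no samples.")
  out$signal_nm <- out$signal_nm - mean(out$signal_nm[idx])
  tibble::as_tibble(out)
}

check_binding_curve <- function(curve) {
  if (!is.data.frame(curve) ||
      !all(c("concentration_uM", "response") %in% names(curve)))
    stop_input("`curve` must have `concentration_uM` and `response` columns.")
  if (nrow(curve) < 4) stop_input("need at least 4 titration points.")
  if (any(curve$concentration_uM <= 0))
    stop_input("concentrations must be positive.")
  d <- diff(curve$concentration_uM)
  if (!(all(d > 0) || all(d < 0)))
    stop_input("concentrations must be strictly monotone.")
  invisible(TRUE)
}
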