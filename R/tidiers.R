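#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for oligoflux fit objects
#'
#' Broom-style accessors: `tidy()` returns one row per estimated parameter,
#' `glance()` a one-row model summary.
#'
#' @param x a fitted object (`logistic_fit`, `elongation_fit`,
#'   `binding_fit`) or a `group_comparison` table.
#' @param ... unused.
#' @return A tibble.
#' @name oligoflux-tidiers
NULL

#' @rdname oligoflux-tidiers
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "kappa", "c", "lambda"),
    estimate = c(x$a, x$kappa, x$c, x$lambda),
    fixed = c(FALSE, FALSE, TRUE, NA)
  )
}

#' @rdname oligoflux-tidiers
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, r_squared = x$r_squared, t_half = x$t_half,
    converged = x$converged, n_obs = x$n_obs
  )
}

#' @rdname oligoflux-tidiers
#' @method tidy elongation_fit
#' @export
tidy.elongation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept)
  )
}

#' @rdname oligoflux-tidiers
#' @method glance elongation_fit
#' @export
glance.elongation_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, n_points_used = x$n_points_used
  )
}

#' @rdname oligoflux-tidiers
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "bmax", "offset"),
    estimate = c(x$kd, x$bmax, x$offset)
  )
}

#' @rdname oligoflux-tidiers
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, converged = x$converged, n_points = x$n_points
  )
}

#' @rdname oligoflux-tidiers
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    omnibus_f = attr(x, "omnibus_f"),
    omnibus_p = attr(x, "omnibus_p"),
    method = attr(x, "method"),
    multiplicity_corrected = attr(x, "multiplicity_corrected")
  )
}
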