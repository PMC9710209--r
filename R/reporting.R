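#' One-way ANOVA with per-condition comparisons against a control
#'
#' Runs the omnibus one-way ANOVA across all conditions, then compares each
#' condition to the control. The default per-condition test is a two-sided
#' Welch t-test against the control group, reported without multiplicity
#' correction (flagged in the result's metadata); `method = "dunnett"` uses
#' Dunnett's many-to-one procedure instead (requires the multcomp package).
#'
#' @param data a tibble with columns `condition` and `value` (>= 2 replicate
#'   values per condition, >= 2 conditions including the control).
#' @param control control condition label.
#' @param method `"welch"` (default) or `"dunnett"`.
#' @param convention star convention passed to [significance_stars()].
#' @return A tibble of class `group_comparison` with one row per condition:
#'   `condition`, `n`, `mean`, `sd`, `p_value` (NA for the control row),
#'   `stars`. Attributes `omnibus_f`, `omnibus_p`, `method`,
#'   `multiplicity_corrected`. See [glance.group_comparison()].
#' @examples
#' df <- tibble::tibble(
#'   condition = rep(c("control", "aS46"), each = 3),
#'   value = c(1.0, 1.1, 0.9, 0.4, 0.5, 0.45))
#' anova_vs_control(df)
#' @export
anova_vs_control <- function(data, control = "control",
                             method = c("welch", "dunnett"),
                             convention = "four_tier") {
  method <- match.arg(method)
  if (!is.data.frame(data) || !all(c("condition", "value") %in% names(data)))
    stop_input("`data` must have `condition` and `value` columns.")
  if (!control %in% data$condition)
    stop_input("control condition '", control, "' not present.")
  counts <- table(data$condition)
  if (length(counts) < 2) stop_input("need at least two conditions.")
  if (any(counts < 2)) stop_input("each condition needs n >= 2 replicates.")
  within_var <- tapply(data$value, data$condition, var)
  if (all(within_var == 0))
    stop_degenerate("degenerate groups: zero within-group variance everywhere.")

  data$condition <- as.character(data$condition)
  om <- anova(lm(value ~ factor(condition), data = data))
  omnibus_f <- om[["F value"]][1]
  omnibus_p <- om[["Pr(>F)"]][1]

  ctrl_vals <- data$value[data$condition == control]
  conds <- unique(data$condition)

  p_for <- if (method == "welch") {
    function(cond) {
      if (cond == control) return(NA_real_)
      t.test(data$value[data$condition == cond], ctrl_vals)$p.value
    }
  } else {
    if (!requireNamespace("multcomp", quietly = TRUE))
      stop_input("method = 'dunnett' requires the multcomp package.")
    data$condition <- stats::relevel(factor(data$condition), ref = control)
    fit <- aov(value ~ condition, data = data)
    dn <- summary(multcomp::glht(
      fit, linfct = multcomp::mcp(condition = "Dunnett")))
    pv <- setNames(as.numeric(dn$test$pvalues),
                   sub(" - .*$", "", names(dn$test$coefficients)))
    function(cond) if (cond == control) NA_real_ else unname(pv[[cond]])
  }

  out <- purrr::map_dfr(conds, function(cond) {
    v <- data$value[data$condition == cond]
    p <- p_for(cond)
    tibble::tibble(
      condition = cond, n = length(v), mean = mean(v), sd = sd(v),
      p_value = p,
      stars = if (is.na(p)) NA_character_ else
        significance_stars(p, convention = convention)
    )
  })
  class(out) <- c("group_comparison", class(out))
  attr(out, "omnibus_f") <- omnibus_f
  attr(out, "omnibus_p") <- omnibus_p
  attr(out, "method") <- method
  attr(out, "multiplicity_corrected") <- method == "dunnett"
  out
}

#' Significance star labels
#'
#' Maps p-values onto star labels. The default `"four_tier"` convention is
#' `* p < 0.1`, `** p < 0.01`, `*** p < 0.001`, `**** p < 0.0001`;
#' `"three_tier"` omits the weak single-star tier (`** p < 0.01` and up).
#' Comparisons are strict, so boundary values fall to the weaker category.
#'
#' @param p vector of p-values in \[0, 1\] (NA allowed, propagated).
#' @param convention `"four_tier"` or `"three_tier"`.
#' @return A character vector of labels (`"ns"` when not significant).
#' @examples
#' significance_stars(c(0.5, 0.05, 0.005, 0.0005, 0.00005))
#' @export
significance_stars <- function(p, convention = c("four_tier", "three_tier")) {
  convention <- match.arg(convention)
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop_input("p-values must lie in [0, 1].")
  cuts <- switch(convention,
    four_tier = c(0.1, 0.01, 0.001, 0.0001),
    three_tier = c(0.01, 0.001, 0.0001))
  labels <- switch(convention,
    four_tier = c("ns", "*", "**", "***", "****"),
    three_tier = c("ns", "**", "***", "****"))
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    labels[1 + sum(pi < cuts)]
  }, character(1))
}

#' Per-replicate oligomer-flux metrics across conditions
#'
#' The pipeline wrapper tying the kinetic stages together: for every
#' condition and replicate in a long table of normalized low-seed traces it
#' fits the generalized logistic model ([fit_logistic()]), extracts the
#' half-time and the three flux summary metrics ([flux_peak_height()],
#' [flux_area()], [flux_peak_time()]), and normalizes the metrics to the
#' control-condition mean ([normalize_flux_metrics()]).
#'
#' @param traces long tibble with columns `condition`, `replicate`,
#'   `time_min`, `signal` (normalized).
#' @param control control condition label.
#' @param c_fixed fixed shape parameter of the logistic fits.
#' @param r_plus effective elongation rate: a single number applied to all
#'   conditions (inhibitors of secondary nucleation typically leave
#'   elongation untouched, so the control value is a sensible shared choice),
#'   or a tibble `(condition, r_plus)` for per-condition rates.
#' @return A tibble with one row per condition x replicate: the fitted
#'   parameters, `t_half`, the absolute and `_rel` flux metrics, and a
#'   `converged` flag (non-converged fits carry NA metrics and are dropped
#'   from the control mean).
#' @export
flux_metrics_table <- function(traces, control = "control", c_fixed = 0.3,
                               r_plus = 1) {
  if (!all(c("condition", "replicate", "time_min", "signal") %in% names(traces)))
    stop_input("`traces` must have condition, replicate, time_min, signal columns.")
  rp_for <- if (is.data.frame(r_plus)) {
    if (!all(c("condition", "r_plus") %in% names(r_plus)))
      stop_input("`r_plus` table needs `condition` and `r_plus` columns.")
    function(cond) {
      v <- r_plus$r_plus[r_plus$condition == cond]
      if (length(v) != 1) stop_input("no unique r_plus for condition '", cond, "'.")
      v
    }
  } else {
    function(cond) r_plus
  }
  metrics <- traces |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_logistic(dplyr::mutate(d, condition = key$condition),
                          c_fixed = c_fixed)
      if (!fit$converged)
        return(tibble::tibble(
          a = NA_real_, kappa = NA_real_, t_half = NA_real_,
          phi_peak = NA_real_, phi_area = NA_real_, phi_time = NA_real_,
          r_squared = NA_real_, converged = FALSE))
      rp <- rp_for(key$condition)
      tibble::tibble(
        a = fit$a, kappa = fit$kappa, t_half = fit$t_half,
        phi_peak = flux_peak_height(fit, rp),
        phi_area = flux_area(fit, rp),
        phi_time = flux_peak_time(fit, rp),
        r_squared = fit$r_squared, converged = TRUE)
    }) |>
    dplyr::ungroup()
  ok <- dplyr::filter(metrics, .data$converged)
  normalize_flux_metrics(ok, control = control) |>
    dplyr::bind_rows(dplyr::filter(metrics, !.data$converged))
}
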