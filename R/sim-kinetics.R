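#' Simulate thioflavin-T aggregation traces
#'
#' Generates replicate ThT time courses from the generalized logistic model
#' ([gl_mass()]) plus i.i.d. Gaussian noise, in the long tidy layout the
#' kinetics functions consume. The default parameters emulate a low-seeded
#' (0.06% preformed seeds) quiescent aggregation of 40 uM monomer read every
#' minute: `a = 50`, `kappa = 0.02` per minute, `c = 0.3`, replicate noise
#' s.d. 0.02 on the normalized signal, three technical replicates.
#'
#' In normalized mode (`raw = FALSE`) the noiseless trace rises to a plateau
#' of 1. Raw-count mode applies `baseline + gain * signal` to mimic
#' plate-reader fluorescence counts, for exercising [normalize_trace()].
#'
#' Replicate `r` draws its noise under sub-stream seed `seed + r`, so a
#' given (`seed`, replicate) pair is reproducible independently of
#' `n_replicates`.
#'
#' @param t time grid in minutes; strictly increasing, starting at 0.
#' @inheritParams gl_mass
#' @param noise_sd additive Gaussian noise s.d. on the normalized signal
#'   (>= 0).
#' @param n_replicates number of technical replicates (>= 1).
#' @param seed integer RNG seed.
#' @param raw if `TRUE`, emit raw fluorescence counts
#'   `baseline + gain * (M(t) + noise)`.
#' @param baseline,gain raw-count mode offset and scale (arbitrary units).
#' @param condition condition label (e.g. antibody plus stoichiometry).
#' @param m_tot total monomer concentration in uM (metadata).
#' @param seed_fraction preformed-seed percentage of monomer (metadata).
#' @return A tibble with columns `time_min`, `well`, `condition`,
#'   `replicate`, `signal`, `normalized`, `m_tot`, `seed_fraction`.
#' @examples
#' tr <- sim_tht_traces(seq(0, 2000, 1), noise_sd = 0.02, seed = 1)
#' @export
sim_tht_traces <- function(t = seq(0, 2000, by = 1), a = 50, kappa = 0.02,
                           c = 0.3, noise_sd = 0.02, n_replicates = 3,
                           seed = 1, raw = FALSE, baseline = 0, gain = 1,
                           condition = "control", m_tot = 40,
                           seed_fraction = 0.06) {
  if (length(t) < 2L || any(diff(t) <= 0))
    stop_input("`t` must be strictly increasing.")
  if (t[1] != 0) stop_input("`t` must start at 0.")
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0.")
  if (n_replicates < 1) stop_input("`n_replicates` must be >= 1.")
  truth <- gl_mass(t, a, kappa, c)
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    noise <- if (noise_sd > 0) {
      withr::with_seed(seed + r, rnorm(length(t), 0, noise_sd))
    } else {
      rep(0, length(t))
    }
    sig <- truth + noise
    if (raw) sig <- baseline + gain * sig
    tibble::tibble(
      time_min = t,
      well = paste0(condition, "_r", r),
      condition = condition,
      replicate = r,
      signal = sig
    )
  })
  dplyr::bind_rows(reps) |>
    dplyr::mutate(
      normalized = !raw,
      m_tot = m_tot,
      seed_fraction = seed_fraction
    )
}

#' Simulate a saturation-binding titration
#'
#' Builds the serial-dilution design used in microscale thermophoresis
#' titrations: `n_points` ligand concentrations in a geometric series
#' `top_conc * dilution^-(i)`, i = 0 .. n_points - 1 (default 16 points at a
#' 1:1.75 dilution), with responses from the saturation binding equation
#' `Y = B_max * x / (K_d + x)` plus Gaussian noise.
#'
#' @param kd equilibrium dissociation constant (uM, > 0).
#' @param bmax maximal specific binding (response units).
#' @param top_conc highest ligand concentration (uM).
#' @param n_points number of titration points (>= 4).
#' @param dilution serial dilution ratio (> 1).
#' @param noise_sd Gaussian noise s.d. on the response (response units).
#' @param seed integer RNG seed.
#' @return A tibble with columns `concentration_uM` (descending) and
#'   `response`.
#' @examples
#' sim_binding_curve(kd = 0.3, bmax = 10, top_conc = 50, seed = 1)
#' @export
sim_binding_curve <- function(kd, bmax, top_conc, n_points = 16,
                              dilution = 1.75, noise_sd = 0, seed = 1) {
  if (kd <= 0) stop_input("`kd` must be > 0.")
  if (dilution <= 1) stop_input("`dilution` must be > 1.")
  if (n_points < 4) stop_input("`n_points` must be >= 4.")
  x <- top_conc * dilution^(-(seq_len(n_points) - 1))
  y <- bmax * x / (kd + x)
  if (noise_sd > 0)
    y <- y + withr::with_seed(seed, rnorm(n_points, 0, noise_sd))
  tibble::tibble(concentration_uM = x, response = y)
}
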