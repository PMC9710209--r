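# Shared fixtures and independent numerical oracles.

# a converged logistic_fit built directly from known parameters, for
# exercising the flux machinery without going through the optimizer
make_gl_fit <- function(a, kappa, c = 0.3) {
  structure(
    list(a = a, kappa = kappa, c = c, lambda = gl_lambda(a, kappa, c),
         rss = 0, r_squared = 1, t_half = gl_half_time(a, kappa, c),
         converged = TRUE, n_obs = 0L, message = NULL,
         data = tibble::tibble(time_min = numeric(), signal = numeric())),
    class = "logistic_fit")
}

# randomized (a, kappa) parameter draws spanning slow and fast reactions
draw_params <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    a = exp(runif(n, log(5), log(500))),
    kappa = exp(runif(n, log(0.005), log(0.1)))
  ))
}

# finite-difference oligomer flux using only the mass curve: P is formed by
# numerically differentiating M, and phi by numerically differentiating P
num_flux <- function(t, a, kappa, c, r_plus, h) {
  P_num <- function(tt) {
    Mdot <- (gl_mass(tt + h, a, kappa, c) - gl_mass(tt - h, a, kappa, c)) / (2 * h)
    Mdot / (r_plus * (1 - gl_mass(tt, a, kappa, c)))
  }
  (P_num(t + h) - P_num(t - h)) / (2 * h)
}

# recall/precision of detected spot centers against planted truth at a
# pixel matching radius
match_spots <- function(detected, truth, tol = 1) {
  if (nrow(detected) == 0)
    return(list(recall = 0, precision = NA_real_))
  hit <- logical(nrow(truth))
  used <- logical(nrow(detected))
  for (i in seq_len(nrow(truth))) {
    d2 <- (detected$row - truth[i, 1])^2 + (detected$col - truth[i, 2])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= tol^2) {
      hit[i] <- TRUE
      used[j] <- TRUE
    }
  }
  list(recall = mean(hit), precision = sum(hit) / nrow(detected))
}

rotate_xy <- function(df, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  xy <- as.matrix(df[, c("x_nm", "y_nm")]) %*% R
  df$x_nm <- xy[, 1]
  df$y_nm <- xy[, 2]
  df
}
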