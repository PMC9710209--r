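#' Simulate a single-molecule pull-down TIRF image stack
#'
#' Builds a multi-frame image stack of immobile diffraction-limited spots:
#' each frame is `background` plus, for every spot, a 2-D Gaussian of s.d.
#' `psf_sigma` pixels and the given photon-count `amplitude`, plus i.i.d.
#' Gaussian read noise. Spot positions are constant across frames (the
#' pull-down assay captures aggregates on the coverslip), so averaging the
#' `n_frames` frames raises the signal-to-noise ratio by `sqrt(n_frames)`.
#' The defaults mirror a typical acquisition: 50 frames of a 512 x 512
#' field of view.
#'
#' @param positions spot centers: a 2-column matrix or data frame of
#'   sub-pixel `(row, col)` coordinates (1-based; may be empty).
#' @param dim field-of-view size `c(rows, cols)`, each >= 64.
#' @param psf_sigma Gaussian PSF s.d. in pixels (> 0).
#' @param amplitude peak intensity added by each spot (counts).
#' @param background camera offset (counts).
#' @param read_noise_sd Gaussian read noise s.d. per pixel per frame (>= 0).
#' @param n_frames frames in the stack (>= 1).
#' @param seed integer RNG seed.
#' @param pixel_nm physical pixel pitch in nm (metadata; default 105.4).
#' @return A numeric array of dimension `c(rows, cols, n_frames)` with class
#'   `image_stack` and attribute `pixel_nm`.
#' @examples
#' pos <- cbind(row = c(20.5, 40), col = c(30, 50.2))
#' stk <- sim_tirf_stack(pos, dim = c(64, 64), n_frames = 5, seed = 1)
#' @export
sim_tirf_stack <- function(positions, dim = c(512, 512), psf_sigma = 1.5,
                           amplitude = 100, background = 100,
                           read_noise_sd = 10, n_frames = 50, seed = 1,
                           pixel_nm = PIXEL_NM_DEFAULT) {
  if (length(dim) != 2L || any(dim < 64))
    stop_input("`dim` must be c(rows, cols) with both >= 64.")
  if (psf_sigma <= 0) stop_input("`psf_sigma` must be > 0.")
  if (n_frames < 1) stop_input("`n_frames` must be >= 1.")
  positions <- as.matrix(positions)
  if (length(positions) && ncol(positions) != 2L)
    stop_input("`positions` must have two columns (row, col).")
  n_spots <- nrow(positions)
  if (n_spots > 0 &&
      (any(positions[, 1] < 1) || any(positions[, 1] > dim[1]) ||
       any(positions[, 2] < 1) || any(positions[, 2] > dim[2])))
    stop_input("all spot positions must lie within the frame bounds.")

  scene <- matrix(background, dim[1], dim[2])
  half <- ceiling(4 * psf_sigma) + 1L
  for (k in seq_len(n_spots)) {
    r0 <- positions[k, 1]; c0 <- positions[k, 2]
    rr <- max(1L, floor(r0) - half):min(dim[1], ceiling(r0) + half)
    cc <- max(1L, floor(c0) - half):min(dim[2], ceiling(c0) + half)
    g <- amplitude *
      exp(-(rr - r0)^2 / (2 * psf_sigma^2)) %o%
      exp(-(cc - c0)^2 / (2 * psf_sigma^2))
    scene[rr, cc] <- scene[rr, cc] + g
  }

  stack <- array(scene, dim = c(dim[1], dim[2], n_frames))
  if (read_noise_sd > 0) {
    noise <- withr::with_seed(
      seed, rnorm(prod(dim) * n_frames, 0, read_noise_sd))
    stack <- stack + array(noise, dim = dim(stack))
  }
  structure(stack, pixel_nm = pixel_nm, class = c("image_stack", "array"))
}

#' Simulate a super-resolution localization table
#'
#' Emulates the localization table produced by reconstructing a dSTORM
#' acquisition of a single aggregate. Ground-truth shapes are either a rod
#' (localizations uniform along a segment of length `length_nm`) or a disc
#' (uniform over a disc of diameter `diameter_nm`); each localization is then
#' jittered by isotropic Gaussian noise of s.d. `precision_nm`, the
#' localization precision.
#'
#' @param kind `"rod"` or `"disc"`.
#' @param length_nm rod end-to-end length in nm (rods).
#' @param diameter_nm disc diameter in nm (discs).
#' @param n_localizations number of localizations (>= 10).
#' @param precision_nm localization precision s.d. in nm (>= 0).
#' @param seed integer RNG seed.
#' @param center `c(x, y)` center of the aggregate in nm.
#' @param angle rod orientation in radians (rods only).
#' @param intensity photon count recorded per localization.
#' @return A tibble with columns `x_nm`, `y_nm`, `frame`, `intensity`.
#' @examples
#' sim_localizations("rod", length_nm = 200, n_localizations = 100, seed = 3)
#' @export
sim_localizations <- function(kind = c("rod", "disc"), length_nm = 200,
                              diameter_nm = 300, n_localizations = 1000,
                              precision_nm = 20, seed = 1,
                              center = c(0, 0), angle = 0,
                              intensity = 1000) {
  kind <- match.arg(kind)
  if (n_localizations < 10) stop_input("`n_localizations` must be >= 10.")
  if (precision_nm < 0) stop_input("`precision_nm` must be >= 0.")
  if (kind == "rod" && length_nm <= 0) stop_input("`length_nm` must be > 0.")
  if (kind == "disc" && diameter_nm <= 0) stop_input("`diameter_nm` must be > 0.")
  n <- n_localizations
  xy <- withr::with_seed(seed, {
    base <- if (kind == "rod") {
      s <- runif(n, -length_nm / 2, length_nm / 2)
      cbind(s * cos(angle), s * sin(angle))
    } else {
      r <- (diameter_nm / 2) * sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th))
    }
    if (precision_nm > 0)
      base <- base + cbind(rnorm(n, 0, precision_nm), rnorm(n, 0, precision_nm))
    base
  })
  tibble::tibble(
    x_nm = xy[, 1] + center[1],
    y_nm = xy[, 2] + center[2],
    frame = seq_len(n),
    intensity = intensity
  )
}
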