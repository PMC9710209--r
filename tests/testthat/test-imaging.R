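test_that("averaging identical frames returns a single frame", {
  stk <- sim_tirf_stack(cbind(20, 20), dim = c(64, 64), read_noise_sd = 0,
                        n_frames = 7)
  expect_equal(average_stack(stk), stk[, , 1], ignore_attr = TRUE)
  one <- sim_tirf_stack(cbind(20, 20), dim = c(64, 64), read_noise_sd = 0,
                        n_frames = 1)
  expect_equal(average_stack(one), one[, , 1], ignore_attr = TRUE)
})

test_that("frame averaging shrinks noise by sqrt(n_frames)", {
  stk <- sim_tirf_stack(matrix(numeric(0), 0, 2), dim = c(128, 128),
                        read_noise_sd = 10, n_frames = 50, seed = 2)
  resid <- average_stack(stk) - 100
  expect_lt(abs(sd(resid) / (10 / sqrt(50)) - 1), 0.2)
})

test_that("one spot on a clean background is found exactly once, in place", {
  stk <- sim_tirf_stack(cbind(31, 47), dim = c(64, 64), background = 0,
                        read_noise_sd = 0, n_frames = 1)
  sp <- detect_spots(average_stack(stk))
  expect_equal(nrow(sp), 1)
  expect_equal(c(sp$row, sp$col), c(31, 47))
  # physical coordinates use the 105.4 nm pixel pitch
  expect_equal(sp$x_nm, (47 - 0.5) * 105.4)
  expect_equal(sp$y_nm, (31 - 0.5) * 105.4)
})

test_that("an all-constant image yields zero spots without error", {
  img <- matrix(7, 64, 64)
  expect_equal(nrow(detect_spots(img)), 0)
})

test_that("detection recovers planted fields with high recall and precision", {
  truth <- withr::with_seed(51, cbind(runif(60, 5, 252), runif(60, 5, 252)))
  stk <- sim_tirf_stack(truth, dim = c(256, 256), amplitude = 100,
                        read_noise_sd = 10, n_frames = 50, seed = 52)
  sp <- detect_spots(average_stack(stk))
  m <- match_spots(sp, truth)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("detection is translation-equivariant", {
  base <- cbind(c(20.2, 40.7, 33.1), c(25.5, 50.1, 12.9))
  s1 <- detect_spots(average_stack(
    sim_tirf_stack(base, dim = c(128, 128), read_noise_sd = 0, n_frames = 1)))
  s2 <- detect_spots(average_stack(
    sim_tirf_stack(base + 11, dim = c(128, 128), read_noise_sd = 0,
                   n_frames = 1)))
  expect_equal(s2$row, s1$row + 11)
  expect_equal(s2$col, s1$col + 11)
})

test_that("spot counts grow monotonically with the number planted", {
  counts <- vapply(c(5, 20, 60), function(n) {
    truth <- withr::with_seed(n, cbind(runif(n, 5, 124), runif(n, 5, 124)))
    stk <- sim_tirf_stack(truth, dim = c(128, 128), read_noise_sd = 5,
                          n_frames = 10, seed = n + 1)
    nrow(detect_spots(average_stack(stk)))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("spots_summary reports group statistics and fold differences", {
  counts <- tibble::tibble(condition = rep("A", 3), count = c(10, 10, 10))
  out <- spots_summary(counts)
  expect_equal(out$mean, 10)
  expect_equal(out$sd, 0)
  two <- tibble::tibble(condition = rep(c("A", "B"), each = 2),
                        count = c(10, 10, 10, 10))
  expect_true(all(spots_summary(two, reference = "A")$fold == 1))
  expect_error(spots_summary(counts[0, ]), class = "oligoflux_degenerate_error")
})

test_that("single-linkage clustering separates and joins point clouds", {
  a <- sim_localizations("disc", diameter_nm = 100, precision_nm = 0,
                         n_localizations = 50, seed = 1, center = c(0, 0))
  b <- sim_localizations("disc", diameter_nm = 100, precision_nm = 0,
                         n_localizations = 50, seed = 2, center = c(1000, 0))
  cl <- cluster_localizations(dplyr::bind_rows(a, b), link_radius_nm = 100,
                              min_size = 10)
  expect_equal(length(unique(cl$cluster)), 2)
  # a chain of points each within the radius is one cluster
  chain <- tibble::tibble(x_nm = seq(0, 900, 30), y_nm = 0)
  cl2 <- cluster_localizations(chain, link_radius_nm = 50, min_size = 10)
  expect_equal(unique(cl2$cluster), 1L)
})

test_that("planted rods are clustered with correct memberships", {
  rods <- purrr::map_dfr(1:5, function(i) {
    sim_localizations("rod", length_nm = 200, precision_nm = 10,
                      n_localizations = 80, seed = i,
                      center = c(i * 2000, 0)) |>
      dplyr::mutate(truth = i)
  })
  cl <- cluster_localizations(rods, link_radius_nm = 50, min_size = 20)
  expect_equal(length(unique(cl$cluster)), 5)
  expect_true(all(table(cl$truth, cl$cluster) %in% c(0, 80)))
})

test_that("noiseless rods and discs give their textbook morphometrics", {
  rod <- sim_localizations("rod", length_nm = 400, precision_nm = 0,
                           n_localizations = 500, seed = 2)
  mr <- shape_metrics(rod)
  expect_gt(mr$eccentricity, 0.9)
  expect_lt(abs(mr$length_nm / 400 - 1), 0.05)
  expect_equal(mr$area_nm2, 0)       # collinear: degenerate hull
  expect_true(is.na(mr$circularity)) # flagged undefined
  md <- purrr::map_dfr(1:201, function(s) {
    shape_metrics(sim_localizations("disc", diameter_nm = 300,
                                    precision_nm = 0, n_localizations = 1000,
                                    seed = s))
  })
  expect_lt(median(md$eccentricity), 0.15)
  expect_gt(median(md$circularity), 0.85)
})

test_that("an isotropic Gaussian cloud reads as non-elongated", {
  eccs <- vapply(1:11, function(s) {
    xy <- withr::with_seed(s, tibble::tibble(x_nm = rnorm(1000, 0, 50),
                                             y_nm = rnorm(1000, 0, 50)))
    shape_metrics(xy)$eccentricity
  }, numeric(1))
  expect_lt(median(eccs), 0.2)
})

test_that("shape metrics are rotation invariant", {
  rod <- sim_localizations("rod", length_nm = 300, precision_nm = 20,
                           n_localizations = 400, seed = 9)
  m0 <- shape_metrics(rod)
  for (theta in c(0.3, 1.1, 2.4)) {
    m1 <- shape_metrics(rotate_xy(rod, theta))
    expect_lt(abs(m1$length_nm / m0$length_nm - 1), 0.02)
    expect_lt(abs(m1$area_nm2 / m0$area_nm2 - 1), 0.02)
    expect_lt(abs(m1$circularity / m0$circularity - 1), 0.02)
    expect_lt(abs(m1$eccentricity - m0$eccentricity), 0.02)
  }
})

test_that("clustered tables produce one metrics row per aggregate", {
  rods <- purrr::map_dfr(1:3, function(i) {
    sim_localizations("rod", length_nm = 200, precision_nm = 10,
                      n_localizations = 60, seed = i, center = c(i * 3000, 0))
  })
  cl <- cluster_localizations(rods, link_radius_nm = 50, min_size = 20)
  out <- shape_metrics(cl)
  expect_equal(nrow(out), 3)
  expect_true(all(out$n_localizations == 60))
})
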