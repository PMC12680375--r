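stripe_image <- function(angle, n = 120, period = 9) {
  xy <- expand.grid(r = 1:n, c = 1:n)
  nx <- cos((angle + 90) * pi / 180)
  ny <- sin((angle + 90) * pi / 180)
  u <- xy$c * nx + (-xy$r) * ny
  matrix(0.5 + 0.4 * sin(2 * pi * u / period), n, n)
}

test_that("percentile_clip rescales to [0, 1] and saturates the tails", {
  set.seed(1)
  img <- matrix(rnorm(1e4), 100, 100)
  cl <- percentile_clip(img)
  expect_equal(range(cl), c(0, 1))
  expect_gte(mean(cl == 0), 0.004)
  expect_gte(mean(cl == 1), 0.004)
  expect_warning(percentile_clip(matrix(1, 5, 5)), "constant")
})

test_that("gradient orientation distribution nails analytic stripes", {
  img <- stripe_image(30)
  d <- gradient_orientation_distribution(img, matrix(1L, 120, 120))
  f <- fit_von_mises(d)
  expect_lt(axial_diff(f$mu, 30), 1)
  expect_lt(f$mtsd, 2)
  expect_gt(f$rbar, 0.99)
})

test_that("orientation distribution is rotation-equivariant", {
  f20 <- fit_von_mises(gradient_orientation_distribution(
    stripe_image(20), matrix(1L, 120, 120)))
  f75 <- fit_von_mises(gradient_orientation_distribution(
    stripe_image(75), matrix(1L, 120, 120)))
  expect_lt(axial_diff(f75$mu - f20$mu, 55), 2)
  expect_lt(abs(f75$mtsd - f20$mtsd), 1)
})

test_that("von Mises fit matches the Bessel-ratio oracle on seeded samples", {
  set.seed(123)
  kappa <- 2
  th2 <- sample_von_mises(1e4, mu = 2 * 45 * pi / 180, kappa = kappa)
  ang <- wrap_axial(th2 * 90 / pi, "[0,180)") # halved doubled angles
  # feed as a binned distribution
  d <- structure(list(
    cells = 1L, edges = 0:180, mids = seq(0.5, 179.5, 1),
    weights = matrix(tabulate(pmin(floor(ang) + 1L, 180L), 180), 1),
    total = 1e4, n_interior = 1e4, excluded = FALSE),
    class = "orientation_distribution")
  f <- fit_von_mises(d)
  expect_lt(axial_diff(f$mu, 45), 3)
  analytic <- mtsd_from_kappa(kappa)
  expect_lt(abs(f$mtsd - analytic) / analytic, 0.1)
  expect_equal(f$kappa, kappa, tolerance = 0.15)
})

test_that("degenerate and uniform distributions follow the exclusion rules", {
  w1 <- matrix(0, 1, 180); w1[1, 31] <- 100 # all weight in one bin at 30.5
  d1 <- structure(list(cells = 1L, edges = 0:180, mids = seq(0.5, 179.5, 1),
                       weights = w1, total = 100, n_interior = 100,
                       excluded = FALSE),
                  class = "orientation_distribution")
  f1 <- fit_von_mises(d1)
  expect_equal(f1$mu, 30.5, tolerance = 1e-6)
  expect_lt(f1$mtsd, 0.1)
  expect_true(f1$valid)

  du <- d1; du$weights[1, ] <- 1 # exactly uniform
  fu <- fit_von_mises(du)
  expect_false(fu$fittable)
  expect_false(fu$valid)
})

test_that("MTSD decreases monotonically in generator concentration", {
  tis <- generate_tissue(tissue_spec(n_cols = 8, n_rows = 7,
                                     cell_diameter = 30, jitter = 0.1,
                                     seed = 12))
  med <- vapply(c(0.5, 1, 2, 4, 8), function(k) {
    rf <- render_filaments(tis, filament_spec(mu = 40, kappa = k,
                                              density = 0.004), seed = 21)
    d <- gradient_orientation_distribution(percentile_clip(rf$image),
                                           tis$labels)
    f <- fit_von_mises(d)
    median(f$mtsd[f$fittable], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med) < 0)) # 56 cells per concentration level
})

test_that("aligned average profiles are unit-sum and peak at zero shift", {
  tis <- generate_tissue(tissue_spec(n_cols = 6, n_rows = 6,
                                     cell_diameter = 30, anisotropy = 1.7,
                                     jitter = 0.05, seed = 13))
  rf <- render_filaments(tis, filament_spec(mu = 0, kappa = 4,
                                            density = 0.004), seed = 22)
  g <- parse_tissue(tis$labels)
  geo <- cell_geometry(g)
  d <- gradient_orientation_distribution(percentile_clip(rf$image), g)
  pr <- suppressWarnings(aligned_average_profile(
    d, geo, centres = median(geo$ecc, na.rm = TRUE), halfwidth = 0.2))
  expect_equal(length(pr), 1)
  p <- pr[[1]]
  expect_equal(sum(p$profile), 1, tolerance = 1e-8)
  expect_equal(which.max(p$profile), 1) # modal bin shifted to zero
  expect_gt(p$n_cells, 5)
})
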