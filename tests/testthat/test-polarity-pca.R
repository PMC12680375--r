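analytic_ring <- function(psi0, n = 360, base = 1, amp = 0.5, a = 1, b = 1,
                          phi = 0, cx = 50, cy = 50, radius = 20) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  # points on the cell ellipse, intensity modulated about axis psi0 (degrees)
  phir <- phi * pi / 180
  ex <- a * radius * cos(th)
  ey <- b * radius * sin(th)
  x <- cos(phir) * ex - sin(phir) * ey
  y <- sin(phir) * ex + cos(phir) * ey
  coords <- cbind(cy - y, cx + x) # (row, col)
  # intensity is a function of the shape-normalised angle (the ellipse
  # parameter), i.e. the same angular profile whatever the cell geometry
  I <- base + amp * cos(2 * (th - psi0 * pi / 180))
  list(coords = coords, I = I,
       gm = list(cx = cx, cy = cy, phi = phi, a = a * radius, b = b * radius,
                 phi_defined = phi != 0))
}

test_that("compute_cell_polarity recovers an analytic angular profile", {
  for (psi0 in c(0, 25, 60, -40)) {
    ring <- analytic_ring(psi0)
    p <- compute_cell_polarity(ring$coords, ring$I, ring$gm)
    expect_true(p$valid)
    expect_lt(axial_diff(p$psi, psi0), 0.5)
    expect_gt(p$magnitude, 0.05)
  }
})

test_that("uniform intensity gives zero magnitude and undefined angle", {
  ring <- analytic_ring(0, amp = 0)
  p <- compute_cell_polarity(ring$coords, ring$I, ring$gm)
  expect_true(p$valid)
  expect_equal(p$magnitude, 0)
  expect_true(is.na(p$psi))
})

test_that("shape normalisation removes elliptical cell geometry", {
  # same angular profile painted on a circle and on a 2:1 ellipse
  pc <- compute_cell_polarity(analytic_ring(30)$coords, analytic_ring(30)$I,
                              analytic_ring(30)$gm)
  re <- analytic_ring(30, a = 2, b = 1, phi = 0)
  pe <- compute_cell_polarity(re$coords, re$I, re$gm)
  expect_lt(abs(pc$magnitude - pe$magnitude) / pc$magnitude, 0.02)
  expect_lt(axial_diff(pc$psi, pe$psi), 1)
})

test_that("polarity magnitude increases with asymmetry amplitude", {
  mags <- vapply(c(0.1, 0.25, 0.5), function(a) {
    ring <- analytic_ring(10, amp = a)
    compute_cell_polarity(ring$coords, ring$I, ring$gm)$magnitude
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("degenerate inputs are rejected cleanly", {
  ring <- analytic_ring(0)
  few <- compute_cell_polarity(ring$coords[1:4, ], ring$I[1:4], ring$gm)
  expect_false(few$valid)
  neg <- compute_cell_polarity(ring$coords, ring$I - 10, ring$gm)
  expect_false(neg$valid)
})

test_that("estimate_background recovers the additive background level", {
  tis <- generate_tissue(tissue_spec(n_cols = 6, n_rows = 6,
                                     cell_diameter = 24, seed = 8))
  fld <- polarity_field(mode = "uniform", psi0 = 0, amplitude = 100,
                        baseline = 100, background = 30, noise_sd = 0)
  ren <- render_channels(tis, fld)
  bg <- estimate_background(ren$graph, ren$channels$sfGFP)
  expect_equal(bg, 30, tolerance = 0.5)
})

test_that("aggregate_wing averages doubled-angle polarity vectors", {
  pol <- data.frame(psi = c(30, 30, 30), magnitude = c(0.2, 0.4, 0.6),
                    valid = TRUE)
  w <- aggregate_wing(pol)
  expect_equal(w$angle, 30, tolerance = 1e-8)
  expect_equal(w$magnitude, 0.4, tolerance = 1e-8)
  expect_equal(w$n, 3)
  # orthogonal axes of equal magnitude cancel
  pol2 <- data.frame(psi = c(0, 90), magnitude = c(0.5, 0.5), valid = TRUE)
  w2 <- aggregate_wing(pol2)
  expect_lt(w2$magnitude, 1e-12)
  expect_true(is.na(w2$angle))
})

test_that("stable_fraction divides background-subtracted band means", {
  tis <- generate_tissue(tissue_spec(n_cols = 6, n_rows = 6,
                                     cell_diameter = 24, seed = 9))
  fld <- polarity_field(mode = "uniform", psi0 = 10, amplitude = 50,
                        baseline = 100, stable_fraction = 0.4,
                        background = 20, noise_sd = 0)
  ren <- render_channels(tis, fld)
  sf <- stable_fraction(ren$graph, ren$channels$mKate2, ren$channels$sfGFP,
                        background = c(20, 20))
  expect_true(all(sf$valid))
  expect_equal(mean(sf$ratio), 0.4, tolerance = 0.01)
})
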