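test_that("generate_tissue produces a labelled mesh with a membrane skeleton", {
  tis <- generate_tissue(tissue_spec(n_cols = 5, n_rows = 5,
                                     cell_diameter = 18, seed = 3))
  lab <- tis$labels
  expect_true(all(lab >= 0))
  expect_setequal(sort(unique(lab[lab > 0])), tis$geometry$cell)
  expect_equal(nrow(tis$geometry), 25)
  # every cell is separated from different-labelled cells by membrane
  H <- nrow(lab); W <- ncol(lab)
  horiz <- lab[, -W] > 0 & lab[, -1] > 0 & lab[, -W] != lab[, -1]
  vert <- lab[-H, ] > 0 & lab[-1, ] > 0 & lab[-H, ] != lab[-1, ]
  expect_false(any(horiz))
  expect_false(any(vert))
})

test_that("generate_tissue is reproducible from its seed", {
  sp <- tissue_spec(n_cols = 4, n_rows = 4, cell_diameter = 16,
                    jitter = 0.3, seed = 77)
  expect_identical(generate_tissue(sp)$labels, generate_tissue(sp)$labels)
})

test_that("anisotropic meshes reach the requested cell eccentricity", {
  s <- 2
  tis <- generate_tissue(tissue_spec(n_cols = 6, n_rows = 6,
                                     cell_diameter = 24, anisotropy = s,
                                     jitter = 0.05, seed = 5))
  g <- parse_tissue(tis$labels)
  geo <- cell_geometry(g)
  interior <- !(tis$geometry$cell %in%
                  unique(c(tis$labels[1, ], tis$labels[nrow(tis$labels), ],
                           tis$labels[, 1], tis$labels[, ncol(tis$labels)])))
  ecc <- geo$ecc[geo$valid & interior]
  expect_equal(median(ecc, na.rm = TRUE), sqrt(1 - 1 / s^2), tolerance = 0.1)
})

test_that("render_channels paints the analytic sin^2 intensity law", {
  tis <- generate_tissue(tissue_spec(n_cols = 5, n_rows = 5,
                                     cell_diameter = 24, jitter = 0.1,
                                     seed = 2))
  fld <- polarity_field(mode = "uniform", psi0 = 25, amplitude = 80,
                        baseline = 100, background = 0, noise_sd = 0)
  ren <- render_channels(tis, fld)
  jt <- ren$junction_truth
  expect_true(all(abs(jt$intensity -
                        (100 + 80 * sin((jt$orientation - jt$psi_bar) *
                                          pi / 180)^2)) < 1e-8))
  # noiseless sfGFP carries exactly the painted band plus background
  expect_true(all(ren$channels$sfGFP >= 0))
  # mKate2 = stable fraction * junctional signal
  f <- fld$stable_fraction
  expect_equal(ren$channels$mKate2, f * (ren$channels$sfGFP), tolerance = 1e-8)
})

test_that("sample_von_mises is uniform at kappa 0 and concentrated at high kappa", {
  set.seed(10)
  u <- sample_von_mises(4000, mu = 1, kappa = 0)
  expect_gt(suppressWarnings(ks.test(u / (2 * pi), "punif"))$p.value, 0.001)
  set.seed(11)
  v <- sample_von_mises(4000, mu = 1, kappa = 50)
  expect_lt(sd(sin(v - 1)), 0.2)
  expect_equal(atan2(mean(sin(v)), mean(cos(v))), 1, tolerance = 0.02)
})

test_that("boundary fields repolarise graded rows in the ground truth", {
  tis <- generate_tissue(tissue_spec(n_cols = 8, n_rows = 10,
                                     cell_diameter = 20, jitter = 0.1,
                                     seed = 4))
  src <- boundary_source_cells(tis, 2)
  g <- parse_tissue(tis$labels)
  rows <- assign_rows(g, src, max_row = 4)
  fld <- polarity_field(mode = "boundary", psi0 = 20, propagation_rows = 1,
                        boundary_axis = 0)
  ren <- render_channels(tis, fld, rows = rows)
  psi <- ren$cell_truth$psi_true
  m <- match(ren$cell_truth$cell, rows$cell)
  expect_true(all(axial_diff(psi[rows$source[m]], 90) < 1e-8))
  expect_true(all(axial_diff(psi[!is.na(rows$row[m]) & rows$row[m] == 0], 90)
                  < 1e-8))
  expect_true(all(axial_diff(psi[!is.na(rows$row[m]) & rows$row[m] == 1], 55)
                  < 1e-8))
  expect_true(all(axial_diff(psi[!is.na(rows$row[m]) & rows$row[m] >= 2], 20)
                  < 1e-8))
})

test_that("render_filaments honours its seed and clips to cells", {
  tis <- generate_tissue(tissue_spec(n_cols = 4, n_rows = 4,
                                     cell_diameter = 24, seed = 6))
  fs <- filament_spec(mu = 10, kappa = 3, density = 0.01, background = 5)
  r1 <- render_filaments(tis, fs, seed = 99)
  r2 <- render_filaments(tis, fs, seed = 99)
  expect_identical(r1$image, r2$image)
  # membrane and exterior pixels carry only background (no filament signal
  # beyond blur bleed): interior mean must dominate
  expect_gt(mean(r1$image[tis$labels > 0]), mean(r1$image[tis$labels == 0]))
  expect_true(all(table(r1$filaments$cell) >= 3))
})
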