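make_two_cell_mask <- function() {
  # two cells separated by a 2-pixel vertical membrane strip
  lab <- matrix(0L, 24, 25)
  lab[2:23, 2:11] <- 1L
  lab[2:23, 14:24] <- 2L
  lab
}

test_that("parse_tissue recovers adjacency and a vertical junction", {
  g <- parse_tissue(make_two_cell_mask())
  expect_s3_class(g, "tissue_graph")
  expect_equal(g$cells, c(1L, 2L))
  expect_equal(nrow(g$adjacency), 1)
  expect_equal(sort(unlist(g$adjacency[1, c("a", "b")], use.names = FALSE)),
               c(1L, 2L))
  expect_equal(nrow(g$junctions), 1)
  expect_equal(g$junctions$orientation[1], 90, tolerance = 1e-6)
})

test_that("parse_tissue validates its input", {
  expect_error(parse_tissue(matrix(1.5, 5, 5)), "integer")
  m <- make_two_cell_mask()
  m[1, 1] <- NA
  expect_error(parse_tissue(m), "integer|NA")
  expect_error(parse_tissue(make_two_cell_mask(), band_width = 2),
               "band_width")
})

test_that("cell bands dilate the cell's membrane perimeter", {
  g <- parse_tissue(make_two_cell_mask())
  lab <- g$labels
  H <- nrow(lab)
  rb <- (g$band_width - 1) / 2
  mem <- which(lab == 0L)
  for (i in seq_along(g$cells)) {
    px <- g$cell_bands[[i]]
    expect_gt(length(px), 0)
    # every band pixel is within the dilation radius of a membrane pixel
    r <- ((px - 1L) %% H) + 1L
    cc <- ((px - 1L) %/% H) + 1L
    mr <- ((mem - 1L) %% H) + 1L
    mc <- ((mem - 1L) %/% H) + 1L
    mind <- vapply(seq_along(px), function(k)
      min(pmax(abs(mr - r[k]), abs(mc - cc[k]))), numeric(1))
    expect_true(all(mind <= rb))
  }
  # the shared junction's membrane pixels belong to both cells' bands
  jp <- g$junction_pixels[[1]]
  expect_true(all(jp %in% g$cell_bands[[1]]))
  expect_true(all(jp %in% g$cell_bands[[2]]))
})

test_that("fit_cell_ellipse recovers an analytic ellipse", {
  H <- 80; W <- 80
  xy <- expand.grid(r = 1:H, c = 1:W)
  phi <- 30 * pi / 180
  x <- xy$c - 40.5
  y <- -(xy$r - 40.5)
  xr <- cos(-phi) * x - sin(-phi) * y
  yr <- sin(-phi) * x + cos(-phi) * y
  inside <- (xr / 24)^2 + (yr / 12)^2 <= 1
  f <- fit_cell_ellipse(cbind(xy$r[inside], xy$c[inside]))
  expect_equal(f$cx, 40.5, tolerance = 0.1)
  expect_equal(f$cy, 40.5, tolerance = 0.1)
  expect_equal(f$phi, 30, tolerance = 1)
  expect_equal(f$a / f$b, 2, tolerance = 0.05)
  # eccentricity of a 2:1 ellipse
  expect_equal(f$ecc, sqrt(1 - 0.25), tolerance = 0.01)
})

test_that("cell_geometry flags degenerate cells instead of fitting them", {
  lab <- matrix(0L, 10, 10)
  lab[2:9, 2:4] <- 1L
  lab[5, 7] <- 2L # single-pixel cell
  g <- parse_tissue(lab)
  geo <- cell_geometry(g)
  expect_true(geo$valid[geo$cell == 1])
  expect_false(geo$valid[geo$cell == 2])
})

test_that("junction orientation follows a rotated straight edge", {
  # two cells split by a 45-degree diagonal membrane
  n <- 40
  lab <- matrix(0L, n, n)
  for (r in 1:n) for (cc in 1:n) {
    d <- (cc - 0.5) - (n - r + 0.5) # distance off the r + c = n diagonal
    if (d <= -1.5) lab[r, cc] <- 1L
    if (d >= 1.5) lab[r, cc] <- 2L
  }
  g <- parse_tissue(lab)
  j <- junction_orientation(g)
  expect_equal(nrow(j), 1)
  expect_lt(axial_diff(j$orientation[1], 45), 3)
})
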