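# Shared scenario builders for the test suite.

# Internal helpers re-exposed for tests.
axial_mean <- function(a, w = NULL) pcpquant:::axial_mean_resultant(a, w)$mean

# A tissue rendered with a uniform polarity field, parsed and measured:
# returns the per-cell polarity table plus ground truth.
measure_uniform_polarity <- function(n_cols, n_rows, cell_diameter, psi0,
                                     amplitude, baseline, noise_sd,
                                     jitter = 0.15, anisotropy = 1, seed = 1,
                                     background = 0) {
  tis <- generate_tissue(tissue_spec(
    n_cols = n_cols, n_rows = n_rows, cell_diameter = cell_diameter,
    anisotropy = anisotropy, jitter = jitter, seed = seed))
  fld <- polarity_field(mode = "uniform", psi0 = psi0, amplitude = amplitude,
                        baseline = baseline, background = background,
                        noise_sd = noise_sd)
  ren <- render_channels(tis, fld)
  pol <- cell_polarity(ren$graph, ren$channels$sfGFP, background = background)
  list(tissue = tis, rendered = ren, polarity = pol)
}

# Independent breadth-first row oracle over the adjacency table using igraph.
igraph_row_oracle <- function(graph, source, max_row = 3) {
  g <- igraph::graph_from_data_frame(
    graph$adjacency[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = graph$cells))
  dmat <- igraph::distances(g, v = as.character(graph$cells),
                            to = as.character(source))
  d <- apply(dmat, 1, min)
  row <- as.integer(d) - 1L
  row[graph$cells %in% source] <- NA_integer_
  row[row > max_row] <- NA_integer_
  data.frame(cell = graph$cells, row = row,
             source = graph$cells %in% source)
}

# Brute-force maximum-variance axis oracle for the PCA polarity method:
# replicates the shape normalisation, then scans projection variance about
# the origin in 0.1-degree steps.
scan_polarity_oracle <- function(px, I, gm, H, step = 0.1) {
  r <- ((px - 1L) %% H) + 1L
  cc <- ((px - 1L) %/% H) + 1L
  x <- cc - gm$cx
  y <- -(r - gm$cy)
  use_phi <- isTRUE(gm$phi_defined) && is.finite(gm$phi)
  phi <- if (use_phi) gm$phi * pi / 180 else 0
  xr <- cos(-phi) * x - sin(-phi) * y
  yr <- sin(-phi) * x + cos(-phi) * y
  a <- gm$a; b <- gm$b
  if (!is.finite(a) || a <= 0) a <- 1
  if (!is.finite(b) || b <= 0) b <- a
  th <- atan2(yr / b, xr / a)
  Ih <- I / mean(I)
  qx <- Ih * cos(th)
  qy <- Ih * sin(th)
  ang <- seq(0, 180 - step, by = step)
  v <- vapply(ang, function(aa) {
    u <- aa * pi / 180
    mean((qx * cos(u) + qy * sin(u))^2)
  }, numeric(1))
  best <- ang[which.max(v)]
  wrap_axial(best + if (use_phi) gm$phi else 0)
}

# Cells whose label touches the image border (their bands are clipped).
border_cells <- function(lab) {
  b <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  b[b > 0]
}
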