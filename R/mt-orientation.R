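# Texture (microtubule) orientation: percentile contrast normalisation,
# 5x5 Sobel gradient orientation distributions per cell, weighted von Mises
# fits with the microtubule standard deviation (MTSD), and aligned average
# profiles by eccentricity bin.

#' Percentile contrast clipping
#'
#' Sets values below the lower percentile to black and above the upper
#' percentile to white, rescaling linearly in between — normalises signal
#' variability between images and increases contrast.
#'
#' @param image numeric matrix.
#' @param lower,upper clipping quantiles (defaults 0.005 and 0.995, i.e. the
#'   0.5% lowest and highest pixels saturate).
#' @return matrix rescaled to `[0, 1]`; a constant image is returned
#'   unchanged with a warning.
#' @export
percentile_clip <- function(image, lower = 0.005, upper = 0.995) {
  q <- stats::quantile(image, c(lower, upper), names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant image: percentile clipping skipped")
    return(image)
  }
  (pmin(pmax(image, q[1]), q[2]) - q[1]) / (q[2] - q[1])
}

# The two 5x5 Sobel operators (separable smoothing x derivative form).
sobel5_kernels <- function() {
  sm <- c(1, 4, 6, 4, 1)
  dv <- c(-1, -2, 0, 2, 1)
  list(kx = outer(sm, dv), ky = outer(dv, sm))
}

# 5x5 correlation with replicate border padding.
filter5 <- function(img, K) {
  H <- nrow(img); W <- ncol(img)
  ri <- pmin(pmax(seq_len(H + 4) - 2L, 1L), H)
  ci <- pmin(pmax(seq_len(W + 4) - 2L, 1L), W)
  P <- img[ri, ci]
  out <- matrix(0, H, W)
  for (u in 1:5) for (v in 1:5) {
    if (K[u, v] == 0) next
    out <- out + K[u, v] * P[(u - 1) + seq_len(H), (v - 1) + seq_len(W)]
  }
  out
}

# Pixels of each cell whose full Chebyshev-radius-`depth` neighbourhood has
# the same label (depth-pixel erosion), as a logical matrix.
eroded_interior <- function(lab, depth = 1) {
  H <- nrow(lab); W <- ncol(lab)
  d <- as.integer(depth)
  P <- matrix(-1L, H + 2L * d, W + 2L * d)
  P[d + seq_len(H), d + seq_len(W)] <- lab
  ok <- lab > 0L
  for (dr in -d:d) for (dc in -d:d) {
    if (dr == 0 && dc == 0) next
    ok <- ok & (P[(d + 1 + dr):(H + d + dr), (d + 1 + dc):(W + d + dc)] == lab)
  }
  ok
}

#' Per-cell gradient orientation distributions
#'
#' Convolves the tubulin channel with the two 5x5 Sobel operators, takes per
#' interior pixel the texture orientation (gradient direction + 90 degrees,
#' wrapped to `[0, 180)`) weighted by the gradient magnitude, and accumulates
#' a binned distribution per cell. Cells are eroded by `erode` pixels before
#' accumulation: the 5x5 Sobel operators reach two pixels past each sample
#' and the channel is typically anti-alias smoothed, so gradients measured
#' within about three pixels of the membrane mix membrane-edge structure into
#' the texture orientations. Cells smaller than `min_pixels` after erosion
#' are excluded.
#'
#' @param image tubulin intensity matrix (typically after
#'   [percentile_clip()]).
#' @param graph a [parse_tissue()] result (or an integer label matrix).
#' @param bin_width bin width in degrees; must divide 180 (default 1).
#' @param erode erosion depth in pixels (default 3, the orientation filter's
#'   effective reach).
#' @param min_pixels minimum interior pixels per cell (default 25).
#' @return object of class `orientation_distribution`: list with `cells`,
#'   `edges`, `mids`, `weights` (cells x bins matrix of summed gradient
#'   magnitudes), `total` and `excluded` (too-small cells, flagged).
#' @export
gradient_orientation_distribution <- function(image, graph, bin_width = 1,
                                              erode = 3, min_pixels = 25) {
  lab <- if (inherits(graph, "tissue_graph")) graph$labels else {
    if (!is.matrix(graph)) stop("graph must be a tissue_graph or label matrix")
    matrix(as.integer(graph), nrow(graph), ncol(graph))
  }
  stopifnot(all(dim(image) == dim(lab)))
  if (180 %% bin_width != 0) stop("bin_width must divide 180")
  ker <- sobel5_kernels()
  gx <- filter5(image, ker$kx)
  gy <- filter5(image, ker$ky) # along increasing row (image downward)
  mag <- sqrt(gx^2 + gy^2)
  ang <- (rad2deg(atan2(-gy, gx)) + 90) %% 180

  interior <- eroded_interior(lab, depth = erode)
  cells <- sort(unique(lab[lab > 0L]))
  nb <- as.integer(180 / bin_width)
  idx <- which(interior)
  cid <- match(lab[idx], cells)
  bin <- pmin(floor(ang[idx] / bin_width) + 1L, nb)
  Wm <- matrix(0, nb, length(cells)) # column-major accumulation per cell
  acc <- rowsum(mag[idx], (cid - 1L) * nb + bin)
  Wm[as.integer(rownames(acc))] <- acc[, 1]
  Wt <- t(Wm)
  npx <- tabulate(cid, nbins = length(cells))
  structure(list(
    cells = cells,
    edges = seq(0, 180, by = bin_width),
    mids = seq(bin_width / 2, 180 - bin_width / 2, by = bin_width),
    weights = Wt, total = rowSums(Wt), n_interior = npx,
    excluded = npx < min_pixels
  ), class = "orientation_distribution")
}

# Inverse of A1(kappa) = I1(kappa) / I0(kappa).
a1inv <- function(r) {
  if (!is.finite(r) || r <= 0) return(0)
  if (r >= 0.9999) return(1 / (2 * (1 - r)))
  stats::uniroot(function(k) besselI(k, 1, expon.scaled = TRUE) /
                   besselI(k, 0, expon.scaled = TRUE) - r,
                 c(1e-9, 1e5), tol = 1e-10)$root
}

#' Analytic MTSD for a given von Mises concentration
#'
#' Circular standard deviation on the axial scale implied by concentration
#' `kappa` on doubled angles: `(180/pi) * sqrt(-2 log A1(kappa)) / 2` with
#' `A1 = I1/I0` (Bessel ratio).
#'
#' @param kappa concentration on doubled angles.
#' @return MTSD in degrees.
#' @export
mtsd_from_kappa <- function(kappa) {
  r <- besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
  if (r <= 0) return(Inf)
  rad2deg(sqrt(-2 * log(r))) / 2
}

#' Weighted von Mises fit of orientation distributions
#'
#' Doubles the angles onto the circle and fits the von Mises by weighted
#' maximum likelihood: the mean direction is the weighted resultant
#' direction, the concentration solves `A1(kappa) = rbar`. MTSD is the
#' circular standard deviation `(180/pi) * sqrt(-2 log rbar) / 2` degrees.
#' Distributions with `rbar` below `tol` carry too little orientation
#' information to identify a mean direction and are flagged unfittable;
#' a cell is `valid` only when fittable and `MTSD < 90`.
#'
#' @param dist an [gradient_orientation_distribution()] result.
#' @param tol unfittable threshold on the mean resultant length of doubled
#'   angles (default 0.15, i.e. fitted concentration below about 0.3).
#' @return data frame: `cell`, `mu` (degrees, axial), `kappa`, `mtsd`,
#'   `rbar`, `total_weight`, `fittable`, `valid`.
#' @export
fit_von_mises <- function(dist, tol = 0.15) {
  stopifnot(inherits(dist, "orientation_distribution"))
  out <- lapply(seq_along(dist$cells), function(i) {
    w <- dist$weights[i, ]
    base <- data.frame(cell = dist$cells[i], mu = NA_real_, kappa = NA_real_,
                       mtsd = NA_real_, rbar = NA_real_,
                       total_weight = sum(w), fittable = FALSE, valid = FALSE)
    if (dist$excluded[i] || sum(w) <= 0) return(base)
    m <- axial_mean_resultant(dist$mids, w)
    base$rbar <- m$rbar
    if (!is.finite(m$rbar) || m$rbar < tol) return(base)
    base$fittable <- TRUE
    base$mu <- m$mean
    base$kappa <- a1inv(m$rbar)
    base$mtsd <- rad2deg(sqrt(-2 * log(m$rbar))) / 2
    base$valid <- base$mtsd < 90
    base
  })
  do.call(rbind, out)
}

#' Aligned average orientation profiles by eccentricity bin
#'
#' Circularly shifts each cell's binned orientation distribution so its modal
#' bin sits at 0 degrees, normalises it to unit sum, and averages the shifted
#' profiles over cells within each eccentricity bin.
#'
#' @param dist an [gradient_orientation_distribution()] result.
#' @param geometry a [cell_geometry()] table (column `ecc`).
#' @param centres eccentricity bin centres (default `c(0.750, 0.800)`).
#' @param halfwidth half-width of each bin (default 0.025).
#' @return named list, one element per non-empty bin: list with `profile`
#'   (length = number of orientation bins, summing to 1), `mids`, `n_cells`.
#'   Empty bins are omitted with a warning.
#' @export
aligned_average_profile <- function(dist, geometry,
                                    centres = c(0.750, 0.800),
                                    halfwidth = 0.025) {
  stopifnot(inherits(dist, "orientation_distribution"))
  ecc <- geometry$ecc[match(dist$cells, geometry$cell)]
  usable <- !dist$excluded & dist$total > 0
  shift_to_zero <- function(w) {
    k <- which.max(w)
    w <- w / sum(w)
    if (k > 1) c(w[k:length(w)], w[seq_len(k - 1)]) else w
  }
  out <- list()
  for (ct in centres) {
    sel <- which(usable & is.finite(ecc) & abs(ecc - ct) <= halfwidth)
    if (length(sel) == 0) {
      warning(sprintf("no cells in eccentricity bin %.3f +/- %.3f; omitted",
                      ct, halfwidth))
      next
    }
    profs <- t(vapply(sel, function(i) shift_to_zero(dist$weights[i, ]),
                      numeric(ncol(dist$weights))))
    out[[sprintf("%.3f", ct)]] <- list(profile = colMeans(profs),
                                       mids = dist$mids,
                                       n_cells = length(sel))
  }
  out
}
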