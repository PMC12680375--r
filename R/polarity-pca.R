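# Per-cell axial polarity by the PCA method: membrane pixel positions are
# shape-normalised (best-fit ellipse to unit circle), intensities normalised
# by their mean, and the pseudo-points I_hat * (cos th, sin th) summarised by
# their second-moment matrix about the origin. The principal axis is the
# polarity angle; the eigenvalue asymmetry (l1 - l2) / (l1 + l2) is the
# polarity magnitude.

#' Compute PCA polarity of one cell
#'
#' @param coords two-column matrix of membrane pixel `(row, col)` coordinates,
#'   or a vector of linear indices with `H` supplied.
#' @param intensities membrane intensities (finite, non-negative), same length.
#' @param geometry cell geometry: list or one-row data frame with `cx`, `cy`,
#'   `phi`, `a`, `b`, `phi_defined` (as returned by [fit_cell_ellipse()] or a
#'   row of [cell_geometry()]).
#' @param H number of image rows (when `coords` is a linear index vector).
#' @param min_pixels minimum number of membrane pixels (default 8).
#' @param uniform_tol coefficient of variation of normalised intensities below
#'   which the distribution is treated as uniform: magnitude 0, angle
#'   undefined.
#' @return list with `psi` (polarity angle, degrees in `(-90, 90]`, image
#'   frame; `NA` when undefined), `magnitude` in `[0, 1]`, eigenvalues `l1`,
#'   `l2`, `valid`, and `n`.
#' @export
compute_cell_polarity <- function(coords, intensities, geometry, H = NULL,
                                  min_pixels = 8, uniform_tol = 1e-3) {
  if (is.null(dim(coords))) {
    stopifnot(!is.null(H))
    coords <- cbind(((coords - 1L) %% H) + 1L, ((coords - 1L) %/% H) + 1L)
  }
  n <- nrow(coords)
  bad <- list(psi = NA_real_, magnitude = NA_real_, l1 = NA_real_,
              l2 = NA_real_, valid = FALSE, n = n)
  if (n < min_pixels) return(bad)
  I <- as.numeric(intensities)
  if (length(I) != n || any(!is.finite(I)) || any(I < 0)) return(bad)
  mI <- mean(I)
  if (mI <= 0) return(bad)

  x <- coords[, 2] - geometry$cx
  y <- -(coords[, 1] - geometry$cy)
  use_phi <- isTRUE(geometry$phi_defined) && is.finite(geometry$phi)
  phi <- if (use_phi) deg2rad(geometry$phi) else 0
  xr <- cos(-phi) * x - sin(-phi) * y
  yr <- sin(-phi) * x + cos(-phi) * y
  a <- geometry$a; b <- geometry$b
  if (!is.finite(a) || a <= 0) a <- 1
  if (!is.finite(b) || b <= 0) b <- a
  th <- atan2(yr / b, xr / a)

  Ih <- I / mI
  if (sd(Ih) < uniform_tol)
    return(list(psi = NA_real_, magnitude = 0, l1 = NA_real_, l2 = NA_real_,
                valid = TRUE, n = n))
  q <- cbind(Ih * cos(th), Ih * sin(th))
  C <- crossprod(q) / n # second moments about the origin
  e <- eigen(C, symmetric = TRUE)
  l1 <- e$values[1]; l2 <- max(e$values[2], 0)
  M <- if (l1 + l2 > 0) (l1 - l2) / (l1 + l2) else 0
  psi_norm <- rad2deg(atan2(e$vectors[2, 1], e$vectors[1, 1]))
  psi <- wrap_axial(psi_norm + if (use_phi) geometry$phi else 0)
  list(psi = psi, magnitude = M, l1 = l1, l2 = l2, valid = TRUE, n = n)
}

#' Per-cell PCA polarity over a tissue graph
#'
#' Applies [compute_cell_polarity()] to every cell's membrane band using a
#' single intensity channel, after background subtraction.
#'
#' @param graph a [parse_tissue()] result.
#' @param channel intensity matrix co-registered with the label mask.
#' @param geometry optional [cell_geometry()] table (computed if `NULL`).
#' @param background scalar background to subtract, or `"estimate"` to use
#'   [estimate_background()].
#' @return data frame: `cell`, `psi`, `magnitude`, `l1`, `l2`, `n_band`,
#'   `valid`.
#' @export
cell_polarity <- function(graph, channel, geometry = NULL, background = 0) {
  stopifnot(inherits(graph, "tissue_graph"),
            all(dim(channel) == graph$dim))
  if (is.null(geometry)) geometry <- cell_geometry(graph)
  if (identical(background, "estimate"))
    background <- estimate_background(graph, channel)
  H <- graph$dim[1]
  out <- lapply(seq_along(graph$cells), function(i) {
    cid <- graph$cells[i]
    px <- graph$cell_bands[[i]]
    gm <- geometry[geometry$cell == cid, ]
    if (length(px) < 8 || nrow(gm) != 1 || !isTRUE(gm$valid))
      return(data.frame(cell = cid, psi = NA, magnitude = NA, l1 = NA,
                        l2 = NA, n_band = length(px), valid = FALSE))
    I <- pmax(channel[px] - background, 0)
    p <- compute_cell_polarity(px, I, gm, H = H)
    data.frame(cell = cid, psi = p$psi, magnitude = p$magnitude,
               l1 = p$l1, l2 = p$l2, n_band = p$n, valid = p$valid)
  })
  do.call(rbind, out)
}

#' Estimate the per-image autofluorescent background
#'
#' Mean intensity over cell-interior pixels, i.e. cell pixels outside the
#' dilated membrane zone where junctional signal can live.
#'
#' @param graph a [parse_tissue()] result.
#' @param channel intensity matrix.
#' @return scalar background estimate.
#' @export
estimate_background <- function(graph, channel) {
  lab <- graph$labels
  zone <- grey_dilate((lab == 0L) * 1, graph$band_width) > 0
  interior <- lab > 0L & !zone
  if (!any(interior)) stop("no interior pixels available to estimate background")
  mean(channel[interior])
}

#' Normalise axial angles to a reference axis
#'
#' @param angles axial angles in degrees.
#' @param reference reference axis in degrees (e.g. the mean cell orientation
#'   of the image, or the boundary axis).
#' @return angles `(angle - reference)` wrapped to `(-90, 90]`.
#' @export
#' @examples
#' normalize_angles(-85, 10) # wraps across the axial boundary to 85
normalize_angles <- function(angles, reference) {
  if (length(reference) != 1 || !is.finite(reference))
    stop("reference axis must be a single finite angle")
  wrap_axial(angles - reference)
}

#' Aggregate per-cell polarity into a per-wing vector
#'
#' Each cell contributes the doubled-angle vector
#' `(M cos 2 psi, M sin 2 psi)`; the wing aggregate is the component-wise
#' mean, reported as magnitude (vector norm) and axial angle (half the
#' vector argument).
#'
#' @param polarity data frame from [cell_polarity()] (columns `psi`,
#'   `magnitude`, `valid`).
#' @return list with `magnitude`, `angle` (degrees in `(-90, 90]`, `NA` if
#'   the resultant is zero), `vector` (length 2) and `n` (cells used).
#' @export
aggregate_wing <- function(polarity) {
  ok <- polarity$valid & is.finite(polarity$psi) & is.finite(polarity$magnitude)
  if (!any(ok)) stop("no valid cells to aggregate")
  m <- polarity$magnitude[ok]
  p2 <- deg2rad(2 * polarity$psi[ok])
  v <- c(mean(m * cos(p2)), mean(m * sin(p2)))
  mag <- sqrt(sum(v^2))
  ang <- if (mag < 1e-12) NA_real_ else wrap_axial(rad2deg(atan2(v[2], v[1])) / 2)
  list(magnitude = mag, angle = ang, vector = v, n = sum(ok))
}

#' Fluorescent-timer stable fraction per cell
#'
#' Ratio of background-subtracted mean membrane mKate2 to mean membrane
#' sfGFP over each cell's membrane band — the proxy for the stable protein
#' fraction.
#'
#' @param graph a [parse_tissue()] result.
#' @param mkate2,sfgfp intensity matrices.
#' @param background length-2 numeric `c(mkate2, sfgfp)` background levels, or
#'   `"estimate"` to estimate each from cell interiors.
#' @return data frame `cell`, `mean_mkate2`, `mean_sfgfp` (background
#'   subtracted), `ratio` (`NA` with `valid = FALSE` when the denominator is
#'   not positive).
#' @export
stable_fraction <- function(graph, mkate2, sfgfp, background = c(0, 0)) {
  stopifnot(inherits(graph, "tissue_graph"),
            all(dim(mkate2) == graph$dim), all(dim(sfgfp) == graph$dim))
  if (identical(background, "estimate"))
    background <- c(estimate_background(graph, mkate2),
                    estimate_background(graph, sfgfp))
  stopifnot(length(background) == 2, all(is.finite(background)))
  out <- lapply(seq_along(graph$cells), function(i) {
    px <- graph$cell_bands[[i]]
    if (length(px) == 0)
      return(data.frame(cell = graph$cells[i], mean_mkate2 = NA,
                        mean_sfgfp = NA, ratio = NA, valid = FALSE))
    num <- mean(mkate2[px]) - background[1]
    den <- mean(sfgfp[px]) - background[2]
    ok <- is.finite(den) && den > 0
    data.frame(cell = graph$cells[i], mean_mkate2 = num, mean_sfgfp = den,
               ratio = if (ok) max(num, 0) / den else NA_real_, valid = ok)
  })
  do.call(rbind, out)
}
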