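#' Circular summary of an axial sample
#'
#' Summarises axial (period-180) angles by doubling them onto the circle,
#' computing the (optionally weighted) mean resultant vector, and halving the
#' mean direction back to the axial scale. The circular standard deviation is
#' `(180/pi) * sqrt(-2 log(rbar)) / 2` degrees, i.e. the circular SD of the
#' doubled angles mapped back to the axial scale.
#'
#' @param angles numeric vector of axial angles in degrees.
#' @param w optional non-negative weights.
#' @return list with `mean` (degrees in `[0,180)`, `NA` when the resultant
#'   length is numerically zero), `rbar` (mean resultant length of doubled
#'   angles), `sd` (circular SD, degrees; `Inf` when `rbar` is 0) and `n`.
#' @export
#' @examples
#' circular_summary(c(10, 20, 30))
circular_summary <- function(angles, w = NULL) {
  if (length(angles) == 0L) stop("empty sample")
  res <- axial_mean_resultant(angles, w)
  sdv <- if (is.na(res$rbar) || res$rbar <= 0) Inf else rad2deg(sqrt(-2 * log(res$rbar))) / 2
  list(mean = res$mean, rbar = res$rbar, sd = sdv, n = length(angles))
}

#' Polar histogram of axial angles
#'
#' Bins axial angles on `[0, 180)` and optionally mirrors the counts to
#' `[180, 360)` for display on a full circle.
#'
#' @param angles numeric vector of axial angles in degrees.
#' @param bins number of bins over `[0, 180)` (default 9, i.e. 20-degree bins).
#' @param mirrored also return the mirrored (duplicated) counts.
#' @return list with `edges` (length `bins + 1`), `counts` (length `bins`,
#'   summing to `length(angles)`), and, if `mirrored`, `mirrored_counts`
#'   (length `2 * bins`, summing to `2 * length(angles)`).
#' @export
polar_histogram <- function(angles, bins = 9, mirrored = TRUE) {
  stopifnot(bins >= 1)
  a <- wrap_axial(angles, "[0,180)")
  edges <- seq(0, 180, length.out = bins + 1)
  idx <- pmin(findInterval(a, edges, rightmost.closed = FALSE), bins)
  counts <- tabulate(idx, nbins = bins)
  out <- list(edges = edges, counts = counts)
  if (mirrored) out$mirrored_counts <- c(counts, counts)
  out
}

#' Split normalised angles into quadrants
#'
#' Counts reference-normalised axial angles falling in the two quadrants
#' `(-45, 45]` and `(45, 135]`. Input angles are wrapped into `(-45, 135]`
#' first; bins are left-open, right-closed.
#'
#' @param angles numeric vector of angles in degrees, normalised to a
#'   reference axis.
#' @return named integer vector `c(first = ..., second = ...)`.
#' @export
quadrant_split <- function(angles) {
  a <- (angles + 45) %% 180 # in [0, 180): 0 maps from -45 (excluded side)
  a[a == 0] <- 180          # -45 itself belongs to the second quadrant (left-open)
  first <- sum(a > 0 & a <= 90)
  second <- sum(a > 90)
  c(first = first, second = second)
}

#' Hotelling's T-squared test on 2-D polarity vectors
#'
#' Two-sample test comparing the mean polarity vectors of two groups of wings
#' (each wing one vector, e.g. `(M cos 2 psi, M sin 2 psi)`), or a one-sample
#' test of one group against a fixed point. Uses the pooled-covariance
#' statistic with its exact F transformation.
#'
#' @param x numeric matrix (n x p) of group-A vectors (p = 2 for polarity).
#' @param y optional numeric matrix of group-B vectors; if `NULL`, a
#'   one-sample test against `mu0` is performed.
#' @param mu0 null point for the one-sample test (default origin).
#' @return list with `statistic` (T-squared), `f`, `df` (length 2), `p.value`,
#'   and the group mean vectors.
#' @export
#' @examples
#' a <- cbind(c(1, 2, 1), c(0, 1, 1))
#' hotelling_t2(a, -a)
hotelling_t2 <- function(x, y = NULL, mu0 = NULL) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (is.null(mu0)) mu0 <- rep(0, p)
  nx <- nrow(x)
  mx <- colMeans(x)
  if (is.null(y)) {
    if (nx < p + 1) stop("need at least ", p + 1, " observations")
    S <- stats::cov(x)
    Si <- solve_pd(S)
    d <- mx - mu0
    t2 <- nx * drop(crossprod(d, Si %*% d))
    f <- (nx - p) / (p * (nx - 1)) * t2
    df <- c(p, nx - p)
    means <- list(x = mx, mu0 = mu0)
  } else {
    y <- as.matrix(y)
    stopifnot(ncol(y) == p)
    ny <- nrow(y)
    if (nx < 2 || ny < 2 || nx + ny < p + 2) stop("groups too small")
    my <- colMeans(y)
    Sp <- ((nx - 1) * stats::cov(x) + (ny - 1) * stats::cov(y)) / (nx + ny - 2)
    Si <- solve_pd(Sp)
    d <- mx - my
    t2 <- (nx * ny) / (nx + ny) * drop(crossprod(d, Si %*% d))
    f <- (nx + ny - p - 1) / (p * (nx + ny - 2)) * t2
    df <- c(p, nx + ny - p - 1)
    means <- list(x = mx, y = my)
  }
  list(statistic = t2, f = f, df = df,
       p.value = stats::pf(f, df[1], df[2], lower.tail = FALSE),
       means = means)
}

# Invert a symmetric covariance matrix, failing with the degenerate direction
# named when it is singular.
solve_pd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  tolv <- max(e$values) * 1e-10
  if (any(e$values <= tolv)) {
    v <- e$vectors[, which.min(e$values)]
    stop(sprintf(
      "singular covariance: no variance along direction (%.3f, %.3f)",
      v[1], v[2]))
  }
  e$vectors %*% (t(e$vectors) / e$values)
}
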