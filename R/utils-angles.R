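# Angle conventions used throughout the package:
#  * pixel coordinates are (row, col), origin top-left; image y runs downward.
#  * all reported angles are mathematical: degrees counter-clockwise from the
#    image horizontal, so a proximo-distal (rightward) axis is 0 degrees.
#  * angles are axial (period 180) unless a function states otherwise.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap axial angles
#'
#' Wrap axial (period-180) angles into a canonical interval.
#'
#' @param x numeric vector of angles in degrees.
#' @param range `"(-90,90]"` (default, signed convention used for reported
#'   cell angles) or `"[0,180)"` (used for junction orientations and axial
#'   samples).
#' @return numeric vector of wrapped angles.
#' @export
wrap_axial <- function(x, range = c("(-90,90]", "[0,180)")) {
  range <- match.arg(range)
  y <- x %% 180
  if (range == "[0,180)") return(y)
  y[y > 90] <- y[y > 90] - 180
  # y == -90 cannot occur: y in [0,180) maps to (-90, 90]
  y
}

#' Axial difference between two angles
#'
#' Smallest absolute difference between two axial (period-180) angles,
#' in `[0, 90]` degrees.
#'
#' @param a,b angles in degrees.
#' @return numeric vector of absolute axial differences.
#' @export
axial_diff <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

# Weighted axial mean via angle doubling. Returns list(mean, rbar); mean is
# NA when the doubled resultant length is below `tol` (axial cancellation).
axial_mean_resultant <- function(angles, w = NULL, tol = 1e-9) {
  if (length(angles) == 0L) return(list(mean = NA_real_, rbar = NA_real_))
  if (is.null(w)) w <- rep(1, length(angles))
  stopifnot(length(w) == length(angles), all(w >= 0))
  sw <- sum(w)
  if (sw <= 0) return(list(mean = NA_real_, rbar = NA_real_))
  th <- deg2rad(2 * angles)
  C <- sum(w * cos(th)) / sw
  S <- sum(w * sin(th)) / sw
  rbar <- sqrt(C^2 + S^2)
  m <- if (rbar < tol) NA_real_ else wrap_axial(rad2deg(atan2(S, C)) / 2, "[0,180)")
  list(mean = m, rbar = rbar)
}

# Orientation (math convention, axial, degrees) of the segment joining two
# pixel coordinates given as (row, col).
segment_orientation <- function(r0, c0, r1, c1) {
  dx <- c1 - c0
  dy <- -(r1 - r0) # image rows run downward
  wrap_axial(rad2deg(atan2(dy, dx)), "[0,180)")
}
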