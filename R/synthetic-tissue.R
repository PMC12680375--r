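# Synthetic epithelium generator: jittered hexagonal meshes with an affine
# stretch for anisotropy, junctional intensity fields driven by a per-cell
# nematic polarity axis, a two-channel fluorescent timer with a scalar stable
# fraction, and per-cell filament textures with von Mises orientations.

#' Specification of a synthetic tissue mesh
#'
#' @param n_cols,n_rows number of cells per axis of the hexagonal lattice.
#' @param cell_diameter centre-to-centre spacing (pixels) before stretching.
#' @param anisotropy affine stretch factor `a/b >= 1` applied along the image
#'   x axis (the proximo-distal axis); the target cell eccentricity is
#'   `sqrt(1 - 1/anisotropy^2)`.
#' @param jitter vertex jitter as a fraction of `cell_diameter` (uniform
#'   displacement of lattice seeds before tessellation).
#' @param seed integer seed fixing all randomness of the mesh.
#' @param width,height image size in pixels; computed from the grid when `NULL`.
#' @return object of class `tissue_spec`.
#' @export
tissue_spec <- function(n_cols = 12, n_rows = 12, cell_diameter = 20,
                        anisotropy = 1, jitter = 0.08, seed = 1,
                        width = NULL, height = NULL) {
  stopifnot(n_cols >= 2, n_rows >= 2, cell_diameter >= 6,
            anisotropy >= 1, jitter >= 0, jitter < 0.5)
  structure(list(n_cols = n_cols, n_rows = n_rows,
                 cell_diameter = cell_diameter, anisotropy = anisotropy,
                 jitter = jitter, seed = as.integer(seed),
                 width = width, height = height),
            class = "tissue_spec")
}

#' Specification of a junctional polarity field
#'
#' Defines how junctional intensity is generated from per-cell nematic
#' polarity axes. Each junction `j` between cells with (axial) polarity axes
#' receives noiseless intensity `I_j = B + A * sin^2(alpha_j - psi_bar)`,
#' where `alpha_j` is the junction orientation and `psi_bar` the axial mean
#' of the two flanking cells' axes, so junctions perpendicular to the
#' polarity axis are brightest.
#'
#' @param mode `"uniform"`, `"swirl"` or `"boundary"`.
#' @param psi0 base polarity axis in degrees (axial).
#' @param amplitude asymmetry amplitude `A >= 0` (intensity units).
#' @param baseline junction baseline `B > 0` (intensity units).
#' @param stable_fraction fluorescent-timer stable fraction `f` in `[0, 1]`;
#'   the mKate2 channel carries `f` times the sfGFP junctional signal.
#' @param background constant autofluorescent background added to every pixel.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param propagation_rows for `"boundary"` mode: the repolarisation reaches
#'   rows `0..L` with linearly decaying strength — the source domain and row 0
#'   take the repolarised (boundary-normal) axis fully, row `k <= L` is
#'   rotated toward it by the fraction `1 - k/(L + 1)`, and higher rows keep
#'   `psi0`.
#' @param boundary_axis orientation of the overexpression boundary in degrees
#'   (default 0, the image horizontal); the repolarised cell axis is
#'   `boundary_axis + 90`.
#' @param swirl_centre for `"swirl"` mode, the vortex centre `c(x, y)` in
#'   pixels (default image centre); the axis at each cell is tangent to
#'   circles about this centre.
#' @param band_width width (pixels, odd) of the membrane band the junctional
#'   signal is painted on.
#' @return object of class `polarity_field`.
#' @export
polarity_field <- function(mode = c("uniform", "swirl", "boundary"),
                           psi0 = 0, amplitude = 100, baseline = 100,
                           stable_fraction = 1, background = 0, noise_sd = 0,
                           propagation_rows = 1, boundary_axis = 0,
                           swirl_centre = NULL, band_width = 3) {
  mode <- match.arg(mode)
  stopifnot(amplitude >= 0, baseline > 0,
            stable_fraction >= 0, stable_fraction <= 1,
            noise_sd >= 0, propagation_rows >= 0,
            band_width >= 1, band_width %% 2 == 1)
  structure(list(mode = mode, psi0 = psi0, amplitude = amplitude,
                 baseline = baseline, stable_fraction = stable_fraction,
                 background = background, noise_sd = noise_sd,
                 propagation_rows = propagation_rows,
                 boundary_axis = boundary_axis, swirl_centre = swirl_centre,
                 band_width = band_width),
            class = "polarity_field")
}

#' Specification of a per-cell filament texture
#'
#' @param mu mean filament orientation in degrees (axial); scalar, or one
#'   value per cell.
#' @param kappa von Mises concentration on doubled angles; `0` gives uniform
#'   orientations.
#' @param density filaments per squared pixel of cell area (default 0.02).
#' @param length_frac filament length as a fraction of the cell's
#'   equivalent-circle diameter. The default 1.5 draws overlong chords that
#'   the per-cell clipping terminates at the membrane: free filament ends,
#'   whose rounded intensity caps scatter gradient orientations in every
#'   direction, then only occur where the membrane already masks them.
#' @param taper length (pixels) of the linear intensity taper at each
#'   filament end (softens end-cap gradients where an end does fall inside
#'   the cell, as out-of-focus tips do).
#' @param amplitude peak filament intensity (arbitrary units).
#' @param blur_sigma Gaussian point-spread sigma applied to the rendered
#'   texture (pixels; `0` leaves only the bilinear anti-aliasing of the
#'   splatting, i.e. the thinnest possible filaments).
#' @param background,noise_sd constant background and Gaussian noise of the
#'   rendered tubulin channel.
#' @return object of class `filament_spec`.
#' @export
filament_spec <- function(mu = 0, kappa = 2, density = 0.02,
                          length_frac = 1.5, taper = 4, amplitude = 100,
                          blur_sigma = 0.7, background = 10, noise_sd = 0) {
  stopifnot(kappa >= 0, density > 0, length_frac > 0, taper >= 0,
            amplitude > 0, blur_sigma >= 0, noise_sd >= 0)
  structure(list(mu = mu, kappa = kappa, density = density,
                 length_frac = length_frac, taper = taper,
                 amplitude = amplitude, blur_sigma = blur_sigma,
                 background = background, noise_sd = noise_sd),
            class = "filament_spec")
}

# Run code with a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic epithelium label mask
#'
#' Rasterises a jittered hexagonal tessellation (affinely stretched along x
#' for anisotropy) into an integer label mask with a two-pixel membrane
#' skeleton (label 0) between adjacent cells, together with a ground-truth
#' geometry table. Output is identical for identical specs.
#'
#' @param spec a [tissue_spec()].
#' @return object of class `synthetic_tissue`: list with `labels` (integer
#'   matrix, background/membrane 0, cells `1..n`), `geometry` (data frame:
#'   `cell`, `cx`, `cy` centroid in pixels, `phi_true` (degrees, `NA` when
#'   isotropic), `ecc_true`, `area`, `border` flag for lattice-edge cells)
#'   and the `spec`.
#' @export
#' @examples
#' tis <- generate_tissue(tissue_spec(n_cols = 6, n_rows = 6, seed = 2))
#' table(tis$labels > 0)
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  d <- spec$cell_diameter
  s <- spec$anisotropy
  dy <- d * sqrt(3) / 2
  ii <- rep(seq_len(spec$n_rows) - 1L, each = spec$n_cols)
  jj <- rep(seq_len(spec$n_cols) - 1L, times = spec$n_rows)
  ux <- d * (jj + 0.75 + 0.5 * (ii %% 2))
  uy <- dy * (ii + 1)
  n <- length(ux)
  jit <- with_seed(spec$seed,
                   matrix(runif(2 * n, -spec$jitter * d, spec$jitter * d), n, 2))
  ux <- ux + jit[, 1]
  uy <- uy + jit[, 2]
  cx <- s * ux
  cy <- uy
  need_w <- ceiling(max(cx) + 0.75 * s * d)
  need_h <- ceiling(max(cy) + dy)
  W <- if (is.null(spec$width)) need_w else spec$width
  H <- if (is.null(spec$height)) need_h else spec$height
  if (W < need_w || H < need_h)
    stop(sprintf("image too small for requested grid: need at least %d x %d",
                 need_w, need_h))

  lab <- matrix(0L, H, W)
  best <- matrix(Inf, H, W)
  rad_y <- 1.3 * d
  rad_x <- 1.3 * d * s
  for (k in seq_len(n)) {
    r0 <- max(1L, floor(cy[k] - rad_y)); r1 <- min(H, ceiling(cy[k] + rad_y))
    c0 <- max(1L, floor(cx[k] - rad_x)); c1 <- min(W, ceiling(cx[k] + rad_x))
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1; cols <- c0:c1
    d2 <- outer((rows - cy[k])^2, ((cols - cx[k]) / s)^2, "+")
    bw <- best[rows, cols, drop = FALSE]
    upd <- d2 < bw
    if (any(upd)) {
      lw <- lab[rows, cols, drop = FALSE]
      lw[upd] <- k
      bw[upd] <- d2[upd]
      lab[rows, cols] <- lw
      best[rows, cols] <- bw
    }
  }

  # membrane skeleton: a pixel differing from any 4-neighbour is reassigned
  # to the membrane (label 0). Marking both sides of every boundary keeps the
  # membrane mirror-symmetric: one-sided rules (e.g. right-or-down only)
  # rasterise positive- and negative-slope boundaries with different pixel
  # densities, which biases any intensity statistic weighted by membrane mass
  mem <- matrix(FALSE, H, W)
  mem[, -W] <- mem[, -W] | (lab[, -W] != lab[, -1])
  mem[, -1] <- mem[, -1] | (lab[, -1] != lab[, -W])
  mem[-H, ] <- mem[-H, ] | (lab[-H, ] != lab[-1, ])
  mem[-1, ] <- mem[-1, ] | (lab[-1, ] != lab[-H, ])
  lab[mem] <- 0L

  idx <- which(lab > 0L)
  rows_px <- ((idx - 1L) %% H) + 1L
  cols_px <- ((idx - 1L) %/% H) + 1L
  area <- tabulate(lab[idx], nbins = n)
  cxm <- rowsum(as.numeric(cols_px), lab[idx])[, 1] / area
  cym <- rowsum(as.numeric(rows_px), lab[idx])[, 1] / area
  border <- (ii == 0L | ii == spec$n_rows - 1L | jj == 0L |
               jj == spec$n_cols - 1L)
  geometry <- data.frame(
    cell = seq_len(n),
    cx = cxm, cy = cym,
    seed_x = cx, seed_y = cy,
    phi_true = if (s > 1) 0 else NA_real_,
    ecc_true = sqrt(1 - 1 / s^2),
    area = area,
    border = border,
    lat_row = ii, lat_col = jj
  )
  structure(list(labels = lab, geometry = geometry, spec = spec),
            class = "synthetic_tissue")
}

#' Source cells of a synthetic overexpression domain
#'
#' The bottom `n_source_rows` lattice rows of a synthetic tissue act as the
#' overexpression domain; the boundary to the remaining tissue then runs
#' along the image horizontal (axis 0 degrees).
#'
#' @param tissue a [generate_tissue()] result.
#' @param n_source_rows number of lattice rows in the domain (default 2).
#' @return integer vector of source cell labels.
#' @export
boundary_source_cells <- function(tissue, n_source_rows = 2) {
  stopifnot(inherits(tissue, "synthetic_tissue"), n_source_rows >= 1)
  geo <- tissue$geometry
  geo$cell[geo$lat_row >= tissue$spec$n_rows - n_source_rows]
}

# Per-cell ground-truth polarity axes for a field (axial degrees).
field_axes <- function(field, geometry, rows = NULL) {
  n <- nrow(geometry)
  psi <- rep(field$psi0, n)
  if (field$mode == "swirl") {
    ctr <- field$swirl_centre
    if (is.null(ctr)) ctr <- c(mean(geometry$cx), mean(geometry$cy))
    dx <- geometry$cx - ctr[1]
    dy <- -(geometry$cy - ctr[2])
    psi <- wrap_axial(rad2deg(atan2(dy, dx)) + 90, "[0,180)")
  } else if (field$mode == "boundary") {
    if (is.null(rows))
      stop("boundary mode requires a row-assignment table (see assign_rows)")
    repol <- wrap_axial(field$boundary_axis + 90, "[0,180)")
    m <- match(geometry$cell, rows$cell)
    rr <- rows$row[m]
    src <- rows$source[m]
    # graded propagation: source and row 0 fully repolarised, deeper rows
    # rotated toward the repolarised axis by a linearly decaying fraction
    L <- field$propagation_rows
    w <- rep(0, n)
    w[!is.na(src) & src] <- 1
    inrow <- !is.na(rr) & rr <= L
    w[inrow] <- 1 - rr[inrow] / (L + 1)
    delta <- ((repol - field$psi0 + 90) %% 180) - 90 # signed axial rotation
    psi <- psi + w * delta
  }
  wrap_axial(psi, "[0,180)")
}

#' Render junctional fluorescence channels for a synthetic tissue
#'
#' Paints each junction's noiseless intensity
#' `I_j = B + A * sin^2(alpha_j - psi_bar)` on a membrane band (box dilation
#' of the junction's membrane pixels), with the junction orientation
#' `alpha_j` taken analytically from the seed geometry (the tessellation edge
#' is the perpendicular bisector of its two seeds in the stretched metric),
#' then produces the sfGFP channel
#' (`I + background + noise`) and the mKate2 channel
#' (`f * I + background + noise`).
#'
#' @param tissue a [generate_tissue()] result.
#' @param field a [polarity_field()].
#' @param rows row-assignment data frame (from [assign_rows()]) — required in
#'   `"boundary"` mode.
#' @param seed seed for the noise draws (default: tissue seed + 1).
#' @return list of class `synthetic_channels` with `channels` (named list of
#'   matrices `sfGFP`, `mKate2`), `cell_truth` (`cell`, `psi_true`),
#'   `junction_truth` (`junction`, `cell_a`, `cell_b`, `orientation`,
#'   `psi_bar`, `intensity` — noiseless), `graph` (the parsed tissue graph
#'   used for painting) and the `field`.
#' @export
render_channels <- function(tissue, field, rows = NULL, seed = NULL) {
  stopifnot(inherits(tissue, "synthetic_tissue"),
            inherits(field, "polarity_field"))
  if (is.null(seed)) seed <- tissue$spec$seed + 1L
  g <- parse_tissue(tissue$labels, band_width = field$band_width)
  psi <- field_axes(field, tissue$geometry, rows)
  jt <- g$junctions
  psi_bar <- numeric(nrow(jt))
  for (i in seq_len(nrow(jt))) {
    pa <- psi[match(jt$cell_a[i], tissue$geometry$cell)]
    pb <- psi[match(jt$cell_b[i], tissue$geometry$cell)]
    m <- axial_mean_resultant(c(pa, pb))
    # orthogonal axes cancel; fall back to the first cell's axis
    psi_bar[i] <- if (is.na(m$mean)) pa else m$mean
  }
  # analytic junction orientation: the tessellation edge between two seeds is
  # their perpendicular bisector in the stretched metric, so its orientation
  # follows from the seed coordinates alone (free of rasterisation error)
  s <- tissue$spec$anisotropy
  ga <- match(jt$cell_a, tissue$geometry$cell)
  gb <- match(jt$cell_b, tissue$geometry$cell)
  dux <- (tissue$geometry$seed_x[gb] - tissue$geometry$seed_x[ga]) / s
  duy <- -(tissue$geometry$seed_y[gb] - tissue$geometry$seed_y[ga])
  alpha <- wrap_axial(rad2deg(atan2(dux, -s * duy)), "[0,180)")
  inten <- field$baseline +
    field$amplitude * sin(deg2rad(alpha - psi_bar))^2

  # paint each junction's value on the dilation of its membrane pixels;
  # overlaps take the maximum, like overlapping fluorophore pools
  H <- nrow(tissue$labels); W <- ncol(tissue$labels)
  base <- matrix(0, H, W)
  rb <- (field$band_width - 1) / 2
  off <- expand.grid(dr = -rb:rb, dc = -rb:rb)
  # vertex pixels flanked by both of a junction's cells extend its paint into
  # the corners: leaving corners unpainted would imprint a six-fold angular
  # dip pattern on every cell's membrane band
  vflank <- if (length(g$vertex_pixels) > 0)
    flanking_labels(tissue$labels, g$vertex_pixels) else NULL
  for (i in seq_len(nrow(jt))) {
    px <- g$junction_pixels[[i]]
    if (!is.null(vflank)) {
      hasa <- (!is.na(vflank$p1) & vflank$p1 == jt$cell_a[i]) |
        (!is.na(vflank$p2) & vflank$p2 == jt$cell_a[i]) |
        (!is.na(vflank$p3) & vflank$p3 == jt$cell_a[i])
      hasb <- (!is.na(vflank$p1) & vflank$p1 == jt$cell_b[i]) |
        (!is.na(vflank$p2) & vflank$p2 == jt$cell_b[i]) |
        (!is.na(vflank$p3) & vflank$p3 == jt$cell_b[i])
      px <- c(px, g$vertex_pixels[hasa & hasb])
    }
    r <- ((px - 1L) %% H) + 1L
    cc <- ((px - 1L) %/% H) + 1L
    br <- rep(r, each = nrow(off)) + off$dr
    bc <- rep(cc, each = nrow(off)) + off$dc
    ok <- br >= 1 & br <= H & bc >= 1 & bc <= W
    cand <- unique((bc[ok] - 1L) * H + br[ok])
    base[cand] <- pmax(base[cand], inten[i])
  }
  band <- base

  noise <- function() {
    if (field$noise_sd > 0) matrix(rnorm(H * W, 0, field$noise_sd), H, W) else 0
  }
  channels <- with_seed(seed, {
    sf <- band + field$background + noise()
    mk <- field$stable_fraction * band + field$background + noise()
    list(sfGFP = sf, mKate2 = mk)
  })
  structure(list(
    channels = channels,
    cell_truth = data.frame(cell = tissue$geometry$cell, psi_true = psi),
    junction_truth = data.frame(junction = jt$junction, cell_a = jt$cell_a,
                                cell_b = jt$cell_b,
                                orientation = alpha,
                                psi_bar = psi_bar, intensity = inten),
    graph = g, field = field
  ), class = "synthetic_channels")
}

# Grayscale dilation (running maximum) with a square box of odd side w,
# separable along rows then columns.
grey_dilate <- function(img, w) {
  if (w <= 1) return(img)
  r <- (w - 1) / 2
  out <- img
  for (k in seq_len(r)) {
    out[, -1] <- pmax(out[, -1], img[, -ncol(img)])
    out[, -ncol(img)] <- pmax(out[, -ncol(img)], img[, -1])
    img <- out
  }
  img2 <- img
  for (k in seq_len(r)) {
    img[-1, ] <- pmax(img[-1, ], img2[-nrow(img2), ])
    img[-nrow(img), ] <- pmax(img[-nrow(img), ], img2[-1, ])
    img2 <- img
  }
  img
}

#' Paint an identical angular intensity profile on every cell's membrane band
#'
#' Test instrument for the geometry independence of the polarity statistic:
#' each membrane-band pixel of each cell receives
#' `base + amplitude * cos(2 * (theta' - psi))`, where `theta'` is the
#' pixel's angle about the cell centroid after undoing the global tissue
#' `stretch` (column offsets divided by `stretch`), so every cell carries
#' the same profile on its normalised perimeter regardless of its
#' eccentricity. A single shared frame is used for all cells — per-cell
#' fitted frames would paint inconsistent values on membrane pixels shared
#' by neighbours. Shared pixels receive the mean of the two contributions
#' (near-equal by the axial symmetry of the profile).
#'
#' @param graph a [parse_tissue()] result.
#' @param geometry per-cell geometry from [cell_geometry()] (centroids only
#'   are used).
#' @param psi profile axis in degrees (axial), in the normalised frame.
#' @param base,amplitude profile parameters (`amplitude < base` keeps the
#'   image positive).
#' @param stretch global x-stretch of the tissue (the generator's
#'   `anisotropy`; 1 for isotropic tissues).
#' @return intensity matrix of the same size as the label mask.
#' @export
render_angular_profile <- function(graph, geometry, psi, base = 1,
                                   amplitude = 0.5, stretch = 1) {
  H <- graph$dim[1]; W <- graph$dim[2]
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_along(graph$cells)) {
    cid <- graph$cells[i]
    px <- graph$cell_bands[[i]]
    if (length(px) == 0) next
    gm <- geometry[geometry$cell == cid, ]
    if (nrow(gm) != 1) next
    r <- ((px - 1L) %% H) + 1L
    cc <- ((px - 1L) %/% H) + 1L
    th <- atan2(-(r - gm$cy), (cc - gm$cx) / stretch)
    val <- base + amplitude * cos(2 * (th - deg2rad(psi)))
    acc[px] <- acc[px] + val
    cnt[px] <- cnt[px] + 1
  }
  pos <- cnt > 0
  acc[pos] <- acc[pos] / cnt[pos]
  acc
}

#' Sample von Mises angles
#'
#' Best–Fisher rejection sampler for the von Mises distribution on the
#' circle; `kappa = 0` returns uniform angles.
#'
#' @param n number of samples.
#' @param mu mean direction (radians).
#' @param kappa concentration (`>= 0`).
#' @return numeric vector of angles in radians in `[0, 2*pi)`.
#' @export
sample_von_mises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rho <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.3))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + rho * z) / (rho + z)
    cv <- kappa * (rho - f)
    keep <- (cv * (2 - cv) - u2 > 0) | (log(cv / u2) + 1 - cv >= 0)
    th <- sign(u3[keep] - 0.5) * acos(f[keep])
    out <- c(out, th)
  }
  (mu + out[seq_len(n)]) %% (2 * pi)
}

#' Render a filament (microtubule-like) texture per cell
#'
#' Draws line segments inside each cell whose orientations follow an axial
#' von Mises law: doubled angles are von Mises with mean `2 * mu` and
#' concentration `kappa`, so `kappa = 0` gives uniform orientations.
#' Segments are clipped to their cell, intensity-tapered at the ends, and
#' the final image is Gaussian-smoothed (anti-aliasing).
#'
#' @param tissue a [generate_tissue()] result.
#' @param fspec a [filament_spec()].
#' @param seed integer seed (default: tissue seed + 2).
#' @return list with `image` (tubulin channel matrix) and `filaments`
#'   (data frame `cell`, `angle` — the generator's own sampled axial angles
#'   in degrees).
#' @export
render_filaments <- function(tissue, fspec, seed = NULL) {
  stopifnot(inherits(tissue, "synthetic_tissue"),
            inherits(fspec, "filament_spec"))
  if (is.null(seed)) seed <- tissue$spec$seed + 2L
  lab <- tissue$labels
  H <- nrow(lab); W <- ncol(lab)
  geo <- tissue$geometry
  ncell <- nrow(geo)
  mu <- rep_len(fspec$mu, ncell)

  res <- with_seed(seed, {
    nf <- pmax(3L, round(fspec$density * geo$area))
    cell_of <- rep(geo$cell, nf)
    ang <- numeric(sum(nf))
    pos <- 0L
    for (i in seq_len(ncell)) {
      th2 <- sample_von_mises(nf[i], deg2rad(2 * mu[i]), fspec$kappa)
      ang[pos + seq_len(nf[i])] <- wrap_axial(rad2deg(th2) / 2, "[0,180)")
      pos <- pos + nf[i]
    }
    d_eq <- 2 * sqrt(geo$area / pi)
    len <- rep(fspec$length_frac * d_eq, nf)
    # segment midpoints: random pixel of the cell, sub-pixel jittered
    pick <- function(i) {
      px <- which(lab == geo$cell[i])
      px[sample.int(length(px), nf[i], replace = TRUE)]
    }
    mid <- unlist(lapply(seq_len(ncell), pick), use.names = FALSE)
    r0 <- ((mid - 1L) %% H) + 1L + runif(length(mid), -0.5, 0.5)
    c0 <- ((mid - 1L) %/% H) + 1L + runif(length(mid), -0.5, 0.5)
    list(cell_of = cell_of, ang = ang, len = len, r0 = r0, c0 = c0)
  })

  nt <- 81L
  tfrac <- seq(-0.5, 0.5, length.out = nt)
  thr <- deg2rad(res$ang)
  dirr <- -sin(thr)  # image rows run downward
  dirc <- cos(thr)
  R <- res$r0 + (res$len * dirr) %o% tfrac
  C <- res$c0 + (res$len * dirc) %o% tfrac
  wgt <- pmin(1, ((0.5 - abs(matrix(tfrac, nrow(R), nt, byrow = TRUE))) *
                    res$len) / max(fspec$taper, 1e-6))
  step <- res$len / (nt - 1)
  wgt <- wgt * step # line-integral weighting, invariant to segment length
  cellm <- matrix(res$cell_of, nrow(R), nt)
  # bilinear splatting: rounding sample points to the nearest pixel leaves a
  # staircase whose local gradient orientations wobble around the filament
  # direction and inflate the apparent orientation dispersion
  fr <- floor(R); fc <- floor(C)
  ar <- R - fr; ac <- C - fc
  sr <- c(fr, fr + 1, fr, fr + 1)
  sc <- c(fc, fc, fc + 1, fc + 1)
  sw <- c(wgt * (1 - ar) * (1 - ac), wgt * ar * (1 - ac),
          wgt * (1 - ar) * ac, wgt * ar * ac)
  scell <- rep(as.vector(cellm), 4L)
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W & sw > 0
  lin <- (pmax(sc, 1) - 1) * H + pmax(sr, 1)
  ok[ok] <- lab[lin[ok]] == scell[ok]
  img <- matrix(0, H, W)
  if (any(ok)) {
    sums <- rowsum(sw[ok], lin[ok])
    img[as.integer(rownames(sums))] <- sums[, 1]
  }
  if (fspec$blur_sigma > 0) img <- EBImage::gblur(img, sigma = fspec$blur_sigma)
  out <- fspec$amplitude * img + fspec$background
  if (fspec$noise_sd > 0)
    out <- out + with_seed(seed + 1L, matrix(rnorm(H * W, 0, fspec$noise_sd), H, W))
  list(image = out,
       filaments = data.frame(cell = res$cell_of, angle = res$ang))
}
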