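# Parsing of integer label masks (Tissue Analyzer style: cells >= 1,
# membrane/background 0) into a tissue graph of cells, adjacencies and
# junction segments, plus per-cell best-fit-ellipse geometry.

#' Parse a label mask into a tissue graph
#'
#' Membrane (label-0) pixels flanked by exactly two distinct cell labels
#' within Chebyshev radius 2 are junction pixels of that cell pair (radius 2
#' tolerates membranes up to two pixels thick); pixels flanked by three or
#' more labels are vertices and belong to no junction. The
#' measurement band of a junction is the box dilation (width `band_width`) of
#' its pixels, clipped to the two flanking cells and the membrane; pixels
#' within `band_width - 1` (Chebyshev) of a vertex are excluded from the band
#' so that adjacent junctions of different brightness do not contaminate each
#' other. Per-cell bands (`cell_bands`) instead cover the full membrane
#' perimeter of the cell, vertices included.
#'
#' @param labels integer matrix; cell labels `>= 1`, membrane/background `0`.
#' @param band_width membrane band width in pixels (odd, `>= 1`).
#' @return object of class `tissue_graph`: list with `labels`, `dim`, `cells`,
#'   `cell_pixels` (list of linear indices, one per cell), `adjacency`
#'   (data frame `a`, `b`), `junctions` (data frame: `junction`, `cell_a`,
#'   `cell_b`, `n_pixels`, endpoint coordinates `r0,c0,r1,c1`, `orientation`
#'   in degrees `[0,180)`, `low_confidence`), `junction_pixels`,
#'   `junction_bands`, `cell_bands` (lists of linear indices),
#'   `vertex_pixels`, `centroids`, and `band_width`.
#' @export
parse_tissue <- function(labels, band_width = 3) {
  if (!is.matrix(labels) || !all(labels == round(labels), na.rm = TRUE) ||
      anyNA(labels))
    stop("labels must be an integer-valued matrix without NA")
  stopifnot(band_width >= 1, band_width %% 2 == 1)
  lab <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  H <- nrow(lab); W <- ncol(lab)
  cells <- sort(unique(lab[lab > 0L]))
  if (length(cells) == 0L) stop("label mask contains no cells")
  pos <- which(lab > 0L)
  cell_pixels <- split(pos, lab[pos])
  cell_pixels <- cell_pixels[as.character(cells)]
  rpos <- ((pos - 1L) %% H) + 1L
  cpos <- ((pos - 1L) %/% H) + 1L
  area <- vapply(cell_pixels, length, 1L)
  cen <- data.frame(
    cell = cells,
    cx = rowsum(as.numeric(cpos), lab[pos])[as.character(cells), 1] / area,
    cy = rowsum(as.numeric(rpos), lab[pos])[as.character(cells), 1] / area
  )

  zero <- which(lab == 0L)
  flank <- flanking_labels(lab, zero)
  is_junc <- !is.na(flank$p2) & is.na(flank$p3)
  is_vert <- !is.na(flank$p3)
  vertex_pixels <- zero[is_vert]

  jpix <- zero[is_junc]
  key <- paste(flank$p1[is_junc], flank$p2[is_junc], sep = "_")
  groups <- split(jpix, key)

  if (length(groups) == 0L) {
    warning("no junctions found (single-cell image?): empty adjacency")
    return(structure(list(
      labels = lab, dim = c(H, W), cells = cells, cell_pixels = cell_pixels,
      adjacency = data.frame(a = integer(0), b = integer(0)),
      junctions = empty_junction_table(), junction_pixels = list(),
      junction_bands = list(), cell_bands = rep(list(integer(0)), length(cells)),
      vertex_pixels = vertex_pixels, centroids = cen, band_width = band_width
    ), class = "tissue_graph"))
  }

  # vertex exclusion zone for measurement bands
  vzone <- matrix(FALSE, H, W)
  if (length(vertex_pixels) > 0) {
    vzone[vertex_pixels] <- TRUE
    vzone <- grey_dilate(vzone * 1, 2 * (band_width - 1) + 1) > 0
  }

  nj <- length(groups)
  pair <- do.call(rbind, strsplit(names(groups), "_"))
  cell_a <- as.integer(pair[, 1]); cell_b <- as.integer(pair[, 2])
  orientation <- numeric(nj); lowc <- logical(nj)
  r0 <- integer(nj); c0 <- integer(nj); r1 <- integer(nj); c1 <- integer(nj)
  bands <- vector("list", nj)
  rb <- (band_width - 1) / 2
  off <- expand.grid(dr = -rb:rb, dc = -rb:rb)

  for (i in seq_len(nj)) {
    px <- groups[[i]]
    r <- ((px - 1L) %% H) + 1L
    cc <- ((px - 1L) %/% H) + 1L
    if (length(px) == 1L) {
      # orientation from the flanking-cell centroid normal
      ca <- cen[match(cell_a[i], cen$cell), ]
      cb <- cen[match(cell_b[i], cen$cell), ]
      orientation[i] <- wrap_axial(
        segment_orientation(ca$cy, ca$cx, cb$cy, cb$cx) + 90, "[0,180)")
      lowc[i] <- TRUE
      r0[i] <- r1[i] <- r; c0[i] <- c1[i] <- cc
    } else {
      mr <- mean(r); mc <- mean(cc)
      i1 <- which.max((r - mr)^2 + (cc - mc)^2)
      i2 <- which.max((r - r[i1])^2 + (cc - cc[i1])^2)
      r0[i] <- r[i1]; c0[i] <- cc[i1]; r1[i] <- r[i2]; c1[i] <- cc[i2]
      # orientation from the principal axis of the pixel cloud: unlike the
      # endpoint segment it is unbiased by the membrane thickness
      x <- cc - mc; y <- -(r - mr)
      sxx <- mean(x^2); syy <- mean(y^2); sxy <- mean(x * y)
      disc <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
      if (disc < 1e-12) {
        # isotropic pixel cloud: fall back to the centroid normal
        ca <- cen[match(cell_a[i], cen$cell), ]
        cb <- cen[match(cell_b[i], cen$cell), ]
        orientation[i] <- wrap_axial(
          segment_orientation(ca$cy, ca$cx, cb$cy, cb$cx) + 90, "[0,180)")
        lowc[i] <- TRUE
      } else {
        orientation[i] <- wrap_axial(
          rad2deg(atan2((syy - sxx) / 2 + disc, sxy)), "[0,180)")
      }
    }
    core <- !vzone[px]
    if (!any(core)) core <- rep(TRUE, length(px))
    rc <- r[core]; ccc <- cc[core]
    br <- rep(rc, each = nrow(off)) + off$dr
    bc <- rep(ccc, each = nrow(off)) + off$dc
    ok <- br >= 1 & br <= H & bc >= 1 & bc <= W
    cand <- unique((bc[ok] - 1L) * H + br[ok])
    lv <- lab[cand]
    bands[[i]] <- cand[lv == 0L | lv == cell_a[i] | lv == cell_b[i]]
  }

  junctions <- data.frame(
    junction = seq_len(nj), cell_a = cell_a, cell_b = cell_b,
    n_pixels = lengths(groups), r0 = r0, c0 = c0, r1 = r1, c1 = c1,
    orientation = orientation, low_confidence = lowc, row.names = NULL
  )
  adjacency <- unique(data.frame(a = pmin(cell_a, cell_b),
                                 b = pmax(cell_a, cell_b)))
  rownames(adjacency) <- NULL

  # cell bands cover the full membrane perimeter (vertices included):
  # vertex exclusion is needed when comparing individual junctions, but
  # leaving corner gaps in a cell's band would couple the missing arcs to
  # any angular intensity profile and bias whole-cell statistics
  memb_of <- split(
    rep(zero, 3L),
    c(flank$p1, flank$p2, flank$p3)
  )
  cell_bands <- lapply(cells, function(cid) {
    mp <- memb_of[[as.character(cid)]]
    mp <- mp[!is.na(mp)]
    if (length(mp) == 0) return(integer(0))
    r <- ((mp - 1L) %% H) + 1L
    cc <- ((mp - 1L) %/% H) + 1L
    br <- rep(r, each = nrow(off)) + off$dr
    bc <- rep(cc, each = nrow(off)) + off$dc
    ok <- br >= 1 & br <= H & bc >= 1 & bc <= W
    sort(unique((bc[ok] - 1L) * H + br[ok]))
  })

  structure(list(
    labels = lab, dim = c(H, W), cells = cells, cell_pixels = cell_pixels,
    adjacency = adjacency, junctions = junctions,
    junction_pixels = unname(groups), junction_bands = bands,
    cell_bands = cell_bands, vertex_pixels = vertex_pixels,
    centroids = cen, band_width = band_width
  ), class = "tissue_graph")
}

empty_junction_table <- function() {
  data.frame(junction = integer(0), cell_a = integer(0), cell_b = integer(0),
             n_pixels = integer(0), r0 = integer(0), c0 = integer(0),
             r1 = integer(0), c1 = integer(0), orientation = numeric(0),
             low_confidence = logical(0))
}

# First, second and third distinct non-zero labels within Chebyshev radius 2
# (5x5 neighbourhood) of each queried pixel (NA when fewer exist); radius 2
# sees across membranes up to two pixels thick. Fully vectorised.
flanking_labels <- function(lab, idx) {
  H <- nrow(lab); W <- ncol(lab)
  P <- matrix(0L, H + 4L, W + 4L)
  P[3:(H + 2L), 3:(W + 2L)] <- lab
  r <- ((idx - 1L) %% H) + 3L
  cc <- ((idx - 1L) %/% H) + 3L
  offs <- as.matrix(expand.grid(dr = -2:2, dc = -2:2))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  nb <- lapply(seq_len(nrow(offs)), function(k) {
    v <- P[cbind(r + offs[k, 1], cc + offs[k, 2])]
    v[v == 0L] <- NA_integer_
    v
  })
  pm <- function(lst) {
    out <- do.call(pmin, c(lst, list(na.rm = TRUE)))
    out
  }
  drop_val <- function(lst, val) {
    lapply(lst, function(v) {
      v[!is.na(v) & !is.na(val) & v == val] <- NA_integer_
      v
    })
  }
  p1 <- suppressWarnings(pm(nb))
  nb2 <- drop_val(nb, p1)
  p2 <- suppressWarnings(pm(nb2))
  nb3 <- drop_val(nb2, p2)
  p3 <- suppressWarnings(pm(nb3))
  list(p1 = p1, p2 = p2, p3 = p3)
}

#' Fit the second-moment (best-fit) ellipse of a pixel set
#'
#' Moments-equivalent ellipse of a cell's pixel coordinates: semi-axes
#' `a = 2*sqrt(lambda1)`, `b = 2*sqrt(lambda2)` of the coordinate covariance,
#' orientation of the major axis in mathematical convention, eccentricity
#' `e = sqrt(1 - (b/a)^2)`.
#'
#' @param coords two-column matrix of pixel `(row, col)` coordinates, or a
#'   vector of linear indices with `H` supplied.
#' @param H number of image rows (required when `coords` is a linear index
#'   vector).
#' @return list with `cx`, `cy` (pixels), `phi` (degrees in `(-90, 90]`),
#'   `a`, `b` (pixels, `a >= b`), `ecc`, `phi_defined` (FALSE for
#'   near-isotropic, `e < 0.05`, or degenerate collinear regions) and `n`.
#' @export
fit_cell_ellipse <- function(coords, H = NULL) {
  if (is.null(dim(coords))) {
    stopifnot(!is.null(H))
    coords <- cbind(((coords - 1L) %% H) + 1L, ((coords - 1L) %/% H) + 1L)
  }
  n <- nrow(coords)
  if (n < 5) stop("need at least 5 pixels to fit an ellipse")
  x <- coords[, 2]
  y <- -coords[, 1] # math convention
  mx <- mean(x); my <- mean(y)
  sxx <- mean(x^2) - mx^2
  syy <- mean(y^2) - my^2
  sxy <- mean(x * y) - mx * my
  e <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
  l1 <- max(e$values[1], 0); l2 <- max(e$values[2], 0)
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)
  degenerate <- l2 < 1e-9 * max(l1, 1)
  ecc <- if (degenerate) NA_real_ else sqrt(1 - (b / a)^2)
  phi <- wrap_axial(rad2deg(atan2(e$vectors[2, 1], e$vectors[1, 1])))
  phi_defined <- !degenerate && is.finite(ecc) && ecc >= 0.05
  list(cx = mx, cy = -my, phi = phi, a = a, b = b, ecc = ecc,
       phi_defined = phi_defined, n = n)
}

#' Per-cell ellipse geometry of a tissue graph
#'
#' `on_border` flags cells whose pixels touch the image frame: such cells are
#' truncated, so their fitted ellipse and membrane band are incomplete, and
#' per-cell angular measurements on them are biased — exclude them from
#' polarity statistics.
#'
#' @param graph a [parse_tissue()] result.
#' @return data frame with one row per cell: `cell`, `cx`, `cy`, `phi`,
#'   `a`, `b`, `ecc`, `phi_defined`, `n_pixels`, `on_border`, `valid`.
#' @export
cell_geometry <- function(graph) {
  stopifnot(inherits(graph, "tissue_graph"))
  H <- graph$dim[1]
  lab <- graph$labels
  edge <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, ncol(lab)]))
  out <- lapply(seq_along(graph$cells), function(i) {
    px <- graph$cell_pixels[[i]]
    brd <- graph$cells[i] %in% edge
    if (length(px) < 5)
      return(data.frame(cell = graph$cells[i], cx = NA, cy = NA, phi = NA,
                        a = NA, b = NA, ecc = NA, phi_defined = FALSE,
                        n_pixels = length(px), on_border = brd,
                        valid = FALSE))
    f <- fit_cell_ellipse(px, H = H)
    data.frame(cell = graph$cells[i], cx = f$cx, cy = f$cy, phi = f$phi,
               a = f$a, b = f$b, ecc = f$ecc, phi_defined = f$phi_defined,
               n_pixels = f$n, on_border = brd, valid = TRUE)
  })
  do.call(rbind, out)
}

#' Junction orientations of a tissue graph
#'
#' Orientation of the segment joining the two endpoint pixels of each
#' junction (degrees in `[0, 180)`, mathematical convention); single-pixel
#' junctions use the normal to the flanking-cell centroid line and are
#' flagged low-confidence. Orientations are computed by [parse_tissue()];
#' this accessor returns them as a data frame.
#'
#' @param graph a [parse_tissue()] result.
#' @return data frame `junction`, `orientation`, `low_confidence`.
#' @export
junction_orientation <- function(graph) {
  stopifnot(inherits(graph, "tissue_graph"))
  graph$junctions[, c("junction", "orientation", "low_confidence")]
}

#' Read a label mask from a TIFF or PNG file
#'
#' @param path file path; 8/16/32-bit single-page TIFF, or PNG when the
#'   `png` package is available.
#' @return integer label matrix.
#' @export
read_label_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG label masks requires the 'png' package")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(matrix(as.integer(round(img * 65535)), nrow(img), ncol(img)))
  }
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(img)) img <- img[[1]]
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img)), nrow(img), ncol(img))
}

#' Write an integer or intensity image as a 16-bit TIFF
#'
#' @param img matrix (or list of matrices for a multi-page TIFF) of values in
#'   `[0, 65535]`; values are rounded.
#' @param path output file path.
#' @export
write_image_tiff <- function(img, path) {
  enc <- function(m) {
    m <- pmin(pmax(round(m), 0), 65535) / 65535
    m
  }
  if (is.list(img)) img <- lapply(img, enc) else img <- enc(img)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}
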