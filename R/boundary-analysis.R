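# Row assignment relative to an overexpression boundary, junction orientation
# classes (horizontal vs medio-lateral), and per-row / per-boundary junction
# intensity summaries.

#' Assign cells to rows from a source (overexpression) domain
#'
#' Breadth-first layering over the junction-adjacency graph: row 0 cells share
#' a junction with at least one source cell, row k cells share a junction with
#' row k-1 and no lower row. Cells further than `max_row` are left unassigned.
#'
#' @param graph a [parse_tissue()] result, or a data frame of adjacency pairs
#'   (columns `a`, `b`).
#' @param source integer vector of source cell labels (non-empty, a proper
#'   subset of the cells).
#' @param max_row largest row index to assign (default 3).
#' @return data frame `cell`, `row` (integer, `NA` for source and unassigned
#'   cells), `source` (logical).
#' @export
assign_rows <- function(graph, source, max_row = 3) {
  if (inherits(graph, "tissue_graph")) {
    cells <- graph$cells
    adj <- graph$adjacency
  } else {
    adj <- as.data.frame(graph)[, 1:2]
    names(adj) <- c("a", "b")
    cells <- sort(unique(c(adj$a, adj$b)))
  }
  source <- unique(as.integer(source))
  if (length(source) == 0) stop("source cell set is empty")
  if (!all(source %in% cells)) stop("source contains unknown cell labels")
  if (length(setdiff(cells, source)) == 0)
    stop("source set covers all cells: no rows to assign")

  nbr <- split(c(adj$b, adj$a), c(adj$a, adj$b))
  row <- rep(NA_integer_, length(cells))
  names(row) <- cells
  frontier <- source
  seen <- as.character(source)
  k <- 0L
  while (k <= max_row && length(frontier) > 0) {
    nxt <- unique(unlist(nbr[as.character(frontier)], use.names = FALSE))
    nxt <- setdiff(nxt, as.integer(seen))
    if (length(nxt) == 0) break
    row[as.character(nxt)] <- k
    seen <- c(seen, as.character(nxt))
    frontier <- nxt
    k <- k + 1L
  }
  data.frame(cell = cells, row = unname(row), source = cells %in% source)
}

#' Classify a junction angle as horizontal or medio-lateral
#'
#' Acute axial angle between a junction orientation and the boundary axis;
#' `"horizontal"` when the angle is in `[0, 45]` (parallel-ish to the
#' boundary, ties at exactly 45 degrees are horizontal), `"medio-lateral"`
#' when in `(45, 90]`.
#'
#' @param orientation junction orientation(s), degrees (axial).
#' @param boundary_axis boundary axis, degrees.
#' @return character vector of classes.
#' @export
classify_junction_angle <- function(orientation, boundary_axis) {
  d <- axial_diff(orientation, boundary_axis)
  ifelse(d <= 45, "horizontal", "medio-lateral")
}

#' Classify junctions relative to an overexpression boundary
#'
#' Assigns each junction its orientation class (45-degree rule against the
#' boundary axis), the row both its cells share (when they do), and a
#' boundary index `k` for junctions linking row `k-1` to row `k`
#' (boundary 0 = source to row 0).
#'
#' @param graph a [parse_tissue()] result.
#' @param assignment row assignment from [assign_rows()], or `NULL` for
#'   class-only output.
#' @param boundary_axis boundary axis in degrees; when `NULL` (default) it is
#'   the length-weighted circular mean orientation of boundary-0 junctions
#'   (requires `assignment`).
#' @return data frame: `junction`, `cell_a`, `cell_b`, `orientation`,
#'   `angle_to_boundary` (degrees in `[0, 90]`), `class` (`NA` for
#'   undefined orientations, flagged `unclassified`), `row`, `boundary`.
#' @export
classify_junctions <- function(graph, assignment = NULL, boundary_axis = NULL) {
  stopifnot(inherits(graph, "tissue_graph"))
  jt <- graph$junctions
  rw <- function(cells) {
    if (is.null(assignment)) return(rep(NA_integer_, length(cells)))
    m <- match(cells, assignment$cell)
    r <- assignment$row[m]
    r[which(assignment$source[m])] <- -1L # source acts as row -1 for boundaries
    r
  }
  ra <- rw(jt$cell_a)
  rb <- rw(jt$cell_b)
  row <- ifelse(!is.na(ra) & !is.na(rb) & ra == rb & ra >= 0, ra, NA_integer_)
  boundary <- ifelse(!is.na(ra) & !is.na(rb) & abs(ra - rb) == 1,
                     pmax(ra, rb), NA_integer_)

  if (is.null(boundary_axis)) {
    if (is.null(assignment))
      stop("boundary_axis must be given when no row assignment is supplied")
    b0 <- which(!is.na(boundary) & boundary == 0L)
    if (length(b0) == 0) stop("no boundary-0 junctions to define the boundary axis")
    boundary_axis <- axial_mean_resultant(jt$orientation[b0],
                                          w = jt$n_pixels[b0])$mean
    if (is.na(boundary_axis))
      stop("boundary-0 junction orientations cancel; supply boundary_axis")
  }
  ok <- is.finite(jt$orientation)
  cls <- rep(NA_character_, nrow(jt))
  cls[ok] <- classify_junction_angle(jt$orientation[ok], boundary_axis)
  data.frame(junction = jt$junction, cell_a = jt$cell_a, cell_b = jt$cell_b,
             orientation = jt$orientation,
             angle_to_boundary = axial_diff(jt$orientation, boundary_axis),
             class = cls, unclassified = !ok,
             row = row, boundary = boundary)
}

#' Summarise junction intensities by row, class and boundary
#'
#' Per-junction mean background-subtracted intensity over the junction's
#' membrane band, then averaged (i) per row and orientation class over
#' junctions whose two cells share that row, and (ii) per named boundary.
#' Classes empty within a row are reported as missing rows of the table, not
#' as zeros.
#'
#' @param graph a [parse_tissue()] result.
#' @param classes result of [classify_junctions()].
#' @param channel intensity matrix.
#' @param background scalar background (or `"estimate"`).
#' @param max_row largest row to report (default 3).
#' @return list with `junctions` (per-junction means), `by_class` (grand mean
#'   per orientation class), `by_row` (row x class means) and `by_boundary`
#'   (per boundary index).
#' @export
summarize_junction_intensity <- function(graph, classes, channel,
                                         background = 0, max_row = 3) {
  stopifnot(inherits(graph, "tissue_graph"),
            all(dim(channel) == graph$dim))
  if (identical(background, "estimate"))
    background <- estimate_background(graph, channel)
  jmean <- vapply(graph$junction_bands, function(px) {
    if (length(px) == 0) NA_real_ else mean(channel[px]) - background
  }, numeric(1))
  per_j <- cbind(classes, mean_intensity = jmean)

  okc <- !is.na(per_j$class) & is.finite(per_j$mean_intensity)
  by_class <- aggregate(mean_intensity ~ class, data = per_j[okc, ],
                        FUN = mean)
  by_class$n <- aggregate(mean_intensity ~ class, data = per_j[okc, ],
                          FUN = length)$mean_intensity

  sel <- okc & !is.na(per_j$row) & per_j$row <= max_row
  by_row <- if (any(sel)) {
    br <- aggregate(mean_intensity ~ row + class, data = per_j[sel, ],
                    FUN = mean)
    br$n <- aggregate(mean_intensity ~ row + class, data = per_j[sel, ],
                      FUN = length)$mean_intensity
    br[order(br$row, br$class), ]
  } else data.frame(row = integer(0), class = character(0),
                    mean_intensity = numeric(0), n = integer(0))

  selb <- okc & !is.na(per_j$boundary) & per_j$boundary <= max_row
  by_boundary <- if (any(selb)) {
    bb <- aggregate(mean_intensity ~ boundary, data = per_j[selb, ],
                    FUN = mean)
    bb$n <- aggregate(mean_intensity ~ boundary, data = per_j[selb, ],
                      FUN = length)$mean_intensity
    bb
  } else data.frame(boundary = integer(0), mean_intensity = numeric(0),
                    n = integer(0))

  list(junctions = per_j, by_class = by_class, by_row = by_row,
       by_boundary = by_boundary)
}
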