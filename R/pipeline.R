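# End-to-end orchestration: configuration, staged execution, CSV/JSON output
# and a provenance record.

#' Pipeline run configuration
#'
#' @param labels label mask: integer matrix or path to a TIFF/PNG file.
#' @param channels named list of intensity matrices or file paths; recognised
#'   roles are `sfGFP`, `mKate2` and `tubulin` (roles must be unique).
#' @param band_width membrane band width in pixels.
#' @param background `"estimate"` (default, per-channel cell-interior mean) or
#'   a single numeric value applied to every channel.
#' @param source_cells integer vector of overexpression-domain cell labels, or
#'   a path to a text file of labels (one per line); required for the `rows`
#'   stage.
#' @param boundary_axis boundary axis in degrees (`NULL`: derived from
#'   boundary-0 junctions).
#' @param max_row largest row index to assign.
#' @param bins polar histogram bins over 0-180 degrees.
#' @param ecc_centres,ecc_halfwidth eccentricity bins for aligned average
#'   orientation profiles.
#' @param stages character vector among `"polarity"`, `"timer"`, `"mt"`,
#'   `"rows"`; stages whose required channel roles are absent must not be
#'   requested.
#' @param seed integer seed for any randomised step.
#' @param out_dir output directory for CSV/JSON results (`NULL`: in-memory
#'   results only).
#' @return object of class `run_config`.
#' @export
run_config <- function(labels, channels = list(), band_width = 3,
                       background = "estimate", source_cells = NULL,
                       boundary_axis = NULL, max_row = 3, bins = 9,
                       ecc_centres = c(0.750, 0.800), ecc_halfwidth = 0.025,
                       stages = c("polarity"), seed = 1, out_dir = NULL) {
  roles <- names(channels)
  if (length(channels) > 0) {
    if (is.null(roles) || any(roles == "") || anyDuplicated(roles))
      stop("channel roles must be uniquely named")
    unknown <- setdiff(roles, c("sfGFP", "mKate2", "tubulin"))
    if (length(unknown) > 0)
      stop("unknown channel role(s): ", paste(unknown, collapse = ", "))
  }
  stages <- match.arg(stages, c("polarity", "timer", "mt", "rows"),
                      several.ok = TRUE)
  need <- list(polarity = "sfGFP", timer = c("sfGFP", "mKate2"),
               mt = "tubulin", rows = "sfGFP")
  for (st in stages) {
    miss <- setdiff(need[[st]], roles)
    if (length(miss) > 0)
      stop(sprintf("stage '%s' requires channel role(s): %s",
                   st, paste(miss, collapse = ", ")))
  }
  paths <- c(if (is.character(labels)) labels,
             unlist(Filter(is.character, channels)),
             if (is.character(source_cells)) source_cells)
  if (length(paths) > 0) {
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files) > 0)
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  structure(list(labels = labels, channels = channels,
                 band_width = band_width, background = background,
                 source_cells = source_cells, boundary_axis = boundary_axis,
                 max_row = max_row, bins = bins, ecc_centres = ecc_centres,
                 ecc_halfwidth = ecc_halfwidth, stages = stages,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

load_channel <- function(x) {
  if (is.character(x)) {
    img <- tiff::readTIFF(x, as.is = TRUE)
    if (is.list(img)) img <- img[[1]]
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(matrix(as.numeric(img), nrow(img), ncol(img)))
  }
  x
}

stage_log <- function(name, t0, detail) {
  message(sprintf("[%s] %s (%.2f s)", name, detail,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full analysis pipeline
#'
#' Executes parse -> geometry -> polarity (+ timer ratio) -> optional
#' microtubule orientation -> optional row/junction analysis on one dataset,
#' writing per-cell and summary tables (and a provenance record) when an
#' output directory is configured. Results are identical for identical
#' configurations and seeds.
#'
#' @param config a [run_config()].
#' @return named list with `graph`, `geometry` and one entry per executed
#'   stage (`polarity`, `timer`, `mt`, `rows`), plus `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  res <- list()

  t0 <- proc.time()[3]
  labels <- if (is.character(config$labels)) read_label_mask(config$labels)
            else config$labels
  graph <- tryCatch(parse_tissue(labels, band_width = config$band_width),
                    error = function(e) stop("stage 'parse' failed: ",
                                             conditionMessage(e)))
  stage_log("parse", t0, sprintf("%d cells, %d junctions",
                                 length(graph$cells), nrow(graph$junctions)))
  res$graph <- graph

  t0 <- proc.time()[3]
  geometry <- cell_geometry(graph)
  stage_log("geometry", t0, sprintf("%d/%d cells valid",
                                    sum(geometry$valid), nrow(geometry)))
  res$geometry <- geometry

  ch <- lapply(config$channels, load_channel)
  bg_of <- function(img) {
    if (identical(config$background, "estimate"))
      estimate_background(graph, img)
    else config$background
  }

  if ("polarity" %in% config$stages) {
    t0 <- proc.time()[3]
    pol <- tryCatch(
      cell_polarity(graph, ch$sfGFP, geometry = geometry,
                    background = bg_of(ch$sfGFP)),
      error = function(e) stop("stage 'polarity' failed: ",
                               conditionMessage(e)))
    ref <- axial_mean_resultant(geometry$phi[geometry$phi_defined])$mean
    pol$psi_normalised <- if (is.null(ref) || is.na(ref)) pol$psi else
      normalize_angles(pol$psi, ref)
    wing <- aggregate_wing(pol)
    stage_log("polarity", t0,
              sprintf("%d cells measured; wing M=%.3f angle=%.1f",
                      wing$n, wing$magnitude,
                      ifelse(is.na(wing$angle), NaN, wing$angle)))
    res$polarity <- list(cells = pol, wing = wing, reference_axis = ref)
  }

  if ("timer" %in% config$stages) {
    t0 <- proc.time()[3]
    sf <- tryCatch(
      stable_fraction(graph, ch$mKate2, ch$sfGFP,
                      background = c(bg_of(ch$mKate2), bg_of(ch$sfGFP))),
      error = function(e) stop("stage 'timer' failed: ", conditionMessage(e)))
    stage_log("timer", t0, sprintf("mean mKate2/sfGFP ratio %.3f over %d cells",
                                   mean(sf$ratio, na.rm = TRUE), sum(sf$valid)))
    res$timer <- sf
  }

  if ("mt" %in% config$stages) {
    t0 <- proc.time()[3]
    mt <- tryCatch({
      tub <- percentile_clip(ch$tubulin)
      dist <- gradient_orientation_distribution(tub, graph)
      fits <- fit_von_mises(dist)
      profiles <- withCallingHandlers(
        aligned_average_profile(dist, geometry,
                                centres = config$ecc_centres,
                                halfwidth = config$ecc_halfwidth),
        warning = function(w) invokeRestart("muffleWarning"))
      list(distribution = dist, fits = fits, profiles = profiles)
    }, error = function(e) stop("stage 'mt' failed: ", conditionMessage(e)))
    stage_log("mt", t0, sprintf("%d/%d cells with valid fits",
                                sum(mt$fits$valid), nrow(mt$fits)))
    res$mt <- mt
  }

  if ("rows" %in% config$stages) {
    if (is.null(config$source_cells))
      stop("stage 'rows' requires source_cells in the configuration")
    t0 <- proc.time()[3]
    src <- config$source_cells
    if (is.character(src)) src <- as.integer(readLines(src))
    rows <- tryCatch({
      assignment <- assign_rows(graph, src, max_row = config$max_row)
      classes <- classify_junctions(graph, assignment,
                                    boundary_axis = config$boundary_axis)
      intensity <- summarize_junction_intensity(
        graph, classes, ch$sfGFP, background = bg_of(ch$sfGFP),
        max_row = config$max_row)
      list(assignment = assignment, classes = classes, intensity = intensity)
    }, error = function(e) stop("stage 'rows' failed: ", conditionMessage(e)))
    stage_log("rows", t0, sprintf("%d cells assigned to rows 0-%d",
                                  sum(!is.na(rows$assignment$row)),
                                  config$max_row))
    res$rows <- rows
  }

  res$provenance <- list(
    package = "pcpquant",
    version = as.character(utils::packageVersion("pcpquant")),
    seed = config$seed,
    stages = config$stages,
    band_width = config$band_width,
    background = config$background,
    timestamp = format(Sys.time(), tz = "UTC")
  )

  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config)
  res
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write.csv(res$geometry, p("cell_geometry.csv"), row.names = FALSE)
  write.csv(res$graph$junctions, p("junctions.csv"), row.names = FALSE)
  write.csv(res$graph$adjacency, p("adjacency.csv"), row.names = FALSE)
  if (!is.null(res$polarity)) {
    write.csv(res$polarity$cells, p("cell_polarity.csv"), row.names = FALSE)
    wing <- res$polarity$wing
    write.csv(data.frame(magnitude = wing$magnitude, angle = wing$angle,
                         n_cells = wing$n),
              p("wing_polarity.csv"), row.names = FALSE)
  }
  if (!is.null(res$timer))
    write.csv(res$timer, p("stable_fraction.csv"), row.names = FALSE)
  if (!is.null(res$mt))
    write.csv(res$mt$fits, p("mt_orientation.csv"), row.names = FALSE)
  if (!is.null(res$rows)) {
    write.csv(res$rows$assignment, p("row_assignment.csv"), row.names = FALSE)
    write.csv(res$rows$classes, p("junction_classes.csv"), row.names = FALSE)
    write.csv(res$rows$intensity$by_row, p("intensity_by_row.csv"),
              row.names = FALSE)
    write.csv(res$rows$intensity$by_boundary, p("intensity_by_boundary.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(res$provenance, p("provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}

#' Simulate a synthetic dataset and write it to disk
#'
#' Generates a tissue, renders the junctional channels (and optionally a
#' filament texture), and writes 16-bit TIFFs, ground-truth CSV tables and a
#' key-value config echo — a complete on-disk dataset for the pipeline.
#'
#' @param dir output directory (created if needed).
#' @param spec a [tissue_spec()].
#' @param field a [polarity_field()]; for `"boundary"` mode the bottom
#'   `n_source_rows` lattice rows act as the overexpression domain.
#' @param fspec optional [filament_spec()] for a tubulin channel.
#' @param n_source_rows lattice rows in the synthetic source domain.
#' @return invisible list with the in-memory `tissue`, `rendered` channels and
#'   file paths.
#' @export
simulate_dataset <- function(dir, spec, field = polarity_field(),
                             fspec = NULL, n_source_rows = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tissue <- generate_tissue(spec)
  rows <- NULL
  src <- NULL
  if (field$mode == "boundary") {
    src <- boundary_source_cells(tissue, n_source_rows)
    g0 <- parse_tissue(tissue$labels, band_width = field$band_width)
    rows <- assign_rows(g0, src, max_row = max(3, field$propagation_rows + 2))
  }
  rendered <- render_channels(tissue, field, rows = rows)
  paths <- list(labels = file.path(dir, "labels.tif"),
                channels = file.path(dir, "channels.tif"))
  write_image_tiff(tissue$labels, paths$labels)
  write_image_tiff(rendered$channels, paths$channels)
  write.csv(tissue$geometry, file.path(dir, "truth_geometry.csv"),
            row.names = FALSE)
  write.csv(rendered$cell_truth, file.path(dir, "truth_cell_polarity.csv"),
            row.names = FALSE)
  write.csv(rendered$junction_truth, file.path(dir, "truth_junctions.csv"),
            row.names = FALSE)
  if (!is.null(src))
    writeLines(as.character(src), file.path(dir, "source_cells.txt"))
  tub <- NULL
  if (!is.null(fspec)) {
    tub <- render_filaments(tissue, fspec)
    paths$tubulin <- file.path(dir, "tubulin.tif")
    write_image_tiff(tub$image, paths$tubulin)
    write.csv(tub$filaments, file.path(dir, "truth_filaments.csv"),
              row.names = FALSE)
  }
  cfg <- c(sprintf("n_cols=%d", spec$n_cols),
           sprintf("n_rows=%d", spec$n_rows),
           sprintf("cell_diameter=%g", spec$cell_diameter),
           sprintf("anisotropy=%g", spec$anisotropy),
           sprintf("jitter=%g", spec$jitter),
           sprintf("seed=%d", spec$seed),
           sprintf("mode=%s", field$mode),
           sprintf("psi0=%g", field$psi0),
           sprintf("amplitude=%g", field$amplitude),
           sprintf("baseline=%g", field$baseline),
           sprintf("stable_fraction=%g", field$stable_fraction),
           sprintf("background=%g", field$background),
           sprintf("noise_sd=%g", field$noise_sd),
           sprintf("band_width=%d", field$band_width))
  writeLines(cfg, file.path(dir, "config.txt"))
  invisible(list(tissue = tissue, rendered = rendered, tubulin = tub,
                 paths = paths))
}
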