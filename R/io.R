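## Readers and writers: single-channel TIFF/PNG images, trajectory and
## protrusion CSV tables, and the pipeline configuration.

#' Read a single-channel TIFF or PNG image
#'
#' @param path file path; format from the extension (.tif/.tiff/.png).
#' @param pixel_size_um micrometres per pixel to attach to the image.
#' @return An \code{\link{ecm_image}} at stage \code{"raw"}; TIFF values are
#'   read at native integer scale, PNG values on [0, 1].  Multi-channel
#'   input is a format error.
#' @export
read_image <- function(path, pixel_size_um = 1) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  v <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = png::readPNG(path),
    stop_invalid("unsupported image format '.", ext, "': ", path))
  if (length(dim(v)) == 3L) {
    if (dim(v)[3] == 1L) v <- v[, , 1] else
      stop_invalid("multi-channel image not supported: ", path)
  }
  if (!is.matrix(v)) stop_invalid("could not decode image: ", path)
  ecm_image(matrix(as.numeric(v), nrow(v), ncol(v)),
            pixel_size_um = pixel_size_um, stage = "raw",
            meta = list(path = path, format = ext))
}

#' Write an image as 16-bit TIFF or 8-bit PNG
#'
#' Intensities are rescaled to the file's full range; the scale used is
#' returned (and can be stored in a JSON sidecar) so values round-trip.
#' Binary images are written as 0/full-scale.
#'
#' @param img \code{\link{ecm_image}} or matrix.
#' @param path output path (.tif/.tiff for 16-bit, .png for 8-bit).
#' @return Invisibly, a list with the \code{scale} divisor applied.
#' @export
write_image <- function(img, path) {
  v <- img_values(img)
  check_matrix(v, "img")
  ext <- tolower(tools::file_ext(path))
  # negative values (e.g. enhanced-stage images) are shifted up; values
  # already on [0, 1] are then written as-is (lossless round-trip on the
  # 16-bit grid); larger ranges are divided by their maximum
  offset <- min(v, 0)
  v <- v - offset
  scale <- max(v)
  if (scale <= 1) scale <- 1
  vn <- v / scale
  ok <- switch(ext,
    tif = , tiff = tiff::writeTIFF(vn, path, bits.per.sample = 16L),
    png = png::writePNG(vn, path),
    stop_invalid("unsupported image format '.", ext, "'"))
  invisible(list(scale = scale, offset = offset, path = path))
}

#' Read cell trajectories from CSV
#'
#' Expected columns: \code{cell_id, t_min, x_um, y_um}.  Rows are grouped by
#' cell; unsorted times are sorted with a warning; duplicated time points for
#' a cell are a validation error naming the cell and file line.
#'
#' @param path CSV file path.
#' @return Named list of \code{\link{trajectory}} objects.
#' @export
read_tracks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "t_min", "x_um", "y_um")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_invalid("schema error in ", path, ": missing column(s) ",
                 paste(miss, collapse = ", "))
  d$.line <- seq_len(nrow(d)) + 1L  # header is line 1
  out <- lapply(split(d, d$cell_id), function(g) {
    dup <- duplicated(g$t_min)
    if (any(dup))
      stop_invalid(sprintf(
        "duplicated time point for cell '%s' at line %d of %s",
        g$cell_id[1], g$.line[dup][1], path))
    if (is.unsorted(g$t_min)) {
      warning(sprintf("times for cell '%s' were unsorted; sorting",
                      g$cell_id[1]))
      g <- g[order(g$t_min), ]
    }
    trajectory(g$cell_id[1], g$t_min, g$x_um, g$y_um)
  })
  out[order(names(out))]
}

#' Read protrusion events from CSV
#'
#' Expected columns: \code{cell_id, t_min, length_um} and exactly one of
#' \code{angle_deg} or \code{partition}.  With angle input, each cell's
#' anterior axis is taken from an optional \code{anterior_axis_deg} column if
#' present, otherwise from the longest protrusion at the earliest observed
#' time (the cell's initial polarization).
#'
#' @param path CSV file path.
#' @param duration_min observation window for every record, minutes.
#' @param min_length_um minimum protrusion length; shorter rows are a
#'   validation error.
#' @return Named list of \code{\link{protrusion_record}} objects.
#' @export
read_protrusions <- function(path, duration_min = 720, min_length_um = 5) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "t_min", "length_um")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_invalid("schema error in ", path, ": missing column(s) ",
                 paste(miss, collapse = ", "))
  has_angle <- "angle_deg" %in% names(d)
  has_part <- "partition" %in% names(d)
  if (has_angle == has_part)
    stop_invalid("schema error in ", path,
                 ": need exactly one of angle_deg or partition")
  out <- lapply(split(d, d$cell_id), function(g) {
    g <- g[order(g$t_min), ]
    if (has_part) {
      ev <- data.frame(time_min = g$t_min,
                       partition = as.integer(g$partition),
                       length_um = g$length_um)
      anterior <- 0
    } else {
      ev <- data.frame(time_min = g$t_min,
                       angle_rad = g$angle_deg * pi / 180,
                       length_um = g$length_um)
      anterior <- if ("anterior_axis_deg" %in% names(g)) {
        g$anterior_axis_deg[1] * pi / 180
      } else {
        first <- g[g$t_min == g$t_min[1], ]
        first$angle_deg[which.max(first$length_um)] * pi / 180
      }
    }
    protrusion_record(g$cell_id[1], ev, anterior_axis_rad = anterior,
                      duration_min = duration_min,
                      min_length_um = min_length_um)
  })
  out[order(names(out))]
}

#' Default pipeline configuration
#'
#' Parameter defaults follow the standard protocol for reflection-confocal
#' collagen analysis: 5 px filter mask, 15 orientations, Gaussian sd 0.7,
#' Otsu threshold, 61 um central analysis crop, 180 angular power samples
#' with DC removal, 5 um minimum protrusion length, 90 min protrusion-rate
#' window.
#'
#' @param pixel_size_um micrometres per pixel of the input images.
#' @param seed integer seed recorded for any stochastic stage.
#' @return Nested named list of class \code{pipeline_config}.
#' @export
default_config <- function(pixel_size_um = 0.2, seed = 1L) {
  structure(list(
    pixel_size_um = pixel_size_um,
    seed = as.integer(seed),
    preprocess = list(mask_size = 5L, n_orientations = 15L,
                      gaussian_sd = 0.7, threshold_method = "otsu",
                      threshold_value = NULL),
    microstructure = list(max_radius_px = 30L, n_thetas = 180L,
                          dc_remove = TRUE, crop_um = 61,
                          alignment_source = "binary"),
    motility = list(min_protrusion_um = 5, window_min = 90,
                    duration_min = 720),
    stats = list(pairs = list(), exclude = character(0))),
    class = "pipeline_config")
}

config_known_keys <- list(
  top = c("pixel_size_um", "seed", "preprocess", "microstructure",
          "motility", "stats"),
  preprocess = c("mask_size", "n_orientations", "gaussian_sd",
                 "threshold_method", "threshold_value"),
  microstructure = c("max_radius_px", "n_thetas", "dc_remove", "crop_um",
                     "alignment_source"),
  motility = c("min_protrusion_um", "window_min", "duration_min"),
  stats = c("pairs", "exclude"))

#' Validate and complete a pipeline configuration
#'
#' Unknown keys at any level are a configuration error listing the keys;
#' missing keys are filled from \code{\link{default_config}}.
#'
#' @param config named list (possibly partial).
#' @return A complete \code{pipeline_config}.
#' @export
validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), config_known_keys$top)
  if (length(unknown))
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (block in c("preprocess", "microstructure", "motility", "stats")) {
    if (!is.null(config[[block]])) {
      bad <- setdiff(names(config[[block]]), config_known_keys[[block]])
      if (length(bad))
        stop_invalid("unknown config key(s) in ", block, ": ",
                     paste(bad, collapse = ", "))
      base[[block]][names(config[[block]])] <- config[[block]]
    }
  }
  for (k in c("pixel_size_um", "seed"))
    if (!is.null(config[[k]])) base[[k]] <- config[[k]]
  base$seed <- as.integer(base$seed)
  structure(base, class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' Serialization round-trips losslessly: \code{read_config(write_config(x))}
#' equals \code{x}.
#'
#' @param config a \code{pipeline_config}.
#' @param path JSON file path.
#' @return \code{read_config} returns a validated \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!is.null(raw$stats$pairs))
    raw$stats$pairs <- lapply(raw$stats$pairs, unlist)
  validate_config(raw)
}
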