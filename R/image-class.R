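#' Image container with physical pixel size and processing stage
#'
#' A thin S3 wrapper around a numeric matrix that carries the pixel size in
#' micrometres per pixel and a tag identifying the processing stage the image
#' is at: \code{"raw"} (I_R), \code{"background"} (I_B), \code{"normalized"}
#' (I_N), \code{"enhanced"} (I_FEF) or \code{"binary"} (I_BW).  All image
#' operations in the package accept either a plain matrix or an
#' \code{ecm_image} and preserve \code{pixel_size_um} unchanged.
#'
#' @param values numeric matrix of non-negative intensities (rows = y,
#'   columns = x, origin top-left).
#' @param pixel_size_um positive scalar, micrometres per pixel.
#' @param stage one of \code{"raw"}, \code{"background"}, \code{"normalized"},
#'   \code{"enhanced"}, \code{"binary"}.
#' @param meta optional named list of stage metadata (e.g. the threshold a
#'   binarization actually used).
#' @return An object of class \code{ecm_image}.
#' @examples
#' img <- ecm_image(matrix(runif(64), 8, 8), pixel_size_um = 0.2)
#' print(img)
#' @export
ecm_image <- function(values, pixel_size_um = 1, stage = "raw", meta = list()) {
  check_matrix(values, "values")
  check_scalar(pixel_size_um, "pixel_size_um", lower = 1e-12)
  stage <- match.arg(stage,
                     c("raw", "background", "normalized", "enhanced", "binary"))
  if (stage == "binary" && !all(values %in% c(0, 1)))
    stop_invalid("binary-stage image must contain only 0 and 1")
  structure(list(values = values, pixel_size_um = pixel_size_um,
                 stage = stage, meta = meta),
            class = "ecm_image")
}

## accept matrix or ecm_image; returns ecm_image
as_ecm_image <- function(x, pixel_size_um = 1, stage = "raw") {
  if (inherits(x, "ecm_image")) return(x)
  ecm_image(x, pixel_size_um = pixel_size_um, stage = stage)
}

img_values <- function(x) if (inherits(x, "ecm_image")) x$values else x

img_px <- function(x, default = 1) {
  if (inherits(x, "ecm_image")) x$pixel_size_um else default
}

#' @export
print.ecm_image <- function(x, ...) {
  v <- x$values
  cat(sprintf("<ecm_image: %d x %d px, %.4g um/px, stage '%s'>\n",
              nrow(v), ncol(v), x$pixel_size_um, x$stage))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(v), max(v), mean(v)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ecm_image <- function(x) dim(x$values)

#' @export
as.matrix.ecm_image <- function(x, ...) x$values

#' @export
plot.ecm_image <- function(x, main = NULL, ...) {
  v <- x$values
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(0, 1)
  graphics::image(t(v)[, nrow(v):1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1),
                  zlim = rng, axes = FALSE, asp = nrow(v) / ncol(v),
                  main = main %||% sprintf("%s image", x$stage), ...)
  invisible(x)
}
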