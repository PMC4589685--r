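## Synthetic-data generators: fiber-network images with ground truth,
## interference-like radial backgrounds, persistent random-walk trajectories
## and protrusion event streams.  Every generator is deterministic given its
## seed, and every generated object carries the ground truth it was built
## from so downstream estimators can be validated against known parameters.

#' Parameters for the synthetic fiber-network image generator
#'
#' @param image_size_px integer vector of length 1 or 2 (rows, cols); each
#'   side must be at least 64 px.
#' @param pixel_size_um micrometres per pixel.
#' @param n_fibers number of fiber segments to draw.
#' @param mean_length_px mean fiber length in pixels.
#' @param length_jitter relative standard deviation of fiber length
#'   (lengths are truncated below at 20% of the mean).
#' @param width_px fiber stroke width in pixels (>= 1).
#' @param orientation_mode \code{"uniform"} for isotropic orientations or
#'   \code{"von-mises"} for a wrapped axial von Mises distribution.
#' @param orientation_center_rad center of the axial orientation
#'   distribution, in \eqn{[0, \pi)}.
#' @param orientation_kappa concentration of the orientation distribution;
#'   0 is isotropic, large values give strongly aligned fibers.
#' @param fiber_intensity intensity value of fiber pixels before background
#'   and noise are added.
#' @param blur_sd optional Gaussian blur (pixels) applied after rendering the
#'   hard strokes; 0 disables blurring so stroke width stays exact.
#' @param seed integer RNG seed.
#' @return A validated parameter list of class \code{fiber_field_params}.
#' @export
fiber_field_params <- function(image_size_px = c(256L, 256L),
                               pixel_size_um = 0.2,
                               n_fibers = 150L,
                               mean_length_px = 120,
                               length_jitter = 0.25,
                               width_px = 3,
                               orientation_mode = c("von-mises", "uniform"),
                               orientation_center_rad = 0,
                               orientation_kappa = 0,
                               fiber_intensity = 1,
                               blur_sd = 0,
                               seed = 1L) {
  if (length(image_size_px) == 1L) image_size_px <- rep(image_size_px, 2L)
  check_scalar(image_size_px[1], "image_size_px[1]", lower = 64, integer = TRUE)
  check_scalar(image_size_px[2], "image_size_px[2]", lower = 64, integer = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", lower = 1e-12)
  check_scalar(n_fibers, "n_fibers", lower = 0, integer = TRUE)
  check_scalar(mean_length_px, "mean_length_px", lower = 1e-9)
  check_scalar(length_jitter, "length_jitter", lower = 0)
  check_scalar(width_px, "width_px", lower = 1)
  check_scalar(orientation_center_rad, "orientation_center_rad",
               lower = 0, upper = pi - 1e-12)
  if (!(is.numeric(orientation_kappa) && length(orientation_kappa) == 1L &&
        !is.na(orientation_kappa) && orientation_kappa >= 0))
    stop_invalid("'orientation_kappa' must be a single number >= 0 (Inf allowed)")
  check_scalar(fiber_intensity, "fiber_intensity", lower = 0)
  check_scalar(blur_sd, "blur_sd", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 n_fibers = as.integer(n_fibers),
                 mean_length_px = mean_length_px,
                 length_jitter = length_jitter,
                 width_px = width_px,
                 orientation_mode = match.arg(orientation_mode),
                 orientation_center_rad = orientation_center_rad,
                 orientation_kappa = orientation_kappa,
                 fiber_intensity = fiber_intensity,
                 blur_sd = blur_sd,
                 seed = as.integer(seed)),
            class = "fiber_field_params")
}

#' Parameters for the radial interference-like background
#'
#' Emulates the slowly varying background of reflection-confocal images,
#' modelled as an isotropic Gaussian falloff of intensity with radial
#' distance from the image center, plus optional zero-mean speckle noise
#' (clipped at zero).
#'
#' @param center_intensity background intensity at the image center.
#' @param falloff_scale_px Gaussian falloff scale in pixels.
#' @param floor_intensity additive intensity offset reached far from the
#'   center.
#' @param speckle_sd standard deviation of the additive Gaussian speckle.
#' @param seed integer RNG seed for the speckle.
#' @return A list of class \code{background_params}.
#' @export
background_params <- function(center_intensity = 0.5,
                              falloff_scale_px = 180,
                              floor_intensity = 0.05,
                              speckle_sd = 0.03,
                              seed = 1L) {
  check_scalar(center_intensity, "center_intensity", lower = 0)
  check_scalar(falloff_scale_px, "falloff_scale_px", lower = 1e-9)
  check_scalar(floor_intensity, "floor_intensity", lower = 0)
  check_scalar(speckle_sd, "speckle_sd", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(center_intensity = center_intensity,
                 falloff_scale_px = falloff_scale_px,
                 floor_intensity = floor_intensity,
                 speckle_sd = speckle_sd,
                 seed = as.integer(seed)),
            class = "background_params")
}

## deterministic noise-free radial surface; function of r only
background_surface <- function(bg, nrow_px, ncol_px) {
  cy <- (nrow_px + 1) / 2
  cx <- (ncol_px + 1) / 2
  r2 <- outer((seq_len(nrow_px) - cy)^2, (seq_len(ncol_px) - cx)^2, "+")
  bg$floor_intensity +
    bg$center_intensity * exp(-r2 / (2 * bg$falloff_scale_px^2))
}

#' Generate an interference-like background image
#'
#' @param bg a \code{\link{background_params}} object.
#' @param image_size_px integer vector (rows, cols).
#' @param speckle logical; add the clipped Gaussian speckle noise.
#' @return An \code{\link{ecm_image}} at stage \code{"background"}; the
#'   noise-free radial surface is kept in \code{meta$surface}.
#' @export
generate_background <- function(bg, image_size_px, speckle = TRUE) {
  stopifnot(inherits(bg, "background_params"))
  if (length(image_size_px) == 1L) image_size_px <- rep(image_size_px, 2L)
  surf <- background_surface(bg, image_size_px[1], image_size_px[2])
  out <- surf
  if (speckle && bg$speckle_sd > 0) {
    set.seed(bg$seed)
    out <- pmax(out + matrix(rnorm(length(out), 0, bg$speckle_sd),
                             nrow(out), ncol(out)), 0)
  }
  ecm_image(out, stage = "background", meta = list(surface = surf))
}

## sample axial orientations on [0, pi) via the doubled-angle trick
sample_orientations <- function(n, mode, center, kappa) {
  if (n == 0L) return(numeric(0))
  if (mode == "uniform" || kappa == 0) return(runif(n, 0, pi))
  if (!is.finite(kappa)) return(rep(center, n))
  wrap_axial(rvonmises(n, 2 * center, kappa) / 2)
}

## mark pixels within width/2 of segment (x0,y0)-(x1,y1); pixel centers at
## integer coordinates
rasterize_segment <- function(canvas, x0, y0, x1, y1, width, value) {
  hw <- width / 2
  nr <- nrow(canvas); nc <- ncol(canvas)
  xlo <- max(1L, floor(min(x0, x1) - hw)); xhi <- min(nc, ceiling(max(x0, x1) + hw))
  ylo <- max(1L, floor(min(y0, y1) - hw)); yhi <- min(nr, ceiling(max(y0, y1) + hw))
  if (xlo > xhi || ylo > yhi) return(canvas)
  xs <- xlo:xhi; ys <- ylo:yhi
  px <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  py <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    d2 <- (px - x0)^2 + (py - y0)^2
  } else {
    t <- pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / len2))
    d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
  }
  hit <- d2 <= hw * hw
  if (any(hit)) {
    sub <- canvas[ys, xs, drop = FALSE]
    sub[hit] <- pmax(sub[hit], value)
    canvas[ys, xs] <- sub
  }
  canvas
}

#' Generate a synthetic fiber-network image with ground truth
#'
#' Draws \code{n_fibers} straight line segments with axial orientations from
#' a uniform or wrapped von Mises distribution, renders them as hard strokes
#' of exactly the requested width (optionally blurred), and adds an optional
#' radial interference background with speckle noise.  The returned object
#' records every segment drawn, so estimators can be checked against the
#' exact geometry.
#'
#' @param params a \code{\link{fiber_field_params}} object.
#' @param bg optional \code{\link{background_params}}; \code{NULL} for no
#'   background and no noise.
#' @return A list of class \code{fiber_field} with elements \code{image}
#'   (an \code{\link{ecm_image}}), \code{ground_truth} (data frame with
#'   columns fiber_id, x0, y0, x1, y1, theta_rad, length_px, width_px) and
#'   \code{params}.
#' @examples
#' ff <- generate_fiber_image(fiber_field_params(n_fibers = 20, seed = 7))
#' nrow(ff$ground_truth)
#' @export
generate_fiber_image <- function(params, bg = NULL) {
  stopifnot(inherits(params, "fiber_field_params"))
  if (!is.null(bg)) stopifnot(inherits(bg, "background_params"))
  set.seed(params$seed)
  nr <- params$image_size_px[1]; nc <- params$image_size_px[2]
  n <- params$n_fibers
  theta <- sample_orientations(n, params$orientation_mode,
                               params$orientation_center_rad,
                               params$orientation_kappa)
  len <- if (n > 0) {
    pmax(0.2 * params$mean_length_px,
         rnorm(n, params$mean_length_px,
               params$length_jitter * params$mean_length_px))
  } else numeric(0)
  cx <- runif(n, 1, nc); cy <- runif(n, 1, nr)
  x0 <- cx - len / 2 * cos(theta); x1 <- cx + len / 2 * cos(theta)
  y0 <- cy - len / 2 * sin(theta); y1 <- cy + len / 2 * sin(theta)
  canvas <- matrix(0, nr, nc)
  for (i in seq_len(n))
    canvas <- rasterize_segment(canvas, x0[i], y0[i], x1[i], y1[i],
                                params$width_px, params$fiber_intensity)
  fiber_mask <- canvas > 0
  if (params$blur_sd > 0) {
    g <- gaussian_kernel_2d(max(3L, 2L * ceiling(3 * params$blur_sd) + 1L),
                            params$blur_sd)
    canvas <- conv2_reflect(canvas, g / sum(g))
  }
  if (!is.null(bg)) {
    bgi <- generate_background(bg, c(nr, nc), speckle = TRUE)
    canvas <- pmax(canvas + bgi$values, 0)
  }
  gt <- data.frame(fiber_id = seq_len(n),
                   x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                   theta_rad = theta, length_px = len,
                   width_px = rep(params$width_px, n))
  structure(list(image = ecm_image(canvas,
                                   pixel_size_um = params$pixel_size_um,
                                   stage = "raw",
                                   meta = list(fiber_mask = fiber_mask)),
                 ground_truth = gt,
                 params = params),
            class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  cat(sprintf("<fiber_field: %d fibers, %d x %d px, kappa = %.3g>\n",
              nrow(x$ground_truth), nrow(x$image$values),
              ncol(x$image$values), x$params$orientation_kappa))
  invisible(x)
}

#' Parameters for the persistent random-walk trajectory generator
#'
#' The walk takes steps of constant length \code{speed_um_per_min * dt_min};
#' heading increments are uniform on
#' \eqn{(-\pi(1 - p), \pi(1 - p)]} where \eqn{p} is the persistence, so
#' \code{persistence = 1} gives a straight line and \code{persistence = 0}
#' gives independent uniform headings (an uncorrelated random walk).
#'
#' @param n_steps number of steps (the trajectory has n_steps + 1 points).
#' @param dt_min sampling interval in minutes (2 min is typical for
#'   timelapse cell tracking).
#' @param speed_um_per_min step speed in micrometres per minute.
#' @param persistence directional persistence in [0, 1].
#' @param seed integer RNG seed.
#' @return A list of class \code{walk_params}.
#' @export
walk_params <- function(n_steps = 495L, dt_min = 2, speed_um_per_min = 0.5,
                        persistence = 0.5, seed = 1L) {
  check_scalar(n_steps, "n_steps", lower = 1, integer = TRUE)
  check_scalar(dt_min, "dt_min", lower = 1e-9)
  check_scalar(speed_um_per_min, "speed_um_per_min", lower = 0)
  check_scalar(persistence, "persistence", lower = 0, upper = 1)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(n_steps = as.integer(n_steps), dt_min = dt_min,
                 speed_um_per_min = speed_um_per_min,
                 persistence = persistence, seed = as.integer(seed)),
            class = "walk_params")
}

#' Generate a persistent random-walk cell trajectory
#'
#' @param params a \code{\link{walk_params}} object.
#' @param cell_id identifier stored in the trajectory.
#' @return A \code{\link{trajectory}} starting at the origin with
#'   \code{n_steps + 1} points sampled every \code{dt_min} minutes.
#' @examples
#' tr <- generate_trajectory(walk_params(n_steps = 10, persistence = 1,
#'                                       speed_um_per_min = 1, seed = 3))
#' cell_speed(tr)  # exactly 1
#' @export
generate_trajectory <- function(params, cell_id = "sim1") {
  stopifnot(inherits(params, "walk_params"))
  set.seed(params$seed)
  n <- params$n_steps
  L <- params$speed_um_per_min * params$dt_min
  half_range <- pi * (1 - params$persistence)
  turn <- if (half_range > 0) runif(n, -half_range, half_range) else numeric(n)
  heading0 <- runif(1, 0, 2 * pi)
  heading <- heading0 + cumsum(c(0, turn[-1]))
  dx <- L * cos(heading); dy <- L * sin(heading)
  trajectory(cell_id = cell_id,
             times_min = params$dt_min * (0:n),
             x_um = c(0, cumsum(dx)),
             y_um = c(0, cumsum(dy)))
}

#' Parameters for the protrusion event-stream generator
#'
#' Events arrive as a Poisson stream over the observation window.  With
#' probability \code{axial_bias} an event is placed uniformly in the
#' anteroposterior partitions \{1, 5\}; otherwise it is placed uniformly over
#' all eight partitions, so \code{axial_bias = 0} is isotropic and
#' \code{axial_bias = 1} is fully polarized.
#'
#' @param duration_min observation window in minutes (12 h default).
#' @param rate_per_90min expected number of protrusions per 90 minutes.
#' @param axial_bias probability mass routed to the anteroposterior axis,
#'   in [0, 1].
#' @param min_length_um minimum protrusion length scored, in micrometres.
#' @param seed integer RNG seed.
#' @return A list of class \code{protrusion_stream_params}.
#' @export
protrusion_stream_params <- function(duration_min = 720, rate_per_90min = 4,
                                     axial_bias = 0.5, min_length_um = 5,
                                     seed = 1L) {
  check_scalar(duration_min, "duration_min", lower = 1e-9)
  check_scalar(rate_per_90min, "rate_per_90min", lower = 0)
  check_scalar(axial_bias, "axial_bias", lower = 0, upper = 1)
  check_scalar(min_length_um, "min_length_um", lower = 1e-9)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(duration_min = duration_min,
                 rate_per_90min = rate_per_90min,
                 axial_bias = axial_bias, min_length_um = min_length_um,
                 seed = as.integer(seed)),
            class = "protrusion_stream_params")
}

#' Generate a synthetic protrusion event stream
#'
#' @param params a \code{\link{protrusion_stream_params}} object.
#' @param cell_id identifier stored in the record.
#' @return A \code{\link{protrusion_record}} whose events carry a partition
#'   label in 1..8 and a length of at least \code{min_length_um}.
#' @export
generate_protrusion_stream <- function(params, cell_id = "sim1") {
  stopifnot(inherits(params, "protrusion_stream_params"))
  set.seed(params$seed)
  n <- rpois(1, params$rate_per_90min * params$duration_min / 90)
  if (n == 0) {
    ev <- data.frame(time_min = numeric(0), partition = integer(0),
                     length_um = numeric(0))
  } else {
    axial <- runif(n) < params$axial_bias
    part <- integer(n)
    part[axial] <- sample(c(1L, 5L), sum(axial), replace = TRUE)
    part[!axial] <- sample(1:8, sum(!axial), replace = TRUE)
    ev <- data.frame(time_min = sort(runif(n, 0, params$duration_min)),
                     partition = part,
                     length_um = params$min_length_um + rexp(n, 1 / 2))
  }
  protrusion_record(cell_id = cell_id, events = ev,
                    anterior_axis_rad = 0,
                    duration_min = params$duration_min,
                    min_length_um = params$min_length_um)
}

## small isotropic Gaussian kernel on an odd grid
gaussian_kernel_2d <- function(size, sd) {
  stopifnot(size %% 2 == 1)
  d <- seq(-(size - 1) / 2, (size - 1) / 2)
  g <- exp(-outer(d^2, d^2, "+") / (2 * sd^2))
  g
}
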