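## Matrix microstructure: pore-size spectrum by sequential morphological
## opening (granulometry) and the bulk fiber-alignment index from the
## eigenvalues of the second-moment matrix of the angular Fourier power.

#' Pore-size spectrum by sequential morphological opening
#'
#' The conjugate of the binary fiber mask (pore = 1 - fiber) is opened with
#' digital disks of increasing radius r; the retained pore area I(r) after
#' each opening counts pore regions wider than r.  The per-radius area
#' P(r) = I(r) - I(r + 1) gives the area occupied by pores of characteristic
#' radius r, and f(r) = P(r) / sum(P) is the pore-size frequency
#' distribution, from which the mean pore radius and diameter follow.
#'
#' The pore mask is zero-padded by \code{max_radius_px} before opening and
#' cropped afterwards, so pores touching the image border are treated as
#' bounded by the frame regardless of the morphology backend's border rule.
#'
#' @param mask binary image I_BW (\code{\link{ecm_image}} or 0/1 matrix)
#'   where 1 = fiber.
#' @param max_radius_px largest disk radius probed, in pixels; must not
#'   exceed half the smaller image side.
#' @param pixel_size_um micrometres per pixel (taken from the image when it
#'   is an \code{ecm_image}).
#' @return An object of class \code{pore_spectrum} with \code{radii_px},
#'   retained area \code{I_r}, per-radius area \code{P_r}, frequency
#'   \code{f_r}, \code{mean_radius_px} and \code{mean_diameter_um}.  When the
#'   conjugate image is empty (no pores) the spectrum is flagged empty and
#'   the means are NA, with a warning.  A mean radius below 2 px sets the
#'   \code{resolution_limited} flag, since pores near the imaging resolution
#'   are unreliable.
#' @examples
#' m <- matrix(1, 64, 64); m[20:40, 20:40] <- 0  # one square pore
#' ps <- pore_spectrum(m, max_radius_px = 15)
#' ps$mean_radius_px
#' @export
pore_spectrum <- function(mask, max_radius_px = 30L, pixel_size_um = NULL) {
  v <- img_values(mask)
  check_matrix(v, "mask")
  if (!all(v %in% c(0, 1)))
    stop_invalid("mask must be binary (0/1)")
  check_scalar(max_radius_px, "max_radius_px", lower = 1, integer = TRUE)
  if (max_radius_px > min(dim(v)) / 2)
    stop_invalid("max_radius_px exceeds half the smaller image side")
  px <- pixel_size_um %||% img_px(mask)
  pores <- 1 - v
  pad <- max_radius_px
  padded <- matrix(0, nrow(v) + 2 * pad, ncol(v) + 2 * pad)
  padded[pad + seq_len(nrow(v)), pad + seq_len(ncol(v))] <- pores
  crop <- function(m) m[pad + seq_len(nrow(v)), pad + seq_len(ncol(v))]
  all_r <- 0:max_radius_px
  I_r <- numeric(length(all_r))
  I_r[1] <- sum(pores)
  for (i in seq_along(all_r)[-1]) {
    opened <- EBImage::opening(padded, disk_kernel(all_r[i]))
    I_r[i] <- sum(crop(opened))
  }
  radii <- 0:(max_radius_px - 1L)  # P(r) = I(r) - I(r + 1)
  P_r <- -diff(I_r)
  tail_unresolved <- I_r[length(I_r)] > 0
  empty <- sum(P_r) == 0
  if (empty) {
    warning("no pores resolved below max_radius_px; spectrum is empty")
    f_r <- rep(NA_real_, length(radii))
    mean_r <- NA_real_
  } else {
    f_r <- P_r / sum(P_r)
    mean_r <- sum(radii * f_r)
  }
  structure(list(radii_px = radii, I_r = I_r, P_r = P_r, f_r = f_r,
                 mean_radius_px = mean_r,
                 mean_diameter_um = 2 * mean_r * px,
                 pixel_size_um = px,
                 empty = empty,
                 tail_unresolved = tail_unresolved,
                 resolution_limited = !empty && is.finite(mean_r) && mean_r < 2),
            class = "pore_spectrum")
}

#' @export
print.pore_spectrum <- function(x, ...) {
  cat("<pore_spectrum>\n")
  if (x$empty) {
    cat("  empty: no pore pixels in the conjugate image\n")
  } else {
    cat(sprintf("  mean pore radius: %.3f px, mean diameter: %.3f um\n",
                x$mean_radius_px, x$mean_diameter_um))
    if (x$resolution_limited)
      cat("  WARNING: mean pore radius < 2 px; near the imaging resolution limit\n")
    if (x$tail_unresolved)
      cat("  note: pores wider than max radius remain; increase max_radius_px\n")
  }
  invisible(x)
}

#' @export
as.data.frame.pore_spectrum <- function(x, ...) {
  data.frame(radius_px = x$radii_px,
             I_r = x$I_r[seq_along(x$radii_px)],
             P_r = x$P_r, f_r = x$f_r)
}

#' @export
plot.pore_spectrum <- function(x, ...) {
  graphics::barplot(x$f_r, names.arg = x$radii_px,
                    xlab = "pore radius (px)", ylab = "frequency f(r)", ...)
  invisible(x)
}

#' Centered 2D Fourier magnitude spectrum
#'
#' Discrete Fourier transform of the image with the zero-frequency component
#' shifted to the grid center; the magnitude is
#' \eqn{\sqrt{R(u,v)^2 + I(u,v)^2}} from the real and imaginary parts.  With
#' \code{dc_remove} the image mean is subtracted before the transform so the
#' isotropic central spike does not dominate the angular power.
#'
#' @param img image (\code{\link{ecm_image}} or matrix).
#' @param dc_remove subtract the image mean before transforming.
#' @return An object of class \code{spectrum_ft} with \code{magnitude},
#'   \code{real_part}, \code{imag_part}, \code{center} (row, col of the zero
#'   frequency), and flags \code{origin_centered}, \code{dc_removed}.
#' @export
ft_magnitude <- function(img, dc_remove = TRUE) {
  v <- img_values(img)
  check_matrix(v, "img")
  if (dc_remove) v <- v - mean(v)
  ft <- stats::fft(v)
  nr <- nrow(v); nc <- ncol(v)
  sr <- nr %/% 2L; sc <- nc %/% 2L
  shift <- function(m) m[c((sr + 1L):nr, 1:sr), c((sc + 1L):nc, 1:sc),
                         drop = FALSE]
  ft <- shift(ft)
  structure(list(magnitude = Mod(ft),
                 real_part = Re(ft), imag_part = Im(ft),
                 center = c(sr + 1L, sc + 1L),
                 origin_centered = TRUE, dc_removed = dc_remove,
                 dims = c(nr, nc)),
            class = "spectrum_ft")
}

#' @export
print.spectrum_ft <- function(x, ...) {
  cat(sprintf("<spectrum_ft: %d x %d, dc %s>\n", x$dims[1], x$dims[2],
              if (x$dc_removed) "removed" else "retained"))
  invisible(x)
}

## bilinear sample of matrix m at fractional (row, col) positions; zero
## outside
bilinear_sample <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- numeric(length(r))
    out[ok] <- m[cbind(r[ok], c[ok])]
    out
  }
  get(r0, c0) * (1 - fr) * (1 - fc) +
    get(r0 + 1, c0) * fr * (1 - fc) +
    get(r0, c0 + 1) * (1 - fr) * fc +
    get(r0 + 1, c0 + 1) * fr * fc
}

#' Angular power distribution of a centered spectrum
#'
#' Radon-style line integrals of the Fourier magnitude: for each orientation
#' \eqn{\theta} the magnitude is sampled (bilinear interpolation, 1 px steps)
#' along the full diameter line through the spectrum center at angle
#' \eqn{\theta} and summed, giving the integrated power \eqn{F_I(\theta)}.
#' The center pixel is excluded when the DC component was not removed, since
#' it would add the same constant at every orientation.
#'
#' @param spec a \code{\link{ft_magnitude}} result.
#' @param n_thetas number of orientations, evenly spaced over
#'   \eqn{[0, \pi)}; at least 8.
#' @return An object of class \code{polar_power} with \code{thetas_rad} and
#'   \code{power}.
#' @export
angular_power <- function(spec, n_thetas = 180L) {
  if (!inherits(spec, "spectrum_ft") || !isTRUE(spec$origin_centered))
    stop_invalid("'spec' must be an origin-centered spectrum_ft")
  check_scalar(n_thetas, "n_thetas", lower = 8, integer = TRUE)
  m <- spec$magnitude
  cy <- spec$center[1]; cx <- spec$center[2]
  L <- floor(min(dim(m)) / 2) - 1L
  t <- seq(-L, L, by = 1)
  if (!spec$dc_removed) t <- t[t != 0]
  thetas <- pi * (seq_len(n_thetas) - 1L) / n_thetas
  power <- vapply(thetas, function(th) {
    sum(bilinear_sample(m, cy + t * sin(th), cx + t * cos(th)))
  }, numeric(1))
  polar_power(thetas, power, dc_removed = spec$dc_removed)
}

#' Construct an angular power distribution
#'
#' @param thetas_rad orientations in \eqn{[0, \pi)}.
#' @param power non-negative integrated power at each orientation.
#' @param dc_removed whether the DC component was removed upstream.
#' @return An object of class \code{polar_power}.
#' @export
polar_power <- function(thetas_rad, power, dc_removed = TRUE) {
  if (length(thetas_rad) < 8L)
    stop_invalid("polar power needs at least 8 orientations")
  if (length(power) != length(thetas_rad))
    stop_invalid("power and thetas must have equal length")
  if (any(!is.finite(power)) || any(power < 0))
    stop_invalid("power must be finite and non-negative")
  structure(list(thetas_rad = as.numeric(thetas_rad),
                 power = as.numeric(power),
                 dc_removed = isTRUE(dc_removed)),
            class = "polar_power")
}

#' @export
print.polar_power <- function(x, ...) {
  cat(sprintf("<polar_power: %d orientations, peak at %.1f deg>\n",
              length(x$thetas_rad),
              x$thetas_rad[which.max(x$power)] * 180 / pi))
  invisible(x)
}

#' Fiber-alignment index from the angular power distribution
#'
#' The polar distribution \eqn{F_I(\theta)} is mapped to Cartesian points
#' \eqn{(F_I(\theta_i) \cos\theta_i, F_I(\theta_i) \sin\theta_i)}, collected
#' as the rows of the n x 2 matrix \eqn{C_{xy}}.  The two eigenvalues
#' \eqn{\lambda_1 \ge \lambda_2} of \eqn{C_{xy}^T C_{xy}} give the alignment
#' index \eqn{\alpha = 1 - \lambda_2 / \lambda_1}: 1 for a completely
#' aligned fiber matrix, 0 for an isotropic one.
#'
#' @param pp a \code{\link{polar_power}} object.
#' @return An object of class \code{alignment_result} with \code{lambda1},
#'   \code{lambda2}, \code{alpha} and \code{principal_orientation_rad} (the
#'   dominant direction of the angular power, in \eqn{[0, \pi)}).
#' @examples
#' th <- pi * (0:179) / 180
#' p <- rep(0, 180); p[10] <- 1
#' alignment_index(polar_power(th, p))$alpha          # 1
#' alignment_index(polar_power(th, rep(1, 180)))$alpha # 0
#' @export
alignment_index <- function(pp) {
  stopifnot(inherits(pp, "polar_power"))
  if (all(pp$power == 0))
    stop_invalid("all-zero angular power: alignment undefined (lambda1 = 0)")
  C <- cbind(pp$power * cos(pp$thetas_rad), pp$power * sin(pp$thetas_rad))
  M <- crossprod(C)
  eg <- eigen(M, symmetric = TRUE)
  l1 <- eg$values[1]; l2 <- max(0, eg$values[2])
  v1 <- eg$vectors[, 1]
  structure(list(lambda1 = l1, lambda2 = l2,
                 alpha = 1 - l2 / l1,
                 principal_orientation_rad = wrap_axial(atan2(v1[2], v1[1]))),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result: alpha = %.4f (lambda1 = %.4g, lambda2 = %.4g)>\n",
              x$alpha, x$lambda1, x$lambda2))
  cat(sprintf("  principal orientation: %.1f deg\n",
              x$principal_orientation_rad * 180 / pi))
  invisible(x)
}

#' Fiber alignment of an image
#'
#' Convenience wrapper: centered Fourier magnitude, angular power, alignment
#' index.
#'
#' @param img image (\code{\link{ecm_image}} or matrix).
#' @param n_thetas orientations for the angular power.
#' @param dc_remove subtract the image mean before the transform.
#' @return An \code{alignment_result}; the angular power is attached as
#'   attribute \code{"polar_power"}.
#' @export
image_alignment <- function(img, n_thetas = 180L, dc_remove = TRUE) {
  pp <- angular_power(ft_magnitude(img, dc_remove = dc_remove),
                      n_thetas = n_thetas)
  res <- alignment_index(pp)
  attr(res, "polar_power") <- pp
  res
}

## central square crop of side floor(crop_um / px) when that is smaller than
## the image
central_crop <- function(img, crop_um) {
  v <- img_values(img)
  px <- img_px(img)
  side <- floor(crop_um / px)
  if (!is.finite(side) || side <= 0 || side >= min(dim(v))) return(img)
  r0 <- (nrow(v) - side) %/% 2L
  c0 <- (ncol(v) - side) %/% 2L
  out <- v[r0 + seq_len(side), c0 + seq_len(side), drop = FALSE]
  if (inherits(img, "ecm_image"))
    ecm_image(out, pixel_size_um = px, stage = img$stage, meta = img$meta)
  else out
}

#' Full microstructure analysis of a raw reflection image
#'
#' Runs the preprocessing chain (background normalization, fiber enhancement,
#' binarization) on a central square crop of the stated physical extent, then
#' computes the pore-size spectrum from the binary mask and the alignment
#' index.  Following the original method the alignment is measured on the
#' binary image by default; the normalized or enhanced stage can be selected
#' instead.
#'
#' @param img raw image (\code{\link{ecm_image}} or matrix).
#' @param pixel_size_um micrometres per pixel (used when \code{img} is a bare
#'   matrix).
#' @param crop_um side of the central analysis crop in micrometres (61 um by
#'   default); \code{Inf} disables cropping.
#' @param max_radius_px largest pore radius probed.
#' @param n_thetas orientations for the angular power.
#' @param dc_remove remove the DC component before the Fourier transform.
#' @param alignment_source image stage the alignment is computed from.
#' @param mask_size,n_orientations,gaussian_sd,threshold_method,threshold_value
#'   preprocessing parameters, see \code{\link{preprocess_image}}.
#' @return An object of class \code{microstructure_report} with elements
#'   \code{pore}, \code{alignment}, \code{stages} and \code{parameters}.
#' @export
analyze_microstructure <- function(img, pixel_size_um = 0.2, crop_um = 61,
                                   max_radius_px = 30L, n_thetas = 180L,
                                   dc_remove = TRUE,
                                   alignment_source = c("binary",
                                                        "normalized",
                                                        "enhanced"),
                                   mask_size = 5L, n_orientations = 15L,
                                   gaussian_sd = 0.7,
                                   threshold_method = "otsu",
                                   threshold_value = NULL) {
  alignment_source <- match.arg(alignment_source)
  img <- as_ecm_image(img, pixel_size_um = pixel_size_um)
  img <- central_crop(img, crop_um)
  stages <- preprocess_image(img, mask_size = mask_size,
                             n_orientations = n_orientations,
                             gaussian_sd = gaussian_sd,
                             threshold_method = threshold_method,
                             threshold_value = threshold_value)
  pore <- pore_spectrum(stages$binary, max_radius_px = max_radius_px)
  al <- image_alignment(stages[[alignment_source]], n_thetas = n_thetas,
                        dc_remove = dc_remove)
  params <- list(pixel_size_um = img$pixel_size_um, crop_um = crop_um,
                 max_radius_px = max_radius_px, n_thetas = n_thetas,
                 dc_remove = dc_remove, alignment_source = alignment_source,
                 mask_size = mask_size, n_orientations = n_orientations,
                 gaussian_sd = gaussian_sd,
                 threshold_method = threshold_method,
                 threshold_used = stages$binary$meta$threshold)
  structure(list(pore = pore, alignment = al, stages = stages,
                 parameters = params),
            class = "microstructure_report")
}

#' @export
print.microstructure_report <- function(x, ...) {
  cat("<microstructure_report>\n")
  cat(sprintf("  alignment alpha: %.4f\n", x$alignment$alpha))
  if (x$pore$empty) {
    cat("  pore spectrum: empty\n")
  } else {
    cat(sprintf("  mean pore diameter: %.3f um (%.2f px radius)\n",
                x$pore$mean_diameter_um, x$pore$mean_radius_px))
  }
  invisible(x)
}

#' Serializable summary of a microstructure report
#'
#' @param object a \code{microstructure_report}.
#' @param ... unused.
#' @return Named list of scalar summaries (suitable for JSON output).
#' @export
summary.microstructure_report <- function(object, ...) {
  list(alpha = object$alignment$alpha,
       lambda1 = object$alignment$lambda1,
       lambda2 = object$alignment$lambda2,
       principal_orientation_deg =
         object$alignment$principal_orientation_rad * 180 / pi,
       mean_pore_radius_px = object$pore$mean_radius_px,
       mean_pore_diameter_um = object$pore$mean_diameter_um,
       resolution_limited = object$pore$resolution_limited,
       threshold_used = object$parameters$threshold_used)
}
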