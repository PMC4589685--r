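## Cell motility statistics: speed, net invasion distance, eight-partition
## protrusion orientation fractions and the polarization index.

#' Cell trajectory
#'
#' @param cell_id identifier.
#' @param times_min strictly increasing observation times in minutes.
#' @param x_um,y_um positions in micrometres.
#' @return An object of class \code{trajectory}.
#' @export
trajectory <- function(cell_id, times_min, x_um, y_um) {
  if (length(times_min) < 1L)
    stop_invalid("trajectory needs at least one point")
  if (length(x_um) != length(times_min) || length(y_um) != length(times_min))
    stop_invalid("times, x and y must have equal length")
  if (any(diff(times_min) <= 0))
    stop_invalid("times must be strictly increasing")
  if (!all(is.finite(c(times_min, x_um, y_um))))
    stop_invalid("trajectory coordinates must be finite")
  structure(list(cell_id = as.character(cell_id),
                 times_min = as.numeric(times_min),
                 x_um = as.numeric(x_um), y_um = as.numeric(y_um)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d points over %.1f min>\n",
              x$cell_id, length(x$times_min), diff(range(x$times_min))))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(cell_id = x$cell_id, t_min = x$times_min,
             x_um = x$x_um, y_um = x$y_um)
}

#' Protrusion event record for one cell
#'
#' Events carry either an absolute angle (radians, measured like all angles
#' in the package from the +x axis) or a partition label in 1..8.  Partition
#' 1 is centred on the anterior axis, which is set by the longest initial
#' protrusion at time zero and never updated; partitions increase
#' counter-clockwise in 45 degree sectors.
#'
#' @param cell_id identifier.
#' @param events data frame with columns \code{time_min}, \code{length_um}
#'   and one of \code{angle_rad} or \code{partition}.
#' @param anterior_axis_rad anterior axis direction in radians.
#' @param duration_min observation window in minutes.
#' @param min_length_um minimum protrusion length scored; shorter events are
#'   rejected.
#' @return An object of class \code{protrusion_record}.
#' @export
protrusion_record <- function(cell_id, events, anterior_axis_rad = 0,
                              duration_min = 720, min_length_um = 5) {
  stopifnot(is.data.frame(events))
  if (!"time_min" %in% names(events) || !"length_um" %in% names(events))
    stop_invalid("events must have columns time_min and length_um")
  has_angle <- "angle_rad" %in% names(events)
  has_part <- "partition" %in% names(events)
  if (!has_angle && !has_part)
    stop_invalid("events must carry either angle_rad or partition")
  if (has_part && nrow(events) &&
      !all(events$partition %in% 1:8))
    stop_invalid("partitions must be integers in 1..8")
  if (nrow(events) && any(events$length_um < min_length_um))
    stop_invalid(sprintf("all event lengths must be >= %g um", min_length_um))
  check_scalar(duration_min, "duration_min", lower = 1e-9)
  structure(list(cell_id = as.character(cell_id),
                 events = events,
                 anterior_axis_rad = anterior_axis_rad,
                 duration_min = duration_min,
                 min_length_um = min_length_um),
            class = "protrusion_record")
}

#' @export
print.protrusion_record <- function(x, ...) {
  cat(sprintf("<protrusion_record '%s': %d events over %.0f min>\n",
              x$cell_id, nrow(x$events), x$duration_min))
  invisible(x)
}

#' Mean cell speed
#'
#' Average over consecutive intervals of the Euclidean step length divided by
#' the interval duration.  Requires near-uniform sampling; tracks with frame
#' gaps are rejected rather than interpolated.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param tolerance maximal relative deviation of any interval from the
#'   median interval.
#' @return Speed in micrometres per minute.
#' @export
cell_speed <- function(traj, tolerance = 0.01) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$times_min) < 2L)
    stop_invalid("speed needs at least two points")
  dt <- diff(traj$times_min)
  if (max(abs(dt / stats::median(dt) - 1)) > tolerance)
    stop_invalid("non-uniform sampling interval (gap or dropped frame)")
  steps <- sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2)
  mean(steps / dt)
}

#' Net invasion distance
#'
#' Maximum Euclidean displacement of the cell from its first recorded
#' position over the whole track.
#'
#' @param traj a \code{\link{trajectory}}.
#' @return Distance in micrometres.
#' @export
net_invasion <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  max(sqrt((traj$x_um - traj$x_um[1])^2 + (traj$y_um - traj$y_um[1])^2))
}

## map absolute angles to partitions 1..8 relative to the anterior axis;
## sector 1 spans anterior +/- 22.5 deg, boundary ties go counter-clockwise
angle_to_partition <- function(angle_rad, anterior_axis_rad) {
  rel <- wrap_circular(angle_rad - anterior_axis_rad)
  as.integer(floor((rel + pi / 8) / (pi / 4)) %% 8) + 1L
}

#' Eight-partition protrusion orientation fractions and axial counts
#'
#' Bins protrusion events into eight 45 degree sectors about the cell
#' centroid, sector 1 centred on the anterior axis.  \code{C1} counts events
#' in the anteroposterior sectors (1 and 5), \code{C2} in the lateral sectors
#' (3 and 7); diagonal sectors contribute to the fractions but to neither
#' count.
#'
#' @param rec a \code{\link{protrusion_record}}.
#' @return A list with \code{fractions} (length 8, summing to 1; all NA when
#'   there are no events), \code{C1} and \code{C2}.
#' @export
partition_events <- function(rec) {
  stopifnot(inherits(rec, "protrusion_record"))
  ev <- rec$events
  if (nrow(ev) == 0L)
    return(list(fractions = rep(NA_real_, 8), C1 = 0L, C2 = 0L))
  part <- if ("partition" %in% names(ev)) as.integer(ev$partition)
          else angle_to_partition(ev$angle_rad, rec$anterior_axis_rad)
  counts <- tabulate(part, nbins = 8L)
  list(fractions = counts / sum(counts),
       C1 = sum(counts[c(1L, 5L)]),
       C2 = sum(counts[c(3L, 7L)]))
}

#' Protrusion polarization index
#'
#' \eqn{(C_1 - C_2) / (C_1 + C_2)}, where \eqn{C_1} is the number of
#' protrusions along the anteroposterior axis and \eqn{C_2} along the lateral
#' axis over the observation window.  A value near 1 means the cell stays
#' polarized along its initial axis; a value near 0 means protrusions explore
#' all angles equally.
#'
#' @param C1 anteroposterior protrusion count (sectors 1 and 5).
#' @param C2 lateral protrusion count (sectors 3 and 7).
#' @return Index in [-1, 1]; NA when both counts are zero.
#' @examples
#' polarization_index(12, 0)  # 1
#' polarization_index(6, 6)   # 0
#' @export
polarization_index <- function(C1, C2) {
  check_scalar(C1, "C1", lower = 0)
  check_scalar(C2, "C2", lower = 0)
  if (C1 + C2 == 0) return(NA_real_)
  (C1 - C2) / (C1 + C2)
}

#' Protrusion rate per time window
#'
#' @param rec a \code{\link{protrusion_record}}.
#' @param window_min reporting window in minutes (90 by default).
#' @return Expected number of events per \code{window_min} minutes.
#' @export
protrusion_rate <- function(rec, window_min = 90) {
  stopifnot(inherits(rec, "protrusion_record"))
  check_scalar(window_min, "window_min", lower = 1e-9)
  nrow(rec$events) * window_min / rec$duration_min
}

#' Per-cell motility summary
#'
#' @param traj a \code{\link{trajectory}} or NULL.
#' @param rec a \code{\link{protrusion_record}} or NULL.
#' @param window_min protrusion-rate window in minutes.
#' @return An object of class \code{motility_summary} with speed, net
#'   invasion, protrusion rate, orientation fractions, C1, C2 and the
#'   polarization index (NA where the input is absent).
#' @export
motility_summary <- function(traj = NULL, rec = NULL, window_min = 90) {
  out <- list(cell_id = NA_character_,
              speed_um_per_min = NA_real_, net_invasion_um = NA_real_,
              protrusions_per_90min = NA_real_,
              orientation_fractions = rep(NA_real_, 8),
              C1 = NA_integer_, C2 = NA_integer_,
              polarization_index = NA_real_)
  if (!is.null(traj)) {
    out$cell_id <- traj$cell_id
    out$speed_um_per_min <- cell_speed(traj)
    out$net_invasion_um <- net_invasion(traj)
  }
  if (!is.null(rec)) {
    out$cell_id <- rec$cell_id
    pe <- partition_events(rec)
    out$protrusions_per_90min <- protrusion_rate(rec, window_min)
    out$orientation_fractions <- pe$fractions
    out$C1 <- pe$C1; out$C2 <- pe$C2
    out$polarization_index <- if (pe$C1 + pe$C2 > 0)
      polarization_index(pe$C1, pe$C2) else NA_real_
  }
  structure(out, class = "motility_summary")
}

#' @export
print.motility_summary <- function(x, ...) {
  cat(sprintf("<motility_summary '%s'>\n", x$cell_id))
  cat(sprintf("  speed: %.3g um/min, net invasion: %.3g um\n",
              x$speed_um_per_min, x$net_invasion_um))
  cat(sprintf("  protrusions/90min: %.3g, C1 = %s, C2 = %s, polarization = %.3g\n",
              x$protrusions_per_90min, x$C1, x$C2, x$polarization_index))
  invisible(x)
}

#' @export
as.data.frame.motility_summary <- function(x, ...) {
  data.frame(cell_id = x$cell_id,
             speed_um_per_min = x$speed_um_per_min,
             net_invasion_um = x$net_invasion_um,
             protrusions_per_90min = x$protrusions_per_90min,
             C1 = x$C1, C2 = x$C2,
             polarization_index = x$polarization_index)
}
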