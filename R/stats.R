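## Condition-level statistics: min-max normalization, pairwise linear
## regression (slope, r^2, p) and the correlation report used for
## cross-metric comparisons; group comparisons delegate to aov()/TukeyHSD().

#' Min-max normalization of a metric column
#'
#' Rescales condition means to [0, 1] so metrics with different units can be
#' cross-correlated without units bias: \eqn{(v - \min v) / (\max v - \min
#' v)}.
#'
#' @param values numeric vector with at least 2 distinct finite values.
#' @return Vector of the same length with minimum 0 and maximum 1.
#' @export
minmax_normalize <- function(values) {
  if (!is.numeric(values) || !all(is.finite(values)))
    stop_invalid("values must be finite numbers")
  rng <- range(values)
  if (diff(rng) == 0)
    stop_invalid("degenerate scale: all values are identical")
  (values - rng[1]) / diff(rng)
}

#' Linear regression between two condition-level metrics
#'
#' Ordinary least squares of y on x; reports the slope, intercept, squared
#' Pearson correlation r^2 and the two-sided p-value for a non-zero slope
#' (t distribution with n - 2 degrees of freedom).
#'
#' @param xs,ys numeric vectors of equal length, at least 3 points.
#' @return An object of class \code{correlation_result} with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{p_slope}, \code{n_points}.
#' @examples
#' regress(0:2, c(0, 1, 2))  # slope 1, r^2 = 1
#' @export
regress <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 3L)
    stop_invalid("regression needs equal-length vectors with >= 3 points")
  if (stats::var(xs) == 0)
    stop_invalid("degenerate input: x has zero variance")
  fit <- stats::lm(ys ~ xs)
  # collinear input is a legitimate case (r^2 = 1); silence summary.lm's
  # "essentially perfect fit" warning
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  p <- if (nrow(co) >= 2L && !is.nan(co[2, 4])) co[2, 4] else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_slope = p,
                 n_points = length(xs),
                 fit = fit),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation: slope = %.4g, r^2 = %.4f, p = %.4g, n = %d>\n",
              x$slope, x$r_squared, x$p_slope, x$n_points))
  invisible(x)
}

#' Cross-metric correlation report over a condition table
#'
#' Takes a table of per-condition metric means (one row per condition, e.g.
#' collagen concentration), min-max normalizes each requested metric across
#' the included conditions, and regresses each requested pair.  Outlier
#' conditions are never dropped automatically: exclusions must be declared
#' explicitly and are recorded verbatim in the report.
#'
#' @param table data frame with a \code{condition} column and one numeric
#'   column per metric.
#' @param pairs list of length-2 character vectors \code{c(x_metric,
#'   y_metric)}, or a single such vector.
#' @param exclude character vector of condition labels to leave out of the
#'   regressions (recorded in the report).
#' @param normalize min-max normalize both metrics before regressing.
#' @param plot_dir optional directory; one scatter + fit PNG per pair is
#'   written there.
#' @return An object of class \code{correlation_report}: data frame
#'   \code{results} (pair, slope, r_squared, p_slope, n_points) plus the
#'   exclusion list and the per-pair \code{correlation_result}s.
#' @export
correlation_report <- function(table, pairs, exclude = NULL,
                               normalize = TRUE, plot_dir = NULL) {
  stopifnot(is.data.frame(table))
  if (!"condition" %in% names(table))
    stop_invalid("table must have a 'condition' column")
  if (!is.list(pairs)) pairs <- list(pairs)
  metrics <- unique(unlist(pairs))
  missing_m <- setdiff(metrics, names(table))
  if (length(missing_m))
    stop_invalid("unknown metric(s): ", paste(missing_m, collapse = ", "))
  keep <- !table$condition %in% (exclude %||% character(0))
  tab <- table[keep, , drop = FALSE]
  fits <- lapply(pairs, function(p) {
    x <- tab[[p[1]]]; y <- tab[[p[2]]]
    if (normalize) { x <- minmax_normalize(x); y <- minmax_normalize(y) }
    regress(x, y)
  })
  names(fits) <- vapply(pairs, paste, "", collapse = ":")
  results <- data.frame(
    pair = names(fits),
    slope = vapply(fits, `[[`, 0, "slope"),
    r_squared = vapply(fits, `[[`, 0, "r_squared"),
    p_slope = vapply(fits, `[[`, 0, "p_slope"),
    n_points = vapply(fits, `[[`, 0L, "n_points"),
    row.names = NULL)
  if (!is.null(plot_dir)) {
    dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(pairs)) {
      p <- pairs[[i]]
      x <- tab[[p[1]]]; y <- tab[[p[2]]]
      if (normalize) { x <- minmax_normalize(x); y <- minmax_normalize(y) }
      f <- fits[[i]]
      grDevices::png(file.path(plot_dir,
                               paste0("corr_", p[1], "_vs_", p[2], ".png")),
                     width = 600, height = 600)
      graphics::plot(x, y, pch = 19,
                     xlab = paste("normalized", p[1]),
                     ylab = paste("normalized", p[2]),
                     main = sprintf("slope %.3g, r2 %.3f, p %.3g",
                                    f$slope, f$r_squared, f$p_slope))
      graphics::abline(f$fit, col = "red")
      grDevices::dev.off()
    }
  }
  structure(list(results = results, excluded = exclude %||% character(0),
                 fits = fits, normalized = normalize),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report>\n")
  print(x$results)
  if (length(x$excluded))
    cat("  excluded conditions:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' One-way ANOVA with Tukey post-test across conditions
#'
#' Thin wrapper over \code{aov()} and \code{TukeyHSD()} for per-cell metric
#' comparisons across conditions; a reporting convenience only.
#'
#' @param values numeric response per cell.
#' @param condition factor or character grouping.
#' @return List with the \code{aov} fit, its ANOVA p-value and the Tukey
#'   table.
#' @export
condition_anova <- function(values, condition) {
  condition <- factor(condition)
  if (nlevels(condition) < 2L)
    stop_invalid("ANOVA needs at least 2 conditions")
  fit <- stats::aov(values ~ condition)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(fit = fit, p_value = p, tukey = stats::TukeyHSD(fit)$condition)
}
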