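## ATD processing and the CIU unfolded-population statistic. The central
## model is a two-component equal-width Gaussian mixture over drift time:
## a compact conformer (the base peak, ~5.5 ms for the 11+ ion) and an
## extended conformer (~7.6 ms) whose area relative to the compact one is
## the unfolding readout.

#' Arrival-time distribution container
#'
#' @param drift_time Drift-time axis (ms), strictly increasing.
#' @param intensity Intensities (counts), nonnegative.
#' @param trap_voltage Trap (activation) voltage (V).
#' @param charge Charge state of the selected ions.
#' @param inhibitor Inhibitor label.
#' @param replicate Replicate id.
#' @param protein Protein label (one protein per analysis collection).
#' @param warnings Character vector of acquisition/simulation warnings.
#' @return An object of class `atd`.
#' @export
atd <- function(drift_time, intensity, trap_voltage = NA_real_,
                charge = NA_integer_, inhibitor = "", replicate = 1L,
                protein = "", warnings = character()) {
  if (length(drift_time) != length(intensity))
    stop_input("drift_time and intensity must have equal length")
  if (length(drift_time) > 1 && any(diff(drift_time) <= 0))
    stop_input("drift_time must be strictly increasing")
  if (any(intensity < 0)) stop_input("intensities must be >= 0")
  structure(list(drift_time = as.numeric(drift_time),
                 intensity = as.numeric(intensity),
                 trap_voltage = trap_voltage,
                 charge = as.integer(charge), inhibitor = inhibitor,
                 replicate = as.integer(replicate), protein = protein,
                 warnings = warnings),
            class = "atd")
}

#' @export
print.atd <- function(x, ...) {
  cat(sprintf("<atd: %d points%s%s%s>\n", length(x$drift_time),
              if (!is.na(x$trap_voltage)) sprintf(", %g V", x$trap_voltage) else "",
              if (!is.na(x$charge)) sprintf(", %d+", x$charge) else "",
              if (nzchar(x$inhibitor)) paste0(", ", x$inhibitor) else ""))
  invisible(x)
}

#' @export
plot.atd <- function(x, ...) {
  plot(x$drift_time, x$intensity, type = "l", xlab = "drift time (ms)",
       ylab = "intensity",
       main = sprintf("%s %s", x$inhibitor,
                      if (!is.na(x$trap_voltage))
                        sprintf("(%g V)", x$trap_voltage) else ""),
       ...)
  invisible(x)
}

#' Select the analysis charge state
#'
#' The lowest charge state present is used for CIU analysis: low-charge
#' native ions are the least Coulombically activated and therefore most
#' representative of the solution conformation.
#'
#' @param atds List of [atd()] objects.
#' @return Integer charge state.
#' @export
select_analysis_charge <- function(atds) {
  if (length(atds) == 0) stop_input("empty ATD collection")
  prot <- unique(vapply(atds, `[[`, character(1), "protein"))
  prot <- prot[nzchar(prot)]
  if (length(prot) > 1)
    stop_input("mixed proteins in one collection: ",
               paste(prot, collapse = ", "))
  charges <- vapply(atds, `[[`, integer(1), "charge")
  if (all(is.na(charges))) stop_input("no charge annotations present")
  min(charges, na.rm = TRUE)
}

# two equal-width Gaussians on a drift-time axis
two_gauss <- function(t, h1, h2, c1, c2, s) {
  h1 * exp(-(t - c1)^2 / (2 * s^2)) + h2 * exp(-(t - c2)^2 / (2 * s^2))
}

#' Fit the two-conformer model to an ATD
#'
#' Least-squares fit of two equal-width Gaussians with centres constrained
#' to `expected_centers +/- center_window`. Initial values come from a
#' Savitzky-Golay-smoothed copy of the trace (window 5 bins, order 2); the
#' fit itself runs on the raw data. An extended component whose fitted
#' area falls below the detection floor (`floor_rel` of the compact area)
#' is reported as zero, never negative.
#'
#' @param x An [atd()].
#' @param expected_centers Numeric length 2: expected compact and extended
#'   centres (ms); default `c(5.5, 7.6)`.
#' @param center_window Allowed centre excursion (ms).
#' @param floor_rel Relative detection floor for the extended area.
#' @return An object of class `conformer_fit`.
#' @export
fit_two_conformers <- function(x, expected_centers = c(5.5, 7.6),
                               center_window = 0.3, floor_rel = 1e-3) {
  stopifnot(inherits(x, "atd"), length(expected_centers) == 2)
  if (center_window <= 0) stop_input("center_window must be > 0")
  t <- x$drift_time; y <- x$intensity
  if (any(expected_centers < min(t)) || any(expected_centers > max(t)))
    stop_input("expected centres must lie within the drift-time span")

  ys <- if (length(y) >= 7) signal::sgolayfilt(y, p = 2, n = 5) else y
  h1_0 <- max(ys[abs(t - expected_centers[1]) <= center_window], 0)
  h2_0 <- max(ys[abs(t - expected_centers[2]) <= center_window], 0)
  # start heights floored at 2% of the trace maximum: a zero-height start
  # makes the centre gradient vanish and the normal equations singular
  start <- list(h1 = max(h1_0, 0.02 * max(y)),
                h2 = max(h2_0, 0.02 * max(y)),
                c1 = expected_centers[1], c2 = expected_centers[2],
                s = 0.35)
  # raw Levenberg-Marquardt on the residual function: a component is
  # allowed to sit exactly on the zero-height bound at the optimum
  par0 <- unlist(start)
  out <- minpack.lm::nls.lm(
    par = par0,
    lower = c(h1 = 0, h2 = 0,
              c1 = expected_centers[1] - center_window,
              c2 = expected_centers[2] - center_window,
              s = 0.02),
    upper = c(h1 = Inf, h2 = Inf,
              c1 = expected_centers[1] + center_window,
              c2 = expected_centers[2] + center_window,
              s = diff(range(t)) / 2),
    fn = function(p) two_gauss(t, p[1], p[2], p[3], p[4], p[5]) - y,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!out$info %in% 1:4)
    stop_analysis("two-conformer fit failed to converge (", out$message,
                  ") [residual rms at stop: ",
                  format(sqrt(out$deviance / length(y)), digits = 4), "]")
  p <- out$par
  area1 <- p[["h1"]] * p[["s"]] * sqrt(2 * pi)
  area2 <- p[["h2"]] * p[["s"]] * sqrt(2 * pi)
  if (area2 < floor_rel * area1) area2 <- 0
  fitted_y <- two_gauss(t, p[["h1"]], p[["h2"]], p[["c1"]], p[["c2"]],
                        p[["s"]])
  resid <- y - fitted_y
  structure(list(compact_center = p[["c1"]], extended_center = p[["c2"]],
                 width_sd = p[["s"]],
                 compact_area = area1, extended_area = area2,
                 compact_height = p[["h1"]], extended_height = p[["h2"]],
                 unfold_percent = if (area1 > 0) 100 * area2 / area1
                                  else NA_real_,
                 residual_rms = sqrt(mean(resid^2)),
                 data = x, fitted = fitted_y),
            class = "conformer_fit")
}

#' Unfolded population statistic of a conformer fit
#'
#' The extended-conformer area expressed as a percentage of the compact
#' base peak: `100 * extended_area / compact_area`.
#'
#' @param fit A `conformer_fit`.
#' @return Unfolded percent (>= 0).
#' @export
unfolded_percent <- function(fit) {
  stopifnot(inherits(fit, "conformer_fit"))
  if (fit$compact_area <= 0)
    stop_analysis("compact area is zero: base peak undefined")
  100 * fit$extended_area / fit$compact_area
}

#' @export
print.conformer_fit <- function(x, ...) {
  cat("Two-conformer ATD fit\n")
  cat(sprintf("  compact:  centre %.3f ms, area %.4g\n",
              x$compact_center, x$compact_area))
  cat(sprintf("  extended: centre %.3f ms, area %.4g\n",
              x$extended_center, x$extended_area))
  cat(sprintf("  common width sd %.3f ms\n", x$width_sd))
  cat(sprintf("  unfolded: %.1f%% of the compact base peak\n",
              x$unfold_percent))
  cat(sprintf("  residual rms %.4g\n", x$residual_rms))
  invisible(x)
}

#' @export
coef.conformer_fit <- function(object, ...) {
  c(compact_center = object$compact_center,
    extended_center = object$extended_center,
    width_sd = object$width_sd,
    compact_height = object$compact_height,
    extended_height = object$extended_height)
}

#' @export
summary.conformer_fit <- function(object, ...) {
  out <- unclass(object)[c("compact_center", "extended_center", "width_sd",
                           "compact_area", "extended_area",
                           "unfold_percent", "residual_rms")]
  structure(out, class = "summary.conformer_fit")
}

#' @export
print.summary.conformer_fit <- function(x, ...) {
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' @export
residuals.conformer_fit <- function(object, ...) {
  object$data$intensity - object$fitted
}

#' @export
predict.conformer_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$drift_time else newdata
  two_gauss(t, object$compact_height, object$extended_height,
            object$compact_center, object$extended_center,
            object$width_sd)
}

#' @export
plot.conformer_fit <- function(x, ...) {
  d <- x$data
  plot(d$drift_time, d$intensity, type = "l", col = "grey40",
       xlab = "drift time (ms)", ylab = "intensity",
       main = sprintf("unfolded %.1f%%", x$unfold_percent), ...)
  lines(d$drift_time, x$fitted, col = "firebrick")
  abline(v = c(x$compact_center, x$extended_center), lty = 3)
  invisible(x)
}

#' Build a CIU fingerprint for one inhibitor
#'
#' Fits every replicate ATD at every voltage and aggregates the
#' unfolded-percent statistic into per-voltage replicate lists, means, and
#' sample standard deviations (sd 0 for a single replicate).
#'
#' @param atds List of [atd()]s for a single inhibitor.
#' @param ... Passed on to [fit_two_conformers()].
#' @return An object of class `ciu_fingerprint` with fields `inhibitor`,
#'   `charge`, `per_voltage` (data.frame: voltage, n, mean, sd) and
#'   `scores` (list of replicate score vectors keyed by voltage).
#' @export
build_fingerprint <- function(atds, ...) {
  if (length(atds) == 0) stop_input("no ATDs supplied")
  inh <- unique(vapply(atds, `[[`, character(1), "inhibitor"))
  if (length(inh) > 1)
    stop_input("fingerprint requires a single inhibitor, got: ",
               paste(inh, collapse = ", "))
  charges <- unique(vapply(atds, `[[`, integer(1), "charge"))
  if (length(charges) > 1)
    stop_input("inconsistent charge states across replicates: ",
               paste(charges, collapse = ", "))
  volt <- vapply(atds, `[[`, numeric(1), "trap_voltage")
  scores <- vapply(atds, function(a)
    unfolded_percent(fit_two_conformers(a, ...)), numeric(1))
  by_v <- split(scores, volt)
  per_voltage <- data.frame(
    voltage = as.numeric(names(by_v)),
    n = lengths(by_v),
    mean = vapply(by_v, mean, numeric(1)),
    sd = vapply(by_v, function(s) if (length(s) > 1) sd(s) else 0,
                numeric(1)),
    row.names = NULL)
  structure(list(inhibitor = inh, charge = charges,
                 per_voltage = per_voltage, scores = by_v),
            class = "ciu_fingerprint")
}

#' @export
print.ciu_fingerprint <- function(x, ...) {
  cat(sprintf("CIU fingerprint: %s (%d+)\n", x$inhibitor, x$charge))
  print(x$per_voltage, row.names = FALSE)
  invisible(x)
}

#' @export
plot.ciu_fingerprint <- function(x, ...) {
  pv <- x$per_voltage
  plot(pv$voltage, pv$mean, ylim = range(0, pv$mean + pv$sd, 100),
       xlab = "trap voltage (V)", ylab = "unfolded (% of base peak)",
       main = x$inhibitor, pch = 19, ...)
  arrows(pv$voltage, pv$mean - pv$sd, pv$voltage, pv$mean + pv$sd,
         angle = 90, code = 3, length = 0.03)
  invisible(x)
}
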