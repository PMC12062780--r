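## The screening decision: convert a CIU fingerprint into a type I /
## type II call against a calibration of class means at each activating
## voltage. Classification is nearest-class-mean per voltage with
## all-voltage agreement required; disagreement yields an explicit
## "ambiguous" call rather than a forced binary.

#' Calibration table constructor
#'
#' @param df data.frame with columns `voltage`, `class` (`"type_I"` /
#'   `"type_II"`), `mean`, `sd`, `lo`, `hi` (percent units; `hi` may be
#'   `Inf` for a one-sided range).
#' @return A `calibration_table`.
#' @export
calibration_table <- function(df) {
  need <- c("voltage", "class", "mean", "sd", "lo", "hi")
  if (!all(need %in% names(df)))
    stop_input("calibration needs columns: ", paste(need, collapse = ", "))
  for (v in unique(df$voltage)) {
    m1 <- df$mean[df$voltage == v & df$class == "type_I"]
    m2 <- df$mean[df$voltage == v & df$class == "type_II"]
    if (length(m1) != 1 || length(m2) != 1)
      stop_input("calibration needs exactly one row per (voltage, class)")
    if (m2 <= m1)
      stop_input("type II mean must exceed type I mean at ", v, " V")
    rng <- df[df$voltage == v, ]
    if (any(rng$mean < rng$lo | rng$mean > rng$hi))
      stop_input("class mean outside its range at ", v, " V")
  }
  structure(df, class = c("calibration_table", "data.frame"))
}

#' Default screening calibration
#'
#' Class statistics of the unfolded-percent readout for a
#' ten-compound FGFR1 inhibitor panel: at 21 V, type I mean 27.6 (sd 3.9,
#' range 22--35) vs type II mean 48.9 (sd 4.4, range above 40); at 24 V,
#' type I mean 44.2 (sd 5.6, range 30--50) vs type II mean 76.7
#' (sd 11.6, range 64--95).
#'
#' @return A [calibration_table()].
#' @export
default_calibration <- function() {
  calibration_table(data.frame(
    voltage = c(21, 21, 24, 24),
    class = c("type_I", "type_II", "type_I", "type_II"),
    mean = c(27.6, 48.9, 44.2, 76.7),
    sd = c(3.9, 4.4, 5.6, 11.6),
    lo = c(22, 40, 30, 64),
    hi = c(35, Inf, 50, 95),
    stringsAsFactors = FALSE))
}

#' Write / read a calibration as JSON
#'
#' Calibration is data, not code: storing it as JSON lets users
#' recalibrate the screen for other kinases without touching the package.
#'
#' @param calib A [calibration_table()].
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly;
#'   `read_calibration` returns a [calibration_table()].
#' @export
write_calibration <- function(calib, path) {
  df <- as.data.frame(calib)
  df$hi[!is.finite(df$hi)] <- NA  # JSON has no Inf
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  df$hi[is.na(df$hi)] <- Inf
  calibration_table(df)
}

#' Classify a single-voltage score
#'
#' Nearest-class-mean rule: the score is assigned the class whose
#' calibrated mean is closer; a score exactly at the midpoint of the two
#' means is `"ambiguous"`.
#'
#' @param score Unfolded percent.
#' @param voltage Trap voltage (V), present in the calibration.
#' @param calib A [calibration_table()].
#' @return `"type_I"`, `"type_II"`, or `"ambiguous"`.
#' @export
classify_voltage <- function(score, voltage, calib = default_calibration()) {
  rows <- calib[calib$voltage == voltage, ]
  if (nrow(rows) == 0)
    stop_input("no calibration at ", voltage, " V")
  m1 <- rows$mean[rows$class == "type_I"]
  m2 <- rows$mean[rows$class == "type_II"]
  d1 <- abs(score - m1); d2 <- abs(score - m2)
  if (d1 == d2) "ambiguous" else if (d1 < d2) "type_I" else "type_II"
}

#' Classify one inhibitor from its CIU fingerprint
#'
#' Applies the nearest-mean rule to the replicate-mean score at every
#' calibrated voltage. The overall call is the common class when all
#' voltages agree and `"ambiguous"` otherwise. The confidence note
#' records, per voltage, the distance from the score to the decision
#' boundary (midpoint of the class means) in units of the assigned
#' class's calibrated sd.
#'
#' @param fp A [build_fingerprint()] result.
#' @param calib A [calibration_table()].
#' @return An object of class `ciu_classification`.
#' @export
classify_inhibitor <- function(fp, calib = default_calibration()) {
  stopifnot(inherits(fp, "ciu_fingerprint"))
  volts <- unique(calib$voltage)
  missing <- setdiff(volts, fp$per_voltage$voltage)
  if (length(missing))
    stop_input("fingerprint for '", fp$inhibitor,
               "' lacks scores at ", paste(missing, collapse = ", "), " V")
  calls <- character(); scores <- numeric(); notes <- character()
  for (v in volts) {
    s <- fp$per_voltage$mean[fp$per_voltage$voltage == v]
    cl <- classify_voltage(s, v, calib)
    rows <- calib[calib$voltage == v, ]
    mid <- mean(rows$mean)
    sd_cl <- if (cl == "ambiguous") mean(rows$sd)
             else rows$sd[rows$class == cl]
    notes <- c(notes, sprintf("%g V: %.1f%% -> %s (%.2f class-sd from boundary)",
                              v, s, cl, abs(s - mid) / sd_cl))
    calls <- c(calls, cl); scores <- c(scores, s)
  }
  names(calls) <- names(scores) <- volts
  overall <- if (length(unique(calls)) == 1 && calls[1] != "ambiguous")
    calls[[1]] else "ambiguous"
  structure(list(inhibitor = fp$inhibitor, call = overall,
                 per_voltage_call = calls, scores = scores,
                 confidence_note = paste(notes, collapse = "; ")),
            class = "ciu_classification")
}

#' @export
print.ciu_classification <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$inhibitor, x$call))
  for (v in names(x$per_voltage_call))
    cat(sprintf("  %s V: %.1f%% -> %s\n", v, x$scores[[v]],
                x$per_voltage_call[[v]]))
  invisible(x)
}

#' Classify a panel of fingerprints
#'
#' @param fingerprints List of [build_fingerprint()] results with unique
#'   inhibitor names.
#' @param calib A [calibration_table()].
#' @return An object of class `ciu_panel_result`: per-inhibitor
#'   classifications, a summary data.frame and class counts.
#' @export
classify_panel <- function(fingerprints, calib = default_calibration()) {
  if (length(fingerprints) == 0) stop_input("empty panel")
  nm <- vapply(fingerprints, `[[`, character(1), "inhibitor")
  if (anyDuplicated(nm))
    stop_input("duplicate inhibitor names: ",
               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  results <- lapply(fingerprints, classify_inhibitor, calib = calib)
  volts <- unique(calib$voltage)
  tab <- do.call(rbind, lapply(results, function(r) {
    row <- data.frame(inhibitor = r$inhibitor, call = r$call,
                      stringsAsFactors = FALSE)
    for (v in volts) {
      row[[sprintf("score_%gV", v)]] <- r$scores[[as.character(v)]]
      row[[sprintf("call_%gV", v)]] <- r$per_voltage_call[[as.character(v)]]
    }
    row
  }))
  counts <- table(factor(tab$call,
                         levels = c("type_I", "type_II", "ambiguous")))
  structure(list(results = results, summary = tab, counts = counts,
                 calibration = calib),
            class = "ciu_panel_result")
}

#' @export
print.ciu_panel_result <- function(x, ...) {
  cat("CIU screen panel result\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("counts: %s\n",
              paste(names(x$counts), as.integer(x$counts), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.ciu_panel_result <- function(object, ...) object$summary
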