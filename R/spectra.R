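## Native mass-spectrum processing: peak picking, charge-state assignment,
## mass determination, and apo/holo quantitation.

#' Native mass spectrum container
#'
#' @param mz m/z axis (Th), strictly increasing.
#' @param intensity Intensities (counts), nonnegative, same length as `mz`.
#' @param trap_voltage Acquisition trap voltage (V), metadata.
#' @param sample_id Sample label, metadata.
#' @return An object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, trap_voltage = NA_real_,
                          sample_id = "") {
  if (length(mz) != length(intensity))
    stop_input("mz and intensity must have equal length")
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop_input("mz must be strictly increasing")
  if (any(intensity < 0)) stop_input("intensities must be >= 0")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 trap_voltage = trap_voltage, sample_id = sample_id),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum: %d points, m/z %.1f-%.1f%s>\n",
              length(x$mz), min(x$mz), max(x$mz),
              if (nzchar(x$sample_id)) paste0(", ", x$sample_id) else ""))
  invisible(x)
}

#' @export
plot.mass_spectrum <- function(x, ...) {
  plot(x$mz, x$intensity, type = "l", xlab = "m/z (Th)",
       ylab = "intensity", main = x$sample_id, ...)
  invisible(x)
}

#' Pick peaks from a profile spectrum
#'
#' Local maxima above `min_rel_height` times the base-peak height,
#' centroided by three-point parabolic interpolation. Detection and
#' centroiding run on a lightly Savitzky-Golay-smoothed copy of the trace
#' so that acquisition noise on peak flanks does not split peaks; maxima
#' closer together than `min_separation` are merged, keeping the highest.
#' Peak areas are trapezoidal integrals between the flanking local minima.
#'
#' @param spectrum A [mass_spectrum()].
#' @param min_rel_height Detection threshold as a fraction of the base
#'   peak, in (0, 1).
#' @param min_separation Minimum spacing between reported peaks (Th);
#'   native protein charge-state and adduct peaks are tens of Th apart,
#'   so the default suppresses flank shoulders without merging species.
#' @return data.frame with columns `mz`, `height`, `area`, sorted by m/z;
#'   empty for an empty or flat spectrum.
#' @export
pick_peaks <- function(spectrum, min_rel_height = 0.05,
                       min_separation = 10) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (min_rel_height <= 0 || min_rel_height >= 1)
    stop_input("min_rel_height must be in (0, 1)")
  y_raw <- spectrum$intensity
  x <- spectrum$mz
  empty <- data.frame(mz = numeric(0), height = numeric(0),
                      area = numeric(0))
  if (length(y_raw) < 3 || max(y_raw) <= 0) return(empty)
  y <- if (length(y_raw) >= 9)
    pmax(signal::sgolayfilt(y_raw, p = 2, n = 7), 0) else y_raw
  if (max(y) <= 0) return(empty)
  thr <- min_rel_height * max(y)
  n <- length(y)
  i <- 2:(n - 1)
  apex <- i[y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] >= thr]
  if (length(apex) == 0) return(empty)
  # merge maxima closer than min_separation, keeping the highest
  apex <- apex[order(-y[apex])]
  kept <- integer(0)
  for (k in apex) {
    if (all(abs(x[k] - x[kept]) >= min_separation)) kept <- c(kept, k)
  }
  apex <- sort(kept)

  out <- lapply(apex, function(k) {
    y0 <- y[k - 1]; y1 <- y[k]; y2 <- y[k + 1]
    denom <- y0 - 2 * y1 + y2
    delta <- if (denom < 0) 0.5 * (y0 - y2) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    step <- if (delta >= 0) x[k + 1] - x[k] else x[k] - x[k - 1]
    mz_c <- x[k] + delta * step
    h_c <- y1 - 0.25 * (y0 - y2) * delta
    # integration bounds: nearest local minima (or trace ends)
    lo <- k; while (lo > 1 && y[lo - 1] < y[lo]) lo <- lo - 1
    hi <- k; while (hi < n && y[hi + 1] < y[hi]) hi <- hi + 1
    idx <- lo:hi
    area <- sum(diff(x[idx]) * (head(y[idx], -1) + tail(y[idx], -1)) / 2)
    data.frame(mz = mz_c, height = h_c, area = area)
  })
  res <- do.call(rbind, out)
  res[order(res$mz), , drop = FALSE]
}

#' Assign charge states and determine species masses
#'
#' For every pair of picked peaks the real-valued charge consistent with
#' the pair being consecutive charge states of one species is solved from
#' the peak spacing: for m/z values mz_hi > mz_lo carrying charges z and
#' z + 1, `z = (mz_lo - m_p) / (mz_hi - mz_lo)`. Solutions within
#' `charge_tol` of an integer seed candidate pairs, which are clustered by
#' implied neutral mass; accepted species must span consecutive integer
#' charges. Peaks that join no species are reported, not silently dropped.
#'
#' @param peaks data.frame from [pick_peaks()].
#' @param max_charge Highest charge considered.
#' @param charge_tol Tolerance on the real-valued charge solution before
#'   integer rounding.
#' @param mass_window Neutral-mass clustering window (Da).
#' @return List of `charge_assignment` objects sorted by mean mass, with
#'   `species_label` `"apo"` for the lightest and `"holo"` otherwise.
#'   Attribute `"unassigned"` holds the unassigned peak rows.
#' @export
assign_charge_states <- function(peaks, max_charge = 30, charge_tol = 0.2,
                                 mass_window = 10) {
  if (nrow(peaks) < 2) {
    out <- list()
    attr(out, "unassigned") <- peaks
    return(out)
  }
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  np <- nrow(peaks)

  # candidate consecutive-charge pairs
  cand <- list()
  for (j in seq_len(np - 1)) {        # lower m/z (higher charge z + 1)
    for (i in (j + 1):np) {           # higher m/z (charge z)
      dz <- peaks$mz[i] - peaks$mz[j]
      zr <- (peaks$mz[j] - PROTON_MASS) / dz
      z <- round(zr)
      if (z < 1 || z + 1 > max_charge) next
      if (abs(zr - z) > charge_tol) next
      m_hi <- z * (peaks$mz[i] - PROTON_MASS)
      m_lo <- (z + 1) * (peaks$mz[j] - PROTON_MASS)
      cand[[length(cand) + 1L]] <- data.frame(
        p_hi = i, p_lo = j, z = z, mass = (m_hi + m_lo) / 2,
        err = abs(zr - z))
    }
  }
  if (length(cand) == 0) {
    out <- list()
    attr(out, "unassigned") <- peaks
    return(out)
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$mass), , drop = FALSE]
  cl <- cumsum(c(1, diff(cand$mass) > mass_window))

  clusters <- lapply(split(cand, cl), function(g) {
    # peak -> charge votes; consistent pairs only
    ch <- integer(np); ch[] <- NA_integer_
    g <- g[order(g$err), , drop = FALSE]
    for (r in seq_len(nrow(g))) {
      zi <- g$z[r]; i <- g$p_hi[r]; j <- g$p_lo[r]
      ok_i <- is.na(ch[i]) || ch[i] == zi
      ok_j <- is.na(ch[j]) || ch[j] == zi + 1L
      if (ok_i && ok_j) { ch[i] <- zi; ch[j] <- zi + 1L }
    }
    members <- which(!is.na(ch))
    if (length(members) < 2) return(NULL)
    # keep the longest consecutive-charge run
    ord <- members[order(ch[members])]
    runs <- split(ord, cumsum(c(1, diff(ch[ord]) != 1)))
    run <- runs[[which.max(lengths(runs))]]
    if (length(run) < 2) return(NULL)
    z <- ch[run]
    pcm <- z * (peaks$mz[run] - PROTON_MASS)
    list(peaks = run, charges = z, per_charge_mass = pcm,
         mean_mass = mean(pcm), mass_sd = sd(pcm),
         heights = peaks$height[run])
  })
  clusters <- Filter(Negate(is.null), clusters)
  if (length(clusters) == 0) {
    out <- list()
    attr(out, "unassigned") <- peaks
    return(out)
  }
  # larger, tighter clusters win contested peaks
  ord <- order(-vapply(clusters, function(s) length(s$peaks), numeric(1)),
               vapply(clusters, function(s) s$mass_sd %||% Inf, numeric(1)))
  used <- logical(np)
  kept <- list()
  for (s in clusters[ord]) {
    if (any(used[s$peaks])) next
    used[s$peaks] <- TRUE
    kept[[length(kept) + 1L]] <- s
  }
  kept <- kept[order(vapply(kept, `[[`, numeric(1), "mean_mass"))]
  for (i in seq_along(kept)) {
    kept[[i]]$species_label <- if (i == 1) "apo" else "holo"
    class(kept[[i]]) <- "charge_assignment"
  }
  attr(kept, "unassigned") <- peaks[!used, , drop = FALSE]
  kept
}

#' @export
print.charge_assignment <- function(x, ...) {
  cat(sprintf("<charge_assignment (%s): z = %s, mass = %.2f Da (sd %.3g)>\n",
              x$species_label, paste(x$charges, collapse = ","),
              x$mean_mass, x$mass_sd %||% NA_real_))
  invisible(x)
}

#' Ligand mass from apo and holo species masses
#'
#' @param apo,holo `charge_assignment` objects for the unbound protein and
#'   the 1:1 complex.
#' @return Ligand mass (Da) with attribute `"sd"`, the propagated
#'   uncertainty `sqrt(sd_apo^2 + sd_holo^2)`.
#' @export
measure_ligand_mass <- function(apo, holo) {
  stopifnot(inherits(apo, "charge_assignment"),
            inherits(holo, "charge_assignment"))
  dm <- holo$mean_mass - apo$mean_mass
  if (dm < 0)
    stop_analysis("holo species lighter than apo: species mis-assignment")
  structure(dm, sd = sqrt((apo$mass_sd %||% 0)^2 + (holo$mass_sd %||% 0)^2))
}

#' Bound fraction from apo/holo peak heights
#'
#' Ratio of summed holo peak heights to the total (apo + holo); peak
#' heights rather than areas follow the convention of quantifying species
#' by peak intensity.
#'
#' @param apo A `charge_assignment` for the unbound protein.
#' @param holo A `charge_assignment` for the complex, or `NULL` when no
#'   bound species is observed (bound fraction 0).
#' @return Scalar bound fraction in \[0, 1\].
#' @export
quantify_bound_fraction <- function(apo, holo = NULL) {
  stopifnot(inherits(apo, "charge_assignment"))
  apo_sum <- sum(apo$heights)
  holo_sum <- if (is.null(holo)) 0 else sum(holo$heights)
  if (apo_sum + holo_sum <= 0)
    stop_analysis("bound fraction undefined: all species intensities zero")
  holo_sum / (apo_sum + holo_sum)
}
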