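#' Titration dataset container
#'
#' Holds a concentration--response series from one of the three affinity
#' assays used in the screen: per-injection heats (ITC), equilibrium
#' responses (SPR), or normalised fluorescence (MST).
#'
#' @param assay One of `"itc"`, `"spr"`, `"mst"`.
#' @param x Numeric predictor: injection index (ITC) or analyte
#'   concentration in molar (SPR/MST).
#' @param y Numeric response: injection heat in ucal (ITC), response units
#'   (SPR), or Fnorm (MST).
#' @param replicate Integer replicate id per observation.
#' @param meta List of design metadata. For ITC this must contain the cell
#'   and syringe concentrations (M), cell volume and injection volume (uL)
#'   and the number of injections; for MST the protein concentration (M).
#'
#' @return An object of class `titration_dataset`.
#' @export
titration_dataset <- function(assay, x, y, replicate = rep(1L, length(x)),
                              meta = list()) {
  assay <- match.arg(assay, c("itc", "spr", "mst"))
  if (length(x) != length(y) || length(x) != length(replicate))
    stop_input("x, y and replicate must have equal length")
  if (assay != "itc" && any(x < 0))
    stop_input("concentrations must be >= 0")
  structure(list(assay = assay, x = as.numeric(x), y = as.numeric(y),
                 replicate = as.integer(replicate), meta = meta),
            class = "titration_dataset")
}

#' @export
print.titration_dataset <- function(x, ...) {
  cat(sprintf("<titration_dataset: %s, %d observations, %d replicate(s)>\n",
              x$assay, length(x$x), length(unique(x$replicate))))
  invisible(x)
}

## ---- ITC one-site model ----------------------------------------------------

#' ITC design descriptor
#'
#' @param cell_conc Protein concentration in the cell (M).
#' @param syringe_conc Ligand concentration in the syringe (M).
#' @param cell_volume Active cell volume (uL).
#' @param inj_volume Volume of each injection (uL).
#' @param n_inj Number of injections.
#' @return A list with the design fields, class `itc_design`.
#' @export
itc_design <- function(cell_conc = 20e-6, syringe_conc = 200e-6,
                       cell_volume = 200, inj_volume = 2, n_inj = 19) {
  if (cell_conc <= 0 || syringe_conc <= 0 || cell_volume <= 0 ||
      inj_volume <= 0 || n_inj < 1)
    stop_input("all ITC design quantities must be positive")
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 cell_volume = cell_volume, inj_volume = inj_volume,
                 n_inj = as.integer(n_inj)),
            class = "itc_design")
}

# Displaced-volume concentration bookkeeping (Origin/Microcal convention).
# v: cumulative injected volume (uL); V0: cell volume (uL).
itc_concentrations <- function(design) {
  v <- cumsum(rep(design$inj_volume, design$n_inj))
  V0 <- design$cell_volume
  list(Mt = design$cell_conc * (1 - v / (2 * V0)) / (1 + v / (2 * V0)),
       Xt = design$syringe_conc * (v / V0) * (1 - v / (2 * V0)),
       v = v, V0 = V0)
}

#' Per-injection heats for the one-site ITC binding model
#'
#' Computes the cumulative heat of a one-site binding isotherm under the
#' displaced-volume dilution scheme and differences it into per-injection
#' heats, including the Origin-style correction for heat carried out of the
#' active volume by each injection:
#' \deqn{\Delta Q_i = Q_i + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2} - Q_{i-1}}
#'
#' @param kd Dissociation constant (M).
#' @param n_stoich Binding stoichiometry (sites per protein).
#' @param dH Molar binding enthalpy (kcal/mol).
#' @param design An [itc_design()].
#' @return Numeric vector of injection heats in ucal.
#' @export
itc_heats <- function(kd, n_stoich, dH, design = itc_design()) {
  if (kd <= 0) stop_input("kd must be > 0")
  conc <- itc_concentrations(design)
  cval <- n_stoich * design$cell_conc / kd
  if (is.finite(cval) && cval > 1e6)
    warning("c-value ", format(cval, digits = 3),
            " > 1e6: isotherm is numerically rectangular", call. = FALSE)
  V0_L <- design$cell_volume * 1e-6
  r <- conc$Xt / (n_stoich * conc$Mt)
  k <- kd / (n_stoich * conc$Mt)
  disc <- (1 + r + k)^2 - 4 * r
  if (any(disc < 0)) {
    warning("negative discriminant clamped at 0", call. = FALSE)
    disc <- pmax(disc, 0)
  }
  # cumulative heat (kcal) referenced to the active cell volume
  Q <- (n_stoich * conc$Mt * dH * V0_L / 2) * (1 + r + k - sqrt(disc))
  Qprev <- c(0, Q[-length(Q)])
  dV <- rep(design$inj_volume, design$n_inj)
  dQ <- Q + (dV / design$cell_volume) * (Q + Qprev) / 2 - Qprev
  dQ * 1e9  # kcal -> ucal
}

#' Fit the one-site ITC binding model
#'
#' Nonlinear least squares over (Kd, n, dH) for per-injection heats, with
#' standard errors from the curvature at the optimum. Kd is fitted on the
#' log scale to enforce positivity. Fits with a Wiseman c-value outside
#' \[1, 1000\] are returned with a reliability warning.
#'
#' @param data A [titration_dataset()] with `assay = "itc"`; `data$meta`
#'   must carry the design fields (as written by [simulate_itc()]).
#' @return An `affinity_fit` object.
#' @export
fit_itc_one_site <- function(data) {
  stopifnot(inherits(data, "titration_dataset"), data$assay == "itc")
  design <- do.call(itc_design, data$meta[c("cell_conc", "syringe_conc",
                                            "cell_volume", "inj_volume",
                                            "n_inj")])
  y <- data$y
  if (length(y) < 6) stop_input("need at least 6 injections to fit")
  if (all(abs(y) < .Machine$double.eps * 100))
    stop_analysis("all injection heats are zero: no signal to fit")

  dH0 <- sum(y) * 1e-9 /
    (design$syringe_conc * design$inj_volume * 1e-6 * design$n_inj)
  dH0 <- if (abs(dH0) < 1e-3) sign(sum(y) + .5) * -1 else dH0
  # coarse Kd grid start, then Levenberg-Marquardt refinement
  kd_grid <- 10^seq(-10, -4, by = 0.5)
  sse <- vapply(kd_grid, function(k)
    sum((y - suppressWarnings(itc_heats(k, 1, dH0, design)))^2),
    numeric(1))
  kd0 <- kd_grid[which.min(sse)]

  df <- data.frame(i = seq_along(y), y = y)
  # model-evaluation warnings during optimisation are not informative;
  # the fitted c-value is checked explicitly below
  fit <- suppressWarnings(minpack.lm::nlsLM(
    y ~ itc_heats(exp(lkd), n, dH, design),
    data = df,
    start = list(lkd = log(kd0), n = 1, dH = dH0),
    lower = c(lkd = log(1e-13), n = 0.05, dH = -1e4),
    upper = c(lkd = log(1), n = 20, dH = 1e4),
    control = minpack.lm::nls.lm.control(maxiter = 200)))

  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  kd <- exp(est[["lkd"]])
  warn <- character()
  cval <- est[["n"]] * design$cell_conc / kd
  if (cval < 1 || cval > 1000)
    warn <- c(warn, sprintf(
      "Wiseman c-value %.3g outside [1, 1000]: Kd poorly constrained by this design",
      cval))
  new_affinity_fit(
    assay = "itc", kd = kd, kd_se = kd * se[["lkd"]],
    params = c(n = unname(est[["n"]]), dH = unname(est[["dH"]])),
    param_se = c(n = unname(se[["n"]]), dH = unname(se[["dH"]])),
    fitted = unname(predict(fit)), data = data,
    warnings = warn, fit = fit)
}

## ---- SPR 1:1 steady state --------------------------------------------------

#' Equilibrium SPR response for a 1:1 interaction
#'
#' @param kd Dissociation constant (M).
#' @param rmax Saturating response (RU).
#' @param conc Analyte concentration(s) (M).
#' @return Response(s) in RU: `rmax * conc / (kd + conc)`.
#' @export
spr_req <- function(kd, rmax, conc) {
  if (kd <= 0) stop_input("kd must be > 0")
  rmax * conc / (kd + conc)
}

#' Fit the 1:1 steady-state SPR affinity model
#'
#' Least squares of equilibrium responses over (Kd, Rmax). A design whose
#' top concentration does not reach Kd leaves the plateau unobserved; such
#' fits are flagged unreliable.
#'
#' @param data A [titration_dataset()] with `assay = "spr"`.
#' @return An `affinity_fit` object.
#' @export
fit_spr_steady_state <- function(data) {
  stopifnot(inherits(data, "titration_dataset"), data$assay == "spr")
  conc <- data$x; y <- data$y
  if (length(unique(conc)) < 5)
    stop_input("need at least 5 distinct concentrations")
  if (all(y <= 0)) stop_analysis("responses nonpositive everywhere")

  kd0 <- stats::approx(y / max(y), conc, xout = 0.5, ties = mean)$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(conc)
  df <- data.frame(conc = conc, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ rmax * conc / (exp(lkd) + conc), data = df,
    start = list(lkd = log(kd0), rmax = max(y)),
    lower = c(lkd = log(1e-13), rmax = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 2))
  kd <- exp(est[["lkd"]])
  warn <- character()
  if (max(conc) < kd)
    warn <- c(warn,
              sprintf("top concentration %.3g M below fitted Kd %.3g M: fit unreliable (plateau unobserved)",
                      max(conc), kd))
  new_affinity_fit(
    assay = "spr", kd = kd, kd_se = kd * se[["lkd"]],
    params = c(rmax = unname(est[["rmax"]])),
    param_se = c(rmax = unname(se[["rmax"]])),
    fitted = unname(predict(fit)), data = data,
    warnings = warn, fit = fit)
}

## ---- MST Hill (n = 1) ------------------------------------------------------

#' Fraction bound from MST normalised fluorescence
#'
#' @param fnorm Observed Fnorm value(s) (Fhot/Fcold).
#' @param fnorm_unbound Fnorm of the free protein.
#' @param fnorm_bound Fnorm of the saturated complex.
#' @return `(fnorm - fnorm_unbound) / (fnorm_bound - fnorm_unbound)`.
#' @export
mst_fraction_bound <- function(fnorm, fnorm_unbound, fnorm_bound) {
  if (fnorm_bound == fnorm_unbound)
    stop_input("no signal window: fnorm_bound equals fnorm_unbound")
  (fnorm - fnorm_unbound) / (fnorm_bound - fnorm_unbound)
}

#' Fit the MST binding model (Hill coefficient fixed at 1)
#'
#' Fits `Fnorm(C) = F0 + (F1 - F0) * C / (Kd + C)` over (Kd, F0, F1); with
#' n = 1 this is the standard no-depletion hyperbolic isotherm, valid when
#' the labelled-protein concentration is far below Kd.
#'
#' @param data A [titration_dataset()] with `assay = "mst"`.
#' @return An `affinity_fit` object.
#' @export
fit_mst_hill <- function(data) {
  stopifnot(inherits(data, "titration_dataset"), data$assay == "mst")
  conc <- data$x; y <- data$y
  ord <- order(conc)
  f0 <- mean(y[ord][seq_len(min(2, length(y)))])
  f1 <- mean(y[rev(ord)][seq_len(min(2, length(y)))])
  if (abs(f1 - f0) < .Machine$double.eps * 100)
    stop_analysis("signal window collapsed: response flat across the series")
  frac <- (y - f0) / (f1 - f0)
  kd0 <- stats::approx(pmin(pmax(frac, 0), 1), conc, xout = 0.5,
                       ties = mean)$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(conc)
  df <- data.frame(conc = conc, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ f0 + (f1 - f0) * conc / (exp(lkd) + conc), data = df,
    start = list(lkd = log(kd0), f0 = f0, f1 = f1),
    lower = c(lkd = log(1e-13), f0 = -Inf, f1 = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  if (abs(est[["f1"]] - est[["f0"]]) < 1e-10)
    stop_analysis("signal window collapsed during fit")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  kd <- exp(est[["lkd"]])
  warn <- character()
  pconc <- data$meta$protein_conc
  if (!is.null(pconc) && pconc > kd / 10)
    warn <- c(warn, sprintf(
      "protein concentration %.3g M is not << fitted Kd %.3g M: no-depletion model questionable",
      pconc, kd))
  new_affinity_fit(
    assay = "mst", kd = kd, kd_se = kd * se[["lkd"]],
    params = c(fnorm_unbound = unname(est[["f0"]]),
               fnorm_bound = unname(est[["f1"]])),
    param_se = c(fnorm_unbound = unname(se[["f0"]]),
                 fnorm_bound = unname(se[["f1"]])),
    fitted = unname(predict(fit)), data = data,
    warnings = warn, fit = fit)
}

## ---- affinity_fit class ----------------------------------------------------

new_affinity_fit <- function(assay, kd, kd_se, params, param_se, fitted,
                             data, warnings = character(), fit = NULL) {
  resid <- data$y - fitted
  obj <- structure(list(assay = assay, kd = kd, kd_se = kd_se,
                        params = params, param_se = param_se,
                        fitted = fitted, residuals = resid,
                        rss = sum(resid^2), data = data,
                        warnings = warnings, fit = fit),
                   class = "affinity_fit")
  for (w in warnings) warning(w, call. = FALSE)
  obj
}

format_kd <- function(kd) {
  if (kd < 1e-6) sprintf("%.3g nM", kd * 1e9) else sprintf("%.3g uM", kd * 1e6)
}

#' @export
print.affinity_fit <- function(x, ...) {
  label <- c(itc = "one-site ITC", spr = "1:1 steady-state SPR",
             mst = "MST Hill (n = 1)")[[x$assay]]
  cat(sprintf("Affinity fit (%s)\n", label))
  cat(sprintf("  Kd = %s (se %s)\n", format_kd(x$kd),
              format_kd(abs(x$kd_se))))
  for (p in names(x$params))
    cat(sprintf("  %s = %.4g (se %.3g)\n", p, x$params[[p]], x$param_se[[p]]))
  cat(sprintf("  RSS = %.4g over %d points\n", x$rss, length(x$fitted)))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.affinity_fit <- function(object, ...) {
  c(kd = object$kd, object$params)
}

#' @export
summary.affinity_fit <- function(object, ...) {
  est <- coef(object)
  se <- c(kd = object$kd_se, object$param_se)
  out <- data.frame(estimate = est, std_error = se[names(est)])
  structure(list(assay = object$assay, coefficients = out, rss = object$rss,
                 n = length(object$fitted), warnings = object$warnings),
            class = "summary.affinity_fit")
}

#' @export
print.summary.affinity_fit <- function(x, ...) {
  cat(sprintf("Affinity fit summary (%s assay, n = %d)\n", x$assay, x$n))
  print(x$coefficients)
  cat(sprintf("Residual sum of squares: %.4g\n", x$rss))
  if (length(x$warnings)) cat("Warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
residuals.affinity_fit <- function(object, ...) object$residuals

#' Model predictions for an affinity fit
#'
#' @param object An `affinity_fit`.
#' @param newdata Optional numeric vector of concentrations (SPR/MST). For
#'   ITC, predictions are always for the fitted injection schedule.
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.affinity_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  switch(object$assay,
    spr = spr_req(object$kd, object$params[["rmax"]], newdata),
    mst = object$params[["fnorm_unbound"]] +
      diff(unname(object$params[c("fnorm_unbound", "fnorm_bound")])) *
      newdata / (object$kd + newdata),
    itc = stop_input("ITC predictions are tied to the injection schedule; call without newdata"))
}

#' @export
plot.affinity_fit <- function(x, ...) {
  d <- x$data
  if (x$assay == "itc") {
    plot(seq_along(d$y), d$y, xlab = "injection", ylab = "heat (ucal)",
         main = "One-site ITC fit", ...)
    lines(seq_along(x$fitted), x$fitted, col = "firebrick")
  } else {
    plot(d$x, d$y, log = "x", xlab = "concentration (M)",
         ylab = if (x$assay == "spr") "response (RU)" else "Fnorm",
         main = sprintf("%s fit, Kd = %s", toupper(x$assay), format_kd(x$kd)),
         ...)
    cs <- exp(seq(log(min(d$x[d$x > 0])), log(max(d$x)), length.out = 100))
    lines(cs, predict(x, cs), col = "firebrick")
    abline(v = x$kd, lty = 3)
  }
  invisible(x)
}

#' Simulate replicate datasets from a fitted affinity model
#'
#' Draws new noisy datasets at the fitted parameter values using the same
#' design as the original data.
#'
#' @param object An `affinity_fit`.
#' @param nsim Number of datasets.
#' @param seed Optional RNG seed.
#' @param noise_sd Standard deviation of the additive Gaussian noise, on
#'   the response scale; defaults to the residual standard deviation.
#' @param ... Unused.
#' @return A list of [titration_dataset()] objects.
#' @export
simulate.affinity_fit <- function(object, nsim = 1, seed = NULL,
                                  noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  noise_sd <- noise_sd %||%
    sqrt(object$rss / max(1, length(object$fitted) - length(coef(object))))
  mu <- object$fitted
  lapply(seq_len(nsim), function(i)
    titration_dataset(object$data$assay, object$data$x,
                      mu + rnorm(length(mu), 0, noise_sd),
                      object$data$replicate, object$data$meta))
}
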