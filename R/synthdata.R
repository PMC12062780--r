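## Seeded forward-model generators for every input the pipeline consumes:
## native spectra, CIU ATD panels with ground truth, and ITC/SPR/MST
## titrations. Raw instrument data for this kind of screen are rarely
## deposited, so the generators emulate the documented acquisition:
## a ~36 kDa kinase domain presenting charges 11+..13+ in one narrow
## envelope, 1:1 ligand adducts, two ATD conformers at 5.5 and 7.6 ms whose
## balance depends on trap voltage and inhibitor class, voltage-dependent
## ligand stripping, and titration curves at realistic Kd values.

#' Noise model for the simulators
#'
#' All noise is additive Gaussian, truncated at zero where the quantity is
#' an intensity.
#'
#' @param spectrum_noise_sd Spectrum noise sd as a fraction of the base
#'   peak (default 0.01).
#' @param atd_noise_sd ATD noise sd as a fraction of the base peak
#'   (default 0.02).
#' @param heat_noise_sd ITC heat noise sd in ucal (default 0.1).
#' @param spr_noise_sd SPR noise sd as a fraction of Rmax (default 0.02).
#' @param mst_noise_sd MST noise sd as a fraction of the Fnorm span
#'   (default 0.01).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(spectrum_noise_sd = 0.01, atd_noise_sd = 0.02,
                        heat_noise_sd = 0.1, spr_noise_sd = 0.02,
                        mst_noise_sd = 0.01) {
  vals <- c(spectrum_noise_sd, atd_noise_sd, heat_noise_sd, spr_noise_sd,
            mst_noise_sd)
  if (any(vals < 0)) stop_input("noise standard deviations must be >= 0")
  structure(list(spectrum_noise_sd = spectrum_noise_sd,
                 atd_noise_sd = atd_noise_sd,
                 heat_noise_sd = heat_noise_sd,
                 spr_noise_sd = spr_noise_sd,
                 mst_noise_sd = mst_noise_sd),
            class = "noise_model")
}

#' Noise-free noise model
#' @return A `noise_model` with every component zero.
#' @export
no_noise <- function() noise_model(0, 0, 0, 0, 0)

#' Inhibitor profile for panel simulation
#'
#' @param name Inhibitor name.
#' @param true_class `"type_I"` ('DFG in' binder) or `"type_II"`
#'   ('DFG out' binder).
#' @param kd Dissociation constant (M).
#' @param ligand_mass Ligand monomer mass (Da).
#' @param unfold_score_truth Optional named numeric: ground-truth unfolded
#'   percent keyed by trap voltage; must be nonnegative and nondecreasing
#'   in voltage. When omitted, [simulate_ciu_panel()] draws it from the
#'   class-calibrated truth model.
#' @return A list of class `inhibitor_profile`.
#' @export
inhibitor_profile <- function(name, true_class = c("type_I", "type_II"),
                              kd, ligand_mass, unfold_score_truth = NULL) {
  true_class <- match.arg(true_class)
  if (kd <= 0) stop_input("kd must be > 0")
  if (!is.null(unfold_score_truth)) {
    v <- as.numeric(names(unfold_score_truth))
    if (anyNA(v)) stop_input("unfold_score_truth must be named by voltage")
    ord <- order(v)
    if (any(unfold_score_truth < 0))
      stop_input("unfold_score_truth values must be >= 0")
    if (is.unsorted(unfold_score_truth[ord]))
      stop_input("unfold_score_truth must be nondecreasing in trap voltage")
  }
  structure(list(name = name, true_class = true_class, kd = kd,
                 ligand_mass = ligand_mass,
                 unfold_score_truth = unfold_score_truth),
            class = "inhibitor_profile")
}

#' Default ten-inhibitor panel
#'
#' Seven type I binders (compounds A--E, JK-P3, JK-P5) and three type II
#' binders (Ponatinib, Linifanib, Sorafenib). Kd values for compound D
#' (36 nM), JK-P3 (25 uM), Ponatinib (8 nM) and Linifanib (37 uM) are the
#' reported affinities of those compounds against FGFR1; the remaining Kd
#' values and the JK-compound/A--E ligand masses are synthetic defaults
#' placed within the observed nM--uM affinity span.
#'
#' @return List of [inhibitor_profile()] objects.
#' @export
default_panel <- function() {
  list(
    inhibitor_profile("A",         "type_I",  120e-9, 412.4),
    inhibitor_profile("B",         "type_I",  350e-9, 389.8),
    inhibitor_profile("C",         "type_I",  1.5e-6, 445.5),
    inhibitor_profile("D",         "type_I",  36e-9,  472.6),
    inhibitor_profile("E",         "type_I",  4.0e-6, 401.3),
    inhibitor_profile("JK-P3",     "type_I",  25e-6,  306.3),
    inhibitor_profile("JK-P5",     "type_I",  2.0e-6, 356.4),
    inhibitor_profile("Ponatinib", "type_II", 8e-9,   532.6),
    inhibitor_profile("Linifanib", "type_II", 37e-6,  375.4),
    inhibitor_profile("Sorafenib", "type_II", 0.5e-6, 464.8)
  )
}

#' Panel specification for the CIU screen simulator
#'
#' @param inhibitors List of [inhibitor_profile()]s; defaults to
#'   [default_panel()].
#' @param voltages Trap voltages (V) at which ATDs are acquired.
#' @param replicates Replicate acquisitions per (inhibitor, voltage).
#' @param seed Integer RNG seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(inhibitors = default_panel(), voltages = c(21, 24),
                       replicates = 3, seed = 1L) {
  if (length(voltages) < 1) stop_input("voltages must be nonempty")
  if (replicates < 1) stop_input("replicates must be >= 1")
  nm <- vapply(inhibitors, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop_input("inhibitor names must be unique")
  structure(list(inhibitors = inhibitors, voltages = sort(voltages),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "panel_spec")
}

## ---- class-calibrated ground-truth model -----------------------------------

# Per (voltage, class) unfolded-percent distribution used to draw ground
# truth: reported class mean and sd, clamped to the reported class range.
# The 21 V type II range is open above in the calibration; the generator
# caps it at 60 so draws stay physical.
truth_table <- function() {
  data.frame(
    voltage = c(21, 21, 24, 24),
    class = c("type_I", "type_II", "type_I", "type_II"),
    mean = c(27.6, 48.9, 44.2, 76.7),
    sd = c(3.9, 4.4, 5.6, 11.6),
    lo = c(22, 40, 30, 64),
    hi = c(35, 60, 50, 95),
    stringsAsFactors = FALSE)
}

#' Ground-truth unfolded percent for a latent stability score
#'
#' A single standard-normal latent score `u` per inhibitor drives its
#' unfolding at every voltage: truth(V) = class mean + u * class sd,
#' clamped to the class range at that voltage. Sharing `u` across voltages
#' models a single gas-phase stability scale and guarantees monotone
#' fingerprints.
#'
#' @param u Latent standard score (scalar or vector).
#' @param class `"type_I"` or `"type_II"`.
#' @param voltage Trap voltage (V); must be 21 or 24.
#' @return Ground-truth unfolded percent.
#' @export
unfold_truth <- function(u, class, voltage) {
  tt <- truth_table()
  row <- tt[tt$voltage == voltage & tt$class == class, ]
  if (nrow(row) != 1)
    stop_input("no truth model for voltage ", voltage, ", class ", class)
  pmin(pmax(row$mean + u * row$sd, row$lo), row$hi)
}

## ---- native mass spectrum --------------------------------------------------

#' Simulate a native ESI mass spectrum of a protein--ligand mixture
#'
#' Produces a profile spectrum with, for each charge z, an apo peak at
#' (M + z m_p)/z and, when `bound_fraction > 0`, a holo peak at
#' (M + L + z m_p)/z. The holo:apo height ratio equals
#' `bound_fraction / (1 - bound_fraction)` and a Gaussian charge-envelope
#' weighting is applied across z (narrow envelopes are the signature of a
#' folded protein). Additive Gaussian noise, truncated at zero, is
#' reproducible under `seed`.
#'
#' @param protein_mass Protein neutral mass (Da).
#' @param ligand_mass Ligand mass (Da).
#' @param bound_fraction Fraction of protein carrying one ligand, in
#'   \[0, 1\].
#' @param charges Integer set of charge states present.
#' @param peak_width Gaussian sd of each m/z peak (Th).
#' @param noise A [noise_model()].
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @param mz_step Grid spacing (Th).
#' @param trap_voltage Recorded acquisition voltage (V), metadata only.
#' @param sample_id Sample label, metadata only.
#' @return A [mass_spectrum()].
#' @export
simulate_native_spectrum <- function(protein_mass, ligand_mass = 0,
                                     bound_fraction = 0, charges = 11:13,
                                     peak_width = 2, noise = noise_model(),
                                     seed = NULL, mz_step = 0.25,
                                     trap_voltage = NA_real_,
                                     sample_id = "") {
  if (protein_mass <= 0) stop_input("protein_mass must be > 0")
  if (length(charges) == 0) stop_input("charge set must be nonempty")
  if (bound_fraction < 0 || bound_fraction > 1)
    stop_input("bound_fraction must be in [0, 1]")
  if (bound_fraction > 0 && ligand_mass <= 0)
    stop_input("bound_fraction > 0 requires a positive ligand_mass")
  if (!is.null(seed)) set.seed(seed)

  charges <- sort(as.integer(charges))
  apo_mz <- (protein_mass + charges * PROTON_MASS) / charges
  holo_mz <- (protein_mass + ligand_mass + charges * PROTON_MASS) / charges
  env_sd <- max(1, (max(charges) - min(charges)) / 2)
  w <- dnorm(charges, mean = mean(range(charges)), sd = env_sd)
  w <- w / max(w)

  centers <- apo_mz
  heights <- w * (1 - bound_fraction)
  if (bound_fraction > 0) {
    centers <- c(centers, holo_mz)
    heights <- c(heights, w * bound_fraction)
  }
  keep <- heights > 0
  centers <- centers[keep]; heights <- heights[keep]

  mz <- seq(min(centers) - 30, max(centers) + 30, by = mz_step)
  intensity <- rep(0, length(mz))
  for (i in seq_along(centers))
    intensity <- intensity +
      heights[i] * exp(-(mz - centers[i])^2 / (2 * peak_width^2))
  if (noise$spectrum_noise_sd > 0) {
    intensity <- intensity +
      rnorm(length(mz), 0, noise$spectrum_noise_sd * max(intensity))
    intensity <- pmax(intensity, 0)
  }
  mass_spectrum(mz, intensity, trap_voltage = trap_voltage,
                sample_id = sample_id)
}

## ---- arrival-time distribution ---------------------------------------------

#' Simulate an arrival-time distribution of two protein conformers
#'
#' Sum of two equal-width Gaussian components, a compact conformer and an
#' extended one, with extended:compact area ratio `unfold_percent / 100`.
#' Equal widths make the area ratio equal to the apex-height ratio.
#'
#' @param unfold_percent Ground-truth extended population as percent of the
#'   compact component (>= 0; 100 means equal areas).
#' @param compact_center,extended_center Component centres (ms).
#' @param width_sd Common Gaussian sd (ms).
#' @param grid Drift-time axis (ms); default 0--14 ms in 0.07 ms steps.
#' @param noise A [noise_model()].
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @param trap_voltage,charge,inhibitor,replicate Acquisition metadata.
#' @return An [atd()] object. If the grid spacing exceeds `width_sd` a
#'   warning is recorded in the object's metadata.
#' @export
simulate_atd <- function(unfold_percent, compact_center = 5.5,
                         extended_center = 7.6, width_sd = 0.35,
                         grid = seq(0, 14, by = 0.07),
                         noise = noise_model(), seed = NULL,
                         trap_voltage = NA_real_, charge = 11L,
                         inhibitor = "", replicate = 1L) {
  if (unfold_percent < 0) stop_input("unfold_percent must be >= 0")
  if (width_sd <= 0) stop_input("width_sd must be > 0")
  if (compact_center < min(grid) || compact_center > max(grid) ||
      extended_center < min(grid) || extended_center > max(grid))
    stop_input("conformer centres must lie within the drift-time grid")
  if (!is.null(seed)) set.seed(seed)

  warns <- character()
  spacing <- max(diff(grid))
  if (spacing > width_sd)
    warns <- c(warns, sprintf(
      "grid spacing %.3g ms exceeds component width %.3g ms: centres may be unresolved",
      spacing, width_sd))

  h_compact <- 100
  h_ext <- unfold_percent  # equal widths: area ratio == height ratio
  intensity <- h_compact * exp(-(grid - compact_center)^2 / (2 * width_sd^2)) +
    h_ext * exp(-(grid - extended_center)^2 / (2 * width_sd^2))
  if (noise$atd_noise_sd > 0) {
    intensity <- intensity +
      rnorm(length(grid), 0, noise$atd_noise_sd * max(intensity))
    intensity <- pmax(intensity, 0)
  }
  atd(grid, intensity, trap_voltage = trap_voltage, charge = charge,
      inhibitor = inhibitor, replicate = replicate, warnings = warns)
}

#' Simulate a CIU panel with ground truth
#'
#' For each inhibitor one latent standard score u ~ Normal(0, 1) is drawn
#' and shared across voltages (see [unfold_truth()]); replicate ATDs then
#' differ only by acquisition noise. An inhibitor profile carrying an
#' explicit `unfold_score_truth` uses it verbatim instead of a draw.
#'
#' @param spec A [panel_spec()].
#' @param noise A [noise_model()].
#' @return A list of class `ciu_panel` with elements `atds` (list of
#'   [atd()]s) and `truth` (data.frame: inhibitor, true_class, voltage,
#'   unfold_truth, u).
#' @export
simulate_ciu_panel <- function(spec = panel_spec(), noise = noise_model()) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  atds <- list()
  truth <- list()
  for (prof in spec$inhibitors) {
    u <- rnorm(1)
    tr <- vapply(spec$voltages, function(v) {
      if (!is.null(prof$unfold_score_truth)) {
        val <- prof$unfold_score_truth[as.character(v)]
        if (is.na(val)) stop_input("profile '", prof$name,
                                   "' has no truth at ", v, " V")
        unname(val)
      } else {
        unfold_truth(u, prof$true_class, v)
      }
    }, numeric(1))
    truth[[length(truth) + 1L]] <- data.frame(
      inhibitor = prof$name, true_class = prof$true_class,
      voltage = spec$voltages, unfold_truth = tr, u = u,
      stringsAsFactors = FALSE)
    for (i in seq_along(spec$voltages)) {
      for (r in seq_len(spec$replicates)) {
        atds[[length(atds) + 1L]] <- simulate_atd(
          tr[i], noise = noise, trap_voltage = spec$voltages[i],
          charge = 11L, inhibitor = prof$name, replicate = r)
      }
    }
  }
  structure(list(atds = atds, truth = do.call(rbind, truth), spec = spec),
            class = "ciu_panel")
}

#' @export
print.ciu_panel <- function(x, ...) {
  cat(sprintf("<ciu_panel: %d inhibitors x %d voltage(s) x %d replicate(s) = %d ATDs>\n",
              length(x$spec$inhibitors), length(x$spec$voltages),
              x$spec$replicates, length(x$atds)))
  invisible(x)
}

#' Simulate voltage-dependent ligand stripping
#'
#' Collisional activation strips noncovalently bound ligand; the retained
#' bound fraction follows a logistic decay in trap voltage:
#' `b(V) = b0 / (1 + exp((V - v50) / steepness))`.
#'
#' @param bound_fraction_0 Bound fraction at low activation, in \[0, 1\].
#' @param voltages Trap voltages (V).
#' @param v50 Voltage of half-maximal stripping (V).
#' @param steepness Transition width (V); must be > 0.
#' @return Named numeric vector of bound fractions, keyed by voltage;
#'   strictly nonincreasing in V.
#' @export
simulate_stripping_series <- function(bound_fraction_0, voltages,
                                      v50 = 18, steepness = 3) {
  if (bound_fraction_0 < 0 || bound_fraction_0 > 1)
    stop_input("bound_fraction_0 must be in [0, 1]")
  if (steepness <= 0) stop_input("steepness must be > 0")
  b <- bound_fraction_0 / (1 + exp((voltages - v50) / steepness))
  setNames(b, voltages)
}

## ---- titrations ------------------------------------------------------------

#' Simulate a one-site ITC titration
#'
#' Per-injection heats from the one-site model ([itc_heats()]) with the
#' displaced-volume dilution scheme, plus additive heat noise. The default
#' design is 2 uL injections of 200 uM ligand into a 200 uL cell holding
#' 20 uM protein, 19 injections.
#'
#' @param kd Dissociation constant (M).
#' @param n_stoich Stoichiometry.
#' @param dH Binding enthalpy (kcal/mol).
#' @param cell_conc,syringe_conc Concentrations (M).
#' @param cell_volume,inj_volume Volumes (uL).
#' @param n_inj Number of injections.
#' @param noise A [noise_model()] (heat noise in ucal).
#' @param seed Optional seed.
#' @return A [titration_dataset()] with `assay = "itc"`; the design is
#'   stored in `meta`.
#' @export
simulate_itc <- function(kd, n_stoich = 1, dH = -10, cell_conc = 20e-6,
                         syringe_conc = 200e-6, cell_volume = 200,
                         inj_volume = 2, n_inj = 19,
                         noise = noise_model(), seed = NULL) {
  design <- itc_design(cell_conc, syringe_conc, cell_volume, inj_volume,
                       n_inj)
  if (!is.null(seed)) set.seed(seed)
  q <- itc_heats(kd, n_stoich, dH, design)
  if (noise$heat_noise_sd > 0)
    q <- q + rnorm(length(q), 0, noise$heat_noise_sd)
  titration_dataset("itc", seq_along(q), q,
                    meta = c(unclass(design),
                             list(kd_truth = kd, n_truth = n_stoich,
                                  dH_truth = dH)))
}

#' Simulate an SPR equilibrium dosing series
#'
#' Equilibrium responses `Req(C) = rmax C / (kd + C)` over a geometric
#' dilution series, replicated. The default design is the standard
#' 256-fold range covered by a 2-fold series (nine concentrations),
#' injected in triplicate.
#'
#' @param kd Dissociation constant (M).
#' @param rmax Saturating response (RU).
#' @param top_conc Highest analyte concentration (M).
#' @param fold_range Ratio of highest to lowest concentration.
#' @param dilution_factor Step of the dilution series.
#' @param replicates Injections per concentration.
#' @param noise A [noise_model()].
#' @param seed Optional seed.
#' @return A [titration_dataset()] with `assay = "spr"`.
#' @export
simulate_spr <- function(kd, rmax = 100, top_conc = 500e-6,
                         fold_range = 256, dilution_factor = 2,
                         replicates = 3, noise = noise_model(),
                         seed = NULL) {
  if (top_conc <= 0) stop_input("top_conc must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n_conc <- round(log(fold_range) / log(dilution_factor)) + 1L
  conc <- top_conc / dilution_factor^(seq_len(n_conc) - 1L)
  x <- rep(conc, times = replicates)
  rep_id <- rep(seq_len(replicates), each = n_conc)
  y <- spr_req(kd, rmax, x)
  if (noise$spr_noise_sd > 0)
    y <- y + rnorm(length(y), 0, noise$spr_noise_sd * rmax)
  titration_dataset("spr", x, y, rep_id,
                    meta = list(kd_truth = kd, rmax_truth = rmax))
}

#' Simulate an MST dose--response series
#'
#' `Fnorm(C) = F_unbound + (F_bound - F_unbound) C / (kd + C)` plus noise.
#' The no-depletion form assumes the labelled-protein concentration is far
#' below Kd; a warning is issued otherwise.
#'
#' @param kd Dissociation constant (M).
#' @param fnorm_unbound,fnorm_bound Fnorm of free and saturated protein
#'   (per mil scale by convention); must differ.
#' @param protein_conc Labelled protein concentration (M; default 60 nM).
#' @param conc_series Ligand concentrations (M); default 16-point 2-fold
#'   series topping at 500 uM.
#' @param noise A [noise_model()].
#' @param seed Optional seed.
#' @return A [titration_dataset()] with `assay = "mst"`.
#' @export
simulate_mst <- function(kd, fnorm_unbound = 850, fnorm_bound = 910,
                         protein_conc = 60e-9,
                         conc_series = 500e-6 / 2^(0:15),
                         noise = noise_model(), seed = NULL) {
  if (fnorm_bound == fnorm_unbound)
    stop_input("no signal window: fnorm_bound equals fnorm_unbound")
  if (protein_conc > kd / 10)
    warning("protein concentration is not << kd: no-depletion model questionable",
            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- fnorm_unbound + (fnorm_bound - fnorm_unbound) *
    conc_series / (kd + conc_series)
  if (noise$mst_noise_sd > 0)
    y <- y + rnorm(length(y), 0,
                   noise$mst_noise_sd * abs(fnorm_bound - fnorm_unbound))
  titration_dataset("mst", conc_series, y,
                    meta = list(protein_conc = protein_conc,
                                kd_truth = kd))
}
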