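---
title: "Classifying kinase inhibitor binding mode from CIU fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying kinase inhibitor binding mode from CIU fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciuscreen)
```

## The measurement

Protein kinases toggle between an active conformation, in which the
conserved Asp-Phe-Gly (DFG) triad points into the ATP site ("DFG in"),
and an inactive one in which the triad is flipped outward ("DFG out").
Type I inhibitors bind the former, type II inhibitors the latter, and
telling the two apart normally requires a co-crystal structure — which
frequently fails for type II complexes precisely because the activation
loop is mobile.

Collision-induced unfolding (CIU) offers a solution in the gas phase. A
natively electrosprayed kinase–inhibitor complex is activated by raising
the trap collision voltage of a travelling-wave ion-mobility mass
spectrometer, and its unfolding is monitored as a shift in the
arrival-time distribution (ATD) of a selected charge state. For the
FGFR1 kinase domain (~36 kDa, charges 11+–13+ in a single narrow
envelope) the 11+ ion populates two conformers under activation: a
compact one at 5.5 ms and an extended one at 7.6 ms. Type II binding
stabilises a conformation that, once the ligand is stripped, unfolds
more readily — so at a fixed voltage the extended population is
systematically larger for type II complexes than for type I. That
difference is the screen.

## The two-conformer model

`fit_two_conformers()` models an ATD as two Gaussians with a shared
width:

$$ I(t) = h_c\, e^{-(t-c_c)^2/2s^2} + h_e\, e^{-(t-c_e)^2/2s^2} $$

The readout, `unfolded_percent()`, is the extended area as a percentage
of the compact base peak, $U = 100\,A_e/A_c$. Two phrasings of this
metric circulate — relative to the base peak, and relative to the total
ion current — with the same numeric class ranges attached to both. We
adopt the base-peak reading because it is the phrasing that accompanies
the defining class averages; with that convention the calibrated class
statistics are internally consistent, and an equal-area mixture reads
100%, not 50%.

Fitting choices, in order of consequence:

* **Equal widths.** One shared $s$ keeps the model identifiable on a
  200-bin trace and makes the area ratio equal the apex-height ratio.
  Real conformers can differ in width; on simulated data the constraint
  is exact by construction, on real data it trades a small bias for a
  large variance reduction.
* **Constrained centres.** Centres are bounded to the expected
  positions (defaults 5.5 and 7.6 ms) ± 0.3 ms. This encodes the prior
  that the two conformers are known landmarks, and prevents the
  extended component from wandering onto noise when its amplitude is
  near zero.
* **Initialisation.** Start heights are read off a Savitzky–Golay
  smoothed copy of the trace (window 5, order 2) at the expected
  centres; the fit itself runs on raw data. Start heights are floored
  at 2% of the trace maximum because a zero-height start makes the
  centre gradient vanish and the normal equations singular.
* **Optimiser.** Bounded Levenberg–Marquardt on the residual function
  (`minpack.lm::nls.lm`). The raw interface is used deliberately: at a
  degenerate optimum the extended height sits exactly on its zero
  bound, which is a legitimate answer, not a failure.
* **Detection floor.** A fitted extended area below $10^{-3}$ of the
  compact area is reported as exactly zero — never negative — so a
  single-conformer trace quantifies to 0%.

## The decision rule

The calibration (`default_calibration()`) stores, per voltage and
class, the mean, standard deviation and range of the unfolded
percentage: at 21 V, type I 27.6% (sd 3.9, range 22–35) vs type II
48.9% (sd 4.4, above 40); at 24 V, type I 44.2% (sd 5.6, 30–50) vs
type II 76.7% (sd 11.6, 64–95). `classify_voltage()` assigns the class
whose mean is nearer; `classify_inhibitor()` applies this to the
replicate-mean score at every calibrated voltage and requires all
voltages to agree, otherwise returning `ambiguous`.

Nearest-mean-with-agreement was a genuine design choice: the source
calibration reports clear separation at each voltage independently and
no fused score, so we classify per voltage and treat disagreement as a
first-class screening outcome (triage semantics) rather than forcing a
binary. No explicit numeric boundary is published; the nearest-mean
rule is this package's formalisation of "clearly separated", and one
can verify that every score inside a calibrated class range is assigned
that class. The calibration is data (JSON-serialisable via
`write_calibration()`), so the same machinery recalibrates to other
kinases.

## What the simulator emulates — and what it does not

The generators exist because raw data for this kind of screen are
rarely deposited. They reproduce the statistical structure the analysis
assumes:

* **Spectra.** Gaussian peaks at $(M + z m_p)/z$ (average-mass proton,
  $m_p = 1.00728$ Da) for apo and 1:1 holo species, a Gaussian charge
  envelope across 11+–13+, holo:apo heights in the odds ratio of the
  bound fraction, additive truncated-Gaussian noise (default sd 1% of
  base peak).
* **ATDs.** The two-conformer model itself, width 0.35 ms, on a 0–14 ms
  grid with 0.07 ms spacing (200 bins), noise sd 2% of base peak.
* **Panels.** Each inhibitor draws one latent standard score
  $u \sim N(0,1)$ shared across voltages; its ground truth at voltage
  $V$ is the class mean plus $u$ times the class sd, clamped to the
  class range (the open 21 V type II range is capped at 60%). The
  shared score models a single gas-phase stability scale, guarantees
  that every inhibitor unfolds more at 24 V than at 21 V, and puts all
  inter-inhibitor variance in the truth and all replicate variance in
  the noise — a split the source statistics do not resolve, adopted
  here as the simplest mechanism consistent with them. Clamping (rather
  than redrawing) preserves the monotone mapping from $u$; the implied
  truncation shift of the class means is at most ~1.4 points, well
  inside the recovery tolerances used in the tests.
* **Stripping.** Bound fraction decays logistically in voltage,
  $b(V) = b_0/(1+e^{(V-v_{50})/k})$, mimicking collisional ligand loss.
* **Titrations.** ITC: 19 × 2 µL of 200 µM ligand into 200 µL of 20 µM
  protein (cell volume and injection count are instrument-typical
  values, fixed here as defaults), one-site cumulative heats under
  Origin-style displaced-volume dilution, heat noise 0.1 µcal. SPR:
  nine concentrations spanning a 256-fold range by 2-fold dilution, in
  triplicate. MST: 60 nM protein, hyperbolic (Hill n = 1) Fnorm
  response. Named Kd defaults (Ponatinib 8 nM, compound D 36 nM,
  Linifanib 37 µM, JK-P3 25 µM) are reported affinities; the remaining
  six are synthetic values placed in the same nM–µM span.

The simulator does **not** model isotope structure, salt adducts,
overlapping envelopes of unrelated proteins, drift-time calibration to
collision cross-sections, SPR kinetics (kon/koff), ITC baseline
integration from power traces, or ligand depletion in MST. Passing
tests therefore demonstrate that the pipeline inverts its own forward
model and reproduces the calibrated statistics under realistic noise —
not that it is robust to every artefact of real instrument data.

## Affinity models

`itc_heats()` implements the one-site cumulative heat

$$ Q = \frac{n M_t \Delta H V_0}{2}\left[1 + \frac{X_t}{nM_t} +
\frac{K_d}{nM_t} - \sqrt{\left(1 + \frac{X_t}{nM_t} +
\frac{K_d}{nM_t}\right)^2 - \frac{4X_t}{nM_t}}\right] $$

with $M_t, X_t$ diluted by the displaced-volume scheme and injection
heats differenced as
$\Delta Q_i = Q_i + \frac{dV_i}{V_0}\frac{Q_i+Q_{i-1}}{2} - Q_{i-1}$.
The test suite checks this against an independent oracle that solves
the binding quadratic for the complex concentration directly. Kd values
are fitted on the log scale (positivity, conditioning); a fitted
Wiseman c-value outside [1, 1000] attaches a reliability warning, as
does an SPR design whose top concentration never reaches Kd, or an MST
protein concentration not far below Kd.

## Problem sizes and determinism

All simulations are seeded and bit-reproducible. The panel-statistics
checks use 200 simulated panels (12 000 ATD fits, tens of seconds on
one core) — enough for the grand means to settle well inside the
tolerances while keeping the default test run quick. Recovery checks on
noiseless data use 1% relative tolerances for Kd and 0.5% for the
unfolded percentage; the ITC model-vs-oracle agreement is checked at
$10^{-6}$ relative.

## Known limitations

* The calibration is specific to FGFR1 at 21/24 V trap voltage; other
  kinases, charge states or instruments need recalibration.
* The classifier is the published two-voltage statistic, deliberately
  not a multivariate CIU-fingerprint model; compounds with genuinely
  intermediate behaviour surface as `ambiguous` rather than being
  resolved.
* Bound-fraction quantitation uses peak heights, matching the
  peak-intensity convention; for peaks of unequal width, areas would
  differ.
* Mass determination assumes a single protein per spectrum; overlapping
  envelopes are out of scope.
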