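# Shared fixtures: all synthetic inputs are generated in code at test time.

# Extract per-inhibitor, per-voltage replicate-mean unfolded scores from a
# seeded default panel by running the full fit pipeline.
panel_scores <- function(seed, noise = noise_model()) {
  panel <- simulate_ciu_panel(panel_spec(seed = seed), noise)
  by_inh <- split(panel$atds,
                  vapply(panel$atds, `[[`, character(1), "inhibitor"))
  rows <- lapply(names(by_inh), function(nm) {
    fp <- build_fingerprint(by_inh[[nm]])
    cls <- panel$truth$true_class[panel$truth$inhibitor == nm][1]
    data.frame(inhibitor = nm, true_class = cls,
               voltage = fp$per_voltage$voltage,
               score = fp$per_voltage$mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Full screen of one seeded panel: overall calls joined with truth.
panel_calls <- function(seed, noise = noise_model()) {
  panel <- simulate_ciu_panel(panel_spec(seed = seed), noise)
  by_inh <- split(panel$atds,
                  vapply(panel$atds, `[[`, character(1), "inhibitor"))
  res <- classify_panel(lapply(by_inh, build_fingerprint))
  truth <- unique(panel$truth[, c("inhibitor", "true_class")])
  merge(res$summary[, c("inhibitor", "call")], truth, by = "inhibitor")
}

# Independent equilibrium oracle for the one-site ITC model: solve the
# binding quadratic for the complex concentration directly and keep the
# same displaced-volume and injection-heat bookkeeping as the model under
# test. Shares only the design arithmetic, not the closed-form heat
# expression.
itc_heats_oracle <- function(kd, n, dH, design) {
  v <- cumsum(rep(design$inj_volume, design$n_inj))
  V0 <- design$cell_volume
  Mt <- design$cell_conc * (1 - v / (2 * V0)) / (1 + v / (2 * V0))
  Xt <- design$syringe_conc * (v / V0) * (1 - v / (2 * V0))
  V0_L <- V0 * 1e-6
  PL <- mapply(function(M, X) {
    # [PL]^2 - [PL](nM + X + Kd) + nMX = 0, physical root
    b <- n * M + X + kd
    (b - sqrt(b^2 - 4 * n * M * X)) / 2
  }, Mt, Xt)
  Q <- dH * V0_L * PL
  Qprev <- c(0, Q[-length(Q)])
  dV <- rep(design$inj_volume, design$n_inj)
  (Q + (dV / V0) * (Q + Qprev) / 2 - Qprev) * 1e9
}
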