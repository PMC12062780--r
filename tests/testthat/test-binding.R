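test_that("one-site ITC heats match the brute-force equilibrium oracle", {
  design <- itc_design()  # 2 uL x 19 of 200 uM into 200 uL of 20 uM
  for (kd in c(36e-9, 1e-6, 25e-6)) {
    model <- itc_heats(kd, 1, -10, design)
    oracle <- itc_heats_oracle(kd, 1, -10, design)
    expect_equal(model, oracle, tolerance = 1e-6)
  }
  # off-unity stoichiometry and positive enthalpy too
  expect_equal(itc_heats(2e-7, 0.5, 4.2, design),
               itc_heats_oracle(2e-7, 0.5, 4.2, design), tolerance = 1e-6)
})

test_that("ITC heat limits behave physically", {
  design <- itc_design()
  expect_equal(itc_heats(36e-9, 1, 0, design), rep(0, 19))
  # stoichiometric limit: constant heats until saturation, then ~0
  suppressWarnings(q <- itc_heats(1e-15, 1, -10, design))
  molar_ratio <- cumsum(rep(2, 19)) / 200 * 200e-6 / 20e-6
  pre <- q[molar_ratio < 0.8]
  post <- q[molar_ratio > 1.3]
  expect_lt(diff(range(pre)) / abs(mean(pre)), 0.05)
  expect_lt(max(abs(post)), 0.05 * abs(mean(pre)))
})

test_that("ITC fit recovers the simulated thermodynamics", {
  fit <- fit_itc_one_site(simulate_itc(36e-9, noise = no_noise()))
  expect_equal(fit$kd, 36e-9, tolerance = 0.01)
  expect_equal(unname(fit$params["n"]), 1, tolerance = 0.01)
  expect_equal(unname(fit$params["dH"]), -10, tolerance = 0.01)
  fit2 <- fit_itc_one_site(simulate_itc(200e-9, n_stoich = 0.5,
                                        noise = no_noise()))
  expect_equal(unname(fit2$params["n"]), 0.50, tolerance = 0.02)
  expect_equal(fit2$kd, 200e-9, tolerance = 0.01)
  expect_error(
    fit_itc_one_site(titration_dataset("itc", 1:19, rep(0, 19),
                                       meta = unclass(itc_design()))),
    class = "ciu_analysis_error")
})

test_that("ITC kd estimator has small median bias at the standard design", {
  kds <- vapply(1:100, function(i) {
    d <- simulate_itc(36e-9, noise = noise_model(heat_noise_sd = 0.1),
                      seed = 1000 + i)
    suppressWarnings(fit_itc_one_site(d)$kd)
  }, numeric(1))
  expect_lt(abs(median(kds) - 36e-9) / 36e-9, 0.05)
})

test_that("SPR steady-state fit recovers kd from the standard dosing", {
  # 9-point 2-fold series spanning a 256-fold range, in triplicate
  fit <- fit_spr_steady_state(simulate_spr(37e-6, rmax = 85,
                                           top_conc = 500e-6,
                                           noise = no_noise()))
  expect_equal(fit$kd, 37e-6, tolerance = 0.01)
  expect_equal(unname(fit$params["rmax"]), 85, tolerance = 0.01)
  fit2 <- fit_spr_steady_state(simulate_spr(8e-9, top_conc = 160e-9,
                                            noise = no_noise()))
  expect_equal(fit2$kd, 8e-9, tolerance = 0.01)
  expect_error(
    fit_spr_steady_state(titration_dataset("spr", 1:9 * 1e-6,
                                           rep(-1, 9))),
    class = "ciu_analysis_error")
})

test_that("an unsaturated SPR design is flagged unreliable", {
  d <- simulate_spr(100e-6, top_conc = 1e-6, noise = no_noise())
  expect_warning(fit <- fit_spr_steady_state(d), "unreliable")
  expect_true(any(grepl("unreliable", fit$warnings)))
})

test_that("MST fraction-bound formula and Hill n=1 fit recover truth", {
  expect_equal(mst_fraction_bound(850, 850, 910), 0)
  expect_equal(mst_fraction_bound(910, 850, 910), 1)
  expect_error(mst_fraction_bound(870, 900, 900), class = "ciu_input_error")
  fit <- fit_mst_hill(simulate_mst(25e-6, noise = no_noise()))
  expect_equal(fit$kd, 25e-6, tolerance = 0.01)
  expect_equal(unname(fit$params["fnorm_unbound"]), 850, tolerance = 0.001)
  expect_equal(unname(fit$params["fnorm_bound"]), 910, tolerance = 0.005)
  expect_error(
    fit_mst_hill(titration_dataset("mst", 500e-6 / 2^(0:15),
                                   rep(875, 16))),
    class = "ciu_analysis_error")
})

test_that("kd estimates are invariant to the concentration unit scale", {
  # same design expressed in M and in nM-as-M rescale
  d_M <- simulate_spr(37e-6, noise = no_noise())
  fit_M <- fit_spr_steady_state(d_M)
  d_nM <- titration_dataset("spr", d_M$x * 1e9, d_M$y, d_M$replicate)
  fit_nM <- fit_spr_steady_state(d_nM)
  expect_equal(fit_nM$kd / 1e9, fit_M$kd, tolerance = 1e-6)

  m_M <- simulate_mst(25e-6, noise = no_noise())
  fit_mM <- fit_mst_hill(m_M)
  m_uM <- titration_dataset("mst", m_M$x * 1e6, m_M$y, m_M$replicate)
  fit_muM <- fit_mst_hill(m_uM)
  expect_equal(fit_muM$kd / 1e6, fit_mM$kd, tolerance = 1e-6)
})

test_that("affinity_fit methods expose coefficients, predictions, residuals", {
  fit <- fit_spr_steady_state(simulate_spr(37e-6, rmax = 85, seed = 4))
  expect_named(coef(fit), c("kd", "rmax"))
  expect_equal(predict(fit, 37e-6), unname(coef(fit)["rmax"]) / 2 *
                 (37e-6 / (fit$kd + 37e-6)) * 2, tolerance = 1e-9)
  expect_equal(length(residuals(fit)), 27)
  expect_equal(fit$rss, sum(residuals(fit)^2))
  s <- summary(fit)
  expect_true(all(s$coefficients$std_error >= 0, na.rm = TRUE))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "titration_dataset")
})
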