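test_that("native spectrum peaks appear at the closed-form m/z positions", {
  mp <- 1.00728
  sp <- simulate_native_spectrum(36000, charges = 11:13, bound_fraction = 0,
                                 noise = no_noise(), mz_step = 0.05)
  pk <- pick_peaks(sp, 0.05)
  expect_equal(nrow(pk), 3)
  # independent closed form: (M + z m_p) / z
  expected <- sort((36000 + (11:13) * mp) / (11:13))
  expect_equal(pk$mz, expected, tolerance = 0.05 / 3000)
  expect_equal(expected, c(2770.238, 3001.007, 3273.734),
               tolerance = 1e-6)
})

test_that("apo-only simulation has no holo peaks; 50% binding is symmetric", {
  apo <- simulate_native_spectrum(36000, ligand_mass = 532.5,
                                  bound_fraction = 0, noise = no_noise())
  holo_mz <- (36532.5 + (11:13) * 1.00728) / (11:13)
  for (m in holo_mz) {
    idx <- which(abs(apo$mz - m) < 2)
    if (length(idx)) expect_lt(max(apo$intensity[idx]), 1e-6)
  }
  half <- simulate_native_spectrum(36000, ligand_mass = 532.5,
                                   bound_fraction = 0.5, noise = no_noise())
  pk <- pick_peaks(half, 0.05)
  expect_equal(nrow(pk), 6)
  # consecutive (apo, holo) pairs per charge have equal apex heights
  for (z in 11:13) {
    apo_h <- pk$height[which.min(abs(pk$mz - (36000 + z * 1.00728) / z))]
    holo_h <- pk$height[which.min(abs(pk$mz - (36532.5 + z * 1.00728) / z))]
    expect_equal(apo_h, holo_h, tolerance = 1e-4)
  }
})

test_that("spectrum simulator validates its inputs", {
  expect_error(simulate_native_spectrum(36000, charges = integer(0)),
               class = "ciu_input_error")
  expect_error(simulate_native_spectrum(36000, ligand_mass = 0,
                                        bound_fraction = 1),
               class = "ciu_input_error")
  expect_error(simulate_native_spectrum(-1), class = "ciu_input_error")
})

test_that("simulators are bit-reproducible under a fixed seed", {
  s1 <- simulate_native_spectrum(36000, 532.5, 0.4, seed = 42)
  s2 <- simulate_native_spectrum(36000, 532.5, 0.4, seed = 42)
  expect_identical(s1, s2)
  a1 <- simulate_atd(30, seed = 7)
  a2 <- simulate_atd(30, seed = 7)
  expect_identical(a1, a2)
  p1 <- simulate_ciu_panel(panel_spec(seed = 5))
  p2 <- simulate_ciu_panel(panel_spec(seed = 5))
  expect_identical(p1, p2)
  t1 <- simulate_itc(1e-7, seed = 3)
  t2 <- simulate_itc(1e-7, seed = 3)
  expect_identical(t1, t2)
})

test_that("ATD mixture degenerates and symmetrises as expected", {
  a0 <- simulate_atd(0, noise = no_noise())
  expect_equal(unfolded_percent(fit_two_conformers(a0)), 0)
  a100 <- simulate_atd(100, noise = no_noise())
  h_compact <- a100$intensity[which.min(abs(a100$drift_time - 5.5))]
  h_ext <- a100$intensity[which.min(abs(a100$drift_time - 7.6))]
  expect_equal(h_compact, h_ext, tolerance = 1e-6)
})

test_that("noiseless ATD integral equals the sum of the component areas", {
  for (u in c(10, 48.9, 76.7)) {
    a <- simulate_atd(u, noise = no_noise())
    trap <- sum(diff(a$drift_time) *
                  (head(a$intensity, -1) + tail(a$intensity, -1)) / 2)
    analytic <- (100 + u) * 0.35 * sqrt(2 * pi)
    expect_equal(trap, analytic, tolerance = 1e-6)
  }
})

test_that("a too-coarse drift grid is flagged in the ATD metadata", {
  a <- simulate_atd(20, grid = seq(0, 14, by = 0.5), noise = no_noise())
  expect_true(any(grepl("unresolved", a$warnings)))
  b <- simulate_atd(20, noise = no_noise())
  expect_length(b$warnings, 0)
})

test_that("class truth model reproduces the calibrated statistics", {
  # a neutral latent score sits exactly at the class mean
  expect_equal(unfold_truth(0, "type_I", 21), 27.6)
  expect_equal(unfold_truth(0, "type_II", 21), 48.9)
  expect_equal(unfold_truth(0, "type_I", 24), 44.2)
  expect_equal(unfold_truth(0, "type_II", 24), 76.7)
  # clamped to the class range
  u <- seq(-4, 4, by = 0.05)
  t2_24 <- unfold_truth(u, "type_II", 24)
  expect_true(all(t2_24 >= 64 & t2_24 <= 95))
  t1_21 <- unfold_truth(u, "type_I", 21)
  expect_true(all(t1_21 >= 22 & t1_21 <= 35))
  # a shared latent score always unfolds more at the higher voltage
  for (cls in c("type_I", "type_II"))
    expect_true(all(unfold_truth(u, cls, 24) > unfold_truth(u, cls, 21)))
})

test_that("panel ground truth is monotone in voltage and class-separated", {
  panel <- simulate_ciu_panel(panel_spec(seed = 11))
  tr <- panel$truth
  expect_equal(length(panel$atds), 10 * 2 * 3)
  for (nm in unique(tr$inhibitor)) {
    v21 <- tr$unfold_truth[tr$inhibitor == nm & tr$voltage == 21]
    v24 <- tr$unfold_truth[tr$inhibitor == nm & tr$voltage == 24]
    expect_gt(v24, v21)
  }
  t1 <- tr$unfold_truth[tr$true_class == "type_I" & tr$voltage == 24]
  t2 <- tr$unfold_truth[tr$true_class == "type_II" & tr$voltage == 24]
  expect_true(max(t1) < min(t2))  # ranges [30,50] vs [64,95] cannot overlap
})

test_that("an explicit unfold_score_truth overrides the class draw", {
  prof <- inhibitor_profile("apo-like", "type_I", 1e-6, 400,
                            unfold_score_truth = c("21" = 10, "24" = 30))
  panel <- simulate_ciu_panel(panel_spec(inhibitors = list(prof), seed = 2),
                              no_noise())
  expect_equal(panel$truth$unfold_truth, c(10, 30))
  expect_error(
    inhibitor_profile("bad", "type_I", 1e-6, 400,
                      unfold_score_truth = c("21" = 30, "24" = 10)),
    class = "ciu_input_error")
})

test_that("ligand stripping follows a logistic decay in voltage", {
  expect_equal(unname(simulate_stripping_series(0.8, 18, v50 = 18)), 0.4)
  expect_equal(unname(simulate_stripping_series(0, c(6, 21, 24))),
               c(0, 0, 0))
  b <- simulate_stripping_series(0.9, c(6, 21, 24))
  expect_true(all(diff(b) < 0))
  expect_error(simulate_stripping_series(0.5, 21, steepness = 0),
               class = "ciu_input_error")
})

test_that("ITC simulation limits behave physically", {
  z <- simulate_itc(36e-9, dH = 0, noise = no_noise())
  expect_equal(z$y, rep(0, 19))
  weak <- simulate_itc(1, noise = no_noise())  # kd far above any conc
  expect_lt(max(abs(weak$y)), 1e-2)
})

test_that("SPR design arithmetic and limits are correct", {
  d <- simulate_spr(37e-6, rmax = 80, noise = no_noise())
  expect_equal(length(unique(d$x)), 9)  # 256-fold range, 2-fold steps
  expect_equal(nrow(as.data.frame(d[c("x", "y")])), 27)
  expect_equal(spr_req(37e-6, 80, 37e-6), 40)
  expect_equal(spr_req(37e-6, 80, 0), 0)
})

test_that("MST simulation hits the Hill n=1 midpoint and window edges", {
  d <- simulate_mst(25e-6, fnorm_unbound = 850, fnorm_bound = 910,
                    conc_series = c(0, 25e-6), noise = no_noise())
  expect_equal(d$y[1], 850)
  expect_equal(mst_fraction_bound(d$y[2], 850, 910), 0.5)
  expect_error(simulate_mst(25e-6, fnorm_unbound = 900, fnorm_bound = 900),
               class = "ciu_input_error")
  expect_warning(simulate_mst(100e-9, protein_conc = 60e-9,
                              conc_series = 1e-6 / 2^(0:7)),
                 "no-depletion")
})
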