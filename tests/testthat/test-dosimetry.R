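test_that("local-deposition sphere S-value is the unit-converted energy density", {
  # nuclide with a beta-only non-penetrating energy of 0.1226 MeV/decay
  nuc <- radionuclide("test", 12.7004, 0.174, 0.390, 0.44,
                      mean_energy_np_mev = 0.1226,
                      mean_energy_photon_mev = 0.1842)
  s1 <- sphere_self_svalue(1, nuc)
  expect_equal(s1$value, 0.1226 * 1.602e-13 * 1e6 / 1e-3, tolerance = 1e-12)
  expect_equal(s1$value, 1.964e-5, tolerance = 1e-3)
  # S scales as 1/m in the local model
  expect_equal(sphere_self_svalue(0.5, nuc)$value, 2 * s1$value,
               tolerance = 1e-12)
  expect_error(sphere_self_svalue(0, nuc), "positive")
})

test_that("Monte Carlo absorbed fraction obeys its limits and the chord oracle", {
  # full-containment limit: radius >> CSDA range. Straight-path transport
  # leaks 3R/(8r) through the surface, 0.0017 at r = 10 cm for 0.2 MeV.
  big <- mc_sphere_absorbed_fraction(10, 0.2, 5e4, seed = 2)
  expect_equal(big$phi, 1, tolerance = 2e-3)
  huge <- mc_sphere_absorbed_fraction(100, 0.2, 5e4, seed = 2)
  expect_equal(huge$phi, 1, tolerance = 1e-3)
  # vanishing sphere: phi ~ 3r/(8R) -> 0
  tiny <- mc_sphere_absorbed_fraction(1e-4, 0.2, 5e4, seed = 2)
  expect_lt(tiny$phi, 0.01)
  # the published biodistribution tumour (0.306 g -> r = 0.418 cm) at the
  # mean positron energy stays in the documented bracket
  mid <- mc_sphere_absorbed_fraction(0.418, 0.2782, 1e5, seed = 3)
  expect_gte(mid$phi, 0.90)
  expect_lte(mid$phi, 1.00)
  # chord-length closed form as oracle across regimes
  for (r in c(0.2, 0.418, 1, 3)) {
    mc <- mc_sphere_absorbed_fraction(r, 0.2782, 1e5, seed = 7)
    expect_lt(abs(mc$phi - chord_absorbed_fraction(r, mc$csda_range_cm)),
              4 * mc$se + 1e-6)
  }
  expect_error(csda_range_water(5), "outside")
})

test_that("Monte Carlo S-value never exceeds the local-deposition value", {
  nuc <- cu64()
  for (m in c(0.05, 0.306, 1, 5)) {
    loc <- sphere_self_svalue(m, nuc)$value
    mc <- sphere_self_svalue(m, nuc, "monte_carlo",
                             mc_params = list(n_histories = 2e4,
                                              seed = 5))$value
    expect_lte(mc, loc * (1 + 1e-9))
  }
})

test_that("blood local-deposition dose converts energy bookkeeping to Gy", {
  nuc <- radionuclide("test", 12.7004, 0.174, 0.390, 0.44,
                      mean_energy_np_mev = 0.1226,
                      mean_energy_photon_mev = 0.1842)
  expect_equal(blood_local_dose(1e4, nuc, "nonpenetrating"), 0.196,
               tolerance = 1e-2)
  expect_equal(blood_local_dose(0, nuc), 0)
  expect_gte(blood_local_dose(1e4, nuc, "all"),
             blood_local_dose(1e4, nuc, "nonpenetrating"))
})

test_that("organ dose is the linear MIRD product", {
  nuc <- cu64()
  f <- fit_tac(c(0.5, 24, 72), c(55, 55, 55), "mono", organ = "tumour")
  cum <- cumulated_activity(f, nuc)
  sv <- sphere_self_svalue(0.306, nuc)
  d <- organ_dose(cum, sv)
  expect_equal(d, cum$a_tilde_mbq_s_per_g * 0.306 * sv$value,
               tolerance = 1e-12)
  # doubling the cumulated activity doubles the dose
  f2 <- fit_tac(c(0.5, 24, 72), c(110, 110, 110), "mono", organ = "tumour")
  expect_equal(organ_dose(cumulated_activity(f2, nuc), sv), 2 * d,
               tolerance = 1e-9)
  zero <- fit_tac(c(0.5, 24, 72), c(0, 0, 0), "mono", organ = "tumour")
  expect_equal(organ_dose(cumulated_activity(zero, nuc), sv), 0)
  expect_error(organ_dose(cum, sv, organ = "liver"), "mismatch")
})

test_that("dose table rounding follows the publication convention", {
  expect_equal(round_away(0.05, 1), 0.1)   # half away from zero
  expect_equal(round_away(-0.05, 1), -0.1)
  expect_equal(round_away(0.5757, 1), 0.6)

  rep1 <- assemble_dose_table(c(Tumour = 21.3 / 37, Liver = 0.2), 37)
  expect_equal(rep1$gy_per_mbq[rep1$organ == "Tumour"], 0.6)
  expect_equal(rep1$gy_at_admin[rep1$organ == "Liver"], 7.4)
  expect_identical(attr(rep1, "provenance"), "self-dose only")

  unit <- assemble_dose_table(c(A = 0.3141), administered_mbq = 1)
  expect_equal(unit$gy_per_mbq, unit$gy_at_admin)
  expect_error(assemble_dose_table(c(A = 1), 0), "> 0")
  expect_error(assemble_dose_table(1, 37), "named")
})

test_that("published dose table is internally consistent row by row", {
  pub <- published_dose_table()
  # dividing the 37 MBq column by 37 and rounding reproduces the printed
  # per-MBq column -- for every row except Heart, where the printed table
  # itself is inconsistent (1.9/37 = 0.051 rounds to 0.1, printed 0.0)
  consistent <- pub$organ != "Heart"
  expect_equal(round_away(pub$gy_37mbq[consistent] / 37, 1),
               pub$gy_per_mbq[consistent])
  expect_false(isTRUE(all.equal(round_away(pub$gy_37mbq / 37, 1),
                                pub$gy_per_mbq)))
  # and the headline ratio
  expect_equal(round(pub$gy_37mbq[pub$organ == "Tumour"] /
                       pub$gy_37mbq[pub$organ == "Liver"], 1), 2.9)
})

test_that("dose pipeline is linear in the input activities", {
  nuc <- cu64()
  t <- c(0.0833, 2, 24, 48, 72)
  y <- 62.5 * (1 - exp(-0.654 * t))
  sv <- sphere_self_svalue(0.306, nuc)
  d1 <- organ_dose(cumulated_activity(fit_tac(t, y, "plateau"), nuc), sv)
  d3 <- organ_dose(cumulated_activity(fit_tac(t, 3 * y, "plateau"), nuc), sv)
  expect_equal(d3, 3 * d1, tolerance = 1e-8)
})
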