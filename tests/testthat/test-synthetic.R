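cfg <- default_config()

test_that("all generators are bit-reproducible under the same seed", {
  expect_identical(gen_biodistribution(cfg$biodist, 7, "healthy"),
                   gen_biodistribution(cfg$biodist, 7, "healthy"))
  expect_identical(gen_tumour_growth(cfg$growth, 7, "treated"),
                   gen_tumour_growth(cfg$growth, 7, "treated"))
  expect_identical(gen_survival(cfg$survival, 7, "saline"),
                   gen_survival(cfg$survival, 7, "saline"))
  expect_identical(gen_bead_assay(seed = 7), gen_bead_assay(seed = 7))
  expect_identical(gen_saturation_binding(seed = 7),
                   gen_saturation_binding(seed = 7))
  # different seeds give different draws
  expect_false(identical(gen_bead_assay(seed = 7), gen_bead_assay(seed = 8)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(gen_bead_assay(seed = 99))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("zero-spread biodistribution config collapses onto the means", {
  zcfg <- cfg$biodist
  zcfg$table$sd_pid_g <- 0
  zcfg$injected_sd_mbq <- 0
  zcfg$mass_cv <- 0
  recs <- percent_id_per_gram(gen_biodistribution(zcfg, 3, "healthy"))
  blood5 <- recs[recs$organ == "blood" & recs$timepoint_h == 0.0833, ]
  expect_equal(blood5$pid_g, rep(26.6, 4), tolerance = 1e-10)
})

test_that("%ID/g back-conversion round-trips through the counting model", {
  recs <- gen_biodistribution(cfg$biodist, 5)
  out <- percent_id_per_gram(recs)
  expect_equal(out$pid_g, out$true_pid_g, tolerance = 1e-9)
})

test_that("whole-body activity is conserved for every synthetic mouse", {
  for (seed in 1:25) {
    recs <- percent_id_per_gram(gen_biodistribution(cfg$biodist, seed))
    totals <- tapply(recs$pid_g * recs$organ_mass_g, recs$mouse_id, sum)
    expect_true(all(totals <= 100 + 1e-6))
  }
})

test_that("generated biodistribution moments converge to the configured cell", {
  # CLT check at 3 sigma on the healthy blood 5-min cell (200 cohorts of 4)
  means <- vapply(1:200, function(i) {
    r <- percent_id_per_gram(gen_biodistribution(cfg$biodist, i, "healthy"))
    group_stats(r, organ = "blood", timepoint = 0.0833)$mean_pid_g
  }, numeric(1))
  se <- 7.8 / sqrt(200 * 4)
  expect_lt(abs(mean(means) - 26.6), 3 * se + 0.15)
})

test_that("noiseless growth round-trips the doubling time", {
  g <- cfg$growth
  g$groups$treated$dt_sd_days <- 0
  g$groups$treated$noise_cv <- 0
  g$groups$treated$dt_mean_days <- 2
  g$groups$treated$regression_mean <- 0
  sim <- gen_tumour_growth(g, 11, "treated")
  one <- sim[sim$mouse_id == "treated_m1", ]
  expect_equal(doubling_time(one$day, one$volume_mm3,
                             c(g$first_dose_day, g$second_dose_day)),
               2, tolerance = 1e-9)
  # dimensions reproduce the volume through the calliper formula
  expect_equal(tumour_volume(one$length_mm, one$width_mm, one$height_mm),
               one$volume_mm3, tolerance = 1e-12)
})

test_that("zero regression fraction means monotone growth and no reduction", {
  g <- cfg$growth
  g$groups$treated$regression_mean <- 0
  g$groups$treated$noise_cv <- 0
  sim <- gen_tumour_growth(g, 13, "treated")
  for (d in split(sim, sim$mouse_id)) {
    expect_true(all(diff(d$volume_mm3) > 0))
    expect_equal(max_volume_reduction(d$day, d$volume_mm3,
                                      g$second_dose_day), 0)
  }
})

test_that("treated growth regresses after the second dose", {
  sim <- gen_tumour_growth(cfg$growth, 17, "treated")
  red <- vapply(split(sim, sim$mouse_id), function(d) {
    max_volume_reduction(d$day, d$volume_mm3, cfg$growth$second_dose_day)
  }, numeric(1))
  expect_gt(mean(red), 40)  # configured mean regression is ~70%
})

test_that("survival generator honours cure fraction and horizon", {
  s <- cfg$survival
  s$groups$repeat_35$cure_fraction <- 1
  all_cured <- gen_survival(s, 19, "repeat_35")
  expect_true(all(all_cured$event == 0L))
  expect_true(all(all_cured$time_days == 100))
  expect_true(all(all_cured$cause == "study_end"))

  reg <- gen_survival(cfg$survival, 19, "saline")
  expect_true(all(reg$time_days > 0 & reg$time_days <= 100))
  expect_true(all(reg$cause[reg$event == 1L] == "paralysis"))

  # near-degenerate shape concentrates events at the median
  s2 <- cfg$survival
  s2$groups$saline$shape <- 500
  tight <- gen_survival(s2, 23, "saline")
  expect_lt(max(abs(tight$time_days - 30)), 2)
})

test_that("survival can be derived from growth via the sacrifice rules", {
  s <- gen_survival(cfg$survival, 29, c("saline", "treated"),
                    method = "from_growth", growth_config = cfg$growth)
  expect_setequal(unique(s$group), c("saline", "treated"))
  sal <- s[s$group == "saline", ]
  # saline tumours (dT 1.9 d from 30 mm3 at day 6) hit 2000 mm3 in ~2.5 weeks
  expect_true(all(sal$event == 1L))
  expect_true(all(sal$cause == "volume_limit"))
  expect_true(all(sal$time_days >= 10 & sal$time_days <= 30))
  km_sal <- km_estimator(sal$time_days, sal$event)$median
  treated <- s[s$group == "treated", ]
  km_tr <- km_estimator(treated$time_days, treated$event)$median
  expect_gt(km_tr, km_sal)
})

test_that("bead assay generator is binomial in the truth fraction", {
  none <- gen_bead_assay(0, 1e5, 10, seed = 1)
  expect_true(all(none$beads_cpm == 0))
  all_b <- gen_bead_assay(1, 1e5, 10, seed = 1)
  expect_true(all(all_b$supernatant_cpm == 0))
  d <- gen_bead_assay(0.794, 1e6, 50, seed = 2)
  expect_true(all(d$beads_cpm + d$supernatant_cpm == 1e6))
})

test_that("saturation binding generator round-trips and is linear at low dose", {
  clean <- gen_saturation_binding(0.626, 100, noise_cv = 0, seed = 1)
  fit <- fit_one_site(clean$concentration_nm, clean$signal)
  expect_equal(unname(coef(fit)), c(0.626, 100), tolerance = 1e-6)
  # far below Kd the signal is linear in concentration
  low <- gen_saturation_binding(10, 100, concentration = c(0.001, 0.002),
                                noise_cv = 0, seed = 1)
  expect_equal(low$signal[2] / low$signal[1], 2, tolerance = 1e-3)
})
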