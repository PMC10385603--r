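test_that("two-point mono fit matches the closed-form solution", {
  t <- c(0.0833, 2)
  y <- c(26.6, 14.6)
  fit <- fit_tac(t, y, "mono")
  lambda <- log(y[1] / y[2]) / diff(t)
  a0 <- y[1] * exp(lambda * t[1])
  expect_equal(unname(coef(fit)["lambda1"]), lambda, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["a1"]), a0, tolerance = 1e-6)
  # the published blood pair gives ~0.313 /h and ~27.3 %ID/g
  expect_equal(unname(coef(fit)["lambda1"]), 0.313, tolerance = 1e-2)
  expect_equal(unname(coef(fit)["a1"]), 27.3, tolerance = 1e-2)
})

test_that("noiseless curves are recovered to high precision", {
  t <- c(0.0833, 2, 8, 24, 72)
  y_mono <- 10 * exp(-0.1 * t)
  f <- fit_tac(t, y_mono, "mono")
  expect_equal(unname(coef(f)), c(10, 0.1), tolerance = 1e-8)

  y_pl <- 62.5 * (1 - exp(-0.654 * t))
  fp <- fit_tac(t, y_pl, "plateau")
  expect_equal(unname(coef(fp)), c(62.5, 0.654), tolerance = 1e-6)

  y_bi <- 50 * exp(-1.2 * t) + 10 * exp(-0.03 * t)
  fb <- fit_tac(c(t, 120, 200), c(y_bi, 10 * exp(-0.03 * c(120, 200)) +
                                    50 * exp(-1.2 * c(120, 200))), "bi")
  expect_equal(sort(unname(coef(fb))[c(2, 4)]), c(0.03, 1.2),
               tolerance = 1e-6)
})

test_that("fit preconditions and accessors behave", {
  expect_error(fit_tac(c(1, 2, 3), c(1, 2, 3), "bi"), "at least 4")
  f <- fit_tac(c(0.0833, 2, 48), c(9.2, 45.6, 62.5), "plateau",
               organ = "tumour")
  expect_s3_class(f, "tac")
  expect_equal(f$organ, "tumour")
  expect_equal(length(residuals(f)), 3L)
  expect_equal(fitted(f) + residuals(f), f$values, tolerance = 1e-12)
  expect_equal(predict(f, 0), 0)  # plateau model starts at zero uptake
})

test_that("AICc model selection prefers parsimony and true curvature", {
  t <- c(0.0833, 2, 8, 24, 72)
  y_mono <- 10 * exp(-0.1 * t)
  fits <- list(fit_tac(t, y_mono, "mono"))
  expect_identical(select_model(fits), fits[[1]])  # single candidate

  # on clean mono data the 4-parameter model cannot be supported (n = 5)
  auto <- fit_tac_auto(t, y_mono)
  expect_identical(auto$model, "mono")

  # data from a genuine bi-exponential, rich sampling: bi wins on AICc
  t2 <- c(0.0833, 0.5, 1, 2, 4, 8, 16, 24, 48, 72)
  y2 <- 30 * exp(-1.5 * t2) + 8 * exp(-0.02 * t2)
  fm <- fit_tac(t2, y2, "mono")
  fb <- fit_tac(t2, y2, "bi")
  # direct AICc computation as oracle
  aicc <- function(rss, n, k) n * log(rss / n) + 2 * k +
    2 * k * (k + 1) / (n - k - 1)
  expect_equal(tac_aicc(fm), aicc(fm$rss, 10, 3), tolerance = 1e-12)
  expect_equal(tac_aicc(fb), aicc(fb$rss, 10, 5), tolerance = 1e-12)
  expect_lt(tac_aicc(fb), tac_aicc(fm))
  expect_identical(select_model(list(fm, fb))$model, "bi")
  expect_error(select_model(list()), "non-empty")
})

test_that("analytic cumulated activity matches closed forms and quadrature", {
  nuc <- cu64()
  lp <- decay_constant(nuc)
  # biologically stable mono: A0/lambda_phys
  f_stable <- fit_tac(c(0.5, 24, 72), c(1, 1, 1), "mono")
  cum <- cumulated_activity(f_stable, nuc)
  expect_equal(cum$a_tilde_mbq_s_per_g, 0.01 / lp * 3600, tolerance = 1e-6)
  expect_equal(cum$a_tilde_mbq_s_per_g, 659.6, tolerance = 1e-3)

  f55 <- fit_tac(c(0.5, 24, 72), c(55, 55, 55), "mono")
  expect_equal(cumulated_activity(f55, nuc)$a_tilde_mbq_s_per_g, 3.628e4,
               tolerance = 1e-3)

  # quadrature oracle across all model families
  t <- c(0.0833, 2, 8, 24, 48, 72)
  fits <- list(
    fit_tac(t, 20 * exp(-0.15 * t), "mono"),
    fit_tac(t, 25 * exp(-1.1 * t) + 6 * exp(-0.04 * t), "bi"),
    fit_tac(t, 62.5 * (1 - exp(-0.654 * t)), "plateau"))
  for (f in fits) {
    ana <- cumulated_activity(f, nuc)$a_tilde_mbq_s_per_g
    num <- quadrature_cumulated(f, nuc)
    expect_equal(ana, num, tolerance = 1e-6)
  }
})

test_that("cumulated activity is monotone in amplitude and clearance", {
  nuc <- cu64()
  t <- c(0.5, 4, 24, 72)
  base <- cumulated_activity(fit_tac(t, 10 * exp(-0.1 * t), "mono"), nuc)
  bigger <- cumulated_activity(fit_tac(t, 20 * exp(-0.1 * t), "mono"), nuc)
  faster <- cumulated_activity(fit_tac(t, 10 * exp(-0.3 * t), "mono"), nuc)
  stable <- cumulated_activity(fit_tac(t, rep(10, 4), "mono"), nuc)
  expect_gt(bigger$a_tilde_mbq_s_per_g, base$a_tilde_mbq_s_per_g)
  expect_lt(faster$a_tilde_mbq_s_per_g, base$a_tilde_mbq_s_per_g)
  expect_lt(base$a_tilde_mbq_s_per_g, stable$a_tilde_mbq_s_per_g)
})

test_that("divergent integrals are refused", {
  nuc <- cu64()
  bad <- structure(list(organ = NULL, model = "mono",
                        coefficients = c(a1 = 10, lambda1 = -0.1),
                        rss = 0, n_points = 3,
                        times = c(1, 2, 3), values = c(1, 1, 1)),
                   class = "tac")
  expect_error(cumulated_activity(bad, nuc), "divergent")
})

test_that("physical-only tail mode is conservative for rising organs", {
  nuc <- cu64()
  f <- fit_tac(c(0.0833, 2, 48), c(9.2, 45.6, 62.5), "plateau")
  full <- cumulated_activity(f, nuc)$a_tilde_mbq_s_per_g
  frozen <- cumulated_activity(f, nuc, "physical_only")$a_tilde_mbq_s_per_g
  # beyond 48 h the plateau model keeps rising towards P, so freezing
  # the biology at t_last must not increase the integral
  expect_lte(frozen, full)
  # and the frozen variant still matches piecewise quadrature
  lp <- decay_constant(nuc)
  head_num <- stats::integrate(function(t) predict(f, t) / 100 *
                                 exp(-lp * t), 0, 48,
                               rel.tol = 1e-10)$value * 3600
  tail_num <- predict(f, 48) / 100 * exp(-lp * 48) / lp * 3600
  expect_equal(frozen, head_num + tail_num, tolerance = 1e-6)
})
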