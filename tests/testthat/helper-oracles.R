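# Independent oracles used across the suite.

# Brute-force Kaplan-Meier product-limit estimate: walks distinct event
# times and multiplies (1 - d/n) risk-set factors directly.
brute_force_km <- function(time, event) {
  stopifnot(length(time) == length(event))
  etimes <- sort(unique(time[event == 1]))
  surv <- numeric(length(etimes))
  s <- 1
  for (i in seq_along(etimes)) {
    t <- etimes[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  med <- if (any(surv <= 0.5)) min(etimes[surv <= 0.5]) else NA_real_
  list(time = etimes, surv = surv, median = med)
}

# Log-rank chi-square from per-event-time hypergeometric moments.
brute_force_logrank <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  etimes <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in etimes) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1L)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chi2 <- if (v > 0) o_minus_e^2 / v else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# Closed-form absorbed fraction for a uniform source in a sphere with
# straight-path transport and uniform deposition over range R: derived
# from the interior chord-length density f(d) = 3/(4r) (1 - (d/2r)^2).
chord_absorbed_fraction <- function(radius_cm, range_cm) {
  rho <- range_cm / radius_cm
  if (rho >= 2) return((3 * radius_cm / 4) / range_cm)
  1 - 3 * rho / 8 + rho^3 / 64
}

# Numerical quadrature of a fitted biological curve times physical decay,
# in MBq s per gram per injected MBq (oracle for cumulated_activity).
quadrature_cumulated <- function(tac, nuclide) {
  lp <- cudosim::decay_constant(nuclide)
  f <- function(t) predict(tac, t) / 100 * exp(-lp * t)
  stats::integrate(f, 0, Inf, rel.tol = 1e-10, subdivisions = 2000L)$value *
    3600
}

# Printed published dose table shipped as a plain-text fixture.
published_dose_table <- function() {
  utils::read.delim(system.file("extdata", "published_dose_table.tsv",
                                package = "cudosim"), sep = "\t",
                    check.names = FALSE)
}
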