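# Time-activity curve fitting and analytic integration to cumulated activity.
#
# Convention used throughout (and the single most consequential one): organ
# series are stored DECAY-CORRECTED (%ID/g at injection time), so the fitted
# curve A(t) describes biological kinetics only; physical decay exp(-lambda_p t)
# is re-applied inside the integral when computing cumulated activity.

.tac_models <- c("mono", "bi", "plateau")

.tac_npar <- c(mono = 2L, bi = 4L, plateau = 2L)

# Represent any fitted model as a sum of exponential terms sum_i a_i exp(-l_i t).
.tac_terms <- function(object) {
  p <- object$coefficients
  switch(object$model,
         mono = list(a = p[["a1"]], l = p[["lambda1"]]),
         bi = list(a = c(p[["a1"]], p[["a2"]]),
                   l = c(p[["lambda1"]], p[["lambda2"]])),
         plateau = list(a = c(p[["plateau"]], -p[["plateau"]]),
                        l = c(0, p[["lambda_uptake"]])))
}

.tac_eval <- function(terms, t) {
  vapply(t, function(tt) sum(terms$a * exp(-terms$l * tt)), numeric(1))
}

#' Fit a time-activity curve to an organ series
#'
#' Least-squares fit of a kinetic model to decay-corrected %ID/g means.
#' Three model forms are supported:
#' \describe{
#'   \item{`mono`}{single exponential clearance `a1 * exp(-lambda1 * t)`;}
#'   \item{`bi`}{sum of two exponentials
#'     `a1 * exp(-lambda1 * t) + a2 * exp(-lambda2 * t)` (the second
#'     amplitude may be negative for uptake phases);}
#'   \item{`plateau`}{rising-to-plateau uptake
#'     `P * (1 - exp(-lambda_u * t))`, the reparameterised two-exponential
#'     form suited to tumours that accumulate and then hold activity.}
#' }
#' Fitting uses Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm()]) with a deterministic multi-start over rate
#' constants log-spaced in \{0.01, 0.1, 1\} per hour; the best (lowest
#' residual sum of squares) converged start wins.
#'
#' @param times Sampling times in hours (or an `"organ_series"` object from
#'   [organ_time_series()], in which case `values` is ignored).
#' @param values Decay-corrected %ID/g at `times`.
#' @param model One of `"mono"`, `"bi"`, `"plateau"`.
#' @param organ Optional organ label carried on the result.
#' @return An object of class `"tac"` with elements `organ`, `model`,
#'   `coefficients`, `rss`, `n_points`, `times`, `values`.
#' @examples
#' fit <- fit_tac(c(0.0833, 2, 48), c(9.2, 45.6, 62.5), "plateau")
#' coef(fit)
#' @export
fit_tac <- function(times, values = NULL, model = c("mono", "bi", "plateau"),
                    organ = NULL) {
  if (inherits(times, "organ_series")) {
    if (is.null(organ)) organ <- times$organ
    values <- times$mean_pid_g
    times <- times$timepoints_h
  }
  model <- match.arg(model)
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  n <- length(times)
  npar <- .tac_npar[[model]]
  if (n < npar) {
    stop(sprintf("model '%s' needs at least %d points, got %d",
                 model, npar, n), call. = FALSE)
  }
  if (any(times < 0)) stop("'times' must be >= 0", call. = FALSE)

  resid_fun <- switch(model,
    mono = function(p) values - p[1] * exp(-p[2] * times),
    bi = function(p) values - (p[1] * exp(-p[2] * times) +
                               p[3] * exp(-p[4] * times)),
    plateau = function(p) values - p[1] * (1 - exp(-p[2] * times)))

  lgrid <- c(0.01, 0.1, 1)
  ymax <- max(values)
  starts <- switch(model,
    mono = lapply(lgrid, function(l) c(ymax, l)),
    plateau = lapply(lgrid, function(l) c(ymax, l)),
    bi = {
      rising <- values[n] > values[1]
      out <- list()
      for (l1 in lgrid) for (l2 in lgrid) {
        if (l1 <= l2) next
        out <- c(out,
                 list(c(ymax / 2, l1, ymax / 2, l2)),
                 if (rising) list(c(ymax, l2, -ymax, l1)))
      }
      out
    })
  lower <- switch(model,
    mono = c(0, 0),
    plateau = c(0, 1e-8),
    bi = c(-Inf, 1e-8, -Inf, 1e-8))

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("time-activity fit failed to converge from any start", call. = FALSE)
  }
  p <- best$fit$par
  coefficients <- switch(model,
    mono = c(a1 = p[1], lambda1 = p[2]),
    bi = c(a1 = p[1], lambda1 = p[2], a2 = p[3], lambda2 = p[4]),
    plateau = c(plateau = p[1], lambda_uptake = p[2]))

  out <- structure(
    list(organ = organ, model = model, coefficients = coefficients,
         rss = best$rss, n_points = n, times = times, values = values),
    class = "tac")
  grid <- seq(0, 500, length.out = 501)
  if (any(.tac_eval(.tac_terms(out), grid) < -1e-8 * max(abs(values)))) {
    warning("fitted curve goes negative on [0, 500 h]", call. = FALSE)
  }
  out
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s model%s, %d points, RSS %.4g\n", x$model,
              if (!is.null(x$organ)) paste0(" for ", x$organ) else "",
              x$n_points, x$rss))
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' @export
coef.tac <- function(object, ...) object$coefficients

#' @export
fitted.tac <- function(object, ...) {
  .tac_eval(.tac_terms(object), object$times)
}

#' @export
residuals.tac <- function(object, ...) object$values - fitted(object)

#' Predict decay-corrected activity from a fitted time-activity curve
#'
#' @param object A `"tac"` fit.
#' @param times Times (hours) at which to evaluate the biological curve.
#' @param ... Unused.
#' @return Predicted decay-corrected %ID/g.
#' @export
predict.tac <- function(object, times = object$times, ...) {
  .tac_eval(.tac_terms(object), times)
}

#' @export
summary.tac <- function(object, ...) {
  structure(list(tac = object,
                 aicc = tac_aicc(object),
                 sigma = sqrt(object$rss /
                                max(1, object$n_points -
                                      .tac_npar[[object$model]]))),
            class = "summary.tac")
}

#' @export
print.summary.tac <- function(x, ...) {
  print(x$tac)
  cat(sprintf("  AICc %.3f, residual sigma %.4g\n", x$aicc, x$sigma))
  invisible(x)
}

#' @export
plot.tac <- function(x, ...) {
  tt <- seq(0, max(x$times) * 1.2, length.out = 200)
  graphics::plot(x$times, x$values, xlab = "time (h)",
                 ylab = "%ID/g (decay-corrected)",
                 main = x$organ %||% x$model, ...)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Small-sample corrected AIC of a time-activity fit
#'
#' Gaussian AICc, `n log(RSS/n) + 2k + 2k(k+1)/(n-k-1)` with
#' `k = n_parameters + 1` (residual variance counted). Returns `Inf` when
#' the correction denominator is not positive, i.e. when the model cannot
#' be supported by so few points.
#'
#' @param object A `"tac"` fit.
#' @return AICc value (may be `-Inf` for an exact fit).
#' @export
tac_aicc <- function(object) {
  n <- object$n_points
  k <- .tac_npar[[object$model]] + 1L
  if (n - k - 1L <= 0L) return(Inf)
  n * log(object$rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Select among candidate time-activity fits
#'
#' Picks the candidate with the lowest small-sample corrected AIC
#' ([tac_aicc()]); ties are broken towards fewer parameters.
#'
#' @param fits A list of `"tac"` objects fitted to the same data.
#' @return The selected `"tac"` object.
#' @export
select_model <- function(fits) {
  if (!is.list(fits) || length(fits) == 0L) {
    stop("'fits' must be a non-empty list of tac objects", call. = FALSE)
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "tac")))
  if (length(fits) == 1L) return(fits[[1L]])
  aicc <- vapply(fits, tac_aicc, numeric(1))
  npar <- vapply(fits, function(f) .tac_npar[[f$model]], integer(1))
  fits[[order(aicc, npar)[1L]]]
}

#' Fit all supported models and select one
#'
#' Convenience wrapper fitting every model the data can support and
#' returning the AICc-selected fit.
#'
#' @inheritParams fit_tac
#' @return A `"tac"` object.
#' @export
fit_tac_auto <- function(times, values = NULL, organ = NULL) {
  if (inherits(times, "organ_series")) {
    if (is.null(organ)) organ <- times$organ
    values <- times$mean_pid_g
    times <- times$timepoints_h
  }
  n <- length(times)
  fits <- list()
  for (m in .tac_models) {
    if (n >= .tac_npar[[m]]) {
      f <- tryCatch(fit_tac(times, values, m, organ = organ),
                    error = function(e) NULL, warning = function(w) NULL)
      if (is.null(f)) {
        f <- tryCatch(suppressWarnings(fit_tac(times, values, m,
                                               organ = organ)),
                      error = function(e) NULL)
      }
      if (!is.null(f)) fits <- c(fits, list(f))
    }
  }
  select_model(fits)
}

#' Cumulated (time-integrated) activity of a fitted curve
#'
#' Analytic integral over \[0, infinity) of the fitted biological curve
#' multiplied by physical decay,
#' \deqn{\tilde A = \int_0^\infty A(t)\, e^{-\lambda_{phys} t}\, dt,}
#' expressed per injected MBq. For a sum of exponential terms
#' `a_i exp(-l_i t)` the integral is `sum(a_i / (l_i + lambda_phys))`; for
#' the plateau model this is `P * (1/lambda_phys - 1/(lambda_phys +
#' lambda_u))`. The %ID/g amplitudes are converted to MBq/g per injected
#' MBq (divide by 100) and hours to seconds (times 3600).
#'
#' With `tail_mode = "physical_only"` the biological model is only used up
#' to the last observed timepoint; beyond it the activity is assumed frozen
#' biologically and removed by physical decay alone (a conservative
#' variant for organs whose late kinetics are unobserved).
#'
#' @param tac A `"tac"` fit (on decay-corrected %ID/g).
#' @param nuclide A [radionuclide()] record; defaults to [cu64()].
#' @param tail_mode `"model"` (default: extrapolate the fitted model) or
#'   `"physical_only"`.
#' @return An object of class `"cumulated_activity"`: list with `organ`,
#'   `a_tilde_mbq_s_per_g` (MBq s per gram per injected MBq),
#'   `a_tilde_mbq_h_per_g`, `includes_physical_decay = TRUE`, `tail_mode`.
#' @export
cumulated_activity <- function(tac, nuclide = cu64(),
                               tail_mode = c("model", "physical_only")) {
  stopifnot(inherits(tac, "tac"))
  tail_mode <- match.arg(tail_mode)
  lp <- decay_constant(nuclide)
  terms <- .tac_terms(tac)
  leff <- terms$l + lp
  active <- terms$a != 0
  if (any(leff[active] <= 0)) {
    stop("divergent integral: effective clearance <= 0 for a nonzero term",
         call. = FALSE)
  }
  if (tail_mode == "model") {
    integral_h <- sum(terms$a[active] / leff[active])
  } else {
    t_last <- max(tac$times)
    head_h <- sum(terms$a[active] / leff[active] *
                    (1 - exp(-leff[active] * t_last)))
    tail_h <- .tac_eval(terms, t_last) * exp(-lp * t_last) / lp
    integral_h <- head_h + tail_h
  }
  a_tilde_h <- integral_h / 100          # %ID/g -> MBq/g per injected MBq
  structure(list(organ = tac$organ,
                 a_tilde_mbq_h_per_g = a_tilde_h,
                 a_tilde_mbq_s_per_g = a_tilde_h * 3600,
                 includes_physical_decay = TRUE,
                 tail_mode = tail_mode),
            class = "cumulated_activity")
}

#' @export
print.cumulated_activity <- function(x, ...) {
  cat(sprintf("<cumulated_activity>%s %.4g MBq s/g per injected MBq (tail: %s)\n",
              if (!is.null(x$organ)) paste0(" ", x$organ, ":") else "",
              x$a_tilde_mbq_s_per_g, x$tail_mode))
  invisible(x)
}

#' Serialise a set of TAC fits to JSON
#'
#' @param fits A list of `"tac"` objects.
#' @param path Output file path.
#' @param nuclide Nuclide used for the reported cumulated activities.
#' @return `path`, invisibly.
#' @export
write_tac_fits <- function(fits, path, nuclide = cu64()) {
  payload <- lapply(fits, function(f) {
    list(organ = f$organ %||% NA_character_, model = f$model,
         coefficients = as.list(f$coefficients), rss = f$rss,
         n_points = f$n_points,
         a_tilde_mbq_s_per_g = cumulated_activity(f, nuclide)$a_tilde_mbq_s_per_g)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
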