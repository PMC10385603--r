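# Radioimmunoconjugate quality-control and binding-assay arithmetic.

#' Immunoreactive fraction from a bead assay
#'
#' Percentage of the counts bound to antigen-coated beads relative to the
#' total activity (beads plus supernatant):
#' `100 * beads / (beads + supernatant)`.
#'
#' @param beads_cpm,supernatant_cpm Counts per minute on the beads and in
#'   the supernatant (>= 0, total > 0). Vectorised.
#' @return Immunoreactive fraction in percent, in \[0, 100\].
#' @export
immunoreactive_fraction <- function(beads_cpm, supernatant_cpm) {
  if (any(!is.finite(beads_cpm)) || any(beads_cpm < 0) ||
      any(!is.finite(supernatant_cpm)) || any(supernatant_cpm < 0)) {
    stop("counts must be finite and >= 0", call. = FALSE)
  }
  total <- beads_cpm + supernatant_cpm
  if (any(total <= 0)) {
    stop("total counts must be > 0", call. = FALSE)
  }
  100 * beads_cpm / total
}

#' Radiochemical purity from a chromatography lane
#'
#' Percentage of the total lane signal found in the bound species, with a
#' pass flag at the release threshold (default 98%).
#'
#' @param origin_signal Signal of the bound (origin) species, >= 0.
#' @param total_signal Total lane signal, > 0.
#' @param threshold Pass threshold in percent.
#' @return A list with `percent` and logical `pass`.
#' @export
radiochemical_purity <- function(origin_signal, total_signal,
                                 threshold = 98) {
  if (any(!is.finite(total_signal)) || any(total_signal <= 0)) {
    stop("'total_signal' must be > 0", call. = FALSE)
  }
  if (any(origin_signal < 0) || any(origin_signal > total_signal)) {
    stop("'origin_signal' must lie in [0, total_signal]", call. = FALSE)
  }
  pct <- 100 * origin_signal / total_signal
  list(percent = pct, pass = pct >= threshold)
}

#' One-site specific binding fit
#'
#' Least-squares fit of the one-site saturation model
#' \deqn{B(c) = B_{max}\, c / (K_d + c)}
#' to signal measured at increasing ligand concentrations, returning the
#' equilibrium dissociation constant Kd (the concentration at half-maximal
#' binding) and Bmax. An optional linear nonspecific term `NS * c` can be
#' added with `nonspecific = TRUE`; the default model is pure specific
#' binding.
#'
#' @param concentration Ligand concentrations (nM), > 0, at least 3 values
#'   spanning the saturation inflection.
#' @param signal Measured binding signal (arbitrary units).
#' @param nonspecific Include a linear nonspecific-binding component.
#' @return An object of class `"one_site"` with `coefficients`
#'   (`kd`, `bmax`, optionally `ns`), `rss`, `n`, `converged`, and the
#'   data; supports `coef`, `predict`, `fitted`, `residuals`, `print`.
#' @examples
#' conc <- c(0.05, 0.1, 0.3, 0.6, 1.2, 2.5, 5, 10)
#' sig <- 100 * conc / (0.626 + conc)
#' coef(fit_one_site(conc, sig))
#' @export
fit_one_site <- function(concentration, signal, nonspecific = FALSE) {
  stopifnot(is.numeric(concentration), is.numeric(signal),
            length(concentration) == length(signal))
  if (length(concentration) < 3L) {
    stop("need at least 3 concentrations", call. = FALSE)
  }
  if (any(concentration <= 0)) {
    stop("'concentration' must be > 0", call. = FALSE)
  }
  bmax0 <- max(signal)
  kd0 <- stats::approx(signal, concentration, xout = bmax0 / 2,
                       ties = "ordered")$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(concentration)
  if (nonspecific) {
    resid_fun <- function(p) {
      signal - (p[2] * concentration / (p[1] + concentration) +
                p[3] * concentration)
    }
    p0 <- c(kd0, bmax0, 0)
    lower <- c(1e-12, 0, 0)
  } else {
    resid_fun <- function(p) {
      signal - p[2] * concentration / (p[1] + concentration)
    }
    p0 <- c(kd0, bmax0)
    lower <- c(1e-12, 0)
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fun, lower = lower,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  if (!fit$info %in% 1:4) {
    stop(sprintf("one-site fit did not converge (nls.lm info %d: %s)",
                 fit$info, fit$message), call. = FALSE)
  }
  coefficients <- c(kd = fit$par[1], bmax = fit$par[2])
  if (nonspecific) coefficients <- c(coefficients, ns = fit$par[3])
  structure(list(coefficients = coefficients, rss = sum(fit$fvec^2),
                 n = length(signal), converged = TRUE,
                 nonspecific = nonspecific,
                 concentration = concentration, signal = signal),
            class = "one_site")
}

#' @export
coef.one_site <- function(object, ...) object$coefficients

#' @export
print.one_site <- function(x, ...) {
  cat(sprintf("<one_site> Kd = %.4g nM, Bmax = %.4g (n = %d, RSS = %.4g)\n",
              x$coefficients[["kd"]], x$coefficients[["bmax"]], x$n, x$rss))
  invisible(x)
}

#' @export
predict.one_site <- function(object, concentration = object$concentration,
                             ...) {
  p <- object$coefficients
  out <- p[["bmax"]] * concentration / (p[["kd"]] + concentration)
  if (object$nonspecific) out <- out + p[["ns"]] * concentration
  out
}

#' @export
fitted.one_site <- function(object, ...) predict(object)

#' @export
residuals.one_site <- function(object, ...) object$signal - fitted(object)

#' Convert antibody concentrations between ug/mL and nM
#'
#' Unit bridge for saturation assays whose axes are in mass concentration,
#' using the IgG molecular weight (default 150 kDa).
#'
#' @param x Concentration value(s).
#' @param mw_kda Molecular weight in kDa.
#' @return Converted concentration.
#' @export
ugml_to_nm <- function(x, mw_kda = 150) x / mw_kda * 1000

#' @rdname ugml_to_nm
#' @export
nm_to_ugml <- function(x, mw_kda = 150) x * mw_kda / 1000

#' Cellular uptake per million cells
#'
#' Percentage of the deposited activity bound to cells, normalised per
#' million cells: `100 * bound / deposited / (cells / 1e6)`.
#'
#' @param cell_bound_activity Cell-bound counts (>= 0, <= deposited).
#' @param deposited_activity Total deposited counts (> 0).
#' @param cell_count Number of cells (> 0).
#' @return Uptake in % of deposited activity per 1e6 cells.
#' @export
cellular_uptake <- function(cell_bound_activity, deposited_activity,
                            cell_count) {
  if (any(deposited_activity <= 0)) {
    stop("'deposited_activity' must be > 0", call. = FALSE)
  }
  if (any(cell_count <= 0)) stop("'cell_count' must be > 0", call. = FALSE)
  if (any(cell_bound_activity < 0) ||
      any(cell_bound_activity > deposited_activity)) {
    stop("'cell_bound_activity' must lie in [0, deposited_activity]",
         call. = FALSE)
  }
  100 * cell_bound_activity / deposited_activity / (cell_count / 1e6)
}

#' Blocking fraction
#'
#' Percent reduction of uptake under antigen blocking relative to the
#' unblocked tracer: `100 * (1 - blocked / tracer)`.
#'
#' @param uptake_tracer Unblocked uptake (> 0).
#' @param uptake_blocked Uptake under blocking (>= 0).
#' @return Percent reduction.
#' @export
blocking_fraction <- function(uptake_tracer, uptake_blocked) {
  if (any(uptake_tracer <= 0)) {
    stop("'uptake_tracer' must be > 0", call. = FALSE)
  }
  if (any(uptake_blocked < 0)) {
    stop("'uptake_blocked' must be >= 0", call. = FALSE)
  }
  100 * (1 - uptake_blocked / uptake_tracer)
}
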