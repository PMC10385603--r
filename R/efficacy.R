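# Tumour growth metrics, sacrifice rules and survival statistics.

#' Calliper tumour volume
#'
#' Ellipsoid-style volume from three calliper dimensions,
#' `V = L * W * h * 3.14 / 6` (the constant is 3.14 exactly, matching the
#' study convention, not pi).
#'
#' @param length_mm,width_mm,height_mm Calliper dimensions in mm (>= 0).
#'   Vectorised.
#' @return Volume in mm^3.
#' @examples
#' tumour_volume(10, 10, 10)  # 523.33
#' @export
tumour_volume <- function(length_mm, width_mm, height_mm) {
  dims <- cbind(length_mm, width_mm, height_mm)
  if (any(!is.finite(dims)) || any(dims < 0)) {
    stop("dimensions must be finite and >= 0", call. = FALSE)
  }
  length_mm * width_mm * height_mm * 3.14 / 6
}

#' Tumour volume doubling time
#'
#' Doubling time from a log-linear least-squares fit of `log(volume)` on
#' day: `dT = ln(2) / slope`. Non-positive volumes are excluded before
#' fitting; a non-positive slope (flat or shrinking tumour) yields `NA`
#' (no doubling).
#'
#' @param days Measurement days. Must be strictly increasing.
#' @param volumes_mm3 Volumes (mm^3) at `days`.
#' @param window Two-element day range `[from, to)`; only measurements with
#'   `from <= day < to` enter the fit. Default: all days.
#' @return Doubling time in days, or `NA` if undefined.
#' @export
doubling_time <- function(days, volumes_mm3, window = c(-Inf, Inf)) {
  stopifnot(length(days) == length(volumes_mm3), length(window) == 2L)
  if (is.unsorted(days, strictly = TRUE)) {
    stop("'days' must be strictly increasing", call. = FALSE)
  }
  keep <- days >= window[1] & days < window[2] & volumes_mm3 > 0 &
    is.finite(volumes_mm3)
  if (sum(keep) < 2L) {
    stop("need at least 2 positive volumes inside the window", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, days[keep]), log(volumes_mm3[keep]))
  slope <- fit$coefficients[2L]
  if (!is.finite(slope) || slope <= 0) return(NA_real_)
  unname(log(2) / slope)
}

#' Maximum volume reduction after a reference day
#'
#' Largest relative shrinkage of the tumour after a reference day
#' (typically the second treatment injection), in percent of the volume on
#' that day: `100 * max(1 - V(t)/V(ref))` over `t >= ref`, floored at 0
#' for tumours that only grow.
#'
#' @param days Measurement days.
#' @param volumes_mm3 Volumes at `days`.
#' @param reference_day Day of the reference measurement; must be present
#'   in `days` with a positive volume.
#' @return Maximum reduction in percent, in \[0, 100\].
#' @export
max_volume_reduction <- function(days, volumes_mm3, reference_day) {
  stopifnot(length(days) == length(volumes_mm3))
  i <- which(days == reference_day)
  if (length(i) != 1L) {
    stop("no (unique) measurement at 'reference_day'", call. = FALSE)
  }
  v0 <- volumes_mm3[i]
  if (!is.finite(v0) || v0 <= 0) {
    stop("reference volume must be > 0", call. = FALSE)
  }
  after <- volumes_mm3[days >= reference_day]
  max(0, 100 * (1 - min(after) / v0))
}

#' Apply humane-endpoint sacrifice rules to a daily state series
#'
#' Scans a per-day state series and returns the first day on which any
#' sacrifice rule fires: detected paralysis, tumour volume at or above the
#' limit (2000 mm^3), or loss of 20% or more of baseline body weight. The
#' rules are checked in that order within a day. If no rule fires by the
#' study horizon (100 days) the animal is censored there.
#'
#' @param day Day numbers (strictly increasing).
#' @param volume_mm3 Tumour volume per day (use 0 for non-palpable).
#' @param weight_g Body weight per day.
#' @param paralysis Logical per day.
#' @param volume_limit Sacrifice volume threshold (mm^3).
#' @param weight_loss_fraction Fractional weight loss threshold.
#' @param horizon Study end (days); survivors are censored here.
#' @param baseline_weight Reference weight; defaults to the first entry.
#' @return A one-row data frame with `time_days`, `event` (1 event /
#'   0 censored) and `cause` (`"paralysis"`, `"volume_limit"`,
#'   `"weight_loss"`, `"study_end"`).
#' @export
apply_sacrifice_rules <- function(day, volume_mm3, weight_g, paralysis,
                                  volume_limit = 2000,
                                  weight_loss_fraction = 0.2,
                                  horizon = 100,
                                  baseline_weight = weight_g[1L]) {
  stopifnot(length(day) == length(volume_mm3),
            length(day) == length(weight_g),
            length(day) == length(paralysis))
  if (is.unsorted(day, strictly = TRUE)) {
    stop("'day' must be strictly increasing", call. = FALSE)
  }
  for (i in seq_along(day)) {
    if (day[i] > horizon) break
    cause <- if (isTRUE(paralysis[i])) {
      "paralysis"
    } else if (volume_mm3[i] >= volume_limit) {
      "volume_limit"
    } else if (weight_g[i] <= (1 - weight_loss_fraction) * baseline_weight) {
      "weight_loss"
    } else {
      NULL
    }
    if (!is.null(cause)) {
      return(data.frame(time_days = day[i], event = 1L, cause = cause,
                        stringsAsFactors = FALSE))
    }
  }
  data.frame(time_days = horizon, event = 0L, cause = "study_end",
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimator
#'
#' Product-limit survival estimate with median survival defined as the
#' smallest observed time at which the estimated survival drops to 0.5 or
#' below; if the curve never reaches 0.5 the median is reported as `NA`.
#' The step function is computed by [survival::survfit()].
#'
#' @param time_days Follow-up times (> 0).
#' @param event Event indicator: 1 (or `TRUE`) death/sacrifice, 0 censored.
#' @return An object of class `"km_fit"`: list with `time`, `surv`,
#'   `n_risk`, `n_event`, `median`, `n`, and the underlying `survfit`
#'   object.
#' @export
km_estimator <- function(time_days, event) {
  stopifnot(length(time_days) == length(event))
  if (any(time_days <= 0)) stop("'time_days' must be > 0", call. = FALSE)
  event <- as.integer(event)
  sf <- survival::survfit(survival::Surv(time_days, event) ~ 1,
                          conf.type = "none")
  s <- summary(sf, censored = TRUE)
  med <- {
    i <- which(sf$surv <= 0.5 & sf$n.event > 0)
    if (length(i)) min(sf$time[i]) else NA_real_
  }
  structure(list(time = s$time, surv = s$surv, n_risk = s$n.risk,
                 n_event = s$n.event, median = med,
                 n = length(time_days), survfit = sf),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n = %d, events = %d, median = %s days\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
plot.km_fit <- function(x, ...) {
  graphics::plot(x$survfit, xlab = "days", ylab = "survival", ...)
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param fit A `"km_fit"` object.
#' @param times Times at which to evaluate the step function.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(fit, times) {
  stopifnot(inherits(fit, "km_fit"))
  vapply(times, function(t) {
    i <- which(fit$time <= t)
    if (length(i)) fit$surv[max(i)] else 1
  }, numeric(1))
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' Standard one-degree-of-freedom log-rank chi-square via
#' [survival::survdiff()], with a two-sided p-value. When the statistic's
#' variance is zero (e.g. no events) the p-value is reported as `NA`.
#'
#' @param time_days Follow-up times.
#' @param event Event indicators (1 event, 0 censored).
#' @param group Two-level group labels.
#' @return A list with `chi2`, `df = 1` and `p`.
#' @export
logrank_test <- function(time_days, event, group) {
  stopifnot(length(time_days) == length(event),
            length(time_days) == length(group))
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("'group' must have 2 levels", call. = FALSE)
  if (sum(event) == 0L) {
    return(list(chi2 = 0, df = 1L, p = NA_real_))
  }
  sd <- tryCatch(
    survival::survdiff(survival::Surv(time_days, as.integer(event)) ~ group),
    error = function(e) NULL)
  if (is.null(sd) || !is.finite(sd$chisq)) {
    return(list(chi2 = NA_real_, df = 1L, p = NA_real_))
  }
  list(chi2 = unname(sd$chisq), df = 1L,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Summarise per-group survival
#'
#' @param records Data frame with `group`, `time_days`, `event` columns
#'   (the schema produced by [gen_survival()]).
#' @return Data frame with per-group `n`, `events`, `median_days`.
#' @export
survival_summary <- function(records) {
  stopifnot(all(c("group", "time_days", "event") %in% names(records)))
  pieces <- lapply(split(records, records$group), function(d) {
    km <- km_estimator(d$time_days, d$event)
    data.frame(group = d$group[1L], n = km$n, events = sum(d$event),
               median_days = km$median, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
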