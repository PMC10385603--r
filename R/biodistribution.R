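# Ex vivo biodistribution: counts -> %ID/g, group summaries, ratios, tests.

#' Injected activity corrected for the tail remainder
#'
#' Activity actually delivered systemically: the injected activity minus
#' what remained at the tail injection site at sacrifice (both decay-
#' corrected to injection time). A zero corrected activity is allowed but
#' flagged with a warning, since every downstream per-cent-of-dose quantity
#' is undefined for it.
#'
#' @param injected Injected activity (MBq). Vectorised.
#' @param tail_remainder Activity remaining at the injection site (MBq);
#'   must not exceed `injected`.
#' @return Corrected injected activity (MBq).
#' @export
corrected_injected_activity <- function(injected, tail_remainder) {
  if (any(!is.finite(injected)) || any(injected < 0) ||
      any(!is.finite(tail_remainder)) || any(tail_remainder < 0)) {
    stop("activities must be finite and >= 0", call. = FALSE)
  }
  if (any(tail_remainder > injected)) {
    stop("'tail_remainder' exceeds 'injected'", call. = FALSE)
  }
  out <- injected - tail_remainder
  if (any(out == 0)) {
    warning("corrected injected activity is zero for some records (degenerate)",
            call. = FALSE)
  }
  out
}

#' Convert counter counts-per-minute to activity
#'
#' @param cpm Counts per minute.
#' @param counter_efficiency Counter efficiency as a fraction in (0, 1].
#' @return Activity in MBq (`cpm / efficiency / 60 / 1e6`).
#' @export
cpm_to_mbq <- function(cpm, counter_efficiency) {
  if (any(!is.finite(counter_efficiency)) || any(counter_efficiency <= 0) ||
      any(counter_efficiency > 1)) {
    stop("'counter_efficiency' must lie in (0, 1]", call. = FALSE)
  }
  if (any(!is.finite(cpm)) || any(cpm < 0)) {
    stop("'cpm' must be finite and >= 0", call. = FALSE)
  }
  cpm / counter_efficiency / 60 / 1e6
}

.biodist_columns <- c("mouse_id", "group", "organ", "timepoint_h",
                      "organ_mass_g", "organ_cpm", "counter_efficiency",
                      "injected_activity_mbq", "tail_remainder_mbq",
                      "sacrifice_time_h")

#' Percent injected dose per gram
#'
#' Convert per-mouse organ counts to %ID/g using the study conventions:
#' counts are converted to activity via the counter efficiency, decay-
#' corrected back to injection time over the sacrifice delay, and expressed
#' as a percentage of the tail-corrected injected activity per gram of
#' tissue:
#' \deqn{\%ID/g = 100 \cdot \frac{A_{organ} / f_{decay}(t_{sac})}
#'   {(A_{inj} - A_{tail}) \cdot m_{organ}}}
#'
#' @param records A data frame of biodistribution records with columns
#'   `mouse_id, group, organ, timepoint_h, organ_mass_g, organ_cpm,
#'   counter_efficiency, injected_activity_mbq, tail_remainder_mbq,
#'   sacrifice_time_h` (the CSV schema written by [gen_biodistribution()]
#'   and read by [read_biodistribution()]).
#' @param nuclide A [radionuclide()] record; defaults to [cu64()].
#' @return The input data frame with an added `pid_g` column (%ID/g).
#' @export
percent_id_per_gram <- function(records, nuclide = cu64()) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.biodist_columns, names(records))
  if (length(missing_cols)) {
    stop("missing biodistribution columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(records$organ_mass_g <= 0)) {
    stop("'organ_mass_g' must be > 0", call. = FALSE)
  }
  inj <- corrected_injected_activity(records$injected_activity_mbq,
                                     records$tail_remainder_mbq)
  if (any(inj <= 0)) {
    stop("corrected injected activity must be > 0 to form %ID/g",
         call. = FALSE)
  }
  organ_mbq <- cpm_to_mbq(records$organ_cpm, records$counter_efficiency)
  organ_mbq_t0 <- decay_correct(organ_mbq, records$sacrifice_time_h, nuclide)
  records$pid_g <- 100 * organ_mbq_t0 / inj / records$organ_mass_g
  records
}

#' Group summary statistics of %ID/g
#'
#' Sample mean, sample standard deviation (n - 1 denominator) and group size
#' of %ID/g per organ/group/timepoint. With a single record the SD is
#' reported as `NA`.
#'
#' @param records A data frame containing at least `group`, `organ`,
#'   `timepoint_h` and `pid_g` columns (see [percent_id_per_gram()]).
#' @param organ,timepoint Optional filters; by default all organs and
#'   timepoints are summarised.
#' @return A data frame with columns `group, organ, timepoint_h, mean_pid_g,
#'   sd_pid_g, n`, ordered by group, organ and time.
#' @export
group_stats <- function(records, organ = NULL, timepoint = NULL) {
  stopifnot(is.data.frame(records), "pid_g" %in% names(records))
  if (!is.null(organ)) records <- records[records$organ %in% organ, ]
  if (!is.null(timepoint)) {
    records <- records[records$timepoint_h %in% timepoint, ]
  }
  if (nrow(records) == 0L) {
    stop("no matching biodistribution records", call. = FALSE)
  }
  key <- interaction(records$group, records$organ, records$timepoint_h,
                     drop = TRUE)
  pieces <- lapply(split(records, key), function(d) {
    data.frame(group = d$group[1L], organ = d$organ[1L],
               timepoint_h = d$timepoint_h[1L],
               mean_pid_g = mean(d$pid_g),
               sd_pid_g = if (nrow(d) > 1L) stats::sd(d$pid_g) else NA_real_,
               n = nrow(d))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$group, out$organ, out$timepoint_h), ]
  rownames(out) <- NULL
  out
}

#' Tumour-to-organ ratio
#'
#' Ratio of a tumour-level quantity to an organ-level quantity in the same
#' units (%ID/g uptake or Gy absorbed dose).
#'
#' @param tumour_value,organ_value Values in common units; `organ_value`
#'   must be positive.
#' @return `tumour_value / organ_value`.
#' @export
tumour_to_organ_ratio <- function(tumour_value, organ_value) {
  if (any(!is.finite(organ_value)) || any(organ_value <= 0)) {
    stop("'organ_value' must be finite and > 0", call. = FALSE)
  }
  tumour_value / organ_value
}

#' Unpaired two-sample t test
#'
#' Two-sided unpaired t test between groups, Welch's unequal-variance form
#' by default (with Welch-Satterthwaite degrees of freedom); the pooled-
#' variance Student form is available with `pooled = TRUE`.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @param pooled Use the pooled-variance (equal-variance) statistic.
#' @return A list with elements `t`, `df` and `p` (two-sided).
#' @export
welch_t_test <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  fit <- stats::t.test(group_a, group_b, var.equal = pooled)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Extract one organ/group time series from a biodistribution summary
#'
#' @param summary A summary data frame from [group_stats()].
#' @param organ,group Which series to extract.
#' @return An object of class `"organ_series"`: a list with `organ`,
#'   `group`, `timepoints_h`, `mean_pid_g`, `sd_pid_g`, `n`.
#' @export
organ_time_series <- function(summary, organ, group) {
  d <- summary[summary$organ == organ & summary$group == group, ]
  if (nrow(d) == 0L) stop("no such organ/group in summary", call. = FALSE)
  d <- d[order(d$timepoint_h), ]
  structure(list(organ = organ, group = group,
                 timepoints_h = d$timepoint_h, mean_pid_g = d$mean_pid_g,
                 sd_pid_g = d$sd_pid_g, n = d$n),
            class = "organ_series")
}

#' @export
print.organ_series <- function(x, ...) {
  cat(sprintf("<organ_series> %s (%s), %d timepoints\n",
              x$organ, x$group, length(x$timepoints_h)))
  print(data.frame(timepoint_h = x$timepoints_h, mean_pid_g = x$mean_pid_g,
                   sd_pid_g = x$sd_pid_g, n = x$n), row.names = FALSE)
  invisible(x)
}

#' Read / write biodistribution record CSVs
#'
#' Plain CSV with the column schema documented in [percent_id_per_gram()].
#'
#' @param path File path.
#' @param records Data frame of records (for writing).
#' @return `read_biodistribution` returns the records data frame.
#' @export
read_biodistribution <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.biodist_columns, names(d))
  if (length(missing_cols)) {
    stop("missing biodistribution columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d
}

#' @rdname read_biodistribution
#' @export
write_biodistribution <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
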