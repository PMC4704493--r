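# Survival validation: Kaplan-Meier estimation, log-rank testing, and the
# percentile cutoff-scan procedure with train/validation confirmation.
# Product-limit estimation and the log-rank statistic are delegated to
# the survival package; the cutoff-scan procedure is implemented here.

#' Randomly split a cohort into training and validation sets
#'
#' @param cohort A \code{\link{survival_cohort}} data frame.
#' @param fractions Two fractions summing to 1 (default 2/3 training,
#'   1/3 validation). Training size is \code{round(f1 * n)}.
#' @param seed Integer seed; splits are reproducible and leave the
#'   session RNG untouched.
#' @return List with elements \code{training} and \code{validation}
#'   (disjoint, exhaustive \code{survival_cohort}s).
#' @export
split_cohort <- function(cohort, fractions = c(2 / 3, 1 / 3), seed = 1L) {
  cohort <- survival_cohort(cohort)
  if (length(fractions) != 2L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    ms_config_error("fractions must be two positive numbers summing to 1")
  }
  n <- nrow(cohort)
  if (n < 6L) ms_config_error("cohort must have at least 6 samples")
  n_train <- round(fractions[1L] * n)
  train_idx <- with_seed(seed, sample.int(n, n_train))
  list(training = cohort[sort(train_idx), , drop = FALSE],
       validation = cohort[setdiff(seq_len(n), train_idx), , drop = FALSE])
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate over the distinct event times; individuals
#' censored at t are counted at risk at t (events precede censorings at
#' tied times). Median survival is the smallest time at which the curve
#' reaches 0.5 or below, undefined (NA) if never reached.
#'
#' @param records A \code{\link{survival_cohort}} (the \code{expression}
#'   column may be absent; only time/event are used).
#' @return An object of class \code{"km_estimate"}: \code{time} (distinct
#'   event times), \code{surv} (S(t) after each), \code{n_risk},
#'   \code{n_event}, \code{median_survival}, \code{n}.
#' @export
km_curve <- function(records) {
  if (NROW(records) < 1L) ms_empty_error("need at least one record")
  time <- as.numeric(records$time)
  event <- as.integer(records$event)
  if (anyNA(time) || any(time < 0)) {
    ms_validation_error("survival time must be non-negative")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  s_time <- fit$time[keep]
  s_surv <- fit$surv[keep]
  med <- if (any(s_surv <= 0.5)) s_time[which(s_surv <= 0.5)[1L]] else
    NA_real_
  structure(list(time = s_time, surv = s_surv,
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 median_survival = med, n = length(time)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> n = %d | %d event time(s) | median = %s\n",
              x$n, length(x$time),
              if (is.na(x$median_survival)) "not reached" else
                format(x$median_survival)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison: at each distinct event time, observed
#' versus expected deaths in group 1 under the hypergeometric null,
#' summarized as a 1-df chi-square.
#'
#' @param group1,group2 Survival record data frames (columns \code{time},
#'   \code{event}).
#' @return List with \code{chi_square} and \code{p} (upper chi-square
#'   tail, 1 df).
#' @export
logrank_test <- function(group1, group2) {
  if (NROW(group1) == 0L || NROW(group2) == 0L) {
    ms_validation_error("both groups must be non-empty")
  }
  time <- c(as.numeric(group1$time), as.numeric(group2$time))
  event <- c(as.integer(group1$event), as.integer(group2$event))
  if (anyNA(time) || any(time < 0)) {
    ms_validation_error("survival time must be non-negative")
  }
  if (sum(event) == 0L) {
    ms_degenerate_error("no events observed: log-rank undefined")
  }
  grp <- rep(c(1L, 2L), c(NROW(group1), NROW(group2)))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  chi <- as.numeric(sd_fit$chisq)
  list(chi_square = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Percentile cutoff scan on a training cohort
#'
#' Dichotomizes the cohort at every candidate expression percentile
#' (default each integer percentile from the 25th to the 75th; "high" =
#' expression strictly above the cutoff value, quantiles by inclusive
#' linear interpolation), runs a log-rank test at each candidate, and
#' records the candidates that split survival significantly.
#'
#' @param training A \code{\link{survival_cohort}}.
#' @param percentile_range Lower/upper candidate percentiles (default
#'   \code{c(25, 75)}).
#' @param step Candidate spacing in percentiles (default 1).
#' @param alpha Training significance level (default 0.05).
#' @return An object of class \code{"cutoff_scan_result"}: data frame
#'   \code{candidates} with per-percentile \code{cutoff_value},
#'   \code{n_low}, \code{n_high}, \code{chi_square}, \code{p},
#'   \code{selected}; plus \code{best} (the minimum-p candidate
#'   percentile) and \code{alpha}. Candidates where a side is empty or no
#'   event occurs carry NA p and are never selected.
#' @export
cutoff_scan <- function(training, percentile_range = c(25, 75), step = 1,
                        alpha = 0.05) {
  training <- survival_cohort(training)
  if (length(percentile_range) != 2L ||
      percentile_range[1L] >= percentile_range[2L] ||
      percentile_range[1L] < 0 || percentile_range[2L] > 100) {
    ms_config_error("percentile_range must be increasing within [0, 100]")
  }
  if (!is_scalar_number(step) || step <= 0) {
    ms_config_error("step must be positive")
  }
  expr <- training$expression
  if (length(unique(expr)) == 1L) {
    ms_degenerate_error("all expression values are equal: no cutoff exists")
  }
  pct <- seq(percentile_range[1L], percentile_range[2L], by = step)
  out <- data.frame(percentile = pct,
                    cutoff_value = as.numeric(
                      stats::quantile(expr, pct / 100, type = 7)),
                    n_low = NA_integer_, n_high = NA_integer_,
                    chi_square = NA_real_, p = NA_real_,
                    selected = FALSE)
  for (i in seq_along(pct)) {
    high <- expr > out$cutoff_value[i]
    out$n_low[i] <- sum(!high)
    out$n_high[i] <- sum(high)
    if (out$n_low[i] == 0L || out$n_high[i] == 0L) next
    lr <- tryCatch(
      logrank_test(training[!high, , drop = FALSE],
                   training[high, , drop = FALSE]),
      mimicscreen_degenerate_error = function(e) NULL)
    if (is.null(lr)) next
    out$chi_square[i] <- lr$chi_square
    out$p[i] <- lr$p
  }
  if (all(is.na(out$p))) {
    ms_degenerate_error("no candidate percentile admits a log-rank test")
  }
  out$selected <- !is.na(out$p) & out$p < alpha
  best <- out$percentile[which.min(out$p)]
  structure(list(candidates = out, best = best, alpha = alpha),
            class = "cutoff_scan_result")
}

#' @export
print.cutoff_scan_result <- function(x, ...) {
  cat(sprintf(
    "<cutoff_scan_result> %d candidate(s) | %d selected at alpha %.3g | best at percentile %g\n",
    nrow(x$candidates), sum(x$candidates$selected), x$alpha, x$best))
  invisible(x)
}

#' Confirm a training-derived cutoff on the validation cohort
#'
#' Dichotomizes the held-out cohort at the absolute expression cutoff
#' learned on training and reports the validation log-rank p together
#' with per-group Kaplan-Meier median survivals.
#'
#' @param validation A \code{\link{survival_cohort}}.
#' @param cutoff_value Absolute expression cutoff from the training scan.
#' @param alpha Significance level recorded on the result (default 0.05).
#' @return List with \code{p}, \code{chi_square}, \code{significant},
#'   \code{median_low}, \code{median_high}, \code{n_low}, \code{n_high}.
#' @export
validate_cutoff <- function(validation, cutoff_value, alpha = 0.05) {
  validation <- survival_cohort(validation)
  if (!is_scalar_number(cutoff_value)) {
    ms_config_error("cutoff_value must be a number")
  }
  high <- validation$expression > cutoff_value
  if (sum(high) == 0L || sum(!high) == 0L) {
    ms_degenerate_error(
      "cutoff leaves an empty group in the validation cohort")
  }
  low_grp <- validation[!high, , drop = FALSE]
  high_grp <- validation[high, , drop = FALSE]
  lr <- logrank_test(low_grp, high_grp)
  list(p = lr$p, chi_square = lr$chi_square,
       significant = lr$p < alpha,
       median_low = km_curve(low_grp)$median_survival,
       median_high = km_curve(high_grp)$median_survival,
       n_low = nrow(low_grp), n_high = nrow(high_grp))
}
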