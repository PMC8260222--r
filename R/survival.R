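#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] with plain (Greenwood) confidence intervals
#' and returns a tidy step-function table. At tied times, events are
#' processed before censorings, so both contribute to the at-risk count at
#' that time.
#'
#' @param time Positive survival times (months).
#' @param event 1 = event observed, 0 = censored.
#' @param sample_id Optional sample ids used in error messages.
#' @return An object of class `km_curve`: data frame `time`, `n.risk`,
#'   `n.event`, `n.censor`, `surv`, `std.err` (Greenwood SE of S), `lower`,
#'   `upper`.
#' @export
km_estimate <- function(time, event, sample_id = NULL) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (any(time <= 0)) {
    bad <- which(time <= 0)
    ids <- if (!is.null(sample_id)) sample_id[bad] else bad
    stop("non-positive survival time(s) for: ", paste(ids, collapse = ", "))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "plain")
  out <- data.frame(time = fit$time, n.risk = fit$n.risk,
                    n.event = fit$n.event, n.censor = fit$n.censor,
                    surv = fit$surv,
                    std.err = fit$std.err * fit$surv,  # Greenwood SE of S
                    lower = fit$lower, upper = fit$upper)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Median survival time of a KM curve
#'
#' The smallest event time at which the survival function drops to 0.5 or
#' below; `NA` when the curve never reaches 0.5.
#'
#' @param curve A `km_curve`.
#' @return Numeric time, or `NA`.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- curve$n.event > 0 & curve$surv <= 0.5 + 1e-12
  if (!any(hit)) return(NA_real_)
  min(curve$time[hit])
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-squared via [survival::survdiff()]. With zero
#' events in either direction the test is undefined and p = 1 is returned
#' with a warning.
#'
#' @param time Positive survival times.
#' @param event 1 = event, 0 = censored.
#' @param group Two-level grouping vector.
#' @return List with `chisq`, `df`, `p.value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("log-rank test needs exactly 2 groups")
  if (any(table(group) == 0L)) stop("both groups must be non-empty")
  if (sum(event) == 0) {
    warning("no events observed; log-rank test degenerate, p = 1")
    return(list(chisq = 0, df = 1L, p.value = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq), df = 1L,
       p.value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Median split of an expression vector
#'
#' Samples strictly above the median go to `"high"`; ties with the median go
#' to `"low"`, keeping the split deterministic.
#'
#' @param values Named numeric vector (sample id -> expression).
#' @return Factor with levels `"low"`, `"high"`, named like `values`.
#' @export
split_median <- function(values) {
  stopifnot(length(values) >= 4L)
  if (length(unique(values)) == 1L)
    stop("all expression values equal; no median split possible")
  med <- stats::median(values)
  out <- factor(ifelse(values > med, "high", "low"),
                levels = c("low", "high"))
  names(out) <- names(values)
  out
}

#' Best-separation split of an expression vector against survival
#'
#' Scans every distinct expression value between the 10th and 90th
#' percentiles as a cutpoint (low: value <= cut, high: value > cut),
#' computes the log-rank p for each, and returns the minimizing cutpoint.
#' The returned p-value is the unadjusted minimum over the scan and is
#' anti-conservative under the null; it is labeled as such in the `caveat`
#' field and should not be read as a calibrated significance level.
#'
#' @param values Named numeric expression vector.
#' @param time,event Survival data aligned with `values`.
#' @param limits Quantile limits of the admissible cutpoint range.
#' @return List with `cutpoint`, `assignment` (factor low/high),
#'   `p.value`, `chisq`, `n_cutpoints` scanned, and `caveat`.
#' @export
split_best <- function(values, time, event, limits = c(0.1, 0.9)) {
  stopifnot(length(values) == length(time), length(time) == length(event))
  if (length(values) < 10L) stop("need at least 10 samples")
  if (sum(event) == 0) stop("need at least one observed event")
  qs <- stats::quantile(values, limits, names = FALSE)
  cand <- sort(unique(values))
  cand <- cand[cand >= qs[1] & cand <= qs[2] & cand < max(values)]
  if (!length(cand)) stop("no admissible cutpoint in the scanned range")
  ps <- vapply(cand, function(cut) {
    grp <- values > cut
    suppressWarnings(logrank_test(time, event, grp)$p.value)
  }, numeric(1))
  best <- which.min(ps)  # ties -> smallest cutpoint
  cut <- cand[best]
  assignment <- factor(ifelse(values > cut, "high", "low"),
                       levels = c("low", "high"))
  names(assignment) <- names(values)
  lr <- logrank_test(time, event, assignment)
  list(cutpoint = cut, assignment = assignment, p.value = lr$p.value,
       chisq = lr$chisq, n_cutpoints = length(cand),
       caveat = "minimum p over scanned cutpoints, unadjusted for the scan")
}
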