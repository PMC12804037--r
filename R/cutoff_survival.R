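# Cut-off derivation and survival analysis on cohort tables.
#
# Two routes to a data-driven TSR cut-off are provided: (i) ROC/Youden on
# outcome binarized at a survival horizon, and (ii) a maximally selected log-rank scan
# that maximizes the two-group log-rank statistic over a percent grid.
# Stratified survival analyses (Kaplan-Meier, log-rank, Cox PH with
# Breslow ties, reversed-KM median follow-up, chi-square associations)
# operate on the same cohort tables.

.endpoint_cols <- function(endpoint) {
  endpoint <- match.arg(endpoint, c("dfs", "os"))
  list(time = paste0(endpoint, "_months"), event = paste0(endpoint, "_event"))
}

#' Read and validate a cohort table
#'
#' Expected TSV columns: \code{id}, \code{tsr_percent}, \code{dfs_months},
#' \code{dfs_event}, \code{os_months}, \code{os_event}, plus free covariate
#' columns. Tab-separated, UTF-8, header required.
#'
#' @param path TSV path.
#' @return A validated data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_cohort(d)
}

#' Validate a cohort data.frame
#'
#' @param d data.frame with the cohort columns.
#' @return The data.frame, invisibly checked.
#' @export
validate_cohort <- function(d) {
  need <- c("id", "tsr_percent", "dfs_months", "dfs_event", "os_months", "os_event")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$id)) stop("duplicate patient ids in cohort")
  if (any(d$tsr_percent < 0 | d$tsr_percent > 100)) stop("tsr_percent outside [0, 100]")
  if (any(d$dfs_months < 0) || any(d$os_months < 0)) stop("negative survival times")
  if (!all(d$dfs_event %in% c(0, 1)) || !all(d$os_event %in% c(0, 1)))
    stop("event flags must be 0/1")
  d
}

#' Binarize survival outcome at a fixed horizon
#'
#' Outcome 1 if the event occurred by the horizon; 0 if event-free with
#' follow-up reaching the horizon; patients censored before the horizon are
#' excluded.
#'
#' @param cohort Cohort data.frame.
#' @param endpoint \code{"dfs"} or \code{"os"}.
#' @param horizon_months Horizon in months (> 0).
#' @return List with \code{scores}, \code{outcomes}, \code{n_excluded}.
#' @export
binarize_at_horizon <- function(cohort, endpoint = "dfs", horizon_months = 36) {
  stopifnot(horizon_months > 0)
  cols <- .endpoint_cols(endpoint)
  tt <- cohort[[cols$time]]; ev <- cohort[[cols$event]]
  event_by <- ev == 1 & tt <= horizon_months
  at_risk <- tt >= horizon_months
  keep <- event_by | at_risk
  out <- as.integer(event_by[keep])
  if (sum(out == 1) < 2 || sum(out == 0) < 2)
    stop("fewer than 2 patients in an outcome class after horizon exclusion")
  list(scores = cohort$tsr_percent[keep], outcomes = out,
       n_excluded = sum(!keep))
}

#' ROC-optimal cut-off by the Youden index
#'
#' Candidate thresholds are the unique observed scores; a patient is test
#' positive when score > threshold; J = sensitivity + specificity - 1 is
#' maximized, ties resolved to the smallest threshold.
#'
#' @param scores Numeric scores (TSR percent).
#' @param outcomes Binary outcomes (1 = event).
#' @param horizon_months Recorded in the result for provenance (optional).
#' @return A \code{cutoff_result}: method, cutoff_percent, criterion (J),
#'   horizon_months, trace (threshold vs criterion).
#' @export
youden_cutoff <- function(scores, outcomes, horizon_months = NULL) {
  stopifnot(length(scores) == length(outcomes))
  if (length(unique(outcomes)) < 2)
    stop("degenerate outcomes: both classes must be present")
  th <- sort(unique(scores))
  npos <- sum(outcomes == 1); nneg <- sum(outcomes == 0)
  j <- vapply(th, function(t) {
    p <- scores > t
    sum(p & outcomes == 1) / npos + sum(!p & outcomes == 0) / nneg - 1
  }, numeric(1))
  best <- which.max(j)  # which.max returns the first (smallest) maximizer
  structure(list(method = "youden",
                 cutoff_percent = th[best],
                 criterion = j[best],
                 horizon_months = horizon_months,
                 trace = data.frame(threshold = th, criterion = j)),
            class = "cutoff_result")
}

# vectorized two-group log-rank chi-square (1 df); grp logical
.logrank_chisq <- function(time, event, grp) {
  o <- order(time)
  time <- time[o]; event <- event[o]; grp <- grp[o]
  n <- length(time)
  evi <- which(event == 1)
  if (!length(evi)) stop("no events in pooled data")
  ut <- unique(time[evi])                     # sorted (time already ordered)
  f <- match(time[evi], ut)                   # integer grouping, exact doubles
  d <- tabulate(f, nbins = length(ut))
  d1 <- vapply(split(as.numeric(grp[evi]), f), sum, numeric(1))
  first <- match(ut, time)                    # first index at each event time
  cg <- c(0, cumsum(grp))
  nrisk <- n - (first - 1L)
  n1 <- sum(grp) - cg[first]
  E1 <- sum(d * n1 / nrisk)
  vterm <- ifelse(nrisk > 1,
                  d * (n1 / nrisk) * (1 - n1 / nrisk) * (nrisk - d) / (nrisk - 1),
                  0)
  V <- sum(vterm)
  if (V <= 0) return(0)
  (sum(d1) - E1)^2 / V
}

#' Cut-off by maximally selected log-rank statistic
#'
#' Scans thresholds on a percent grid; at each admissible threshold (both
#' groups at least \code{min_group_fraction} of the cohort) the two-group
#' log-rank chi-square is computed; the threshold maximizing it is
#' returned together with the scan trace. The scan tests many thresholds,
#' so the maximal statistic's nominal p-value is anti-conservative; the
#' result carries \code{multiplicity_warning = TRUE} and the number of
#' thresholds tested rather than a corrected p-value.
#'
#' @param cohort Cohort data.frame.
#' @param endpoint \code{"dfs"} or \code{"os"}.
#' @param grid_step Threshold grid step in percent (default 1).
#' @param min_group_fraction Minimum fraction of patients per group
#'   (default 0.10).
#' @return A \code{cutoff_result} with fields method, cutoff_percent,
#'   criterion (chi-square), p_uncorrected, n_thresholds,
#'   multiplicity_warning, trace.
#' @export
logrank_scan_cutoff <- function(cohort, endpoint = "dfs", grid_step = 1,
                                min_group_fraction = 0.10) {
  cols <- .endpoint_cols(endpoint)
  tt <- cohort[[cols$time]]; ev <- cohort[[cols$event]]
  if (sum(ev) < 20) stop("log-rank scan requires at least 20 events")
  n <- nrow(cohort)
  th <- seq(0, 100, by = grid_step)
  nh <- vapply(th, function(t) sum(cohort$tsr_percent > t), numeric(1))
  ok <- pmin(nh, n - nh) >= min_group_fraction * n
  th <- th[ok]
  if (!length(th)) stop("no admissible thresholds under min_group_fraction")
  chi <- vapply(th, function(t) .logrank_chisq(tt, ev, cohort$tsr_percent > t),
                numeric(1))
  best <- which.max(chi)
  structure(list(method = "logrank_scan",
                 cutoff_percent = th[best],
                 criterion = chi[best],
                 p_uncorrected = stats::pchisq(chi[best], df = 1, lower.tail = FALSE),
                 n_thresholds = length(th),
                 multiplicity_warning = TRUE,
                 trace = data.frame(threshold = th, criterion = chi)),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result %s: cutoff %.4g%%, criterion %.4g>\n",
              x$method, x$cutoff_percent, x$criterion))
  invisible(x)
}

#' Kaplan-Meier estimate with horizon survival rates
#'
#' @param times Follow-up times (months, >= 0).
#' @param events Event indicators (1 = event, 0 = censored).
#' @param horizons Optional vector of horizons (months) at which survival
#'   rates are reported.
#' @return List with \code{curve} (data.frame time, n_risk, n_event,
#'   survival) and \code{horizon_survival} (named numeric).
#' @export
km_estimate <- function(times, events, horizons = NULL) {
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, survival = fit$surv)
  hs <- NULL
  if (!is.null(horizons)) {
    sm <- summary(fit, times = horizons, extend = TRUE)
    hs <- stats::setNames(sm$surv, paste0("t", horizons))
  }
  list(curve = curve, horizon_survival = hs)
}

#' Two-group log-rank test
#'
#' @param times_a,events_a Group A follow-up times and event flags.
#' @param times_b,events_b Group B follow-up times and event flags.
#' @return List with \code{chi_square} and \code{p} (1 df).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b)) stop("both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0) stop("no events in pooled data")
  tt <- c(times_a, times_b); ev <- c(events_a, events_b)
  g <- factor(rep(c("A", "B"), c(length(times_a), length(times_b))))
  sd <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  chi <- sd$chisq
  list(chi_square = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling; returns exponentiated
#' coefficients with Wald 95% confidence intervals.
#'
#' @param cohort Cohort data.frame.
#' @param endpoint \code{"dfs"} or \code{"os"}.
#' @param terms Character vector of covariate column names (or expressions)
#'   entering the linear predictor.
#' @return data.frame with columns term, coef, hr, ci_lower, ci_upper, p;
#'   the fitted model is attached as attribute \code{"fit"}.
#' @export
cox_fit <- function(cohort, endpoint = "dfs", terms) {
  cols <- .endpoint_cols(endpoint)
  if (sum(cohort[[cols$event]]) < 1) stop("no events: Cox model undefined")
  fml <- stats::as.formula(paste0("survival::Surv(", cols$time, ", ", cols$event,
                                  ") ~ ", paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = cohort, ties = "breslow")
  if (any(is.na(stats::coef(fit))))
    stop("collinear design: Cox coefficients not estimable")
  s <- summary(fit)
  co <- s$coefficients
  out <- data.frame(term = rownames(co),
                    coef = co[, "coef"],
                    hr = exp(co[, "coef"]),
                    ci_lower = s$conf.int[, "lower .95"],
                    ci_upper = s$conf.int[, "upper .95"],
                    p = co[, "Pr(>|z|)"],
                    row.names = NULL)
  attr(out, "fit") <- fit
  out
}

#' Median follow-up by reversed Kaplan-Meier
#'
#' KM with the censoring indicator inverted: censored patients contribute
#' "events" (observed follow-up), deceased patients are censored.
#'
#' @param cohort Cohort data.frame.
#' @param endpoint \code{"dfs"} or \code{"os"} (default \code{"os"}).
#' @return List with \code{median_months} (NA when not reached),
#'   \code{reached}, and \code{lower_bound} (largest follow-up time; an
#'   open lower bound when the median is not reached).
#' @export
reverse_km_followup <- function(cohort, endpoint = "os") {
  cols <- .endpoint_cols(endpoint)
  tt <- cohort[[cols$time]]; ev <- cohort[[cols$event]]
  if (!length(tt)) stop("empty cohort")
  fit <- survival::survfit(survival::Surv(tt, 1 - ev) ~ 1)
  med <- unname(summary(fit)$table["median"])
  list(median_months = med, reached = !is.na(med), lower_bound = max(tt))
}

#' Chi-square association between TSR group and a categorical variable
#'
#' Pearson chi-square (uncorrected) on the group-by-variable contingency
#' table.
#'
#' @param cohort Cohort data.frame.
#' @param variable Name of the categorical covariate column.
#' @param group_label Name of the TSR-group column, or a vector of group
#'   labels of length \code{nrow(cohort)}.
#' @return List with \code{chi_square}, \code{p}, \code{contingency}.
#' @export
association_test <- function(cohort, variable, group_label = "tsr_class") {
  g <- if (length(group_label) == 1L && is.character(group_label))
    cohort[[group_label]] else group_label
  v <- cohort[[variable]]
  if (length(unique(v)) < 2) stop("variable needs at least 2 levels")
  tab <- table(g, v)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0)) stop("expected cell count of zero")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi_square = unname(ct$statistic), p = unname(ct$p.value),
       contingency = tab)
}
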