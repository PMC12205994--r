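# Product-limit survival curves and multi-group log-rank tests over the six
# subgroups for the RFS, DMFS and OS endpoints. The estimators are computed
# by the survival package (survfit / survdiff); this module fixes the
# conventions (events before censorings at tied times, months throughout,
# no administrative truncation) and the comparison layout.

#' Kaplan-Meier product-limit estimate
#'
#' Returns the survival curve evaluated at the distinct event times. At a
#' tied time, events are processed before censorings (the standard
#' product-limit convention, stated explicitly because months-resolution
#' follow-up ties heavily). Censoring leaves the curve unchanged.
#'
#' @param times Nonnegative follow-up times (months).
#' @param events Event indicators, 1 = event, 0 = censored.
#' @return An object of class `km_curve`: ascending `event_times`,
#'   `n_at_risk`, `n_events`, and the `survival` probabilities at those
#'   times. With no events all fields are empty and survival is identically
#'   one.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 0))$survival  # 2/3, 1/3
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) stop("times and events must match")
  if (!length(times)) stop("need at least one observation")
  if (anyNA(times) || anyNA(events)) stop("times/events must not contain NA")
  if (any(times < 0)) stop("negative time")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep],
                 n_at_risk = fit$n.risk[keep],
                 n_events = fit$n.event[keep],
                 survival = fit$surv[keep]),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Step-function evaluation: survival just after the last event time at or
#' before `t`, one before the first event.
#'
#' @param curve A `km_curve`.
#' @param t Times at which to evaluate.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- sum(curve$event_times <= tt)
    if (i == 0L) 1 else curve$survival[i]
  }, numeric(1L))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$event_times), "event time(s)")
  if (length(x$event_times))
    cat(", final survival", format(x$survival[length(x$survival)], digits = 4))
  cat("\n")
  invisible(x)
}

#' k-group log-rank test
#'
#' Standard k-sample log-rank: at each distinct event time the observed
#' events per group are compared with their hypergeometric expectation given
#' the risk sets, and the quadratic form of the summed differences against
#' their covariance is referred to a chi-square distribution with k - 1
#' degrees of freedom.
#'
#' @param groups List of two or more groups, each a list with `times` and
#'   `events`.
#' @return An object of class `logrank_result`: `statistic`, `df`,
#'   `p_value`, `group_sizes`.
#' @export
logrank_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least two groups")
  sizes <- vapply(groups, function(g) length(g$times), integer(1L))
  if (any(sizes == 0L)) stop("every group must be non-empty")
  t <- unlist(lapply(groups, `[[`, "times"))
  e <- unlist(lapply(groups, `[[`, "events"))
  if (any(t < 0)) stop("negative time")
  if (!all(e %in% c(0, 1))) stop("events must be 0 or 1")
  if (sum(e) == 0) stop("log-rank statistic undefined with zero events")
  g <- factor(rep(seq_along(groups), sizes))
  sd <- survival::survdiff(survival::Surv(t, e) ~ g, rho = 0)
  df <- length(groups) - 1L
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  structure(list(statistic = sd$chisq,
                 df = df,
                 p_value = min(max(p, .Machine$double.xmin), 1),
                 group_sizes = sizes),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank: chi-square %.4g on %d df, p = %.4g (n = %s)\n",
              x$statistic, x$df, x$p_value,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Compare survival between HER2 classes within an HR stratum
#'
#' For the chosen endpoint and hormone-receptor stratum, runs the global
#' log-rank test across the HER2 classes present (positive / low / ultralow)
#' plus every pairwise test, reporting pairwise p-values both unadjusted and
#' Bonferroni-adjusted. Samples lacking the endpoint are dropped with a
#' message; a compared group that is empty or has fewer than two samples
#' after filtering causes that comparison to be skipped with a warning, not
#' an error.
#'
#' @param assignments Output of [assign_subgroups()].
#' @param clinical Clinical table with the endpoint columns.
#' @param endpoint `"rfs"`, `"dmfs"`, or `"os"`.
#' @param stratum `"all"`, `"hr_positive"`, or `"hr_negative"`.
#' @return An object of class `subgroup_survival`: a list of comparisons
#'   (each with `name`, `test`, `p_bonferroni` for pairwise ones, and the
#'   per-group `km` curves), plus `endpoint`, `stratum`, `n_used`,
#'   `n_dropped`.
#' @export
compare_subgroup_survival <- function(assignments, clinical,
                                      endpoint = c("rfs", "dmfs", "os"),
                                      stratum = c("all", "hr_positive",
                                                  "hr_negative")) {
  endpoint <- match.arg(endpoint)
  stratum <- match.arg(stratum)
  tcol <- paste0("time_", endpoint)
  ecol <- paste0("event_", endpoint)
  if (!all(c(tcol, ecol) %in% names(clinical)))
    stop("clinical table lacks ", tcol, "/", ecol)
  m <- merge(as.data.frame(assignments)[c("sample_id", "hr", "her2")],
             clinical[c("sample_id", tcol, ecol)], by = "sample_id")
  if (stratum != "all")
    m <- m[m$hr == sub("hr_", "", stratum), ]
  drop <- is.na(m[[tcol]]) | is.na(m[[ecol]])
  if (any(drop))
    message("dropping ", sum(drop), " sample(s) lacking the ", endpoint,
            " endpoint")
  m <- m[!drop, ]

  classes <- c("positive", "low", "ultralow")
  by_class <- split(m, factor(as.character(m$her2), levels = classes))
  usable <- names(by_class)[vapply(by_class, nrow, integer(1L)) >= 2L]
  too_small <- setdiff(names(by_class)[vapply(by_class, nrow, integer(1L)) > 0L],
                       usable)
  as_groups <- function(nms) {
    g <- lapply(by_class[nms], function(d)
      list(times = d[[tcol]], events = d[[ecol]]))
    names(g) <- nms
    g
  }
  try_test <- function(nms, label) {
    g <- as_groups(nms)
    if (sum(unlist(lapply(g, `[[`, "events"))) == 0) {
      warning("comparison ", label, " skipped: no events")
      return(NULL)
    }
    list(name = label, test = logrank_test(g),
         km = lapply(g, function(x) km_estimate(x$times, x$events)))
  }
  comparisons <- list()
  if (length(usable) >= 2L) {
    if (length(usable) >= 3L) {
      glob <- try_test(usable, "global")
      if (!is.null(glob)) comparisons <- c(comparisons, list(glob))
    }
    pairs <- utils::combn(usable, 2L, simplify = FALSE)
    pw <- list()
    for (pr in pairs) {
      cmp <- try_test(pr, paste(pr, collapse = "_vs_"))
      if (!is.null(cmp)) pw <- c(pw, list(cmp))
    }
    pw <- lapply(pw, function(cmp) {
      cmp$p_bonferroni <- min(1, cmp$test$p_value * length(pw))
      cmp
    })
    comparisons <- c(comparisons, pw)
  } else {
    warning("fewer than two HER2 classes with enough samples in stratum ",
            stratum, "; no comparisons run")
  }
  if (length(too_small))
    warning("group(s) skipped with fewer than two samples: ",
            paste(too_small, collapse = ", "))
  structure(list(comparisons = comparisons, endpoint = endpoint,
                 stratum = stratum, n_used = nrow(m),
                 n_dropped = sum(drop)),
            class = "subgroup_survival")
}

#' @export
print.subgroup_survival <- function(x, ...) {
  cat("Survival comparisons (", x$endpoint, ", ", x$stratum, "), n = ",
      x$n_used, ":\n", sep = "")
  for (cmp in x$comparisons)
    cat(sprintf("  %-22s chi-sq %8.4g  df %d  p %.4g%s\n", cmp$name,
                cmp$test$statistic, cmp$test$df, cmp$test$p_value,
                if (!is.null(cmp$p_bonferroni))
                  sprintf("  (Bonferroni %.4g)", cmp$p_bonferroni) else ""))
  invisible(x)
}
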