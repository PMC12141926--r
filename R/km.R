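# Kaplan-Meier estimation and the two-group log-rank test, wrapping the
# survival package's product-limit machinery.

#' Kaplan-Meier product-limit estimate
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param horizon Day at which a survival snapshot is reported (default 30).
#' @return Object of class \code{"km_result"}: \code{time}, \code{surv},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, and
#'   \code{surv_at_horizon}.
#' @export
km_estimate <- function(time, event, horizon = 30) {
  ok <- !is.na(time) & !is.na(event)
  time <- time[ok]; event <- event[ok]
  if (any(time < 0)) stop("times must be non-negative")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  s_at <- summary(sf, times = horizon, extend = TRUE)$surv
  structure(
    list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
         n_event = sf$n.event, n_censor = sf$n.censor,
         horizon = horizon, surv_at_horizon = s_at, n = length(time),
         events = sum(event)),
    class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d, S(%g) = %.3f\n",
              x$n, x$events, x$horizon, x$surv_at_horizon))
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param time,event As in \code{\link{km_estimate}}.
#' @param group Binary group labels (two distinct values required).
#' @param horizon Snapshot day for per-group survival (default 30).
#' @return List of class \code{"logrank_result"}: \code{chisq} (1 df),
#'   \code{p}, \code{n_per_group}, \code{surv_at_horizon} per group.
#' @export
logrank <- function(time, event, group, horizon = 30) {
  ok <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[ok]; event <- event[ok]; group <- group[ok]
  lv <- sort(unique(group))
  if (length(lv) < 2L) stop("log-rank test needs two groups")
  if (length(lv) > 2L) stop("only two-group comparison is supported")
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- sd0$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  s_at <- vapply(lv, function(g) {
    km_estimate(time[group == g], event[group == g], horizon)$surv_at_horizon
  }, 0)
  names(s_at) <- paste0("group_", lv)
  structure(
    list(chisq = chisq, p = p,
         n_per_group = stats::setNames(as.vector(table(group)),
                                       paste0("group_", lv)),
         surv_at_horizon = s_at, horizon = horizon),
    class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-squared = %.3f (1 df), p = %.4g\n",
              x$chisq, x$p))
  cat(sprintf("  S(%g): %s\n", x$horizon,
              paste(sprintf("%s = %.1f%%", names(x$surv_at_horizon),
                            100 * x$surv_at_horizon), collapse = ", ")))
  invisible(x)
}
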