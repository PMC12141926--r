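# Proportional-hazards wrapper around survival::coxph with complete-case
# handling, Efron ties by default, and a tidy per-covariate table.

#' Multivariate Cox proportional-hazards fit
#'
#' Fits a Cox model by partial-likelihood maximization (via
#' \code{\link[survival]{coxph}}) on the complete cases of the supplied
#' covariate table and returns a per-covariate table of \eqn{\beta}, its
#' standard error, the hazard ratio \eqn{e^\beta} with the Wald 95\% CI
#' \eqn{(e^{\beta - 1.96 SE}, e^{\beta + 1.96 SE})}, and the Wald p-value.
#' Rows with any missing covariate, time or event are dropped and counted.
#'
#' @param time Follow-up times (days).
#' @param event Event indicators (1 = event).
#' @param covariates Data.frame of covariates; factors become indicator
#'   contrasts against their first level.
#' @param ties \code{"efron"} (default; less biased with tied times) or
#'   \code{"breslow"}.
#' @return Object of class \code{"cox_result"}: \code{table} (data.frame with
#'   \code{term}, \code{beta}, \code{se}, \code{hazard_ratio},
#'   \code{ci_lower}, \code{ci_upper}, \code{p}), \code{model_n},
#'   \code{events_n}, \code{n_dropped}, \code{ties}, \code{converged},
#'   \code{separation_flag}, and the underlying \code{fit}.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  n_in <- length(time)
  stopifnot(length(event) == n_in, nrow(covariates) == n_in)
  ok <- !is.na(time) & !is.na(event) & stats::complete.cases(covariates)
  n_dropped <- n_in - sum(ok)
  time <- time[ok]; event <- event[ok]
  covariates <- covariates[ok, , drop = FALSE]
  if (sum(event) < 1) stop("no events in the complete-case data")

  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  warn <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (is.null(fit$coefficients)) stop("Cox model has no estimable coefficients")
  sm <- summary(fit)
  beta <- sm$coefficients[, "coef"]
  se <- sm$coefficients[, "se(coef)"]
  sep <- any(grepl("infinite|did not converge|converge", warn)) ||
    any(abs(beta) > 15)
  if (!is.null(fit$info) && !is.null(fit$iter) &&
      fit$iter >= 100) stop("Cox fit did not converge: iteration limit reached")
  tab <- data.frame(
    term = rownames(sm$coefficients),
    beta = unname(beta), se = unname(se),
    hazard_ratio = unname(exp(beta)),
    ci_lower = unname(exp(beta - 1.96 * se)),
    ci_upper = unname(exp(beta + 1.96 * se)),
    p = unname(sm$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE)
  structure(
    list(table = tab, model_n = sum(ok), events_n = sum(event),
         n_dropped = n_dropped, ties = ties,
         converged = TRUE, separation_flag = sep, warnings = warn,
         fit = fit),
    class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards model (%s ties): n = %d, events = %d",
              x$ties, x$model_n, x$events_n))
  if (x$n_dropped > 0) cat(sprintf(", %d incomplete row(s) dropped", x$n_dropped))
  cat("\n")
  t <- x$table
  for (k in seq_len(nrow(t)))
    cat(sprintf("  %-28s beta %+.3f (SE %.3f)  HR %.3f [%.3f, %.3f]  p = %.4g\n",
                t$term[k], t$beta[k], t$se[k], t$hazard_ratio[k],
                t$ci_lower[k], t$ci_upper[k], t$p[k]))
  if (x$separation_flag)
    cat("  warning: possible complete separation / unstable coefficients\n")
  invisible(x)
}
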