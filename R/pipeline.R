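# End-to-end evaluation battery over a PD matrix: group comparison per edge,
# Cox models for edges passing the group test, ROC / Youden classification
# and Kaplan-Meier with log-rank for Cox-significant PD axes.

#' Run the survival-evaluation pipeline over a PD matrix
#'
#' For every edge of the PD matrix: (1) a Mann-Whitney comparison of PD
#' between the outcome groups; (2) for edges with group-test p < 0.05, a
#' multivariate Cox model with the z-normalized PD plus the edge's two
#' variables, SOFA and ventilation status (the \code{"standard"} covariate
#' set; \code{"extended"} adds age, sex, ethnicity contrasts and the
#' Elixhauser index); (3) for edges whose PD term is Cox-significant
#' (p < 0.05), ROC analysis with the DeLong CI, Youden cut-off
#' classification (score >= cut-off predicts the poor outcome), and a
#' Kaplan-Meier / log-rank comparison of the two predicted classes.
#'
#' Z-normalization statistics for each PD use all patients with that PD
#' available. Complete-case drops are counted per model. No multiplicity
#' correction is applied across edges beyond the network-stage Bonferroni
#' gate (set \code{holm = TRUE} for a Holm-adjusted sensitivity column on
#' the Cox PD p-values).
#'
#' @param cohort The cohort data.frame the PD matrix was computed from.
#' @param pd A \code{"pd_matrix"}.
#' @param outcome \code{"mortality30"} (groups by \code{event30}, time-to-
#'   event Cox on \code{time_days}) or \code{"deterioration48"} (groups by
#'   \code{deteriorated48}; the Cox stage treats deterioration as the event
#'   with all follow-up ending at the 48-h assessment, which reduces the
#'   partial likelihood to a conditional-logit comparison). The ROC/KM stage
#'   always evaluates 30-day survival, as only mortality has a follow-up
#'   time.
#' @param covariates \code{"standard"} or \code{"extended"}.
#' @param ties Cox tie handling, \code{"efron"} or \code{"breslow"}.
#' @param alpha_stage Stage-gate level (default 0.05).
#' @param holm Add Holm-adjusted p-values across the Cox PD terms.
#' @return Object of class \code{"parenclitic_report"}: data.frames
#'   \code{group_comparison}, \code{cox}, \code{roc}, list \code{km}
#'   (per-edge log-rank + curves), \code{log} (per-stage notes), and the
#'   configuration used.
#' @export
run_survival_pipeline <- function(cohort, pd,
                                  outcome = c("mortality30", "deterioration48"),
                                  covariates = c("standard", "extended"),
                                  ties = "efron", alpha_stage = 0.05,
                                  holm = FALSE) {
  outcome <- match.arg(outcome)
  covariates <- match.arg(covariates)
  stopifnot(inherits(pd, "pd_matrix"))
  if (!identical(as.character(cohort$patient_id), pd$patient_ids))
    stop("PD matrix patients do not match the cohort")
  gvar <- if (outcome == "mortality30") "event30" else "deteriorated48"
  g <- cohort[[gvar]]
  if (is.null(g)) stop("cohort lacks outcome column ", gvar)

  edge_names <- colnames(pd$values)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  ## stage 1: group comparison per edge
  gc_rows <- list()
  for (en in edge_names) {
    v <- pd$values[, en]
    ok <- !is.na(v) & !is.na(g)
    a <- v[ok & g == 0]; b <- v[ok & g == 1]
    if (length(a) < 2 || length(b) < 2) {
      note("edge %s: skipped group comparison (group sizes %d/%d)",
           en, length(a), length(b))
      next
    }
    mw <- mann_whitney(a, b)
    gc_rows[[en]] <- data.frame(
      edge = en, n0 = mw$n0, n1 = mw$n1, mean0 = mw$mean0, sd0 = mw$sd0,
      mean1 = mw$mean1, sd1 = mw$sd1, U = mw$U, Z = mw$Z,
      effect_r = mw$effect_r, p = mw$p, stringsAsFactors = FALSE)
  }
  group_comparison <- if (length(gc_rows)) do.call(rbind, gc_rows) else
    data.frame(edge = character(), n0 = integer(), n1 = integer(),
               mean0 = numeric(), sd0 = numeric(), mean1 = numeric(),
               sd1 = numeric(), U = numeric(), Z = numeric(),
               effect_r = numeric(), p = numeric(), stringsAsFactors = FALSE)
  rownames(group_comparison) <- NULL

  ## stage 2: Cox models for edges passing the group test
  if (outcome == "mortality30") {
    cox_time <- cohort$time_days
    cox_event <- cohort$event30
  } else {
    cox_time <- rep(2, nrow(cohort))  # deterioration assessed at 48 h
    cox_event <- cohort$deteriorated48
  }
  cox_rows <- list(); cox_fits <- list()
  passed <- group_comparison$edge[group_comparison$p < alpha_stage]
  for (en in passed) {
    k <- match(en, edge_names)
    vx <- pd$edges$var_x[k]; vy <- pd$edges$var_y[k]
    cv <- data.frame(pd_z = tryCatch(z_normalize(pd$values[, en]),
                                     error = function(e) NA_real_))
    cv[[vx]] <- cohort[[vx]]
    cv[[vy]] <- cohort[[vy]]
    cv$sofa <- cohort$sofa
    cv$ventilated <- cohort$ventilated
    if (covariates == "extended") {
      cv$age <- cohort$age
      cv$sex <- factor(cohort$sex)
      cv$ethnicity <- stats::relevel(factor(cohort$ethnicity), ref =
        if ("White" %in% cohort$ethnicity) "White" else
          levels(factor(cohort$ethnicity))[1])
      cv$elixhauser <- cohort$elixhauser
    }
    names(cv)[1] <- paste0(en, "_z")
    fit <- tryCatch(
      cox_fit(cox_time, cox_event, cv, ties = ties),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      note("edge %s: Cox model failed (%s)", en, fit)
      next
    }
    note("edge %s: Cox n = %d (%d dropped), events = %d",
         en, fit$model_n, fit$n_dropped, fit$events_n)
    tab <- fit$table
    tab <- cbind(edge = en, tab, model_n = fit$model_n,
                 events_n = fit$events_n, stringsAsFactors = FALSE)
    cox_rows[[en]] <- tab
    cox_fits[[en]] <- fit
  }
  cox <- if (length(cox_rows)) do.call(rbind, cox_rows) else
    data.frame(edge = character(), term = character(), beta = numeric(),
               se = numeric(), hazard_ratio = numeric(),
               ci_lower = numeric(), ci_upper = numeric(), p = numeric(),
               model_n = integer(), events_n = integer(),
               stringsAsFactors = FALSE)
  rownames(cox) <- NULL
  if (holm && nrow(cox) > 0) {
    is_pd <- grepl("^PD__.*_z$", cox$term)
    cox$p_holm <- NA_real_
    cox$p_holm[is_pd] <- stats::p.adjust(cox$p[is_pd], method = "holm")
  }

  ## stage 3: ROC + Youden + KM for Cox-significant PD terms
  roc_rows <- list(); km_list <- list()
  if (nrow(cox) > 0) {
    pd_terms <- cox[grepl("^PD__.*_z$", cox$term), , drop = FALSE]
    sig_edges <- pd_terms$edge[pd_terms$p < alpha_stage]
    for (en in sig_edges) {
      v <- pd$values[, en]
      ok <- !is.na(v) & !is.na(g)
      roc <- tryCatch(roc_analysis(v[ok], g[ok]),
                      error = function(e) conditionMessage(e))
      if (is.character(roc)) {
        note("edge %s: ROC failed (%s)", en, roc)
        next
      }
      if (roc$flipped) note("edge %s: score orientation flipped for ROC", en)
      roc_rows[[en]] <- data.frame(
        edge = en, auc = roc$auc, ci_lower = roc$auc_ci95[1],
        ci_upper = roc$auc_ci95[2], youden_cutoff = roc$youden_cutoff,
        youden_j = roc$youden_j, sensitivity_pct = 100 * roc$sensitivity,
        specificity_pct = 100 * roc$specificity, n_pos = roc$n_pos,
        n_neg = roc$n_neg, stringsAsFactors = FALSE)
      pred <- as.integer(v >= roc$youden_cutoff)  # ties -> predicted poor outcome
      okk <- ok & !is.na(cohort$time_days) & !is.na(cohort$event30)
      if (length(unique(pred[okk])) == 2L) {
        lr <- logrank(cohort$time_days[okk], cohort$event30[okk], pred[okk])
        km_curves <- lapply(c(0, 1), function(cls) {
          sel <- okk & pred == cls
          km_estimate(cohort$time_days[sel], cohort$event30[sel])
        })
        names(km_curves) <- c("predicted_good", "predicted_poor")
        km_list[[en]] <- list(logrank = lr, curves = km_curves)
      } else {
        note("edge %s: Youden cut-off puts all patients in one class; KM skipped", en)
      }
    }
  }
  roc <- if (length(roc_rows)) do.call(rbind, roc_rows) else
    data.frame(edge = character(), auc = numeric(), ci_lower = numeric(),
               ci_upper = numeric(), youden_cutoff = numeric(),
               youden_j = numeric(), sensitivity_pct = numeric(),
               specificity_pct = numeric(), n_pos = integer(),
               n_neg = integer(), stringsAsFactors = FALSE)
  rownames(roc) <- NULL

  structure(
    list(group_comparison = group_comparison, cox = cox, roc = roc,
         km = km_list, log = log,
         config = list(outcome = outcome, covariates = covariates,
                       ties = ties, alpha_stage = alpha_stage,
                       reference_label = pd$reference_label)),
    class = "parenclitic_report")
}

#' @export
print.parenclitic_report <- function(x, ...) {
  cat(sprintf("Parenclitic survival report (%s, %s covariates, reference: %s)\n",
              x$config$outcome, x$config$covariates,
              x$config$reference_label))
  cat(sprintf("  %d edges compared; %d Cox models; %d ROC analyses; %d KM comparisons\n",
              nrow(x$group_comparison),
              length(unique(x$cox$edge)), nrow(x$roc), length(x$km)))
  if (nrow(x$roc) > 0) {
    for (k in seq_len(nrow(x$roc)))
      cat(sprintf("  %s: AUC %.3f [%.3f, %.3f], cut-off %.4g (sens %.1f%%, spec %.1f%%)\n",
                  x$roc$edge[k], x$roc$auc[k], x$roc$ci_lower[k],
                  x$roc$ci_upper[k], x$roc$youden_cutoff[k],
                  x$roc$sensitivity_pct[k], x$roc$specificity_pct[k]))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the machine-readable bundle: \code{table2_group_comparison.csv},
#' \code{table4_cox.csv}, \code{table6_roc.csv}, \code{km_curves.csv} and
#' \code{report.json} in \code{dir}. Output contains no timestamps, so
#' identical inputs yield byte-identical files.
#'
#' @param report A \code{"parenclitic_report"}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "parenclitic_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$group_comparison, "table2_group_comparison.csv")
  wr(report$cox, "table4_cox.csv")
  wr(report$roc, "table6_roc.csv")
  km_rows <- list()
  for (en in names(report$km)) {
    for (cls in names(report$km[[en]]$curves)) {
      cv <- report$km[[en]]$curves[[cls]]
      if (length(cv$time) == 0) next
      km_rows[[paste(en, cls)]] <- data.frame(
        edge = en, class = cls, time = cv$time, surv = cv$surv,
        n_risk = cv$n_risk, n_event = cv$n_event, n_censor = cv$n_censor,
        stringsAsFactors = FALSE)
    }
  }
  wr(if (length(km_rows)) do.call(rbind, km_rows) else
       data.frame(edge = character(), class = character(), time = numeric(),
                  surv = numeric(), n_risk = integer(), n_event = integer(),
                  n_censor = integer()),
     "km_curves.csv")
  js <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(config = report$config,
         group_comparison = report$group_comparison,
         cox = report$cox, roc = report$roc,
         logrank = lapply(report$km, function(e)
           list(chisq = e$logrank$chisq, p = e$logrank$p,
                surv_at_horizon = as.list(e$logrank$surv_at_horizon),
                n_per_group = as.list(e$logrank$n_per_group))),
         log = report$log),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, js)
  invisible(paths)
}
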