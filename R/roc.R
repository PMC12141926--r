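# ROC analysis: empirical AUC via the rank-sum identity, DeLong
# placement-value variance for confidence intervals and curve comparison,
# and the Youden-index cut-off.

# DeLong placement values: for each positive the fraction of negatives it
# beats (ties count 1/2), and vice versa. Means equal the empirical AUC.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_pos) / n0            # per positive
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1   # per negative
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC curve analysis with DeLong CI and Youden cut-off
#'
#' Computes the empirical AUC (exactly \eqn{U/(n_0 n_1)} of the Mann-Whitney
#' rank-sum, via shared rank computation), its DeLong 95\% confidence
#' interval from placement values, and the cut-off maximizing the Youden
#' index \eqn{J = sensitivity + specificity - 1} with the classification rule
#' score \eqn{\ge} cut-off \eqn{\Rightarrow} predicted positive (ties at the
#' cut-off go to the predicted-positive class).
#'
#' Scores are expected to be oriented so that higher values indicate the
#' positive class; if the raw AUC is below 0.5 the orientation is flipped and
#' flagged in the result.
#'
#' @param scores Numeric scores; \code{NA} pairs are dropped.
#' @param labels Binary labels (1 = positive class, e.g. non-survivor).
#' @param auto_orient Flip scores when the raw AUC < 0.5 (default TRUE).
#' @return Object of class \code{"roc_result"}: \code{auc}, \code{auc_se},
#'   \code{auc_ci95}, \code{youden_cutoff}, \code{youden_j},
#'   \code{sensitivity}, \code{specificity}, \code{n_pos}, \code{n_neg},
#'   \code{flipped}, \code{curve} (data.frame of all cut-offs).
#' @export
roc_analysis <- function(scores, labels, auto_orient = TRUE) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  flipped <- FALSE
  pl <- delong_placements(scores, labels)
  if (auto_orient && pl$auc < 0.5) {
    flipped <- TRUE
    scores <- -scores
    pl <- delong_placements(scores, labels)
  }
  auc <- pl$auc
  vv <- stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
  se <- sqrt(vv)
  zq <- stats::qnorm(0.975)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))

  cuts <- sort(unique(scores))
  idx <- match(scores, cuts)
  pos_at <- tabulate(idx[labels == 1], nbins = length(cuts))
  neg_at <- tabulate(idx[labels == 0], nbins = length(cuts))
  sens <- rev(cumsum(rev(pos_at))) / n1        # P(pos >= cut)
  spec <- (cumsum(neg_at) - neg_at) / n0       # P(neg < cut)
  j <- sens + spec - 1
  best <- which.max(j)  # first (lowest) cut-off on ties
  curve <- data.frame(cutoff = cuts, sensitivity = sens, specificity = spec,
                      youden_j = j)
  structure(
    list(auc = auc, auc_se = se, auc_ci95 = ci,
         youden_cutoff = if (flipped) -cuts[best] else cuts[best],
         youden_j = j[best], sensitivity = sens[best],
         specificity = spec[best],
         n_pos = n1, n_neg = n0, flipped = flipped, curve = curve),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC analysis: %d positives, %d negatives%s\n", x$n_pos, x$n_neg,
              if (x$flipped) " (score orientation flipped)" else ""))
  cat(sprintf("  AUC = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$auc, x$auc_ci95[1], x$auc_ci95[2]))
  cat(sprintf("  Youden cut-off = %.4g (J = %.3f): sensitivity %.1f%%, specificity %.1f%%\n",
              x$youden_cutoff, x$youden_j, 100 * x$sensitivity,
              100 * x$specificity))
  invisible(x)
}

#' DeLong comparison of two ROC curves
#'
#' Tests the difference between the empirical AUCs of two scores for the
#' same binary outcome using DeLong placement-value (co)variances. In paired
#' mode the comparison is restricted to patients with both scores available
#' and the covariance between the correlated AUCs is subtracted; in unpaired
#' mode each score uses its own complete cases and the AUCs are treated as
#' independent.
#'
#' @param scores_a,scores_b Two score vectors on the same patients.
#' @param labels Binary outcome labels.
#' @param paired \code{TRUE} (default) for the paired complete-case
#'   comparison; \code{FALSE} for the unpaired fallback.
#' @return List with \code{auc_a}, \code{auc_b}, \code{delta_auc}, \code{z},
#'   \code{p}, \code{mode}, \code{n} (per-score complete-case counts).
#' @export
delong_compare <- function(scores_a, scores_b, labels, paired = TRUE) {
  if (paired) {
    ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
    if (sum(ok) < 10L)
      stop("paired DeLong comparison needs at least 10 patients with both scores")
    la <- labels[ok]
    if (!any(la == 1) || !any(la == 0)) stop("both classes must be present")
    pa <- delong_placements(scores_a[ok], la)
    pb <- delong_placements(scores_b[ok], la)
    n1 <- sum(la == 1); n0 <- sum(la == 0)
    s10 <- stats::cov(cbind(pa$v10, pb$v10))
    s01 <- stats::cov(cbind(pa$v01, pb$v01))
    S <- s10 / n1 + s01 / n0
    vd <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
    delta <- pa$auc - pb$auc
    z <- if (vd <= 0) 0 else delta / sqrt(vd)
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta, z = z,
                p = 2 * stats::pnorm(-abs(z)), mode = "paired",
                n = c(a = sum(ok), b = sum(ok))))
  }
  oka <- !is.na(scores_a) & !is.na(labels)
  okb <- !is.na(scores_b) & !is.na(labels)
  pa <- delong_placements(scores_a[oka], labels[oka])
  pb <- delong_placements(scores_b[okb], labels[okb])
  va <- stats::var(pa$v10) / sum(labels[oka] == 1) +
        stats::var(pa$v01) / sum(labels[oka] == 0)
  vb <- stats::var(pb$v10) / sum(labels[okb] == 1) +
        stats::var(pb$v01) / sum(labels[okb] == 0)
  delta <- pa$auc - pb$auc
  z <- if (va + vb <= 0) 0 else delta / sqrt(va + vb)
  list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta, z = z,
       p = 2 * stats::pnorm(-abs(z)), mode = "unpaired",
       n = c(a = sum(oka), b = sum(okb)))
}
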