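# Mann-Whitney U with the tie-corrected normal approximation and the
# |Z|/sqrt(N) effect size, oriented so U counts comparison-group wins.

#' Mann-Whitney U test with effect size
#'
#' Compares a comparison group \code{b} against a reference group \code{a}.
#' U is oriented toward the comparison group:
#' \eqn{U = \#\{(i,j): b_j > a_i\} + \frac{1}{2}\#\{ties\}}, so
#' \eqn{U/(n_0 n_1)} is the probability that a comparison-group value exceeds
#' a reference-group value, and equals the empirical ROC AUC for the same
#' scores and labels. The Z deviate uses the large-sample normal
#' approximation with tie correction and \emph{no} continuity correction
#' (the SPSS convention), and the effect size is \eqn{r = |Z|/\sqrt{n_0+n_1}}.
#'
#' @param a Reference-group values (group 0, e.g. survivors).
#' @param b Comparison-group values (group 1, e.g. non-survivors).
#' @param exact If \code{TRUE} and both groups have at most 50 values with no
#'   ties, the p-value is the exact U distribution (via
#'   \code{\link[stats]{wilcox.test}}); otherwise the normal approximation.
#' @return List of class \code{"group_comparison"}: \code{n0}, \code{n1},
#'   \code{mean0}, \code{sd0}, \code{mean1}, \code{sd1}, \code{U}, \code{Z},
#'   \code{effect_r}, \code{p}.
#' @export
mann_whitney <- function(a, b, exact = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n0 <- length(a); n1 <- length(b)
  if (n0 == 0L || n1 == 0L) stop("both groups must be non-empty")
  N <- n0 + n1
  rk <- rank(c(a, b))
  U <- sum(rk[(n0 + 1):N]) - n1 * (n1 + 1) / 2
  mu <- n0 * n1 / 2
  tie_sizes <- table(c(a, b))
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  sigma2 <- n0 * n1 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    Z <- 0  # all values tied: no evidence either way
  } else {
    Z <- (U - mu) / sqrt(sigma2)
  }
  p <- 2 * stats::pnorm(-abs(Z))
  if (exact && n0 <= 50 && n1 <= 50 && tie_term == 0) {
    p <- stats::wilcox.test(b, a, exact = TRUE)$p.value
  }
  structure(
    list(n0 = n0, n1 = n1,
         mean0 = mean(a), sd0 = stats::sd(a),
         mean1 = mean(b), sd1 = stats::sd(b),
         U = U, Z = Z, effect_r = abs(Z) / sqrt(N), p = min(1, p)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney: n0 = %d (mean %.4g, SD %.4g), n1 = %d (mean %.4g, SD %.4g)\n",
    x$n0, x$mean0, x$sd0, x$n1, x$mean1, x$sd1))
  cat(sprintf("  U = %g, Z = %.3f, effect r = %.3f, p = %.4g\n",
              x$U, x$Z, x$effect_r, x$p))
  invisible(x)
}

#' Effect size from a printed (U, n0, n1) triple
#'
#' Recovers the normal-approximation deviate and the effect size
#' \eqn{r = |Z|/\sqrt{n_0+n_1}} from a reported Mann-Whitney U statistic and
#' the two group sizes, assuming untied data (the tie term is unknown when
#' only U is printed). Useful for auditing published test tables.
#'
#' @param U Mann-Whitney statistic oriented as in \code{\link{mann_whitney}}.
#' @param n0,n1 Group sizes.
#' @return List with \code{Z}, \code{effect_r}, \code{p}, \code{auc}
#'   (\code{U/(n0*n1)}).
#' @export
effect_size_from_u <- function(U, n0, n1) {
  stopifnot(U >= 0, U <= n0 * n1, n0 >= 1, n1 >= 1)
  N <- n0 + n1
  sigma <- sqrt(n0 * n1 * (N + 1) / 12)
  Z <- (U - n0 * n1 / 2) / sigma
  list(Z = Z, effect_r = abs(Z) / sqrt(N),
       p = 2 * stats::pnorm(-abs(Z)), auc = U / (n0 * n1))
}
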