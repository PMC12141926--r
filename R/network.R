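# Population correlation network maps: pairwise-deletion Pearson statistics
# over the laboratory panel, gated by a Bonferroni family-wise threshold.

#' Pearson correlation with pairwise deletion
#'
#' Computes the Pearson correlation between two variables using only the
#' complete pairs (rows where both values are observed), the convention used
#' throughout for handling missing laboratory data. The two-sided p-value
#' comes from the t statistic \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2}
#' degrees of freedom. Perfectly collinear pairs (\eqn{|r| = 1} to machine
#' precision) are reported with \code{p = 0}, the boundary convention.
#'
#' @param xs,ys Numeric vectors of equal length; \code{NA} marks missing.
#' @return A list with \code{r}, \code{p}, \code{n_pairs}.
#' @examples
#' pairwise_pearson(c(1, 2, 3, NA), c(2, 4, 6, 8))
#' @export
pairwise_pearson <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  ok <- !is.na(xs) & !is.na(ys)
  n <- sum(ok)
  if (n < 3L) stop("insufficient pairs: need at least 3 complete pairs, got ", n)
  x <- xs[ok]; y <- ys[ok]
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("degenerate variable: zero variance on complete pairs")
  r <- stats::cov(x, y) / (sx * sy)
  r <- max(-1, min(1, r))
  if (1 - r * r < .Machine$double.eps) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r * r))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n_pairs = n)
}

#' Bonferroni threshold for an all-pairs correlation screen
#'
#' Family-wise significance threshold for testing all \eqn{C(m, 2)} variable
#' pairs: \code{alpha / choose(m, 2)}. For the 15-variable panel at
#' \code{alpha = 0.05} this is 0.05/105 = 0.00047619.
#'
#' @param m_variables Number of variables (>= 2).
#' @param alpha Family-wise error level in (0, 1).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(m_variables, alpha = 0.05) {
  if (m_variables < 2) stop("need at least 2 variables")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / choose(m_variables, 2)
}

#' Build a population correlation network map
#'
#' Evaluates every pair of panel variables over one outcome group with
#' pairwise deletion and marks as edges the pairs whose Pearson p-value is at
#' or below the Bonferroni threshold \code{alpha / choose(m, 2)} (inclusive).
#' Pairs that cannot be evaluated (fewer than 3 complete pairs, or zero
#' variance) are recorded as non-significant with the reason, never dropped
#' silently; pairs evaluated on fewer than 10 complete cases carry a
#' \code{low_n} flag.
#'
#' @param cohort A cohort data.frame.
#' @param group Either one of \code{"survived30"}, \code{"died30"},
#'   \code{"deteriorated48"}, \code{"stable48"}, \code{"all"}, or a logical
#'   vector selecting rows of \code{cohort}.
#' @param alpha Family-wise level (default 0.05).
#' @param variables Variable names to correlate (default the 15-lab panel).
#' @return An object of class \code{"correlation_network"}: list with
#'   \code{variables}, \code{edges} (all pairs with r, p, n_pairs,
#'   significant, low_n, reason), \code{adjacency} (binary, symmetric, zero
#'   diagonal), \code{threshold}, \code{alpha}, \code{group_label},
#'   \code{n_group}.
#' @export
build_network <- function(cohort, group = "all", alpha = 0.05,
                          variables = lab_variables()) {
  sel <- resolve_group(cohort, group)
  label <- attr(sel, "label")
  if (!any(sel)) stop("selected subgroup is empty")
  sub <- cohort[sel, , drop = FALSE]
  missing_vars <- setdiff(variables, names(sub))
  if (length(missing_vars) > 0L)
    stop("cohort lacks variable column(s): ", paste(missing_vars, collapse = ", "))

  m <- length(variables)
  thr <- bonferroni_threshold(m, alpha)
  pairs <- utils::combn(m, 2)
  np <- ncol(pairs)
  edges <- data.frame(
    var_x = variables[pairs[1, ]], var_y = variables[pairs[2, ]],
    r = NA_real_, p = NA_real_, n_pairs = NA_integer_,
    significant = 0L, low_n = FALSE, reason = "", stringsAsFactors = FALSE)
  for (k in seq_len(np)) {
    res <- tryCatch(
      pairwise_pearson(sub[[edges$var_x[k]]], sub[[edges$var_y[k]]]),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      edges$reason[k] <- res
      next
    }
    edges$r[k] <- res$r
    edges$p[k] <- res$p
    edges$n_pairs[k] <- res$n_pairs
    edges$significant[k] <- as.integer(res$p <= thr)
    edges$low_n[k] <- res$n_pairs < 10L
  }
  adj <- matrix(0L, m, m, dimnames = list(variables, variables))
  sig <- which(edges$significant == 1L)
  for (k in sig) {
    adj[edges$var_x[k], edges$var_y[k]] <- 1L
    adj[edges$var_y[k], edges$var_x[k]] <- 1L
  }
  structure(
    list(variables = variables, edges = edges, adjacency = adj,
         threshold = thr, alpha = alpha, group_label = label,
         n_group = nrow(sub)),
    class = "correlation_network")
}

# Turn a group spec (keyword or logical mask) into a row selector.
resolve_group <- function(cohort, group) {
  if (is.logical(group)) {
    if (length(group) != nrow(cohort))
      stop("logical group selector must match the number of patients")
    sel <- group & !is.na(group)
    attr(sel, "label") <- "custom"
    return(sel)
  }
  group <- match.arg(group, c("all", "survived30", "died30",
                              "deteriorated48", "stable48"))
  sel <- switch(group,
    all = rep(TRUE, nrow(cohort)),
    survived30 = !is.na(cohort$event30) & cohort$event30 == 0,
    died30 = !is.na(cohort$event30) & cohort$event30 == 1,
    deteriorated48 = !is.na(cohort$deteriorated48) & cohort$deteriorated48 == 1,
    stable48 = !is.na(cohort$deteriorated48) & cohort$deteriorated48 == 0)
  attr(sel, "label") <- group
  sel
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("Correlation network map (", x$group_label, ", n = ", x$n_group, ")\n",
      sep = "")
  cat(sprintf("  %d variables, %d pairs, threshold p <= %.8g (alpha %.3g)\n",
              length(x$variables), nrow(x$edges), x$threshold, x$alpha))
  sig <- x$edges[x$edges$significant == 1L, , drop = FALSE]
  cat("  significant edges:", nrow(sig), "\n")
  if (nrow(sig) > 0) {
    for (k in seq_len(nrow(sig)))
      cat(sprintf("    %s -- %s  r = %+.3f  p = %.3g  n = %d%s\n",
                  sig$var_x[k], sig$var_y[k], sig$r[k], sig$p[k],
                  sig$n_pairs[k], if (sig$low_n[k]) "  [low-n]" else ""))
  }
  skipped <- x$edges[x$edges$reason != "", , drop = FALSE]
  if (nrow(skipped) > 0)
    cat("  unevaluable pairs:", nrow(skipped), "(see $edges$reason)\n")
  invisible(x)
}

#' Significant edge set of a network
#'
#' @param net A \code{"correlation_network"}.
#' @return Data.frame of the significant edges (subset of \code{net$edges}).
#' @export
significant_edges <- function(net) {
  stopifnot(inherits(net, "correlation_network"))
  net$edges[net$edges$significant == 1L,
            c("var_x", "var_y", "r", "p", "n_pairs"), drop = FALSE]
}

#' Compare the significant edge sets of two networks
#'
#' Partitions the significant edges of two networks over the same variable
#' list into shared edges, edges unique to the first, and edges unique to the
#' second (edges are unordered pairs).
#'
#' @param a,b \code{"correlation_network"} objects over identical variables.
#' @return A list with data.frames \code{shared}, \code{only_a}, \code{only_b}.
#' @export
compare_networks <- function(a, b) {
  stopifnot(inherits(a, "correlation_network"), inherits(b, "correlation_network"))
  if (!identical(a$variables, b$variables))
    stop("networks have different variable lists")
  key <- function(net) {
    e <- significant_edges(net)
    paste(pmin(e$var_x, e$var_y), pmax(e$var_x, e$var_y), sep = "|")
  }
  ka <- key(a); kb <- key(b)
  ea <- significant_edges(a); eb <- significant_edges(b)
  list(shared = ea[ka %in% kb, , drop = FALSE],
       only_a = ea[!ka %in% kb, , drop = FALSE],
       only_b = eb[!kb %in% ka, , drop = FALSE])
}

#' Export a correlation network
#'
#' Writes a CSV edge list (all pairs with their statistics) and a GraphML
#' graph whose nodes are the panel variables and whose edges carry the
#' Pearson r (signed), |r| as \code{weight}, p, complete-case count and the
#' significance flag. Re-importing the GraphML reproduces the adjacency.
#'
#' @param net A \code{"correlation_network"}.
#' @param path Output path stem; writes \code{<path>.csv} and
#'   \code{<path>.graphml} (a path already ending in \code{.csv} or
#'   \code{.graphml} writes only that format).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, path) {
  stopifnot(inherits(net, "correlation_network"))
  written <- character()
  want_csv <- !grepl("\\.graphml$", path)
  want_gml <- !grepl("\\.csv$", path)
  csv_path <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  gml_path <- if (grepl("\\.graphml$", path)) path else paste0(path, ".graphml")
  if (want_csv) {
    utils::write.csv(net$edges, csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (want_gml) {
    ev <- net$edges[!is.na(net$edges$r), , drop = FALSE]
    g <- igraph::make_empty_graph(n = length(net$variables), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = net$variables)
    if (nrow(ev) > 0) {
      idx <- rbind(match(ev$var_x, net$variables),
                   match(ev$var_y, net$variables))
      g <- igraph::add_edges(g, as.vector(idx))
      g <- igraph::set_edge_attr(g, "r", value = ev$r)
      g <- igraph::set_edge_attr(g, "weight", value = abs(ev$r))
      g <- igraph::set_edge_attr(g, "p", value = ev$p)
      g <- igraph::set_edge_attr(g, "n_pairs", value = ev$n_pairs)
      g <- igraph::set_edge_attr(g, "significant", value = ev$significant)
    }
    g <- igraph::set_graph_attr(g, "group_label", net$group_label)
    g <- igraph::set_graph_attr(g, "threshold", net$threshold)
    igraph::write_graph(g, gml_path, format = "graphml")
    written <- c(written, gml_path)
  }
  invisible(written)
}
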