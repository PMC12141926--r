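# Parenclitic core: orthogonal (total least squares) reference lines and
# per-patient orthogonal distances (parenclitic deviations, PD).
#
# The TLS line through a 2-D point cloud is the first principal axis of the
# 2x2 covariance matrix: it passes through the centroid and minimizes the
# summed squared perpendicular distances. Unlike ordinary least squares it is
# symmetric in the two variables and well defined for vertical trends, which
# is why slope/intercept are derived outputs only.

#' Fit an orthogonal (total least squares) regression line
#'
#' Fits the line minimizing the sum of squared orthogonal distances to a 2-D
#' point cloud: the line through the centroid along the leading eigenvector
#' of the sample covariance matrix. \code{orthogonal_sse} equals the smaller
#' covariance eigenvalue times \eqn{n - 1}.
#'
#' @param x,y Numeric vectors (pairs with a missing coordinate are dropped),
#'   or \code{x} a two-column matrix/data.frame and \code{y} omitted.
#' @param var_x,var_y Optional variable names carried in the result.
#' @return Object of class \code{"reference_line"}: \code{centroid} (length-2),
#'   \code{direction} (unit length-2, sign fixed so the first non-zero
#'   component is positive), \code{n_fit}, \code{orthogonal_sse}, and derived
#'   \code{slope}/\code{intercept} (\code{NA} for vertical lines).
#' @examples
#' fit_orthogonal_line(c(0, 1, 2), c(1, 3, 5))  # y = 2x + 1
#' @export
fit_orthogonal_line <- function(x, y = NULL, var_x = "x", var_y = "y") {
  if (is.null(y)) {
    pts <- as.matrix(x)
    if (ncol(pts) != 2L) stop("points must have two columns")
    x <- pts[, 1]; y <- pts[, 2]
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete points to fit a line, got ", n)
  if (all(x == x[1]) && all(y == y[1])) stop("all points identical")
  cxy <- stats::cov(cbind(x, y))
  ev <- eigen(cxy, symmetric = TRUE)
  scale2 <- max(ev$values[1], .Machine$double.eps)
  if ((ev$values[1] - ev$values[2]) / scale2 < 1e-12)
    stop("direction ambiguous: isotropic point cloud (equal covariance eigenvalues)")
  d <- ev$vectors[, 1]
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d
  structure(
    list(var_x = var_x, var_y = var_y,
         centroid = c(mean(x), mean(y)),
         direction = d,
         n_fit = n,
         orthogonal_sse = max(0, ev$values[2]) * (n - 1),
         slope = if (abs(d[1]) > 0) d[2] / d[1] else NA_real_,
         intercept = if (abs(d[1]) > 0)
           mean(y) - d[2] / d[1] * mean(x) else NA_real_),
    class = "reference_line")
}

#' @export
print.reference_line <- function(x, ...) {
  cat(sprintf(
    "Orthogonal regression line %s ~ %s: centroid (%.4g, %.4g), direction (%.4f, %.4f), n = %d, orthogonal SSE = %.4g\n",
    x$var_y, x$var_x, x$centroid[1], x$centroid[2],
    x$direction[1], x$direction[2], x$n_fit, x$orthogonal_sse))
  invisible(x)
}

#' Orthogonal distance from points to a reference line
#'
#' Euclidean (perpendicular) distance from each point to the infinite line;
#' zero exactly when the point lies on the line. This distance is the
#' parenclitic deviation of a patient for one variable pair.
#'
#' @param point Length-2 vector, or an n x 2 matrix of points.
#' @param line A \code{"reference_line"}.
#' @param signed If \code{TRUE}, return the signed perpendicular residual
#'   (positive on the side of the unit normal \code{(-d2, d1)}); the default
#'   is the unsigned distance used for PD.
#' @return Non-negative numeric vector (signed if requested).
#' @export
orthogonal_distance <- function(point, line, signed = FALSE) {
  stopifnot(inherits(line, "reference_line"))
  pts <- if (is.null(dim(point))) matrix(point, ncol = 2) else as.matrix(point)
  if (ncol(pts) != 2L) stop("points must have two columns")
  nrm <- c(-line$direction[2], line$direction[1])
  s <- (pts[, 1] - line$centroid[1]) * nrm[1] +
       (pts[, 2] - line$centroid[2]) * nrm[2]
  if (signed) s else abs(s)
}

#' Compute the parenclitic deviation matrix
#'
#' For each network edge, fits the orthogonal regression line on the
#' reference population (in raw variable units, no standardization) and
#' scores every patient in the whole cohort by the orthogonal distance of
#' their (x, y) point from that line. A patient missing either variable gets
#' \code{NA} for that edge; an edge with fewer than 3 complete reference
#' pairs is omitted with a recorded reason.
#'
#' @param cohort A cohort data.frame.
#' @param reference Group keyword or logical vector defining the reference
#'   population (see \code{\link{build_network}}); survivors for the 30-day
#'   outcome, non-deteriorated patients for the 48-h outcome.
#' @param edges Data.frame with columns \code{var_x}, \code{var_y} (e.g.
#'   from \code{\link{significant_edges}} or \code{\link{pd_edge_union}}).
#' @return Object of class \code{"pd_matrix"}: \code{values} (patients x
#'   edges, \code{NA} where inputs missing), \code{patient_ids},
#'   \code{edges}, \code{lines} (per-edge \code{"reference_line"}),
#'   \code{reference_label}, \code{dropped} (omitted edges + reasons).
#' @export
compute_pd_matrix <- function(cohort, reference, edges) {
  stopifnot(all(c("var_x", "var_y") %in% names(edges)))
  sel <- resolve_group(cohort, reference)
  label <- attr(sel, "label")
  ref <- cohort[sel, , drop = FALSE]
  if (nrow(ref) == 0L) stop("reference population is empty")

  keep <- list(); lines <- list(); dropped <- list()
  for (k in seq_len(nrow(edges))) {
    vx <- edges$var_x[k]; vy <- edges$var_y[k]
    ln <- tryCatch(
      fit_orthogonal_line(ref[[vx]], ref[[vy]], var_x = vx, var_y = vy),
      error = function(e) conditionMessage(e))
    if (is.character(ln)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(var_x = vx, var_y = vy, reason = ln,
                   stringsAsFactors = FALSE)
      next
    }
    keep[[length(keep) + 1L]] <- c(vx, vy)
    lines[[paste0("PD__", vx, "__", vy)]] <- ln
  }
  if (length(keep) == 0L) stop("no edge has enough reference pairs to fit a line")
  edge_df <- data.frame(var_x = vapply(keep, `[`, "", 1),
                        var_y = vapply(keep, `[`, "", 2),
                        stringsAsFactors = FALSE)
  edge_names <- paste0("PD__", edge_df$var_x, "__", edge_df$var_y)
  vals <- matrix(NA_real_, nrow(cohort), nrow(edge_df),
                 dimnames = list(as.character(cohort$patient_id), edge_names))
  for (k in seq_len(nrow(edge_df))) {
    x <- cohort[[edge_df$var_x[k]]]; y <- cohort[[edge_df$var_y[k]]]
    ok <- !is.na(x) & !is.na(y)
    if (any(ok))
      vals[ok, k] <- orthogonal_distance(cbind(x[ok], y[ok]),
                                         lines[[edge_names[k]]])
  }
  structure(
    list(values = vals, patient_ids = as.character(cohort$patient_id),
         edges = edge_df, lines = lines, reference_label = label,
         dropped = if (length(dropped)) do.call(rbind, dropped) else
           data.frame(var_x = character(), var_y = character(),
                      reason = character(), stringsAsFactors = FALSE)),
    class = "pd_matrix")
}

#' @export
print.pd_matrix <- function(x, ...) {
  cat(sprintf("Parenclitic deviation matrix: %d patients x %d edges (reference: %s)\n",
              nrow(x$values), ncol(x$values), x$reference_label))
  avail <- colSums(!is.na(x$values))
  for (k in seq_len(ncol(x$values)))
    cat(sprintf("  %s  available n = %d, mean PD = %.4g\n",
                colnames(x$values)[k], avail[k],
                mean(x$values[, k], na.rm = TRUE)))
  if (nrow(x$dropped) > 0)
    cat("  omitted edges:", nrow(x$dropped), "(see $dropped)\n")
  invisible(x)
}

#' Union of significant edges from two group networks
#'
#' The edge set scored in the individual-patient stage: all pairs significant
#' in either outcome group's map, each later scored against the
#' reference-population line.
#'
#' @param net_pos,net_neg \code{"correlation_network"} objects (e.g. survivor
#'   and non-survivor maps).
#' @return Data.frame with \code{var_x}, \code{var_y}, \code{in_pos},
#'   \code{in_neg}, deduplicated as unordered pairs.
#' @export
pd_edge_union <- function(net_pos, net_neg) {
  cmp <- compare_networks(net_pos, net_neg)
  mk <- function(df, in_pos, in_neg) {
    if (nrow(df) == 0L) return(NULL)
    data.frame(var_x = df$var_x, var_y = df$var_y,
               in_pos = in_pos, in_neg = in_neg, stringsAsFactors = FALSE)
  }
  out <- rbind(mk(cmp$shared, TRUE, TRUE), mk(cmp$only_a, TRUE, FALSE),
               mk(cmp$only_b, FALSE, TRUE))
  if (is.null(out))
    out <- data.frame(var_x = character(), var_y = character(),
                      in_pos = logical(), in_neg = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Z-transformation with missing-value propagation
#'
#' Centers and scales the non-missing entries to mean 0 and sample standard
#' deviation 1; \code{NA} entries stay \code{NA}. Used to standardize PD
#' values before entering proportional-hazards models, with statistics
#' computed over all patients with the value available.
#'
#' @param values Numeric vector, \code{NA} allowed.
#' @return Vector of the same length.
#' @export
z_normalize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  s <- stats::sd(values[ok])
  if (s == 0) stop("zero spread: cannot z-normalize a constant vector")
  (values - mean(values[ok])) / s
}

#' Write a PD matrix to CSV with a JSON line sidecar
#'
#' Writes \code{patient_id} plus one \code{PD__<x>__<y>} column per edge
#' (empty cell = missing), and a JSON sidecar \code{<path>.lines.json}
#' describing each reference line (centroid, direction, n_fit,
#' orthogonal_sse) and the reference label.
#'
#' @param pd A \code{"pd_matrix"}.
#' @param path CSV output path.
#' @return Invisibly, the paths written.
#' @export
write_pd_matrix <- function(pd, path) {
  stopifnot(inherits(pd, "pd_matrix"))
  df <- data.frame(patient_id = pd$patient_ids, pd$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_cohort(df, path)  # same shortest-roundtrip numeric formatting
  meta <- list(
    reference_label = pd$reference_label,
    lines = lapply(pd$lines, function(ln)
      list(var_x = ln$var_x, var_y = ln$var_y, centroid = ln$centroid,
           direction = ln$direction, n_fit = ln$n_fit,
           orthogonal_sse = ln$orthogonal_sse)),
    dropped = pd$dropped)
  side <- paste0(path, ".lines.json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(path, side))
}

#' Read a PD matrix written by \code{write_pd_matrix}
#'
#' @param path CSV path (expects \code{<path>.lines.json} beside it).
#' @return A \code{"pd_matrix"}.
#' @export
read_pd_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  side <- paste0(path, ".lines.json")
  if (!file.exists(side)) stop("missing line sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  edge_cols <- setdiff(names(df), "patient_id")
  vals <- sapply(edge_cols, function(cn) {
    x <- df[[cn]]; x[x == ""] <- NA_character_; as.numeric(x)
  })
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(df$patient_id, edge_cols))
  lines <- lapply(edge_cols, function(cn) {
    m <- meta$lines[[cn]]
    structure(list(var_x = m$var_x, var_y = m$var_y,
                   centroid = as.numeric(m$centroid),
                   direction = as.numeric(m$direction),
                   n_fit = as.integer(m$n_fit),
                   orthogonal_sse = as.numeric(m$orthogonal_sse),
                   slope = if (m$direction[1] != 0)
                     m$direction[2] / m$direction[1] else NA_real_,
                   intercept = if (m$direction[1] != 0)
                     m$centroid[2] - m$direction[2] / m$direction[1] *
                       m$centroid[1] else NA_real_),
              class = "reference_line")
  })
  names(lines) <- edge_cols
  parts <- strsplit(sub("^PD__", "", edge_cols), "__", fixed = TRUE)
  structure(
    list(values = vals, patient_ids = df$patient_id,
         edges = data.frame(var_x = vapply(parts, `[`, "", 1),
                            var_y = vapply(parts, `[`, "", 2),
                            stringsAsFactors = FALSE),
         lines = lines, reference_label = meta$reference_label,
         dropped = as.data.frame(meta$dropped)),
    class = "pd_matrix")
}
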