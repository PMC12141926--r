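#' Read a patient cohort table
#'
#' Reads a comma-separated cohort file (one row per patient) into a validated
#' cohort data.frame. Empty cells in laboratory columns denote missing values
#' and become \code{NA}; row order and row count are preserved.
#'
#' The expected layout is
#' \code{patient_id,time_days,event30,deteriorated48,sofa,ventilated,age,sex,ethnicity,elixhauser}
#' followed by the 15 laboratory columns of \code{\link{lab_registry}}.
#' Only \code{patient_id}, \code{time_days} and \code{event30} are mandatory;
#' analyses requiring other columns fail later with a clear message.
#'
#' @param path Path to a CSV file with a header row.
#' @param registry Variable registry data.frame (default \code{lab_registry()});
#'   its \code{name} column defines which columns are treated as labs.
#' @return A data.frame of class \code{"parenclitic_cohort"}.
#' @seealso \code{\link{write_cohort}}, \code{\link{validate_cohort}}
#' @export
read_cohort <- function(path, registry = lab_registry()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL, fileEncoding = "UTF-8")
  mandatory <- c("patient_id", "time_days", "event30")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent) > 0L)
    stop("cohort file is missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  if (anyDuplicated(raw$patient_id))
    stop("duplicate patient_id value(s): ",
         paste(unique(raw$patient_id[duplicated(raw$patient_id)]), collapse = ", "))

  numeric_meta <- intersect(
    c("time_days", "event30", "deteriorated48", "sofa", "ventilated",
      "age", "elixhauser"), names(raw))
  labs <- intersect(registry$name, names(raw))

  parse_num <- function(col, kind) {
    x <- raw[[col]]
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric %s value '%s' in column '%s', row %d",
                   kind, x[bad[1]], col, bad[1]))
    out
  }
  for (col in numeric_meta) raw[[col]] <- parse_num(col, "covariate")
  for (col in labs) raw[[col]] <- parse_num(col, "laboratory")
  rownames(raw) <- NULL
  attr(raw, "registry") <- registry
  class(raw) <- c("parenclitic_cohort", "data.frame")
  raw
}

#' Write a patient cohort table
#'
#' Writes a cohort to CSV with the header first and missing values rendered
#' as empty cells, so that \code{read_cohort(write_cohort(x))} reproduces the
#' cohort exactly.
#'
#' @param cohort A cohort data.frame (as from \code{\link{read_cohort}} or
#'   \code{\link{generate_cohort}}).
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  # shortest decimal representation that parses back to the same double,
  # so round-trips are bit-exact without printing 17 digits everywhere
  fmt1 <- function(z) {
    if (is.na(z)) return("")
    for (d in 1:17) {
      s <- format(z, digits = d, scientific = FALSE, trim = TRUE)
      if (as.numeric(s) == z) return(s)
    }
    s
  }
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      df[[col]] <- vapply(df[[col]], fmt1, "")
    } else {
      df[[col]][is.na(df[[col]])] <- ""
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a cohort table
#'
#' Screens a cohort for implausible or inconsistent values and returns one
#' issue record per finding. Checks: laboratory values outside the registry
#' plausibility range, follow-up times beyond the 30-day horizon, and deaths
#' (\code{event30 = 1}) recorded with \code{time_days >= 30}. The input is
#' never modified; validation is reporting only.
#'
#' @param cohort A cohort data.frame.
#' @param registry Variable registry (default: the one attached to the
#'   cohort, else \code{lab_registry()}).
#' @return A data.frame with columns \code{row}, \code{patient_id},
#'   \code{field}, \code{value}, \code{issue}; zero rows when nothing is
#'   flagged.
#' @export
validate_cohort <- function(cohort, registry = NULL) {
  if (is.null(registry))
    registry <- attr(cohort, "registry", exact = TRUE)
  if (is.null(registry)) registry <- lab_registry()
  issues <- list()
  add <- function(row, field, value, issue) {
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, patient_id = as.character(cohort$patient_id[row]),
      field = field, value = value, issue = issue, stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(registry))) {
    v <- registry$name[k]
    if (!v %in% names(cohort)) next
    x <- cohort[[v]]
    out <- which(!is.na(x) & (x < registry$plausible_low[k] |
                              x > registry$plausible_high[k]))
    for (i in out)
      add(i, v, x[i], sprintf("%s value %g outside plausible range [%g, %g]",
                              registry$label[k], x[i],
                              registry$plausible_low[k],
                              registry$plausible_high[k]))
  }
  if ("time_days" %in% names(cohort)) {
    for (i in which(!is.na(cohort$time_days) & cohort$time_days > 30))
      add(i, "time_days", cohort$time_days[i],
          "follow-up time exceeds the 30-day horizon")
  }
  if (all(c("time_days", "event30") %in% names(cohort))) {
    for (i in which(!is.na(cohort$event30) & cohort$event30 == 1 &
                    !is.na(cohort$time_days) & cohort$time_days >= 30))
      add(i, "event30", cohort$time_days[i],
          "death recorded with time_days at or beyond the 30-day horizon")
  }
  if (length(issues) == 0L)
    return(data.frame(row = integer(), patient_id = character(),
                      field = character(), value = numeric(),
                      issue = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Group summary table (descriptive comparison by outcome)
#'
#' Summarizes the cohort by an outcome grouping: for continuous variables the
#' median and quartiles per group with a Mann-Whitney p-value, for categorical
#' variables counts and percentages with a chi-squared p-value (no continuity
#' correction). Quartiles use linear interpolation between order statistics
#' (R's default quantile type 7).
#'
#' @param cohort A cohort data.frame.
#' @param group_field \code{"event30"} or \code{"deteriorated48"}.
#' @return A data.frame with one row per variable: \code{variable},
#'   \code{type}, \code{n0}, \code{n1}, group summaries, \code{p}.
#' @export
group_summary <- function(cohort, group_field = c("event30", "deteriorated48")) {
  group_field <- match.arg(group_field)
  g <- cohort[[group_field]]
  if (is.null(g)) stop("cohort lacks grouping column ", group_field)
  keep <- !is.na(g)
  if (sum(g[keep] == 0) < 2L || sum(g[keep] == 1) < 2L)
    stop("each outcome group needs at least 2 members")

  continuous <- intersect(c("age", "sofa", "elixhauser", lab_variables()),
                          names(cohort))
  categorical <- intersect(c("sex", "ethnicity", "ventilated"), names(cohort))

  rows <- list()
  for (v in continuous) {
    x <- cohort[[v]][keep]; gg <- g[keep]
    ok <- !is.na(x)
    x0 <- x[ok & gg == 0]; x1 <- x[ok & gg == 1]
    p <- if (length(x0) >= 1 && length(x1) >= 1)
      mann_whitney(x0, x1)$p else NA_real_
    qs <- function(z) if (length(z) == 0) rep(NA_real_, 3) else
      stats::quantile(z, c(.25, .5, .75), type = 7, names = FALSE)
    q0 <- qs(x0); q1 <- qs(x1)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "continuous",
      n0 = length(x0), n1 = length(x1),
      summary0 = sprintf("%.3g (%.3g-%.3g)", q0[2], q0[1], q0[3]),
      summary1 = sprintf("%.3g (%.3g-%.3g)", q1[2], q1[1], q1[3]),
      median0 = q0[2], q1_0 = q0[1], q3_0 = q0[3],
      median1 = q1[2], q1_1 = q1[1], q3_1 = q1[3],
      p = p, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- cohort[[v]][keep]; gg <- g[keep]
    ok <- !is.na(x) & x != ""
    tab <- table(factor(gg[ok], levels = c(0, 1)), x[ok])
    p <- if (ncol(tab) >= 2L)
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    else NA_real_
    pct <- function(row) paste(sprintf("%s: %d (%.1f%%)", colnames(tab),
                                       tab[row, ],
                                       100 * tab[row, ] / sum(tab[row, ])),
                               collapse = "; ")
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "categorical",
      n0 = sum(gg[ok] == 0), n1 = sum(gg[ok] == 1),
      summary0 = pct(1), summary1 = pct(2),
      median0 = NA, q1_0 = NA, q3_0 = NA,
      median1 = NA, q1_1 = NA, q3_1 = NA,
      p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "group_field") <- group_field
  out
}
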