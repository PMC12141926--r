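# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own closed-form paths.

# TLS by angle scan: minimize orthogonal SSE over a dense grid of line
# angles through the centroid. Returns the best angle and its SSE.
oracle_tls_angle <- function(x, y, n_grid = 1e5) {
  cx <- mean(x); cy <- mean(y)
  th <- seq(0, pi, length.out = n_grid + 1)[-(n_grid + 1)]
  u <- x - cx; v <- y - cy
  # squared distance to line at angle th: (u * -sin + v * cos)^2
  sse <- colSums((outer(u, -sin(th)) + outer(v, cos(th)))^2)
  k <- which.min(sse)
  list(angle = th[k], sse = sse[k], grid_step = pi / n_grid)
}

# Distance to a line by dense sampling of points along it.
oracle_line_distance <- function(point, centroid, direction, span = 50,
                                 n_samples = 1e5) {
  tt <- seq(-span, span, length.out = n_samples)
  px <- centroid[1] + tt * direction[1]
  py <- centroid[2] + tt * direction[2]
  sqrt(min((px - point[1])^2 + (py - point[2])^2))
}

# Mann-Whitney U by exhaustive pair counting (comparison group b vs
# reference a): wins + half-ties.
oracle_u_count <- function(a, b) {
  u <- 0
  for (bj in b) u <- u + sum(bj > a) + 0.5 * sum(bj == a)
  u
}

# Empirical AUC by exhaustive pair comparison.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  oracle_u_count(neg, pos) / (length(pos) * length(neg))
}

# Small fully-observed cohort around the planted structures, for fast tests.
tiny_cohort <- function(n = 80, seed = 1, beta_pd = 0.733) {
  cfg <- scaled_config(n_patients = n, beta_pd = beta_pd, miss_scale = 0)
  generate_cohort(cfg, seed = seed)
}

# Write a small cohort CSV from a data.frame of columns.
write_csv_text <- function(lines, path) {
  writeLines(lines, path)
  path
}
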