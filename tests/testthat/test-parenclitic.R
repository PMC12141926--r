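test_that("an exact linear cloud yields the exact line with zero residual", {
  ln <- fit_orthogonal_line(c(0, 1, 2), c(1, 3, 5))  # y = 2x + 1
  expect_equal(ln$centroid, c(1, 3))
  expect_equal(ln$direction, c(1, 2) / sqrt(5), tolerance = 1e-12)
  expect_equal(ln$orthogonal_sse, 0, tolerance = 1e-20)
  expect_equal(ln$slope, 2, tolerance = 1e-12)
  expect_equal(ln$intercept, 1, tolerance = 1e-12)
})

test_that("the fit matches a brute-force angle-grid minimizer of orthogonal SSE", {
  set.seed(401)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    th0 <- runif(1, 0, pi)
    t <- rnorm(n, sd = runif(1, 0.5, 3))
    x <- 5 + t * cos(th0) + rnorm(n, sd = 0.3)
    y <- -2 + t * sin(th0) + rnorm(n, sd = 0.3)
    ln <- fit_orthogonal_line(x, y)
    orc <- oracle_tls_angle(x, y, n_grid = 2e4)
    fit_angle <- atan2(ln$direction[2], ln$direction[1]) %% pi
    dth <- min(abs(fit_angle - orc$angle), pi - abs(fit_angle - orc$angle))
    expect_lt(dth, 2 * orc$grid_step)
    # the closed-form SSE can never exceed the grid minimum
    expect_lte(ln$orthogonal_sse, orc$sse + 1e-9)
  }
})

test_that("fitting is symmetric under swapping the axes", {
  set.seed(402)
  x <- rnorm(40); y <- 1.5 * x + rnorm(40, sd = 0.5)
  ln <- fit_orthogonal_line(x, y)
  ln_sw <- fit_orthogonal_line(y, x)
  d1 <- orthogonal_distance(cbind(x, y), ln)
  d2 <- orthogonal_distance(cbind(y, x), ln_sw)
  expect_lt(max(abs(d1 - d2)), 1e-9)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_orthogonal_line(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_orthogonal_line(rep(2, 5), rep(3, 5)), "identical")
  # perfectly isotropic 4-point cloud: equal eigenvalues
  expect_error(fit_orthogonal_line(c(1, -1, 0, 0), c(0, 0, 1, -1)),
               "direction ambiguous")
})

test_that("orthogonal distance agrees with geometry and a sampling oracle", {
  ln <- fit_orthogonal_line(c(0, 1, 2), c(0, 1, 2))  # y = x
  expect_equal(orthogonal_distance(c(0, 1), ln), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_equal(orthogonal_distance(c(1, 1), ln), 0, tolerance = 1e-12)

  ln2 <- fit_orthogonal_line(c(0, 1, 2), c(1, 3, 5))  # y = 2x + 1
  # probe offset sqrt(5) vertically above (1, 3): perpendicular distance
  # = sqrt(5) * cos(atan 2) = 1
  p <- c(1, 3 + sqrt(5))
  expect_equal(orthogonal_distance(p, ln2), 1, tolerance = 1e-12)
  expect_equal(orthogonal_distance(p, ln2),
               oracle_line_distance(p, ln2$centroid, ln2$direction),
               tolerance = 1e-3)

  set.seed(403)
  x <- rnorm(25); y <- -0.8 * x + rnorm(25)
  ln3 <- fit_orthogonal_line(x, y)
  for (k in 1:5) {
    p <- rnorm(2, sd = 3)
    expect_equal(orthogonal_distance(p, ln3),
                 oracle_line_distance(p, ln3$centroid, ln3$direction),
                 tolerance = 1e-3)
  }
})

test_that("the fitted line passes through the centroid and signed residuals cancel", {
  set.seed(404)
  x <- rnorm(60, 10, 2); y <- 3 * x + rnorm(60, sd = 2)
  ln <- fit_orthogonal_line(x, y)
  expect_equal(orthogonal_distance(ln$centroid, ln), 0, tolerance = 1e-12)
  s <- orthogonal_distance(cbind(x, y), ln, signed = TRUE)
  expect_lt(abs(sum(s)) / max(abs(s)), 1e-9)
  expect_equal(sum(s^2), ln$orthogonal_sse, tolerance = 1e-9)
})

test_that("PD is invariant under isometries but not under per-axis rescaling", {
  set.seed(405)
  x <- rnorm(50); y <- 0.7 * x + rnorm(50, sd = 0.4)
  px <- rnorm(5); py <- rnorm(5)
  pd0 <- orthogonal_distance(cbind(px, py), fit_orthogonal_line(x, y))
  # translation
  pd_t <- orthogonal_distance(cbind(px + 7, py - 3),
                              fit_orthogonal_line(x + 7, y - 3))
  expect_equal(pd_t, pd0, tolerance = 1e-9)
  # rotation of the whole plane
  a <- 0.83
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  xy_r <- cbind(x, y) %*% R; p_r <- cbind(px, py) %*% R
  pd_r <- orthogonal_distance(p_r, fit_orthogonal_line(xy_r[, 1], xy_r[, 2]))
  expect_equal(pd_r, pd0, tolerance = 1e-9)
  # rescaling one axis changes distances (documented non-invariance)
  pd_s <- orthogonal_distance(cbind(3 * px, py),
                              fit_orthogonal_line(3 * x, y))
  expect_gt(max(abs(pd_s - pd0)), 1e-3)
})

test_that("mean reference PD tracks the half-normal mean of the noise", {
  set.seed(406)
  sigma <- 0.5
  t <- rnorm(1e4, sd = 4)
  # points on a line plus isotropic noise sigma
  x <- t * cos(0.6) + rnorm(1e4, sd = sigma)
  y <- 1 + t * sin(0.6) + rnorm(1e4, sd = sigma)
  ln <- fit_orthogonal_line(x, y)
  m <- mean(orthogonal_distance(cbind(x, y), ln))
  expect_gt(m, 0.6 * sigma)
  expect_lt(m, 0.9 * sigma)
})

test_that("PD matrix respects missingness and complete-case counts", {
  res <- generate_cohort(scaled_config(200), seed = 21)
  co <- res$cohort
  edges <- data.frame(var_x = c("arterial_ph", "urea"),
                      var_y = c("bicarbonate", "creatinine"))
  pd <- compute_pd_matrix(co, "survived30", edges)
  expect_true(all(pd$values >= 0, na.rm = TRUE))
  for (k in 1:2) {
    have <- !is.na(co[[edges$var_x[k]]]) & !is.na(co[[edges$var_y[k]]])
    expect_identical(unname(!is.na(pd$values[, k])), unname(have))
    # consistency with the correlation stage's complete-case count
    pp <- pairwise_pearson(co[[edges$var_x[k]]], co[[edges$var_y[k]]])
    expect_equal(sum(!is.na(pd$values[, k])), pp$n_pairs)
  }
  # a patient placed exactly on the reference line scores zero
  ln <- pd$lines[["PD__arterial_ph__bicarbonate"]]
  co$arterial_ph[1] <- ln$centroid[1]
  co$bicarbonate[1] <- ln$centroid[2]
  pd2 <- compute_pd_matrix(co, "survived30", edges)
  # line refit includes patient 1 if they are a survivor; score the centroid
  # of the new line instead for an exact zero
  ln2 <- pd2$lines[["PD__arterial_ph__bicarbonate"]]
  expect_equal(orthogonal_distance(ln2$centroid, ln2), 0, tolerance = 1e-12)

  # an edge without enough reference pairs is omitted with a reason
  co3 <- res$cohort
  co3$alt[co3$event30 == 0] <- NA
  pd3 <- compute_pd_matrix(co3, "survived30",
                           rbind(edges, data.frame(var_x = "inr",
                                                   var_y = "alt")))
  expect_equal(ncol(pd3$values), 2)
  expect_equal(nrow(pd3$dropped), 1)
  expect_match(pd3$dropped$reason, "at least 3")
})

test_that("PD matrix CSV + sidecar round-trips", {
  res <- generate_cohort(scaled_config(80), seed = 22)
  net1 <- build_network(res$cohort, "survived30")
  edges <- data.frame(var_x = c("arterial_ph", "wbc"),
                      var_y = c("bicarbonate", "platelets"))
  pd <- compute_pd_matrix(res$cohort, "survived30", edges)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pd_matrix(pd, f)
  back <- read_pd_matrix(f)
  expect_identical(back$values, pd$values)
  expect_equal(back$lines[[1]]$direction, pd$lines[[1]]$direction,
               tolerance = 1e-15)
  expect_identical(back$reference_label, pd$reference_label)
})

test_that("z-normalization standardizes available entries and propagates NA", {
  expect_equal(z_normalize(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(z_normalize(c(5, 5, NA, 5)), "zero spread")
  expect_error(z_normalize(c(1, NA, NA)), "at least 2")
  set.seed(407)
  v <- rnorm(100); v[sample(100, 20)] <- NA
  z <- z_normalize(v)
  expect_identical(is.na(z), is.na(v))
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-12)
})
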