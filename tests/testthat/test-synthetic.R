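test_that("the default configuration is deterministic and well-formed", {
  cfg1 <- default_config(); cfg2 <- default_config()
  expect_identical(cfg1, cfg2)
  expect_equal(cfg1$n_patients, 162L)
  expect_equal(cfg1$mortality_fraction, 33 / 162)
  expect_equal(cfg1$deterioration_fraction, 30 / 162)
  for (R in list(cfg1$corr_ref, cfg1$corr_poor)) {
    expect_true(isSymmetric(R))
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_equal(unname(diag(R)), rep(1, 15))
  }
  expect_true(all(cfg1$miss_prob >= 0 & cfg1$miss_prob < 1))
  expect_gt(cfg1$lambda0, 0)
})

test_that("the baseline rate calibration hits the target mortality on average", {
  cfg <- default_config()
  set.seed(801)
  deaths <- vapply(1:30, function(i)
    sum(generate_cohort(cfg, seed = i)$cohort$event30), 0)
  # marginal 30-day mortality should sit near 33/162 = 0.204
  expect_lt(abs(mean(deaths) / cfg$n_patients - cfg$mortality_fraction), 0.03)
})

test_that("generation is reproducible and respects the missingness switch", {
  cfg <- default_config()
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$patients, b$truth$patients)
  c2 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a$cohort$lactate, c2$cohort$lactate))

  full <- generate_cohort(scaled_config(miss_scale = 0), seed = 1)$cohort
  expect_false(anyNA(full[, lab_variables()]))
})

test_that("planted correlations are recovered within sampling error at n = 5000", {
  cfg <- scaled_config(n_patients = 5000, miss_scale = 0)
  res <- generate_cohort(cfg, seed = 13)
  co <- res$cohort
  ref <- res$truth$patients$class == "reference"
  planted <- list(c("wbc", "platelets", 0.6), c("inr", "alt", 0.6),
                  c("arterial_ph", "bicarbonate", 0.7),
                  c("urea", "creatinine", 0.8))
  for (p in planted) {
    emp <- cor(co[[p[1]]][ref], co[[p[2]]][ref])
    expect_lt(abs(emp - as.numeric(p[3])), 0.1,
              label = paste(p[1], p[2]))
  }
  poor <- !ref
  emp <- cor(co$lactate[poor], co$arterial_ph[poor])
  expect_lt(abs(emp - (-0.7)), 0.1)
})

test_that("group contrasts run in the clinically expected directions", {
  # poor-outcome patients: higher lactate/urea/creatinine/phosphate,
  # lower pH and bicarbonate
  up <- c("lactate", "urea", "creatinine", "phosphate")
  down <- c("arterial_ph", "bicarbonate")
  ok <- 0L
  for (s in 1:20) {
    co <- generate_cohort(default_config(), seed = 900 + s)$cohort
    d <- co$event30 == 1
    good <- all(vapply(up, function(v)
      median(co[[v]][d], na.rm = TRUE) >=
        median(co[[v]][!d], na.rm = TRUE), TRUE)) &&
      all(vapply(down, function(v)
        median(co[[v]][d], na.rm = TRUE) <=
          median(co[[v]][!d], na.rm = TRUE), TRUE))
    ok <- ok + good
  }
  expect_gte(ok / 20, 0.95)
})

test_that("true deviations drive mortality and the truth record is faithful", {
  res <- generate_cohort(scaled_config(2000, beta_pd = 0.7), seed = 14)
  tr <- res$truth$patients
  expect_true(all(tr$true_deviation >= 0))
  expect_identical(tr$patient_id, res$cohort$patient_id)
  # deaths concentrate at high deviation
  expect_gt(mean(tr$z_deviation[res$cohort$event30 == 1]),
            mean(tr$z_deviation[res$cohort$event30 == 0]) + 0.3)
  # censoring convention: survivors sit exactly at the horizon
  expect_true(all(res$cohort$time_days[res$cohort$event30 == 0] == 30))
  expect_true(all(res$cohort$time_days[res$cohort$event30 == 1] < 30))
  # the recorded deviation is the orthogonal distance to the planted line
  i <- which.max(tr$true_deviation)
  # recompute from the truth line and the observed (complete) labs
  full <- generate_cohort(scaled_config(2000, beta_pd = 0.7, miss_scale = 0),
                          seed = 14)
  d <- orthogonal_distance(
    cbind(full$cohort$arterial_ph, full$cohort$bicarbonate),
    full$truth$planted_line)
  expect_equal(d, full$truth$patients$true_deviation, tolerance = 1e-9)
})

test_that("truth records round-trip through JSON", {
  res <- generate_cohort(scaled_config(50), seed = 15)
  f <- withr::local_tempfile(fileext = ".json")
  truth_report(res$truth, f)
  back <- read_truth(f)
  expect_equal(back$planted_line$centroid, res$truth$planted_line$centroid)
  expect_equal(back$planted_line$direction, res$truth$planted_line$direction)
  expect_equal(back$beta_pd, res$truth$beta_pd)
  expect_equal(back$lambda0, res$truth$lambda0)
  expect_equal(back$patients$true_deviation,
               res$truth$patients$true_deviation)
  expect_equal(as.matrix(back$corr_ref), res$truth$corr_ref,
               tolerance = 1e-15)
  # regenerating from the stored seed reproduces the file's truth
  again <- generate_cohort(scaled_config(50), seed = back$seed)
  expect_equal(again$truth$patients$true_deviation,
               back$patients$true_deviation)
})

test_that("null hazard produces PD-independent survival downstream", {
  # with beta_pd = 0 the Cox CI for the planted-axis PD should cover 1
  covered <- 0L
  for (s in 1:10) {
    res <- generate_cohort(scaled_config(500, beta_pd = 0, miss_scale = 0),
                           seed = 1000 + s)
    co <- res$cohort
    pd <- compute_pd_matrix(co, "survived30",
                            data.frame(var_x = "arterial_ph",
                                       var_y = "bicarbonate"))
    cv <- data.frame(pd_z = z_normalize(pd$values[, 1]),
                     arterial_ph = co$arterial_ph,
                     bicarbonate = co$bicarbonate,
                     sofa = co$sofa, ventilated = co$ventilated)
    fit <- cox_fit(co$time_days, co$event30, cv)
    row <- fit$table[fit$table$term == "pd_z", ]
    covered <- covered + (row$ci_lower <= 1 && 1 <= row$ci_upper)
  }
  expect_gte(covered, 9)
})
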