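test_that("pairwise Pearson matches the formula-level oracle and cor.test", {
  set.seed(101)
  x <- rnorm(50); y <- 0.6 * x + rnorm(50, sd = 0.8)
  res <- pairwise_pearson(x, y)
  # brute-force Pearson formula
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(48 / (1 - r_hand^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 48), tolerance = 1e-12)
  # independent route: stats::cor.test
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_equal(res$n_pairs, 50)
})

test_that("pairwise deletion, collinearity boundary, and degeneracy errors", {
  res <- pairwise_pearson(c(1, 2, 3, NA), c(2, 4, 6, 8))
  expect_equal(res$n_pairs, 3)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)
  expect_equal(pairwise_pearson(1:5, 1:5)$r, 1)
  expect_error(pairwise_pearson(c(1, 2, NA), c(NA, 2, 3)), "insufficient pairs")
  expect_error(pairwise_pearson(c(1, 1, 1, 1), 1:4), "degenerate variable")
})

test_that("Pearson r is symmetric and invariant under positive affine maps", {
  set.seed(202)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30) + 0.3 * x
    a <- runif(1, 0.1, 5); b <- runif(1, -10, 10)
    expect_equal(pairwise_pearson(x, y)$r, pairwise_pearson(y, x)$r,
                 tolerance = 1e-12)
    expect_lt(abs(pairwise_pearson(a * x + b, y)$r -
                  pairwise_pearson(x, y)$r), 1e-12)
  }
})

test_that("Bonferroni threshold matches the all-pairs count", {
  expect_equal(bonferroni_threshold(15, 0.05), 0.05 / 105)
  expect_equal(bonferroni_threshold(2, 0.05), 0.05)
  expect_equal(bonferroni_threshold(4, 0.05), 0.05 / 6)
  expect_error(bonferroni_threshold(1), "at least 2")
})

test_that("network building recovers a planted correlation and nothing under the null", {
  vars <- lab_variables()
  # null: independent noise, n = 200 -> no significant edge for this seed
  set.seed(301)
  d <- as.data.frame(matrix(rnorm(200 * 15), 200, 15))
  names(d) <- vars; d$patient_id <- seq_len(200)
  net0 <- build_network(d, rep(TRUE, 200))
  expect_equal(sum(net0$edges$significant), 0)

  # planted rho = 0.9 between lactate and pH, n = 100 -> exactly that edge
  set.seed(302)
  d2 <- as.data.frame(matrix(rnorm(100 * 15), 100, 15))
  names(d2) <- vars
  d2$lactate <- 0.9 * d2$arterial_ph + sqrt(1 - 0.81) * rnorm(100)
  d2$patient_id <- seq_len(100)
  net1 <- build_network(d2, rep(TRUE, 100))
  sig <- significant_edges(net1)
  expect_equal(nrow(sig), 1)
  expect_setequal(c(sig$var_x, sig$var_y), c("arterial_ph", "lactate"))

  # structural invariants
  expect_true(isSymmetric(net1$adjacency))
  expect_true(all(diag(net1$adjacency) == 0))
  expect_equal(net1$threshold, 0.05 / 105)
})

test_that("unevaluable pairs are recorded with reasons, not dropped", {
  vars <- lab_variables()
  set.seed(303)
  d <- as.data.frame(matrix(rnorm(30 * 15), 30, 15))
  names(d) <- vars
  d$potassium <- 4.0            # zero variance
  d$alt[1:28] <- NA             # only 2 complete pairs against anything
  d$patient_id <- seq_len(30)
  net <- build_network(d, rep(TRUE, 30))
  expect_equal(nrow(net$edges), 105)
  a_pair <- net$edges$var_x == "alt" | net$edges$var_y == "alt"
  k_edges <- (net$edges$var_x == "potassium" |
              net$edges$var_y == "potassium") & !a_pair
  expect_true(all(grepl("degenerate", net$edges$reason[k_edges])))
  a_edges <- a_pair & !(net$edges$var_x == "potassium" |
                        net$edges$var_y == "potassium")
  expect_true(all(grepl("insufficient", net$edges$reason[a_edges])))
  expect_true(all(net$edges$significant[k_edges | a_pair] == 0))
})

test_that("network comparison partitions edge sets", {
  res <- tiny_cohort(n = 400, seed = 11)
  n1 <- build_network(res$cohort, "survived30")
  expect_identical(compare_networks(n1, n1)$only_a,
                   significant_edges(n1)[0, ])
  expect_equal(nrow(compare_networks(n1, n1)$shared),
               nrow(significant_edges(n1)))
  n2 <- build_network(res$cohort, "died30")
  cmp <- compare_networks(n1, n2)
  expect_equal(nrow(cmp$shared) + nrow(cmp$only_a),
               nrow(significant_edges(n1)))
  expect_equal(nrow(cmp$shared) + nrow(cmp$only_b),
               nrow(significant_edges(n2)))
  n3 <- n2; n3$variables <- rev(n3$variables)
  expect_error(compare_networks(n1, n3), "different variable lists")
})

test_that("export writes a full edge-list CSV and round-trips via GraphML", {
  res <- tiny_cohort(n = 300, seed = 12)
  net <- build_network(res$cohort, "survived30")
  stem <- withr::local_tempfile()
  export_network(net, stem)
  csv <- read.csv(paste0(stem, ".csv"))
  expect_equal(nrow(csv), 105)
  expect_equal(sum(csv$significant), sum(net$edges$significant))

  g <- igraph::read_graph(paste0(stem, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 15)
  sig <- igraph::E(g)[igraph::edge_attr(g, "significant") == 1]
  adj_back <- matrix(0L, 15, 15,
                     dimnames = list(net$variables, net$variables))
  ends <- igraph::ends(g, sig)
  for (k in seq_len(nrow(ends))) {
    adj_back[ends[k, 1], ends[k, 2]] <- 1L
    adj_back[ends[k, 2], ends[k, 1]] <- 1L
  }
  expect_identical(adj_back, net$adjacency)
  # |r| is carried as the edge weight
  expect_equal(sort(igraph::edge_attr(g, "weight")),
               sort(abs(net$edges$r[!is.na(net$edges$r)])), tolerance = 1e-9)
})

test_that("a network with no significant edges exports valid GraphML", {
  vars <- lab_variables()
  set.seed(304)
  d <- as.data.frame(matrix(rnorm(50 * 15), 50, 15))
  names(d) <- vars; d$patient_id <- 1:50
  net <- build_network(d, rep(TRUE, 50))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 15)
  expect_equal(sum(igraph::edge_attr(g, "significant")), 0)
})
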