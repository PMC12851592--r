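test_that("a two-point pattern puts mass only in the bin holding its distance", {
  pp <- point_pattern(c(10, 15), c(10, 10), unit_window(100))
  g <- estimate_rdf(pp, 1, 10)
  expect_equal(sum(g$g_values > 0), 1)
  expect_equal(g$r_centers[g$g_values > 0], 5.5)  # distance 5 in bin [5, 6)
  expect_error(estimate_rdf(point_pattern(1, 1, unit_window(10)), 0.5, 2),
               "at least 2 points")
})

test_that("r_max is clipped to a quarter of the smaller window dimension", {
  pp <- gen_poisson_pattern(200, owindow(0, 40, 0, 100), seed = 1)
  g <- estimate_rdf(pp, 1, 50)
  expect_lte(g$r_max, 10)
  expect_lte(max(g$r_centers) + g$bin_width / 2, 10 + 1e-9)
})

test_that("CSR estimate is unbiased and the hard-core exclusion zone is empty", {
  w <- unit_window(200)
  gs <- vapply(1:20, function(s) {
    mean(estimate_rdf(gen_poisson_pattern(2000, w, seed = s), 1, 25)$g_values)
  }, 0)
  expect_gte(mean(gs), 0.95)
  expect_lte(mean(gs), 1.05)

  for (s in 1:5) {
    pp <- gen_hardcore_pattern(500, unit_window(100), 3, seed = s)
    g <- estimate_rdf(pp, 0.5, 10)
    below <- g$r_centers + g$bin_width / 2 <= 3
    expect_equal(g$g_values[below], rep(0, sum(below)))
  }
})

test_that("estimator bias under CSR shrinks with pattern size", {
  w <- unit_window(200)
  bias_at <- function(n) {
    abs(mean(vapply(1:12, function(s) {
      mean(estimate_rdf(gen_poisson_pattern(n, w, seed = 100 + s), 1, 25)$g_values)
    }, 0)) - 1)
  }
  expect_lt(bias_at(2000), bias_at(200) + 0.02)
})

test_that("the estimator is invariant to translation and 90-degree rotation", {
  pp <- gen_poisson_pattern(300, unit_window(80), seed = 4)
  g0 <- estimate_rdf(pp, 0.5, 15)
  shifted <- point_pattern(pp$x + 37, pp$y - 12, owindow(37, 117, -12, 68))
  expect_equal(estimate_rdf(shifted, 0.5, 15)$g_values, g0$g_values)
  rotated <- point_pattern(-pp$y, pp$x, owindow(-80, 0, 0, 80))
  expect_equal(estimate_rdf(rotated, 0.5, 15)$g_values, g0$g_values)
})

test_that("null ensembles are density-matched and reduce to CSR at d_min = 0", {
  pp <- gen_poisson_pattern(400, unit_window(100), seed = 2)
  ens1 <- simulate_null_rdfs(pp, 2, n_sims = 1, 0.5, 10, seed = 7)
  expect_equal(ens1$mean_curve$g_values, ens1$curves[[1]]$g_values)
  expect_true(all(vapply(ens1$curves, `[[`, 0L, "n_points") == 400))
  expect_equal(ens1$curves[[1]]$density, intensity(pp))
  below <- ens1$mean_curve$r_centers + 0.25 <= 2
  expect_equal(ens1$mean_curve$g_values[below], rep(0, sum(below)))

  ens0 <- simulate_null_rdfs(pp, 0, n_sims = 15, 1, 20, seed = 8)
  expect_lt(mean(abs(ens0$mean_curve$g_values - 1)), 0.06)
})

test_that("paired Wilcoxon comparison of curves behaves at the identity and under separation", {
  pp <- gen_poisson_pattern(2000, unit_window(200), seed = 3)
  g <- estimate_rdf(pp, 0.5, 15)
  self <- compare_rdf_wilcoxon(g, g)
  expect_equal(self$p_value, 1)
  expect_equal(self$n_bins_paired, 0L)

  other <- estimate_rdf(gen_poisson_pattern(500, unit_window(120), seed = 4), 1, 30)
  expect_error(compare_rdf_wilcoxon(g, other), "binning")

  # CSR curve vs hard-core null ensemble mean: detected at n_bins >= 30
  expect_equal(length(g$r_centers), 30)
  ens <- simulate_null_rdfs(pp, 3, n_sims = 20, 0.5, 15, seed = 5)
  expect_lt(compare_rdf_wilcoxon(g, ens$mean_curve)$p_value, 0.05)
})

test_that("Wilcoxon comparison of exchangeable replicates is directionally symmetric", {
  # per-bin differences between one pair of curves share a pattern-level
  # offset, so bins are not independent and the p-value is only a
  # descriptive index for curve pairs; what must hold is that p is a valid
  # probability and that neither replicate is systematically favored
  w <- unit_window(150)
  res <- vapply(1:40, function(s) {
    ga <- estimate_rdf(gen_poisson_pattern(600, w, seed = 2 * s), 1, 30)
    gb <- estimate_rdf(gen_poisson_pattern(600, w, seed = 2 * s + 1), 1, 30)
    c(p = compare_rdf_wilcoxon(ga, gb)$p_value,
      a_higher = mean(ga$g_values) > mean(gb$g_values))
  }, numeric(2))
  expect_true(all(res["p", ] > 0 & res["p", ] <= 1))
  expect_gte(mean(res["a_higher", ]), 0.25)
  expect_lte(mean(res["a_higher", ]), 0.75)
})

test_that("R-squared order score matches a direct sum-of-squares oracle", {
  pp <- gen_poisson_pattern(400, unit_window(100), seed = 6)
  g <- estimate_rdf(pp, 0.5, 12)
  self <- rdf_r_squared(g, g)
  expect_equal(self$r_squared, 1)
  expect_false(self$deviates)

  hc <- estimate_rdf(gen_hardcore_pattern(400, unit_window(100), 3, seed = 7), 0.5, 12)
  flat <- rep(1, length(hc$g_values))
  score <- rdf_r_squared(hc, flat)
  oracle <- 1 - sum((hc$g_values - flat)^2) /
    sum((hc$g_values - mean(hc$g_values))^2)
  expect_equal(score$r_squared, oracle)
  expect_identical(score$deviates, oracle < 0.9)

  const <- rdf_curve(g$r_centers, rep(2, length(g$r_centers)), 0.5, 12, 10, 0.1)
  expect_error(rdf_r_squared(const, g), "constant")
})

test_that("scores below the 0.9 boundary are flagged as deviating", {
  r <- seq(0.25, 9.75, by = 0.5)
  g_emp <- 1 + 0.5 * sin(r)
  # reference engineered so that R^2 is about 0.85
  sse_target <- 0.15 * sum((g_emp - mean(g_emp))^2)
  g_ref <- g_emp + sqrt(sse_target / length(r))
  score <- rdf_r_squared(rdf_curve(r, g_emp, 0.5, 10, 100, 0.1), g_ref)
  expect_equal(score$r_squared, 0.85, tolerance = 1e-9)
  expect_true(score$deviates)
})

test_that("RDF curves round-trip through CSV", {
  pp <- gen_poisson_pattern(300, unit_window(90), seed = 8)
  g <- estimate_rdf(pp, 0.5, 15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rdf_csv(g, path)
  g2 <- read_rdf_csv(path)
  expect_equal(g2$g_values, g$g_values)
  expect_equal(g2$r_centers, g$r_centers)
  expect_equal(g2$n_points, g$n_points)
})
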