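test_that("circular mean and resultant length match unit-vector arithmetic", {
  s <- circ_mean_resultant(rep(37, 10))
  expect_equal(s$R, 1)
  expect_equal(s$mu_deg, 37)

  anti <- circ_mean_resultant(c(0, 180))
  expect_equal(anti$R, 0, tolerance = 1e-12)
  expect_false(anti$mu_defined)
  expect_true(is.na(anti$mu_deg))

  q <- circ_mean_resultant(c(0, 90))
  expect_equal(q$R, sqrt(2) / 2)
  expect_equal(q$mu_deg, 45)

  expect_error(circ_mean_resultant(numeric(0)), "at least one")
})

test_that("R is in [0, 1] and equals 1 only for identical angles", {
  for (s in 1:20) {
    set.seed(s)
    ang <- runif(sample(2:30, 1), 0, 360)
    R <- circ_mean_resultant(ang)$R
    expect_gte(R, 0); expect_lte(R, 1)
    if (length(unique(ang %% 360)) > 1) expect_lt(R, 1)
  }
  expect_equal(circ_mean_resultant(c(10, 370, -350))$R, 1)
})

test_that("Watson U2 agrees with the brute-force rotation-scan oracle", {
  expect_equal(watson_u2(c(10, 50, 90, 200), c(10, 50, 90, 200)), 0)
  expect_error(watson_u2(numeric(0), c(1, 2, 3)), "non-empty")
  expect_error(watson_u2(c(1), c(2)), "at least 4")

  for (s in 1:15) {
    set.seed(s)
    a <- runif(5, 0, 360); b <- runif(5, 0, 360)
    expect_equal(watson_u2(a, b), watson_u2_bruteforce(a, b), tolerance = 1e-12)
    # rotation invariance and sample-order symmetry
    rot <- runif(1, 0, 360)
    expect_equal(watson_u2(a, b), watson_u2(a + rot, b + rot), tolerance = 1e-12)
    expect_equal(watson_u2(a, b), watson_u2(b, a), tolerance = 1e-12)
    expect_gte(watson_u2(a, b), 0)
  }
})

test_that("stratified permutation preserves per-eye group sizes and the p floor", {
  d <- make_two_group_angles(1)
  res <- stratified_permutation_test(d, "watson_u2", 10000, seed = 2)
  expect_gte(res$p_value, 1 / 10001)
  expect_lte(res$p_value, 1)

  # extreme separation attains exactly the floor (k = 0)
  sep <- make_two_group_angles(3, mu_a = 0, kappa_a = 400,
                               mu_b = 180, kappa_b = 400)
  res_sep <- stratified_permutation_test(sep, "watson_u2", 10000, seed = 4)
  expect_equal(res_sep$p_value, 1 / 10001)

  # reproducibility for a fixed seed
  expect_identical(stratified_permutation_test(d, "watson_u2", 500, seed = 9),
                   stratified_permutation_test(d, "watson_u2", 500, seed = 9))

  expect_error(
    stratified_permutation_test(d[d$genotype == "ctrl", ], "watson_u2", 99, 1),
    "two genotype")
  # eyes missing one label are excluded with a warning
  mixed <- rbind(d, data.frame(eye_id = "lonely", ommatidium_id = 1,
                               genotype = "ctrl", angle_deg = 10))
  expect_warning(stratified_permutation_test(mixed, "watson_u2", 99, 1),
                 "lonely")
})

test_that("permutation inference has nominal size under the null", {
  ps <- vapply(1:120, function(s) {
    stratified_permutation_test(make_two_group_angles(s), "watson_u2",
                                400, seed = 10^6 + s)$p_value
  }, 0)
  rej <- mean(ps <= 0.05)
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.10)
})

test_that("the U2 test detects a pure dispersion difference", {
  ps <- vapply(1:30, function(s) {
    d <- make_two_group_angles(s, kappa_a = 8, kappa_b = 0.5)
    stratified_permutation_test(d, "watson_u2", 499, seed = 10^5 + s)$p_value
  }, 0)
  expect_gt(mean(ps <= 0.05), 0.8)
})

test_that("resultant-length comparison behaves at identity and under concentration gaps", {
  a <- gen_orientation_dataset(6, 5, 20, 3, "ctrl", seed = 11)
  b <- a; b$genotype <- "mut"
  res <- compare_resultant_lengths(rbind(a, b), 999, seed = 12)
  expect_equal(res$observed_stat, 0)
  expect_equal(res$p_value, 1, tolerance = 1e-3)

  d <- make_two_group_angles(13, kappa_a = 20, kappa_b = 0.2)
  strong <- compare_resultant_lengths(d, 999, seed = 14)
  expect_gt(strong$observed_stat, 0.3)
  expect_lte(strong$p_value, 0.01)
  expect_equal(strong$statistic_kind, "resultant_diff")
})

test_that("ventral mirroring and pure-genotype filtering transform records as documented", {
  d <- data.frame(eye_id = "e1", ommatidium_id = 1:4, genotype = "g",
                  angle_deg = c(10, 350, 90, 0),
                  side = c("dorsal", "ventral", "ventral", "dorsal"),
                  pure = c(TRUE, TRUE, FALSE, FALSE))
  m <- mirror_ventral(d)
  expect_equal(m$angle_deg, c(10, 10, 270, 0))
  f <- filter_pure_genotype(d)
  expect_equal(nrow(f), 2)
  # without the optional columns both are the identity
  plain <- d[setdiff(names(d), c("side", "pure"))]
  expect_identical(mirror_ventral(plain), plain)
  expect_identical(filter_pure_genotype(plain), plain)
})
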