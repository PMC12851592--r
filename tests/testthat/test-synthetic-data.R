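test_that("generators are deterministic for a fixed seed", {
  w <- unit_window()
  expect_identical(gen_poisson_pattern(50, w, seed = 9),
                   gen_poisson_pattern(50, w, seed = 9))
  expect_identical(gen_hardcore_pattern(50, w, 2, seed = 9),
                   gen_hardcore_pattern(50, w, 2, seed = 9))
  expect_identical(gen_jittered_hex_lattice(3, 0.2, w, seed = 9),
                   gen_jittered_hex_lattice(3, 0.2, w, seed = 9))
  expect_identical(gen_orientation_dataset(3, 4, 10, 2, "g", seed = 9),
                   gen_orientation_dataset(3, 4, 10, 2, "g", seed = 9))
  expect_identical(gen_phototaxis_counts(35, 0.7, seed = 9),
                   gen_phototaxis_counts(35, 0.7, seed = 9))
  # seed does not leak into the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_poisson_pattern(10, w, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("binomial pattern respects count, window and the CSR spacing law", {
  w <- unit_window(100)
  expect_equal(npoints(gen_poisson_pattern(0, w, seed = 1)), 0)
  pp <- gen_poisson_pattern(1000, w, seed = 1)
  expect_equal(npoints(pp), 1000)
  expect_true(all(pp$x >= 0 & pp$x <= 100 & pp$y >= 0 & pp$y <= 100))
  expect_error(gen_poisson_pattern(-1, w, seed = 1), "integer")

  # mean nearest-neighbour distance for CSR is 0.5 / sqrt(rho)
  w2 <- unit_window(200)
  nn_means <- vapply(1:20, function(s) {
    p <- gen_poisson_pattern(2000, w2, seed = s)
    dm <- as.matrix(dist(cbind(p$x, p$y)))
    diag(dm) <- Inf
    mean(apply(dm, 1, min))
  }, 0)
  rho <- 2000 / 200^2
  expect_lt(abs(mean(nn_means) / (0.5 / sqrt(rho)) - 1), 0.05)
})

test_that("hard-core patterns respect the minimum separation and saturate honestly", {
  w <- unit_window(100)
  pp2 <- gen_hardcore_pattern(2, owindow(0, 20, 0, 20), 3, seed = 5)
  expect_gte(min(dist(cbind(pp2$x, pp2$y))), 3)
  for (s in 1:5) {
    pp <- gen_hardcore_pattern(500, w, 2, seed = s)
    expect_equal(npoints(pp), 500)
    expect_gte(min(dist(cbind(pp$x, pp$y))), 2)  # brute-force all-pairs
  }
  expect_error(gen_hardcore_pattern(10000, owindow(0, 10, 0, 10), 2, seed = 1),
               "infeasible|saturation")
  # saturation (not infeasibility) reports the achieved count
  expect_error(
    gen_hardcore_pattern(60, owindow(0, 20, 0, 20), 2, seed = 1,
                         max_attempts = 70),
    "placed only")
})

test_that("jittered hexagonal lattice has the expected order structure", {
  w <- unit_window(40)
  exact <- gen_jittered_hex_lattice(2, 0, w, seed = 1)
  d <- as.matrix(dist(cbind(exact$x, exact$y)))
  diag(d) <- Inf
  # interior points: all nearest-neighbour distances equal the spacing
  interior <- exact$x > 4 & exact$x < 36 & exact$y > 4 & exact$y < 36
  expect_equal(apply(d[interior, ], 1, min), rep(2, sum(interior)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(gen_jittered_hex_lattice(-1, 0.1, w, seed = 1), "positive")

  # small jitter: first RDF peak stays near the lattice spacing
  big <- gen_jittered_hex_lattice(2, 0.15, unit_window(80), seed = 2)
  g <- estimate_rdf(big, 0.1, 6)
  peak_r <- g$r_centers[which.max(g$g_values)]
  expect_gte(peak_r, 1.8)
  expect_lte(peak_r, 2.2)

  # huge jitter destroys the order: close to CSR away from the origin
  blur <- gen_jittered_hex_lattice(2, 10, unit_window(200), seed = 3)
  gb <- estimate_rdf(blur, 1, 25)
  expect_lt(mean(abs(gb$g_values[gb$r_centers > 2] - 1)), 0.1)
})

test_that("orientation generator matches von Mises expectations", {
  d <- gen_orientation_dataset(8, 5, 30, 4, "ctrl", seed = 1)
  expect_equal(nrow(d), 40)
  expect_false(anyDuplicated(d[c("eye_id", "ommatidium_id")]) > 0)
  expect_true(all(d$angle_deg >= 0 & d$angle_deg < 360))

  # degenerate concentration: near-perfect alignment
  tight <- gen_orientation_dataset(1, 50, 30, 1e6, "g", seed = 2)
  expect_gt(circ_mean_resultant(tight$angle_deg)$R, 0.999)

  # sampling distribution of the circular mean around mu
  mus <- vapply(1:20, function(s) {
    dd <- gen_orientation_dataset(8, 5, 30, 4, "g", seed = s)
    circ_mean_resultant(dd$angle_deg)$mu_deg
  }, 0)
  expect_true(all(abs((mus - 30 + 180) %% 360 - 180) < 15))

  # circular uniform: E[R] ~ sqrt(pi)/(2 sqrt(n))
  unif <- gen_orientation_dataset(1, 10000, 0, 0, "g", seed = 3)
  expect_lt(circ_mean_resultant(unif$angle_deg)$R, 0.03)
})

test_that("hexagon generator matches closed-form geometry", {
  hex <- gen_hexagon_polygon(1, 0, seed = 1)
  desc <- polygon_descriptors(hex)
  expect_equal(desc$area, 3 * sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(desc$perimeter, 6, tolerance = 1e-12)
  expect_equal(desc$circularity, pi * sqrt(3) / 6, tolerance = 1e-12)

  # expected circularity decreases as vertex noise grows
  mean_circ <- function(sd_noise) {
    mean(vapply(1:40, function(s) {
      polygon_descriptors(gen_hexagon_polygon(1, sd_noise, seed = 1000 * sd_noise + s))$circularity
    }, 0))
  }
  cs <- vapply(c(0.02, 0.06, 0.12), mean_circ, 0)
  expect_true(all(diff(cs) < 0))
})

test_that("phototaxis simulator follows the three-trial binomial law", {
  expect_equal(gen_phototaxis_counts(35, 1, seed = 1)$tube_counts,
               c(0L, 0L, 0L, 35L))
  expect_equal(gen_phototaxis_counts(35, 0, seed = 1)$tube_counts,
               c(35L, 0L, 0L, 0L))
  # tube-k fractions converge to C(3,k) p^k (1-p)^(3-k)
  p <- 0.6
  counts <- Reduce(`+`, lapply(1:400, function(s) {
    gen_phototaxis_counts(35, p, seed = s)$tube_counts
  }))
  frac <- counts / sum(counts)
  expect_equal(frac, dbinom(0:3, 3, p), tolerance = 0.03, ignore_attr = TRUE)
})
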