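# Shared fixtures for the test suite. Everything is generated in code.

unit_window <- function(size = 100) owindow(0, size, 0, size)

# Two-genotype nested orientation dataset; both groups share the same eyes
# (mosaic design). Distinct sub-seeds keep the groups independent.
make_two_group_angles <- function(seed, n_eyes = 8, n_per_eye = 5,
                                  mu_a = 30, kappa_a = 2,
                                  mu_b = 30, kappa_b = 2) {
  a <- gen_orientation_dataset(n_eyes, n_per_eye, mu_a, kappa_a, "ctrl",
                               seed = 2L * seed)
  b <- gen_orientation_dataset(n_eyes, n_per_eye, mu_b, kappa_b, "mut",
                               seed = 2L * seed + 1L)
  b$eye_id <- a$eye_id
  rbind(a, b)
}

# Noise-free curve sampled from the hard-core disk model on a fine grid.
model_curve <- function(params, bin_width = 0.1, r_max = 10,
                        n_points = 500, density = 0.05) {
  r <- seq(bin_width / 2, r_max - bin_width / 2, by = bin_width)
  rdf_curve(r, pmax(model_rdf(r, params), 0), bin_width, r_max,
            n_points, density)
}

rel_err <- function(est, truth) abs(est / truth - 1)

fit_param_vec <- function(fit) {
  c(d = fit$params$d, A = fit$params$A,
    lambda = fit$params$lambda, P = fit$params$P)
}

# Independent brute-force two-sample Watson U^2: evaluates the ECDF
# difference sequence for every possible starting rotation of the combined
# circular sample and takes the minimizing value. Used as an oracle for the
# closed-form implementation.
watson_u2_bruteforce <- function(a, b) {
  a <- a %% 360; b <- b %% 360
  n <- length(a); m <- length(b); N <- n + m
  vals <- c(a, b)
  memb <- c(rep(TRUE, n), rep(FALSE, m))
  best <- Inf
  for (start in seq_len(N)) {
    ord <- order((vals - vals[start] - 1e-9) %% 360)
    mm <- memb[ord]
    dk <- cumsum(mm) / n - cumsum(!mm) / m
    stat <- (n * m / N^2) * sum((dk - mean(dk))^2)
    best <- min(best, stat)
  }
  best
}
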