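#' Draw von Mises random angles
#'
#' Best–Fisher rejection sampler for the von Mises distribution, the circular
#' analogue of the normal and the standard model for concentrated directional
#' data such as ommatidial orientations. `kappa = 0` reduces to the
#' circular-uniform distribution.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction in degrees.
#' @param kappa Concentration parameter (>= 0).
#' @param seed Integer seed.
#' @return Angles in degrees, normalized to `[0, 360)`.
#' @export
rvonmises_deg <- function(n, mu_deg, kappa, seed) {
  n <- check_count(n, "n")
  kappa <- check_positive(kappa, "kappa", strict = FALSE)
  mu <- mu_deg * pi / 180
  with_seed(seed, {
    if (kappa == 0) {
      theta <- stats::runif(n, 0, 2 * pi)
    } else {
      a <- 1 + sqrt(1 + 4 * kappa^2)
      b <- (a - sqrt(2 * a)) / (2 * kappa)
      r <- (1 + b^2) / (2 * b)
      theta <- numeric(n)
      i <- 1L
      while (i <= n) {
        u <- stats::runif(3)
        z <- cos(pi * u[1])
        f <- (1 + r * z) / (r + z)
        cc <- kappa * (r - f)
        if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
          theta[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f))) + mu
          i <- i + 1L
        }
      }
    }
    (theta * 180 / pi) %% 360
  })
}

#' Generate a nested ommatidial-orientation dataset
#'
#' Simulates the sampling design of an orientation experiment: several eyes
#' (biological replicates), each contributing several ommatidia whose angles
#' relative to the eye equator are von Mises-distributed around a common mean
#' direction. One stratum per eye, as required by the stratified permutation
#' tests downstream.
#'
#' @param n_eyes Number of eyes (>= 1).
#' @param n_per_eye Ommatidia measured per eye (>= 1).
#' @param mu_deg Mean direction, degrees.
#' @param kappa von Mises concentration (0 = circular uniform).
#' @param genotype Genotype label applied to all records.
#' @param seed Integer seed.
#' @param eye_prefix Prefix for generated eye identifiers.
#' @return A data frame with columns `eye_id`, `ommatidium_id`, `genotype`,
#'   `angle_deg` (degrees in `[0, 360)`); each `(eye_id, ommatidium_id)` pair
#'   is unique.
#' @examples
#' d <- gen_orientation_dataset(8, 5, mu_deg = 30, kappa = 4,
#'                              genotype = "control", seed = 11)
#' @export
gen_orientation_dataset <- function(n_eyes, n_per_eye, mu_deg, kappa,
                                    genotype, seed, eye_prefix = "eye") {
  n_eyes <- check_count(n_eyes, "n_eyes", min = 1L)
  n_per_eye <- check_count(n_per_eye, "n_per_eye", min = 1L)
  angles <- rvonmises_deg(n_eyes * n_per_eye, mu_deg, kappa, seed)
  data.frame(
    eye_id = rep(paste0(eye_prefix, seq_len(n_eyes)), each = n_per_eye),
    ommatidium_id = rep(seq_len(n_per_eye), times = n_eyes),
    genotype = as.character(genotype),
    angle_deg = angles,
    stringsAsFactors = FALSE
  )
}

#' Generate a noisy hexagonal polygon
#'
#' Six vertices of a regular hexagon (circumradius = `side`), each displaced
#' by isotropic Gaussian noise: a synthetic stand-in for a traced corneal
#' outline. Vertices are returned in counter-clockwise order; the polygon is
#' implicitly closed (the first vertex is not repeated).
#'
#' @param side Side length of the regular hexagon, micrometres (equals the
#'   circumradius).
#' @param vertex_noise_sd Gaussian noise SD applied independently to each
#'   vertex coordinate, micrometres.
#' @param seed Integer seed.
#' @return A 6 x 2 numeric matrix with columns `x`, `y`.
#' @examples
#' hex <- gen_hexagon_polygon(1, 0, seed = 1)
#' polygon_descriptors(hex)$circularity  # pi*sqrt(3)/6
#' @export
gen_hexagon_polygon <- function(side, vertex_noise_sd, seed) {
  side <- check_positive(side, "side")
  vertex_noise_sd <- check_positive(vertex_noise_sd, "vertex_noise_sd", strict = FALSE)
  ang <- (0:5) * pi / 3
  vx <- side * cos(ang)
  vy <- side * sin(ang)
  with_seed(seed, {
    vx <- vx + stats::rnorm(6, 0, vertex_noise_sd)
    vy <- vy + stats::rnorm(6, 0, vertex_noise_sd)
  })
  cbind(x = vx, y = vy)
}

#' Simulate a three-trial countercurrent phototaxis assay
#'
#' Each fly independently passes each of the three light trials with
#' probability `p_trial`; its final tube is its number of successes (0..3).
#' This independence model is a test fixture for the scorer, not a
#' behavioral claim.
#'
#' @param n_flies Number of flies in the assay (>= 1).
#' @param p_trial Per-trial success probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param assay_id,genotype,sex Metadata labels.
#' @return A [phototaxis_assay()] whose tube counts sum to `n_flies`.
#' @examples
#' a <- gen_phototaxis_counts(35, 0.794, seed = 5)
#' score_assay(a)
#' @export
gen_phototaxis_counts <- function(n_flies, p_trial, seed, assay_id = "assay1",
                                  genotype = "control", sex = "mixed") {
  n_flies <- check_count(n_flies, "n_flies", min = 1L)
  if (!is.numeric(p_trial) || length(p_trial) != 1L || p_trial < 0 || p_trial > 1) {
    stop("`p_trial` must be a probability in [0, 1]", call. = FALSE)
  }
  counts <- with_seed(seed, {
    successes <- stats::rbinom(n_flies, size = 3L, prob = p_trial)
    tabulate(successes + 1L, nbins = 4L)
  })
  phototaxis_assay(assay_id = assay_id, genotype = genotype, sex = sex,
                   tube_counts = counts)
}
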