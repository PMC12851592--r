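#' Generate a binomial (CSR) point pattern
#'
#' Places exactly `n` points uniformly and independently inside the window:
#' the complete-spatial-randomness reference against which ordered
#' corneal-nipple arrays are compared (its pair correlation is g(r) = 1).
#'
#' @param n Number of points (>= 0).
#' @param window An [owindow()].
#' @param seed Integer seed; output is reproducible bit-for-bit.
#' @param eye_id,genotype Metadata labels attached to the pattern.
#' @return A [point_pattern()] with exactly `n` points.
#' @examples
#' pp <- gen_poisson_pattern(100, owindow(0, 50, 0, 50), seed = 1)
#' @export
gen_poisson_pattern <- function(n, window, seed, eye_id = "sim", genotype = "csr") {
  n <- check_count(n, "n")
  stopifnot(inherits(window, "owindow"))
  with_seed(seed, {
    x <- stats::runif(n, window$x_min, window$x_max)
    y <- stats::runif(n, window$y_min, window$y_max)
    point_pattern(x, y, window, eye_id = eye_id, genotype = genotype)
  })
}

#' Generate a hard-core point pattern by random sequential adsorption
#'
#' Sequentially proposes uniform points and rejects any proposal closer than
#' `d_min` to an already-accepted point. This is the density-matched null
#' model for nipple arrays: random placement constrained by a minimum
#' separation equal to the average nipple diameter.
#'
#' A cell-grid neighbour search keeps acceptance checks O(1), so patterns of
#' thousands of points are generated quickly. If `n` points cannot be placed
#' within `max_attempts` proposals (packing saturation) an error is raised
#' that reports the achieved count.
#'
#' @param n Number of points to place.
#' @param window An [owindow()].
#' @param d_min Minimum pairwise separation in micrometres (> 0).
#' @param seed Integer seed.
#' @param max_attempts Proposal budget before declaring saturation.
#' @param eye_id,genotype Metadata labels.
#' @return A [point_pattern()] whose pairwise distances are all >= `d_min`.
#' @examples
#' pp <- gen_hardcore_pattern(200, owindow(0, 100, 0, 100), d_min = 3, seed = 7)
#' min(dist(cbind(pp$x, pp$y))) >= 3
#' @export
gen_hardcore_pattern <- function(n, window, d_min, seed,
                                 max_attempts = 200L * max(n, 1L) + 10000L,
                                 eye_id = "sim", genotype = "hardcore") {
  n <- check_count(n, "n")
  d_min <- check_positive(d_min, "d_min")
  max_attempts <- check_count(max_attempts, "max_attempts", min = 1L)
  stopifnot(inherits(window, "owindow"))
  disk_area <- n * pi * (d_min / 2)^2
  if (disk_area >= 0.5 * window_area(window)) {
    stop(sprintf(paste0("requested packing infeasible: %d disks of diameter %g ",
                        "cover >= 50%% of the window"), n, d_min), call. = FALSE)
  }
  if (n == 0L) {
    return(point_pattern(numeric(0), numeric(0), window,
                         eye_id = eye_id, genotype = genotype))
  }
  wx <- window$x_max - window$x_min
  wy <- window$y_max - window$y_min
  # Grid of cells with side d_min: conflicts can only involve the 3x3 block
  # of cells around a proposal.
  # cell side >= d_min keeps the 3x3 neighbourhood sufficient; cap the grid
  # so a tiny d_min cannot request an absurd number of cells
  ncx <- max(1L, min(512L, as.integer(floor(wx / d_min))))
  ncy <- max(1L, min(512L, as.integer(floor(wy / d_min))))
  with_seed(seed, {
    xs <- numeric(n); ys <- numeric(n)
    cells <- vector("list", ncx * ncy)
    accepted <- 0L
    attempts <- 0L
    d2 <- d_min^2
    while (accepted < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      px <- stats::runif(1, window$x_min, window$x_max)
      py <- stats::runif(1, window$y_min, window$y_max)
      cx <- pmin(ncx, 1L + as.integer(floor((px - window$x_min) / wx * ncx)))
      cy <- pmin(ncy, 1L + as.integer(floor((py - window$y_min) / wy * ncy)))
      neigh <- integer(0)
      for (ix in max(1L, cx - 1L):min(ncx, cx + 1L)) {
        for (iy in max(1L, cy - 1L):min(ncy, cy + 1L)) {
          neigh <- c(neigh, cells[[(iy - 1L) * ncx + ix]])
        }
      }
      if (length(neigh) == 0L ||
          all((xs[neigh] - px)^2 + (ys[neigh] - py)^2 >= d2)) {
        accepted <- accepted + 1L
        xs[accepted] <- px
        ys[accepted] <- py
        id <- (cy - 1L) * ncx + cx
        cells[[id]] <- c(cells[[id]], accepted)
      }
    }
    if (accepted < n) {
      stop(sprintf(paste0("hard-core saturation: placed only %d of %d points ",
                          "in %d attempts (d_min = %g)"),
                   accepted, n, attempts, d_min), call. = FALSE)
    }
    point_pattern(xs, ys, window, eye_id = eye_id, genotype = genotype)
  })
}

#' Generate a jittered hexagonal lattice pattern
#'
#' Emulates the wild-type corneal-nipple array: a pseudo-ordered pattern with
#' short-range hexagonal order. Lattice points at the given spacing are
#' displaced by isotropic Gaussian jitter; points that land outside the
#' window are discarded (the pattern is a cropped field, not a torus).
#'
#' @param spacing Lattice constant (nearest-neighbour distance) in
#'   micrometres; sets the location of the first pair-correlation peak.
#' @param jitter_sd Standard deviation of the Gaussian displacement per axis,
#'   micrometres. `0` gives the exact lattice; values much larger than
#'   `spacing` destroy the order entirely.
#' @param window An [owindow()].
#' @param seed Integer seed.
#' @param eye_id,genotype Metadata labels.
#' @return A [point_pattern()].
#' @examples
#' pp <- gen_jittered_hex_lattice(2, 0.15, owindow(0, 40, 0, 40), seed = 3)
#' @export
gen_jittered_hex_lattice <- function(spacing, jitter_sd, window, seed,
                                     eye_id = "sim", genotype = "hex") {
  spacing <- check_positive(spacing, "spacing")
  jitter_sd <- check_positive(jitter_sd, "jitter_sd", strict = FALSE)
  stopifnot(inherits(window, "owindow"))
  row_h <- spacing * sqrt(3) / 2
  # Overfill by one lattice unit so jittered border points can fall back in.
  rows <- seq(window$y_min - row_h, window$y_max + row_h, by = row_h)
  pts_x <- numeric(0); pts_y <- numeric(0)
  for (i in seq_along(rows)) {
    offset <- if (i %% 2 == 0) spacing / 2 else 0
    cols <- seq(window$x_min - spacing + offset, window$x_max + spacing, by = spacing)
    pts_x <- c(pts_x, cols)
    pts_y <- c(pts_y, rep(rows[i], length(cols)))
  }
  with_seed(seed, {
    x <- pts_x + stats::rnorm(length(pts_x), 0, jitter_sd)
    y <- pts_y + stats::rnorm(length(pts_y), 0, jitter_sd)
    keep <- x >= window$x_min & x <= window$x_max &
      y >= window$y_min & y <= window$y_max
    point_pattern(x[keep], y[keep], window, eye_id = eye_id, genotype = genotype)
  })
}
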