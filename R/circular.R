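#' Circular mean direction and mean resultant length
#'
#' Converts angles to unit vectors and averages them. The mean resultant
#' length R is the norm of the vector mean: 0 for maximally dispersed data,
#' 1 for perfect alignment. The circular mean direction mu is the direction
#' of the vector mean; when R = 0 the mean direction is undefined and
#' returned as `NA` with `mu_defined = FALSE`.
#'
#' @param angles_deg Angles in degrees (any real values; reduced mod 360).
#' @return A list of class `"circular_summary"`: `mu_deg` in `[0, 360)` (or
#'   `NA`), `R` in `[0, 1]`, `n`, `mu_defined`.
#' @examples
#' circ_mean_resultant(c(0, 90))  # R = sqrt(2)/2, mu = 45
#' @export
circ_mean_resultant <- function(angles_deg) {
  if (length(angles_deg) < 1L) stop("need at least one angle", call. = FALSE)
  if (!is.numeric(angles_deg) || any(!is.finite(angles_deg))) {
    stop("angles must be finite numbers (degrees)", call. = FALSE)
  }
  th <- angles_deg * pi / 180
  cbar <- mean(cos(th)); sbar <- mean(sin(th))
  R <- min(1, sqrt(cbar^2 + sbar^2))
  defined <- R > .Machine$double.eps^0.5
  mu <- if (defined) (atan2(sbar, cbar) * 180 / pi) %% 360 else NA_real_
  structure(list(mu_deg = mu, R = R, n = length(angles_deg),
                 mu_defined = defined),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("circular summary (n = %d): mu = %s deg, R = %.4f\n",
              x$n, if (x$mu_defined) sprintf("%.2f", x$mu_deg) else "undefined",
              x$R))
  invisible(x)
}

# Watson U^2 from pooled group membership in circular sorted order.
# is_a: logical, TRUE where the pooled sorted observation belongs to sample a.
# Valid for tie-free data; the public watson_u2() weights tied values.
watson_u2_sorted <- function(is_a) {
  n <- sum(is_a); m <- sum(!is_a); N <- n + m
  dk <- cumsum(is_a) / n - cumsum(!is_a) / m
  (n * m / N^2) * sum((dk - mean(dk))^2)
}

#' Watson's U-squared two-sample statistic for circular data
#'
#' Compares the empirical cumulative distribution functions of two circular
#' samples by their integrated squared deviation: over the combined
#' circularly ordered sample, with \eqn{d_k} the ECDF difference after the
#' k-th point,
#' \deqn{U^2 = \frac{nm}{N^2} \sum_k t_k (d_k - \bar d)^2,}
#' where \eqn{t_k} is the multiplicity of the k-th distinct value. The
#' mean-centering makes the statistic invariant to the (arbitrary) cut point
#' of the circle and hence to any common rotation of both samples. The test
#' assumes neither equal dispersion nor a common shape, so it is sensitive
#' to differences in both location and scale.
#'
#' @param sample_a,sample_b Angle vectors in degrees, both non-empty,
#'   combined length >= 4.
#' @return The U-squared statistic (a single non-negative number).
#' @examples
#' watson_u2(c(10, 20, 30, 350), c(100, 140, 180, 220))
#' @export
watson_u2 <- function(sample_a, sample_b) {
  if (length(sample_a) < 1L || length(sample_b) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  a <- as.numeric(sample_a) %% 360
  b <- as.numeric(sample_b) %% 360
  n <- length(a); m <- length(b); N <- n + m
  if (N < 4L) stop("combined sample size must be at least 4", call. = FALSE)
  vals <- c(a, b)
  memb <- c(rep(TRUE, n), rep(FALSE, m))
  ord <- order(vals)
  vals <- vals[ord]; memb <- memb[ord]
  # collapse ties: d_k is evaluated after each distinct value, weighted by
  # its multiplicity
  grp <- cumsum(c(TRUE, diff(vals) > 0))
  ca <- cumsum(memb); cb <- cumsum(!memb)
  last <- which(c(diff(grp) > 0, TRUE))
  tk <- diff(c(0L, last))
  dk <- ca[last] / n - cb[last] / m
  dbar <- sum(tk * dk) / N
  (n * m / N^2) * sum(tk * (dk - dbar)^2)
}

# resultant-length-difference statistic |R_a - R_b| on pooled per-group angles
resultant_diff_stat <- function(cos_th, sin_th, is_a) {
  n <- sum(is_a); m <- length(is_a) - n
  Ra <- sqrt(sum(cos_th[is_a])^2 + sum(sin_th[is_a])^2) / n
  Rb <- sqrt(sum(cos_th[!is_a])^2 + sum(sin_th[!is_a])^2) / m
  abs(Ra - Rb)
}

validate_orientation_df <- function(data) {
  need <- c("eye_id", "genotype", "angle_deg")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop("orientation data must be a data frame with columns eye_id, genotype, angle_deg",
         call. = FALSE)
  }
  data
}

#' Stratified permutation test for two-genotype orientation data
#'
#' Tests whether the orientation distributions of two genotypes differ while
#' respecting the nested sampling design (several ommatidia per eye):
#' genotype labels are shuffled only *within* each eye, so every permutation
#' preserves the per-eye group sizes and the between-eye structure of the
#' data. Two statistics are available: Watson's U-squared
#' (`"watson_u2"`, sensitive to location and scale) and the absolute
#' difference of mean resultant lengths (`"resultant_diff"`, targeted at
#' dispersion).
#'
#' The p-value uses the small-sample correction \eqn{(k + 1)/(n + 1)} with
#' k the number of permuted statistics greater than or equal to the observed
#' one (ties counted as extreme), so the smallest attainable p is
#' `1/(n_permutations + 1)`.
#'
#' Eyes that do not contain at least one record of each genotype cannot be
#' permuted and are excluded with a warning.
#'
#' @param data Data frame with columns `eye_id`, `genotype`, `angle_deg`
#'   (see [gen_orientation_dataset()]); exactly two genotype labels.
#' @param statistic_kind `"watson_u2"` or `"resultant_diff"`.
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Integer seed; results are reproducible.
#' @return A list of class `"permutation_result"`: `observed_stat`,
#'   `p_value`, `n_permutations`, `statistic_kind`, `per_group` (named list
#'   of [circ_mean_resultant()] summaries), `n_eyes_used`.
#' @examples
#' a <- gen_orientation_dataset(4, 5, 30, 4, "control", seed = 1)
#' b <- gen_orientation_dataset(4, 5, 30, 4, "mutant", seed = 2)
#' b$eye_id <- a$eye_id  # same eyes carry both genotypes (mosaic clones)
#' stratified_permutation_test(rbind(a, b), "watson_u2", 999, seed = 3)
#' @export
stratified_permutation_test <- function(data,
                                        statistic_kind = c("watson_u2", "resultant_diff"),
                                        n_permutations, seed) {
  statistic_kind <- match.arg(statistic_kind)
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1L)
  data <- validate_orientation_df(data)
  labs <- sort(unique(data$genotype))
  if (length(labs) != 2L) {
    stop("exactly two genotype labels are required (got ",
         length(labs), ")", call. = FALSE)
  }
  # drop eyes lacking one of the labels: they cannot contribute permutations
  both <- vapply(split(data$genotype, data$eye_id),
                 function(g) all(labs %in% g), TRUE)
  bad <- names(both)[!both]
  if (length(bad)) {
    warning("excluding eyes without both genotypes: ",
            paste(bad, collapse = ", "), call. = FALSE)
    data <- data[!(data$eye_id %in% bad), , drop = FALSE]
  }
  if (nrow(data) == 0L) stop("no eyes with both genotypes remain", call. = FALSE)
  ang <- data$angle_deg %% 360
  is_a <- data$genotype == labs[1]
  eye_idx <- split(seq_along(ang), data$eye_id)
  th <- ang * pi / 180
  cos_th <- cos(th); sin_th <- sin(th)
  if (statistic_kind == "watson_u2") {
    ord <- order(ang)
    stat_fun <- function(memb) watson_u2_sorted(memb[ord])
  } else {
    stat_fun <- function(memb) resultant_diff_stat(cos_th, sin_th, memb)
  }
  observed <- stat_fun(is_a)
  k <- 0L
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      perm <- is_a
      for (ix in eye_idx) {
        perm[ix] <- perm[ix][sample.int(length(ix))]
      }
      if (stat_fun(perm) >= observed) k <- k + 1L
    }
  })
  per_group <- list(circ_mean_resultant(ang[is_a]),
                    circ_mean_resultant(ang[!is_a]))
  names(per_group) <- labs
  structure(list(observed_stat = observed,
                 p_value = (k + 1) / (n_permutations + 1),
                 n_permutations = n_permutations,
                 statistic_kind = statistic_kind,
                 per_group = per_group,
                 n_eyes_used = length(eye_idx)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("stratified permutation test (%s): stat = %.5g, p = %.5g (%d permutations, %d eyes)\n",
              x$statistic_kind, x$observed_stat, x$p_value,
              x$n_permutations, x$n_eyes_used))
  invisible(x)
}

#' Compare concentrations via resultant-length difference
#'
#' Convenience wrapper around [stratified_permutation_test()] with the
#' `"resultant_diff"` statistic: tests whether the two genotypes differ in
#' angular concentration (|R_A - R_B| on pooled per-group angles) under the
#' same within-eye permutation null and (k+1)/(n+1) correction.
#'
#' @inheritParams stratified_permutation_test
#' @return A `"permutation_result"`; see [stratified_permutation_test()].
#' @export
compare_resultant_lengths <- function(data, n_permutations, seed) {
  stratified_permutation_test(data, "resultant_diff", n_permutations, seed)
}

#' Mirror ventral-eye angles into the dorsal frame
#'
#' Ommatidia rotate in opposite senses on the dorsal and ventral sides of
#' the eye equator, so ventral angles must be reflected (`360 - angle`)
#' before pooling with dorsal ones. Records are mirrored where the optional
#' `side` column equals `"ventral"`; data without a `side` column are
#' returned unchanged.
#'
#' @param data Orientation data frame, optionally with a `side` column
#'   (`"dorsal"`/`"ventral"`).
#' @return The data frame with ventral angles reflected into `[0, 360)`.
#' @export
mirror_ventral <- function(data) {
  data <- validate_orientation_df(data)
  if (!"side" %in% names(data)) return(data)
  v <- data$side == "ventral"
  data$angle_deg[v] <- (360 - data$angle_deg[v]) %% 360
  data
}

#' Keep only ommatidia of a single (pure) genotype
#'
#' In mosaic eyes, ommatidia whose external photoreceptors are of mixed
#' genotype are ambiguous and excluded from orientation analysis. Records
#' carrying an optional logical `pure` column are filtered to `pure == TRUE`;
#' data without the column pass through unchanged.
#'
#' @param data Orientation data frame, optionally with a logical `pure`
#'   column.
#' @return The filtered data frame.
#' @export
filter_pure_genotype <- function(data) {
  data <- validate_orientation_df(data)
  if (!"pure" %in% names(data)) return(data)
  data[as.logical(data$pure), , drop = FALSE]
}
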