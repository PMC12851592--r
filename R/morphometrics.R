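#' Shape descriptors of a simple polygon
#'
#' Computes the standard morphometric descriptors of a traced outline
#' (cornea, nipple): area by the shoelace formula, perimeter as the closed
#' vertex-chain length, circularity \eqn{4\pi A / P^2} (1 for a circle,
#' \eqn{\pi\sqrt 3/6 \approx 0.907} for a regular hexagon), and equivalent
#' diameter \eqn{2\sqrt{A/\pi}} (diameter of the circle of equal area).
#' Circularity is scale invariant.
#'
#' @param vertices An n x 2 numeric matrix (or data frame / list of `[x, y]`
#'   pairs) of polygon vertices in order, n >= 3, not self-intersecting; the
#'   polygon is closed implicitly.
#' @return A list with `area` (square micrometres), `perimeter`
#'   (micrometres), `circularity`, `equivalent_diameter` (micrometres).
#' @examples
#' hex <- gen_hexagon_polygon(1, 0, seed = 1)
#' polygon_descriptors(hex)
#' @export
polygon_descriptors <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  if (n < 3L) stop("a polygon needs at least 3 vertices", call. = FALSE)
  if (polygon_self_intersects(v)) {
    stop("polygon is self-intersecting", call. = FALSE)
  }
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  if (area <= 0) stop("degenerate polygon (zero area)", call. = FALSE)
  perimeter <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  list(area = area,
       perimeter = perimeter,
       circularity = 4 * pi * area / perimeter^2,
       equivalent_diameter = 2 * sqrt(area / pi))
}

as_vertex_matrix <- function(vertices) {
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices)
  if (is.list(vertices) && !is.matrix(vertices)) {
    vertices <- do.call(rbind, lapply(vertices, as.numeric))
  }
  if (!is.matrix(vertices) || ncol(vertices) != 2 || !is.numeric(vertices)) {
    stop("vertices must be an n x 2 numeric matrix", call. = FALSE)
  }
  # drop a repeated closing vertex if present
  n <- nrow(vertices)
  if (n > 1 && all(vertices[1, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  vertices
}

# proper-crossing test between non-adjacent edges; O(n^2), fine for outlines
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]))
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent around the wrap
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Pixel-to-micrometre calibration from fiduciary microspheres
#'
#' Builds a length scale from fiduciary beads of known physical diameter
#' imaged alongside the specimen: `scale = nominal / measured` micrometres
#' per pixel. With several beads in a frame the per-bead scales are
#' averaged.
#'
#' @param nominal_diameter_um Known bead diameter(s), micrometres (> 0).
#' @param measured_diameter_px Measured bead diameter(s) in pixels (> 0),
#'   same length as `nominal_diameter_um`.
#' @return An object of class `"calibration"` with `scale` (micrometres per
#'   pixel), the per-bead inputs, and `n_beads`.
#' @examples
#' cal <- calibration(4, 40)
#' calibrate_lengths(120, cal)  # 12 um
#' @export
calibration <- function(nominal_diameter_um, measured_diameter_px) {
  nom <- as.numeric(nominal_diameter_um)
  mea <- as.numeric(measured_diameter_px)
  if (length(nom) != length(mea) || length(nom) < 1L) {
    stop("nominal and measured diameters must be non-empty and equal length",
         call. = FALSE)
  }
  if (any(nom <= 0) || any(mea <= 0)) {
    stop("calibration diameters must be positive", call. = FALSE)
  }
  structure(list(nominal_diameter_um = nom, measured_diameter_px = mea,
                 scale = mean(nom / mea), n_beads = length(nom)),
            class = "calibration")
}

#' @rdname calibration
#' @param measurements_px Pixel lengths to convert (> 0).
#' @param cal A `"calibration"` object.
#' @return `calibrate_lengths` returns the measurements in micrometres with
#'   the calibration attached as attribute `"calibration"`.
#' @export
calibrate_lengths <- function(measurements_px, cal) {
  stopifnot(inherits(cal, "calibration"))
  m <- as.numeric(measurements_px)
  if (length(m) < 1L || any(!is.finite(m)) || any(m <= 0)) {
    stop("measurements must be positive finite pixel lengths", call. = FALSE)
  }
  out <- m * cal$scale
  attr(out, "calibration") <- cal
  out
}

bristle_classes <- c("normal", "paintbrush", "duplicated", "triplicated",
                     "quadruplicated")

#' Tally interommatidial bristle phenotypes
#'
#' Counts bristles per eye and pooled across eyes by phenotypic class
#' (`normal`, `paintbrush`, `duplicated`, `triplicated`, `quadruplicated`).
#' The headline summary is the high-order fraction: the percentage of
#' multiple bristles (duplicated or more) that are triplicated or
#' quadruplicated. With no multiple bristles the fraction has an empty
#' denominator and is reported as `NA` (absent), never as 0.
#'
#' @param records Data frame with columns `eye_id` and `class` (values from
#'   the fixed vocabulary above); one row per bristle.
#' @return A list of class `"bristle_tally"`: `per_eye` (data frame of
#'   per-class counts plus `multiple_fraction`, the per-eye share of
#'   bristles that are duplicated or more), `pooled` (named class counts),
#'   `high_order_fraction_pct` ((triplicated + quadruplicated) /
#'   (duplicated + triplicated + quadruplicated) * 100, or `NA`).
#' @examples
#' df <- data.frame(eye_id = "e1",
#'                  class = c(rep("duplicated", 97), rep("triplicated", 3)))
#' tally_bristles(df)$high_order_fraction_pct  # 3
#' @export
tally_bristles <- function(records) {
  if (!is.data.frame(records) || !all(c("eye_id", "class") %in% names(records))) {
    stop("records must be a data frame with columns eye_id and class", call. = FALSE)
  }
  bad <- setdiff(unique(records$class), bristle_classes)
  if (length(bad)) {
    stop("unknown bristle class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cls <- factor(records$class, levels = bristle_classes)
  tab <- table(eye_id = records$eye_id, class = cls)
  per_eye <- as.data.frame.matrix(tab)
  per_eye$eye_id <- rownames(per_eye)
  rownames(per_eye) <- NULL
  per_eye <- per_eye[, c("eye_id", bristle_classes)]
  multi <- per_eye$duplicated + per_eye$triplicated + per_eye$quadruplicated
  total <- rowSums(per_eye[, bristle_classes])
  per_eye$multiple_fraction <- ifelse(total > 0, multi / total, NA_real_)
  pooled <- colSums(per_eye[, bristle_classes])
  denom <- pooled[["duplicated"]] + pooled[["triplicated"]] + pooled[["quadruplicated"]]
  high <- if (denom > 0) {
    100 * (pooled[["triplicated"]] + pooled[["quadruplicated"]]) / denom
  } else {
    NA_real_
  }
  structure(list(per_eye = per_eye, pooled = pooled,
                 high_order_fraction_pct = high),
            class = "bristle_tally")
}

#' Two-sample Kolmogorov–Smirnov comparison of size distributions
#'
#' Non-parametric test of equality of two continuous distributions (e.g.
#' ommatidial or nipple size distributions): the statistic is the maximum
#' absolute difference between the two empirical CDFs. The exact p-value is
#' used for combined samples of 50 or fewer observations (the study's
#' per-eye samples are small), the asymptotic one otherwise.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return A list with `statistic` (D) and `p_value`.
#' @export
compare_distributions_ks <- function(values_a, values_b) {
  if (length(values_a) < 1L || length(values_b) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  exact <- (length(values_a) + length(values_b)) <= 50
  kt <- suppressWarnings(
    stats::ks.test(values_a, values_b, alternative = "two.sided", exact = exact)
  )
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
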