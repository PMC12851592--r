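#' Rectangular observation window
#'
#' The region (in micrometres) within which a point pattern was observed,
#' corresponding to the field of view of a high-power SEM image.
#'
#' @param x_min,x_max,y_min,y_max Window bounds in micrometres; `x_max > x_min`
#'   and `y_max > y_min` are required.
#' @return An object of class `"owindow"` with fields `x_min`, `x_max`,
#'   `y_min`, `y_max`.
#' @examples
#' w <- owindow(0, 100, 0, 100)
#' window_area(w)
#' @export
owindow <- function(x_min, x_max, y_min, y_max) {
  for (v in list(x_min, x_max, y_min, y_max)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("window bounds must be single finite numbers", call. = FALSE)
    }
  }
  if (x_max <= x_min || y_max <= y_min) {
    stop("window must satisfy x_max > x_min and y_max > y_min", call. = FALSE)
  }
  structure(list(x_min = as.numeric(x_min), x_max = as.numeric(x_max),
                 y_min = as.numeric(y_min), y_max = as.numeric(y_max)),
            class = "owindow")
}

#' @rdname owindow
#' @param window An `owindow` object.
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "owindow"))
  (window$x_max - window$x_min) * (window$y_max - window$y_min)
}

#' @export
print.owindow <- function(x, ...) {
  cat(sprintf("window: [%g, %g] x [%g, %g] um (area %g um^2)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, window_area(x)))
  invisible(x)
}

#' Planar point pattern of corneal-nipple centroids
#'
#' Bundles 2D centroid coordinates with their observation window and the
#' eye/genotype metadata carried through every downstream analysis.
#'
#' @param x,y Numeric coordinate vectors in micrometres, equal length.
#' @param window An [owindow()] containing every point.
#' @param eye_id Identifier of the source eye.
#' @param genotype Genotype label (e.g. `"control"`, `"mutant"`).
#' @return An object of class `"point_pattern"`.
#' @examples
#' pp <- point_pattern(c(1, 4), c(2, 2), owindow(0, 10, 0, 10))
#' npoints(pp)
#' @export
point_pattern <- function(x, y, window, eye_id = "eye1", genotype = "unknown") {
  stopifnot(inherits(window, "owindow"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) > 0) {
    inside <- x >= window$x_min & x <= window$x_max &
      y >= window$y_min & y <= window$y_max
    if (!all(inside)) stop("all points must lie inside the window", call. = FALSE)
    if (anyDuplicated(cbind(x, y))) stop("duplicated coordinates are not allowed", call. = FALSE)
  }
  structure(list(x = x, y = y, window = window,
                 eye_id = as.character(eye_id), genotype = as.character(genotype)),
            class = "point_pattern")
}

#' @rdname point_pattern
#' @param pattern A `point_pattern`.
#' @export
npoints <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  length(pattern$x)
}

#' Point intensity (spatial density) of a pattern
#'
#' @param pattern A [point_pattern()].
#' @return Points per square micrometre, `n / area(window)`.
#' @export
intensity <- function(pattern) {
  npoints(pattern) / window_area(pattern$window)
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points, eye %s (%s)\n",
              npoints(x), x$eye_id, x$genotype))
  print(x$window)
  invisible(x)
}

#' @export
as.data.frame.point_pattern <- function(x, ...) {
  data.frame(eye_id = rep(x$eye_id, length(x$x)),
             genotype = rep(x$genotype, length(x$x)),
             x_um = x$x, y_um = x$y,
             stringsAsFactors = FALSE)
}

#' Read and write point patterns as CSV plus a window sidecar JSON
#'
#' The CSV holds columns `eye_id, genotype, x_um, y_um`; the observation
#' window is stored separately as JSON with fields
#' `x_min, x_max, y_min, y_max`.
#'
#' @param pattern A [point_pattern()].
#' @param csv_path Path of the coordinate CSV.
#' @param window_path Path of the window JSON sidecar.
#' @return `write_point_pattern` returns the CSV path invisibly;
#'   `read_point_pattern` returns a `point_pattern`.
#' @export
write_point_pattern <- function(pattern, csv_path, window_path) {
  stopifnot(inherits(pattern, "point_pattern"))
  utils::write.csv(as.data.frame(pattern), csv_path, row.names = FALSE)
  jsonlite::write_json(pattern$window[c("x_min", "x_max", "y_min", "y_max")],
                       window_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_point_pattern
#' @export
read_point_pattern <- function(csv_path, window_path) {
  if (!file.exists(csv_path)) stop("point CSV not found: ", csv_path, call. = FALSE)
  if (!file.exists(window_path)) stop("window JSON not found: ", window_path, call. = FALSE)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  wj <- jsonlite::read_json(window_path, simplifyVector = TRUE)
  w <- owindow(wj$x_min, wj$x_max, wj$y_min, wj$y_max)
  point_pattern(df$x_um, df$y_um, w,
                eye_id = if (nrow(df)) df$eye_id[1] else "eye1",
                genotype = if (nrow(df)) df$genotype[1] else "unknown")
}
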