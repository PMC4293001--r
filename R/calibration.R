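#' Calibrate device coordinates against the figure's axes
#'
#' Builds the invertible affine map between printer-point device coordinates
#' and data coordinates (time on x, probability/hazard on y) from two
#' user-identified anchors per axis — typically the axis endpoints or two
#' labelled tick marks.  Each axis gets an independent linear map; a negative
#' y slope is perfectly normal (it arises whenever device y is measured from
#' the top of the page, or the data axis points downward).
#'
#' @param x_anchors,y_anchors Two anchors per axis, each given either as a
#'   2-column matrix/data frame (`device`, `data`) or as a list of two
#'   `c(device, data)` pairs.  The two device values on an axis must differ.
#' @return An object of class `axis_calibration`: a list with per-axis
#'   `slope` and `intercept` (data = slope * device + intercept) and the
#'   anchors as entered.
#' @examples
#' # the worked 2-in x-axis (t = 0..5) and 1.5-in y-axis (S = 0..1),
#' # y measured downward from the top of the page:
#' cal <- calibrate_axes(list(c(72, 0), c(216, 5)),
#'                       list(c(360, 0), c(252, 1)))
#' device_to_data(data.frame(x = 144, y = 300), cal)
#' @export
calibrate_axes <- function(x_anchors, y_anchors) {
  xa <- as_anchor_matrix(x_anchors, "x")
  ya <- as_anchor_matrix(y_anchors, "y")
  structure(list(
    x = axis_map(xa, "x"),
    y = axis_map(ya, "y"),
    x_anchors = xa,
    y_anchors = ya
  ), class = "axis_calibration")
}

as_anchor_matrix <- function(a, axis) {
  if (is.list(a) && !is.data.frame(a)) a <- do.call(rbind, a)
  a <- as.matrix(a)
  if (!all(dim(a) == c(2, 2)) || !is.numeric(a) || any(!is.finite(a))) {
    abort(sprintf("%s_anchors must be two finite (device, data) pairs", axis))
  }
  colnames(a) <- c("device", "data")
  a
}

axis_map <- function(a, axis) {
  dd <- a[2, "device"] - a[1, "device"]
  if (abs(dd) < .Machine$double.eps * max(1, abs(a[, "device"]))) {
    abort(sprintf("degenerate calibration: coincident %s-axis anchors", axis),
          class = "kmrecover_degenerate_calibration")
  }
  slope <- unname((a[2, "data"] - a[1, "data"]) / dd)
  if (slope == 0) {
    abort(sprintf("degenerate calibration: coincident %s-axis data values", axis),
          class = "kmrecover_degenerate_calibration")
  }
  list(slope = slope, intercept = unname(a[1, "data"] - slope * a[1, "device"]))
}

#' @export
print.axis_calibration <- function(x, ...) {
  cat("<axis_calibration>\n")
  cat(sprintf("  t = %.6g * device_x + %.6g  (%.6g points per time unit)\n",
              x$x$slope, x$x$intercept, 1 / x$x$slope))
  cat(sprintf("  S = %.6g * device_y + %.6g  (%.6g points per probability unit)\n",
              x$y$slope, x$y$intercept, 1 / x$y$slope))
  invisible(x)
}

#' Map device coordinates to data coordinates (and back)
#'
#' `device_to_data()` applies a calibration to points or segments in printer
#' points; `data_to_device()` is its exact inverse.  Both accept a data frame
#' first so calls chain with the pipe.  Segment tables (columns
#' `x0`,`y0`,`x1`,`y1`) are converted column-wise to `t0`,`S0`,`t1`,`S1` (and
#' back); point tables use `x`,`y` vs `t`,`S`.
#'
#' Points whose mapped height falls outside `[-0.05, 1.05]` are allowed
#' (curves may start slightly outside the axis box) but a message reports how
#' many, as a calibration sanity check.
#'
#' @param points A data frame of device points (`x`, `y`) or segments
#'   (`x0`,`y0`,`x1`,`y1`); other columns pass through.
#' @param calib An `axis_calibration` from [calibrate_axes()].
#' @param quiet Suppress the out-of-range message.
#' @return A tibble with the mapped coordinate columns (other columns
#'   preserved).
#' @export
device_to_data <- function(points, calib, quiet = FALSE) {
  stopifnot(inherits(calib, "axis_calibration"))
  fx <- function(v) calib$x$slope * v + calib$x$intercept
  fy <- function(v) calib$y$slope * v + calib$y$intercept
  out <- map_coords(points, fx, fy,
                    from = c("x", "y", "x0", "y0", "x1", "y1"),
                    to = c("t", "S", "t0", "S0", "t1", "S1"))
  if (!quiet) {
    Sv <- unlist(out[intersect(c("S", "S0", "S1"), names(out))])
    n_out <- sum(Sv < -0.05 | Sv > 1.05, na.rm = TRUE)
    if (n_out > 0) {
      message(sprintf(
        "%d mapped height(s) outside [-0.05, 1.05]; extrapolating beyond anchors",
        n_out))
    }
  }
  out
}

#' @rdname device_to_data
#' @export
data_to_device <- function(points, calib) {
  stopifnot(inherits(calib, "axis_calibration"))
  fx <- function(v) (v - calib$x$intercept) / calib$x$slope
  fy <- function(v) (v - calib$y$intercept) / calib$y$slope
  map_coords(points, fx, fy,
             from = c("t", "S", "t0", "S0", "t1", "S1"),
             to = c("x", "y", "x0", "y0", "x1", "y1"))
}

map_coords <- function(points, fx, fy, from, to) {
  out <- tibble::as_tibble(as.data.frame(points))
  found <- FALSE
  for (i in seq_along(from)) {
    if (from[i] %in% names(out)) {
      found <- TRUE
      f <- if (grepl("^(x|t)", from[i])) fx else fy
      out[[to[i]]] <- f(out[[from[i]]])
      out[[from[i]]] <- NULL
    }
  }
  if (!found) abort("no coordinate columns found to map")
  out
}

#' Points-per-data-unit scale of a calibration axis
#'
#' @param calib An `axis_calibration`.
#' @param axis `"x"` or `"y"`.
#' @return Absolute device points per data unit (always positive).
#' @export
axis_scale <- function(calib, axis = c("y", "x")) {
  axis <- match.arg(axis)
  abs(1 / calib[[axis]]$slope)
}
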