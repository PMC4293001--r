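#' Simulate a ground-truth survival study
#'
#' Generates individual time-to-event records with exponential event times
#' and one of three censoring mechanisms, together with the exact risk-set
#' table obtained by direct counting — the oracle every recovery test is
#' checked against.  Event (and censoring) times are rounded to
#' `tie_digits` decimals, emulating discrete follow-up and forcing tied
#' event times (`d_j > 1`) at realistic rates.
#'
#' Censoring models:
#' * `"none"`: complete follow-up.
#' * `"uniform"`: random censoring `C ~ U(0, censor_max)`, default
#'   `censor_max = 2/hazard` (roughly 30% censored).
#' * `"admin"`: staggered-entry administrative censoring — subjects enter in
#'   `cohorts` equal waves one time unit apart and all follow-up stops at
#'   `followup`, so censoring times cluster at exactly `cohorts` distinct
#'   durations (the end-of-study pattern of multi-year recruitment).
#'
#' @param n0 Initial sample size (>= 2).
#' @param hazard Constant event hazard rate (events per time unit).
#' @param censoring One of `"none"`, `"uniform"`, `"admin"`.
#' @param censor_max Upper limit of uniform censoring.
#' @param cohorts,followup Admin-censoring design: number of entry waves
#'   (one time unit apart) and the administrative end of follow-up measured
#'   from the first wave's entry (default `1.5/hazard + cohorts`).
#' @param tie_digits Decimal places the recorded times are rounded to.
#' @param seed RNG seed (one seed in, reproducible study out).
#' @return An object of class `simulated_study`: list with `ipd` (tibble
#'   `time`, `status`), `truth` (a `risk_set_table` by direct counting) and
#'   `params`.
#' @examples
#' sim <- simulate_study(20, hazard = 0.2, censoring = "uniform", seed = 1)
#' sim$truth
#' @export
simulate_study <- function(n0, hazard = 0.1,
                           censoring = c("none", "uniform", "admin"),
                           censor_max = NULL, cohorts = 4, followup = NULL,
                           tie_digits = 1, seed = NULL) {
  censoring <- match.arg(censoring)
  if (!is.numeric(n0) || n0 < 2) abort("n0 must be at least 2")
  if (hazard <= 0) abort("hazard must be positive")
  if (!is.null(seed)) set.seed(seed)

  T_ev <- rexp(n0, hazard)
  C <- switch(censoring,
    none = rep(Inf, n0),
    uniform = runif(n0, 0, censor_max %||% (2 / hazard)),
    admin = {
      entry <- rep(seq_len(cohorts) - 1, length.out = n0)
      # default cutoff sits midway between assessment grid points, as a
      # calendar closing date generically does
      (followup %||% (1.5 / hazard + cohorts + 0.5 * 10^-tie_digits)) - entry
    })
  # event times are recorded on the assessment grid (forcing ties); censoring
  # happens at the exact cutoff/dropout date, generically between grid points
  status <- as.integer(T_ev <= C)
  res <- 10^-tie_digits
  time <- ifelse(status == 1, pmax(round(T_ev, tie_digits), res), C)

  ipd <- dplyr::arrange(tibble::tibble(time = time, status = status),
                        .data$time, -.data$status)
  structure(list(
    ipd = ipd,
    truth = risk_table_from_ipd(ipd),
    params = list(n0 = n0, hazard = hazard, censoring = censoring,
                  censor_max = censor_max, cohorts = cohorts,
                  followup = followup, tie_digits = tie_digits, seed = seed)
  ), class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study: n0 = %d, %s censoring, %d events at %d distinct times>\n",
              nrow(x$ipd), x$params$censoring, sum(x$ipd$status), nrow(x$truth)))
  invisible(x)
}

#' Risk-set table by direct counting of individual records
#'
#' The bookkeeping ground truth: for each distinct event time, the number
#' still under observation (`time >= t_j`; censoring tied with an event is
#' processed after the event, the standard convention), the events at it,
#' and the censorings in `[t_j, t_{j+1})`.
#'
#' @param ipd A data frame with `time` and `status` (1 event, 0 censored).
#' @return A `risk_set_table` (possibly zero rows if no events).
#' @export
risk_table_from_ipd <- function(ipd) {
  stopifnot(all(c("time", "status") %in% names(ipd)))
  tj <- sort(unique(ipd$time[ipd$status == 1]))
  k <- length(tj)
  n <- vapply(tj, function(t) sum(ipd$time >= t), double(1))
  d <- vapply(tj, function(t) sum(ipd$time == t & ipd$status == 1), double(1))
  upper <- c(tj[-1], Inf)
  c_j <- vapply(seq_len(k), function(j) {
    sum(ipd$status == 0 & ipd$time >= tj[j] & ipd$time < upper[j])
  }, double(1))
  out <- tibble::new_tibble(
    tibble::tibble(t = tj, n = as.integer(n), d = as.integer(d),
                   c = as.integer(c_j)),
    class = "risk_set_table")
  attr(out, "n0") <- nrow(ipd)
  attr(out, "c0") <- sum(ipd$status == 0 & (k == 0L | ipd$time < tj[1]))
  attr(out, "curve_type") <- "survival"
  attr(out, "end_time") <- max(ipd$time)
  out
}

#' Product-limit (Kaplan-Meier) estimate as a step curve
#'
#' Computes the Kaplan-Meier estimator from first principles —
#' `S(t) = prod over t_j <= t of (1 - d_j/n_j)` — with ties summed and
#' censoring tied at an event processed after the event.
#'
#' @param ipd A data frame with `time` and `status`, or a
#'   `simulated_study`.
#' @return A list of class `km_fit`: `curve` (a survival `step_curve`),
#'   `table` (the counting `risk_set_table`) and `marks` (tick positions at
#'   censoring times strictly between event times, plus any after the last
#'   event).
#' @examples
#' km_curve(aml_maintained())
#' @export
km_curve <- function(ipd) {
  fit_counting_curve(ipd, "survival")
}

#' Nelson-Aalen cumulative-hazard estimate as a step curve
#'
#' `H(t) = sum over t_j <= t of d_j/n_j`, by direct counting.
#'
#' @inheritParams km_curve
#' @return As [km_curve()], with a `cumulative_hazard` curve.
#' @export
na_curve <- function(ipd) {
  fit_counting_curve(ipd, "cumulative_hazard")
}

#' Cumulative-incidence (1 - KM) estimate as a step curve
#'
#' The complement of the product-limit estimator, the upward-going form
#' usually plotted on a truncated axis in trial reports.
#'
#' @inheritParams km_curve
#' @return As [km_curve()], with a `cumulative_incidence` curve.
#' @export
ci_curve <- function(ipd) {
  fit_counting_curve(ipd, "cumulative_incidence")
}

fit_counting_curve <- function(ipd, type) {
  if (inherits(ipd, "simulated_study")) ipd <- ipd$ipd
  table <- risk_table_from_ipd(ipd)
  if (nrow(table) == 0L) {
    warn("all observations censored: curve has no jumps")
    origin <- if (type == "survival") 1 else 0
    curve <- step_curve(tibble::tibble(t = 0, S = origin), curve_type = type,
                        end_time = max(ipd$time), source = "estimated from records")
    return(structure(list(curve = curve, table = table,
                          marks = censor_tick_positions(ipd, table),
                          ipd = ipd),
                     class = "km_fit"))
  }
  S <- estimator_heights(table$n, table$d, type)
  origin <- if (type == "survival") 1 else 0
  curve <- step_curve(
    tibble::tibble(t = c(0, table$t), S = c(origin, S)),
    curve_type = type, end_time = max(ipd$time),
    source = "estimated from records")
  structure(list(curve = curve, table = table,
                 marks = censor_tick_positions(ipd, table), ipd = ipd),
            class = "km_fit")
}

# Tick positions a plotting package would draw: one per censored subject
# whose time does not coincide with an event time (tied censoring is
# recorded as "t+" and gets no mark); simultaneous censorings overplot.
censor_tick_positions <- function(ipd, table) {
  ct <- ipd$time[ipd$status == 0]
  sort(ct[!ct %in% table$t])   # one mark per censored subject (overplotted)
}

#' @export
print.km_fit <- function(x, ...) {
  print(x$curve)
  invisible(x)
}

#' Page layout for the PostScript renderer
#'
#' Mirrors the worked device geometry used throughout the documentation: a
#' 144-point x-axis starting at device x = 72 and a 108-point y-axis whose
#' `S = 0` end sits at device y = 360 with heights measured *upward from
#' there being downward on the page* (the y slope is negative), so the
#' calibration exercises the orientation handling.
#'
#' @param x_dev Device x of the time-axis ends (points).
#' @param y_dev Device y of the `S`-axis ends: `S_range[1]` first.
#' @param t_range Data range of the time axis (default: set at render time
#'   to the curve's follow-up).
#' @param S_range Data range of the height axis.
#' @return A list of class `render_layout`.
#' @export
render_layout <- function(x_dev = c(72, 216), y_dev = c(360, 252),
                          t_range = NULL, S_range = c(0, 1)) {
  structure(list(x_dev = x_dev, y_dev = y_dev, t_range = t_range,
                 S_range = S_range), class = "render_layout")
}

#' Render a step curve to PostScript
#'
#' Emits a self-contained PostScript program drawing the axes and the curve,
#' using only the operator subset the extractor interprets, with all
#' coordinates rounded to `decimals` decimal places.  Three drawing dialects
#' reproduce the path structures found in published figures:
#'
#' * `"segments"`: the minimal alternating horizontal/vertical polyline, one
#'   stroked path.
#' * `"per_observation_dots"`: the disclosure dialect — one free-standing
#'   element per subject: each censored subject a zero-length dot at its
#'   exact (time, height) position, each event one vertical sub-segment of
#'   its jump.  No horizontal segments at all; with many subjects the dots
#'   themselves trace the curve.
#' * `"elaborate"`: every horizontal/vertical piece overdrawn as four
#'   redundant collinear sub-segments (a full-length stroke plus its three
#'   thirds), emulating post-processed figures that use thousands of
#'   segments for a handful of steps.
#'
#' Censor marks (`censor_style`) are drawn as short vertical ticks through
#' the curve or as zero-length dots, at `censor_times` that do not coincide
#' with an event time.
#'
#' @param curve A `step_curve` (or a `km_fit`, whose marks are used as
#'   default `censor_times`).
#' @param event_counts Integer vector of events per jump (`d_j`), used by
#'   the per-observation dialect to split each jump into one sub-segment per
#'   event subject; defaults to one per jump (or the `km_fit` table).
#' @param censor_times Times of censoring marks; for
#'   `"per_observation_dots"` also the positions of the censored subjects'
#'   dots (defaults to the `km_fit` marks, or none).
#' @param layout A [render_layout()].
#' @param decimals Coordinate rounding (0-6 decimal places of a point).
#' @param dialect Drawing dialect, see above.
#' @param censor_style `"tick"`, `"dot"` or `"none"`.
#' @param tick_halflength Tick half-length in device points.
#' @return A list of class `ps_render`: `ps` (the PostScript text), `calib`
#'   (the matching [calibrate_axes()] object), `layout`, `decimals`.
#' @examples
#' fit <- km_curve(aml_maintained())
#' r <- render_postscript(fit, decimals = 3, censor_style = "tick")
#' substr(r$ps, 1, 60)
#' @export
render_postscript <- function(curve, censor_times = NULL,
                              event_counts = NULL,
                              layout = render_layout(), decimals = 3,
                              dialect = c("segments", "per_observation_dots",
                                          "elaborate"),
                              censor_style = c("tick", "dot", "none"),
                              tick_halflength = 2.5) {
  dialect <- match.arg(dialect)
  censor_style <- match.arg(censor_style)
  if (inherits(curve, "km_fit")) {
    censor_times <- censor_times %||% (
      if (dialect == "per_observation_dots") {
        curve$ipd$time[curve$ipd$status == 0]   # one dot per censored subject
      } else curve$marks)
    event_counts <- event_counts %||% curve$table$d
    curve <- curve$curve
  }
  stopifnot(inherits(curve, "step_curve"), decimals >= 0, decimals <= 6)
  end_time <- attr(curve, "end_time")
  t_range <- layout$t_range %||% c(0, end_time)
  if (curve_type(curve) != "survival" && identical(layout$S_range, c(0, 1))) {
    layout$S_range <- c(0, max(curve$S) * 1.05)
  }

  dx <- function(t) layout$x_dev[1] + (t - t_range[1]) /
    diff(t_range) * diff(layout$x_dev)
  dy <- function(S) layout$y_dev[1] + (S - layout$S_range[1]) /
    diff(layout$S_range) * diff(layout$y_dev)
  fmt <- function(v) formatC(round(v, decimals), format = "f",
                             digits = decimals)
  seg_cmd <- function(x0, y0, x1, y1) {
    sprintf("%s %s moveto %s %s lineto stroke",
            fmt(x0), fmt(y0), fmt(x1), fmt(y1))
  }

  out <- c("%!PS-Adobe-3.0",
           "% synthetic step-curve figure",
           "/dummy { pop } def",
           "1 setlinewidth 0 setgray newpath",
           # axes
           seg_cmd(layout$x_dev[1], layout$y_dev[1],
                   layout$x_dev[2], layout$y_dev[1]),
           seg_cmd(layout$x_dev[1], layout$y_dev[1],
                   layout$x_dev[1], layout$y_dev[2]),
           "0.5 setlinewidth")

  # curve pieces in device space
  k <- nrow(curve)
  vx <- dx(curve$t); vy <- dy(curve$S)
  ex <- dx(min(end_time, t_range[2]))

  if (dialect == "segments") {
    pts_x <- c(vx[1], rep(vx[-1], each = 2), ex)
    pts_y <- c(vy[1], vy[rep(seq_len(k - 1), each = 2) + rep(c(0, 1), k - 1)], vy[k])
    if (k == 1L) { pts_x <- c(vx[1], ex); pts_y <- c(vy[1], vy[1]) }
    cmds <- c(sprintf("%s %s moveto", fmt(pts_x[1]), fmt(pts_y[1])),
              sprintf("%s %s lineto", fmt(pts_x[-1]), fmt(pts_y[-1])),
              "stroke")
    out <- c(out, cmds)
  } else if (dialect == "elaborate") {
    pieces <- step_pieces(vx, vy, ex)
    for (i in seq_len(nrow(pieces))) {
      p <- pieces[i, ]
      fr <- rbind(c(0, 1), c(0, 1 / 3), c(1 / 3, 2 / 3), c(2 / 3, 1))
      for (r in seq_len(nrow(fr))) {
        out <- c(out, seg_cmd(p$x0 + fr[r, 1] * (p$x1 - p$x0),
                              p$y0 + fr[r, 1] * (p$y1 - p$y0),
                              p$x0 + fr[r, 2] * (p$x1 - p$x0),
                              p$y0 + fr[r, 2] * (p$y1 - p$y0)))
      }
    }
  } else {  # per_observation_dots
    # events: one vertical sub-segment per event subject
    for (j in seq_len(k)[-1]) {
      top <- vy[j - 1]; bot <- vy[j]
      dj <- event_counts[j - 1] %||% 1L
      cuts <- seq(0, 1, length.out = dj + 1)
      for (s in seq_len(dj)) {
        out <- c(out, seg_cmd(vx[j], top + cuts[s] * (bot - top),
                              vx[j], top + cuts[s + 1] * (bot - top)))
      }
    }
    # censored subjects: zero-length dots at their exact positions
    for (tc in (censor_times %||% numeric(0))) {
      xc <- dx(tc); yc <- dy(step_height(curve, tc))
      out <- c(out, seg_cmd(xc, yc, xc, yc))
    }
  }

  if (dialect != "per_observation_dots" && censor_style != "none") {
    for (tc in (censor_times %||% numeric(0))) {
      xc <- dx(tc); yc <- dy(step_height(curve, tc))
      out <- c(out, if (censor_style == "tick") {
        seg_cmd(xc, yc - tick_halflength, xc, yc + tick_halflength)
      } else {
        seg_cmd(xc, yc, xc, yc)
      })
    }
  }

  out <- c(out, "showpage")
  calib <- calibrate_axes(
    list(c(layout$x_dev[1], t_range[1]), c(layout$x_dev[2], t_range[2])),
    list(c(layout$y_dev[1], layout$S_range[1]),
         c(layout$y_dev[2], layout$S_range[2])))
  structure(list(ps = paste(out, collapse = "\n"), calib = calib,
                 layout = layout, decimals = decimals, dialect = dialect),
            class = "ps_render")
}

step_pieces <- function(vx, vy, ex) {
  k <- length(vx)
  out <- list()
  for (j in seq_len(k)) {
    x_end <- if (j < k) vx[j + 1] else ex
    if (x_end > vx[j]) {
      out[[length(out) + 1L]] <- data.frame(x0 = vx[j], y0 = vy[j],
                                            x1 = x_end, y1 = vy[j])
    }
    if (j < k) {
      out[[length(out) + 1L]] <- data.frame(x0 = vx[j + 1], y0 = vy[j],
                                            x1 = vx[j + 1], y1 = vy[j + 1])
    }
  }
  do.call(rbind, out)
}

#' @export
print.ps_render <- function(x, ...) {
  cat(sprintf("<ps_render: %s dialect, %d decimals, %d lines>\n",
              x$dialect, x$decimals,
              length(strsplit(x$ps, "\n", fixed = TRUE)[[1]])))
  invisible(x)
}

#' Write a rendered figure to a PostScript file
#'
#' @param render A `ps_render` from [render_postscript()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ps <- function(render, file) {
  stopifnot(inherits(render, "ps_render"))
  writeLines(render$ps, file)
  invisible(file)
}
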