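#' Construct a step-curve object from vertex coordinates
#'
#' The package's central container: an ordered table of step-function corner
#' vertices `(t, S)`, where `S` is the *post-jump* height at `t` (the curve
#' is right-continuous, jumping at event times).  The first vertex is the
#' curve origin (`t = 0`, height 1 for survival, 0 for cumulative incidence
#' or hazard).  This constructor is also the direct entry point for
#' digitizer-exported coordinate tables (CSV with columns `t`, `S`),
#' bypassing PostScript extraction entirely.
#'
#' @param vertices A data frame with columns `t` and `S`.  Vertices closer
#'   than `t_tol` in time are merged (last height wins); `t` must otherwise
#'   be strictly increasing.
#' @param curve_type One of `"survival"`, `"cumulative_incidence"`,
#'   `"cumulative_hazard"`.
#' @param end_time Time up to which the final horizontal run extends (the
#'   last follow-up); defaults to the last vertex time.
#' @param t_tol Time tolerance for merging duplicate vertices.
#' @param source Free-text provenance note.
#' @return A tibble of class `step_curve` with columns `t`, `S` and
#'   attributes `curve_type`, `end_time`, `source`.
#' @export
step_curve <- function(vertices,
                       curve_type = c("survival", "cumulative_incidence",
                                      "cumulative_hazard"),
                       end_time = NULL, t_tol = 1e-9, source = "constructed") {
  curve_type <- match.arg(curve_type)
  v <- tibble::as_tibble(as.data.frame(vertices)[, c("t", "S")])
  if (nrow(v) == 0L) abort("step curve needs at least one vertex")
  v <- dplyr::arrange(v, .data$t)
  keep <- c(TRUE, diff(v$t) > t_tol)
  # merged duplicates: keep the later (post-jump) height
  v <- v[rev(!duplicated(rev(cumsum(keep)))), , drop = FALSE]
  v <- v[order(v$t), , drop = FALSE]
  if (any(diff(v$t) <= 0)) abort("vertex times must be strictly increasing")
  out <- tibble::new_tibble(v, class = "step_curve")
  attr(out, "curve_type") <- curve_type
  attr(out, "end_time") <- end_time %||% max(v$t)
  attr(out, "source") <- source
  out
}

#' @export
print.step_curve <- function(x, ...) {
  cat(sprintf("<step_curve: %s, %d vertices, follow-up to t = %g>\n",
              curve_type(x), nrow(x), attr(x, "end_time")))
  NextMethod()
}

#' Curve type of a step curve
#' @param curve A `step_curve`.
#' @return `"survival"`, `"cumulative_incidence"` or `"cumulative_hazard"`.
#' @export
curve_type <- function(curve) attr(curve, "curve_type") %||% "survival"

#' Height of a step curve at arbitrary times
#'
#' Right-continuous evaluation: the post-jump height of the last vertex at
#' or before `t`.
#'
#' @param curve A `step_curve`.
#' @param t Numeric vector of times.
#' @return Numeric vector of heights.
#' @export
step_height <- function(curve, t) {
  idx <- findInterval(t, curve$t)
  ifelse(idx == 0, curve$S[1], curve$S[pmax(idx, 1)])
}

#' Group calibrated segments into candidate curves
#'
#' Figures contain several arms plus axes, tick marks and annotation.
#' Segments are partitioned first by stroke attributes (line width and
#' colour) and then by path connectivity: segments sharing an endpoint
#' (within `tol`) or a `path_id` belong to the same group.  Groups are
#' returned largest first; the user picks the arm of interest by index.
#'
#' A group containing horizontal runs at different heights over the same
#' time span is flagged with a warning — that is what two overlapping
#' same-style arms merged into one group look like, and resolving it needs
#' manual `path_id` selection.
#'
#' @param segments A `ps_segments` tibble (device space is fine; grouping is
#'   metric-free apart from `tol`).
#' @param tol Endpoint-coincidence tolerance in the segments' coordinate
#'   units.
#' @return A list of segment tibbles, ordered by decreasing segment count.
#' @export
group_curves <- function(segments, tol = 1e-6) {
  segs <- tibble::as_tibble(as.data.frame(segments))
  if (nrow(segs) == 0L) abort("no curve-like path found (no segments)")
  has_attrs <- all(c("linewidth", "red", "green", "blue") %in% names(segs))
  akey <- if (has_attrs) {
    paste(signif(segs$linewidth, 8), signif(segs$red, 8),
          signif(segs$green, 8), signif(segs$blue, 8))
  } else rep("all", nrow(segs))

  groups <- list()
  for (key in unique(akey)) {
    sub <- segs[akey == key, , drop = FALSE]
    comp <- connected_components(sub, tol)
    # the disclosure dialect draws one free-standing element per subject, so
    # connectivity shatters the arm into singletons; when no component
    # dominates, the attribute group itself is the curve
    if (max(table(comp)) < 0.5 * nrow(sub) && nrow(sub) >= 4L) {
      groups[[length(groups) + 1L]] <- sub
      next
    }
    for (cid in unique(comp)) {
      groups[[length(groups) + 1L]] <- sub[comp == cid, , drop = FALSE]
    }
  }
  sizes <- vapply(groups, nrow, integer(1))
  groups <- groups[order(-sizes)]
  if (max(sizes) < 2L) {
    abort("no curve-like path found (no group with >= 2 segments)",
          class = "kmrecover_no_curve")
  }
  for (g in groups) {
    if (has_overlapping_levels(g)) {
      warn(paste("a segment group contains horizontal runs at different",
                 "heights over the same time span; it may hold two",
                 "overlapping arms - select by path_id manually"))
    }
  }
  groups
}

# Two same-style arms merged into one group betray themselves by horizontal
# runs at clearly different heights covering overlapping x-ranges (redundant
# overdrawing, by contrast, repeats the *same* height).
has_overlapping_levels <- function(g, y_tol = 1e-6) {
  h <- g[!g$is_dot & abs(g$y1 - g$y0) <= y_tol, , drop = FALSE]
  if (nrow(h) < 2L) return(FALSE)
  y <- round((h$y0 + h$y1) / 2 / max(y_tol, 1e-12))
  x0 <- pmin(h$x0, h$x1); x1 <- pmax(h$x0, h$x1)
  lev <- split(seq_len(nrow(h)), y)
  if (length(lev) < 2L) return(FALSE)
  rng <- lapply(lev, function(i) c(min(x0[i]), max(x1[i])))
  for (i in seq_along(rng)[-1]) {
    for (j in seq_len(i - 1L)) {
      ov <- min(rng[[i]][2], rng[[j]][2]) - max(rng[[i]][1], rng[[j]][1])
      span <- min(diff(rng[[i]]), diff(rng[[j]]))
      if (span > 0 && ov > 0.5 * span) return(TRUE)
    }
  }
  FALSE
}

connected_components <- function(segs, tol) {
  n <- nrow(segs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  # same stroked path => same component
  for (pid in unique(segs$path_id)) {
    idx <- which(segs$path_id == pid)
    if (length(idx) > 1L) for (i in idx[-1]) union2(idx[1], i)
  }
  # shared endpoints (snapped to a tol grid) => same component
  pts <- rbind(cbind(segs$x0, segs$y0), cbind(segs$x1, segs$y1))
  key <- paste(round(pts[, 1] / max(tol, 1e-12)), round(pts[, 2] / max(tol, 1e-12)))
  owner <- rep(seq_len(n), 2L)
  for (k in split(owner, key)) {
    if (length(k) > 1L) for (i in k[-1]) union2(k[1], i)
  }
  vapply(seq_len(n), find, integer(1))
}


#' Build a clean step curve from one calibrated segment group
#'
#' Converts a group of figure segments into a `step_curve`, tolerating the
#' redundant path structure real exports contain: collinear and overdrawn
#' sub-segments are merged, horizontal runs split at censoring times are
#' rejoined, and near-horizontal segments (publication rounding) are treated
#' as horizontal.  Segments steeper than tolerance but not vertical are an
#' error — the input is then not a step function.
#'
#' The default tolerances follow the coordinate-rounding model: with
#' coordinates printed to `decimals` decimal places of a printer point, the
#' time-merge tolerance is `10^-decimals` points (converted to data units)
#' and the height noise bound is `2 * 10^-decimals / y_scale`.
#'
#' @param group A segment tibble, either in device space (columns
#'   `x0`,`y0`,`x1`,`y1`; supply `calib`) or already in data space
#'   (`t0`,`S0`,`t1`,`S1`).
#' @param calib An [calibrate_axes()] calibration (required for device-space
#'   input).
#' @param curve_type Declared curve type; see [step_curve()].
#' @param decimals Coordinate rounding of the source file, used for default
#'   tolerances.
#' @param t_tol,noise_bound Explicit overrides for the time-merge tolerance
#'   and the per-vertex monotonicity noise bound, in data units.
#' @param snap Apply [snap_monotone()] to the result (default `TRUE`).
#' @return A `step_curve`.
#' @export
build_step_curve <- function(group, calib = NULL,
                             curve_type = c("survival", "cumulative_incidence",
                                            "cumulative_hazard"),
                             decimals = 3, t_tol = NULL, noise_bound = NULL,
                             snap = TRUE) {
  curve_type <- match.arg(curve_type)
  segs <- as_data_segments(group, calib)
  if (!is.null(calib)) {
    t_tol <- t_tol %||% (10^-decimals * abs(calib$x$slope) * 2)
    noise_bound <- noise_bound %||% (2 * 10^-decimals * abs(calib$y$slope))
  } else {
    rng <- max(segs$t0, segs$t1) - min(segs$t0, segs$t1)
    t_tol <- t_tol %||% (1e-6 * max(rng, 1))
    noise_bound <- noise_bound %||% 1e-6
  }

  geo <- segs[!segs$is_dot, , drop = FALSE]
  if (nrow(geo) < 1L) abort("no non-dot segments in group")
  # orient left-to-right
  flip <- geo$t0 > geo$t1
  geo[flip, c("t0", "S0", "t1", "S1")] <- geo[flip, c("t1", "S1", "t0", "S0")]

  dt <- abs(geo$t1 - geo$t0)
  dS <- abs(geo$S1 - geo$S0)
  vert <- dt <= t_tol & dS > 0
  horiz <- !vert & dS <= noise_bound
  diag <- !vert & !horiz
  if (any(diag)) {
    bad <- geo[diag, , drop = FALSE]
    abort(sprintf("not a step function near t = %g (diagonal segment, slope %g)",
                  bad$t0[1], (bad$S1[1] - bad$S0[1]) / (bad$t1[1] - bad$t0[1])),
          class = "kmrecover_not_step")
  }

  runs <- merge_horizontal_runs(geo[horiz, , drop = FALSE], t_tol, noise_bound)
  jumps <- merge_vertical_jumps(geo[vert, , drop = FALSE], t_tol)
  if (nrow(runs) == 0L && nrow(jumps) == 0L) {
    abort("no horizontal runs or vertical jumps found; not a step curve")
  }
  dots <- segs[segs$is_dot, , drop = FALSE]

  if (nrow(jumps) > 0L) {
    # jumps carry the full vertex information (the disclosure dialect draws
    # no horizontal segments at all: the 'runs' are traced by per-subject
    # dots); horizontal runs, when present, only refine the origin and the
    # end of follow-up.  Orientation follows the curve type: survival drops,
    # the cumulative forms rise.
    if (curve_type != "survival") {
      tmp <- jumps$S_start
      jumps$S_start <- jumps$S_end
      jumps$S_end <- tmp
    }
    S0 <- if (nrow(runs) && runs$t_lo[1] < jumps$t[1]) runs$S[1] else jumps$S_start[1]
    t0 <- min(c(runs$t_lo, dots$t0, jumps$t[1]))
    if (t0 >= jumps$t[1] - t_tol) {
      # nothing observed before the first jump: anchor the origin at 0 when
      # that is to the left, else just before the first jump
      t0 <- if (jumps$t[1] > t_tol) 0 else jumps$t[1] - 1
    }
    v <- dplyr::bind_rows(tibble::tibble(t = t0, S = S0),
                          tibble::tibble(t = jumps$t, S = jumps$S_end))
  } else {
    v <- tibble::tibble(t = runs$t_lo, S = runs$S)
  }
  end_time <- max(c(runs$t_hi, jumps$t, dots$t0, v$t))
  curve <- step_curve(v, curve_type = curve_type, end_time = end_time,
                      t_tol = t_tol, source = "built from segments")
  check_origin(curve, noise_bound)
  if (snap) curve <- snap_monotone(curve, noise_bound = noise_bound)
  curve
}

as_data_segments <- function(group, calib) {
  segs <- tibble::as_tibble(as.data.frame(group))
  if (all(c("x0", "y0", "x1", "y1") %in% names(segs))) {
    if (is.null(calib)) abort("device-space segments need a calibration")
    segs <- device_to_data(segs, calib, quiet = TRUE)
  }
  if (!all(c("t0", "S0", "t1", "S1") %in% names(segs))) {
    abort("segments must have columns x0..y1 (device) or t0..S1 (data)")
  }
  if (!"is_dot" %in% names(segs)) {
    segs$is_dot <- segs$t0 == segs$t1 & segs$S0 == segs$S1
  }
  segs
}

merge_horizontal_runs <- function(h, t_tol, noise_bound) {
  if (nrow(h) == 0L) {
    return(tibble::tibble(t_lo = double(0), t_hi = double(0), S = double(0)))
  }
  h$S <- (h$S0 + h$S1) / 2
  h <- h[order(h$t0, h$t1), , drop = FALSE]
  t_lo <- h$t0[1]; t_hi <- h$t1[1]; hts <- h$S[1]
  out <- list()
  flush <- function() {
    out[[length(out) + 1L]] <<- tibble::tibble(t_lo = t_lo, t_hi = t_hi,
                                               S = mean(hts))
  }
  for (i in seq_len(nrow(h))[-1]) {
    if (h$t0[i] <= t_hi + t_tol && abs(h$S[i] - mean(hts)) <= noise_bound) {
      t_hi <- max(t_hi, h$t1[i]); hts <- c(hts, h$S[i])
    } else {
      flush()
      t_lo <- h$t0[i]; t_hi <- h$t1[i]; hts <- h$S[i]
    }
  }
  flush()
  dplyr::bind_rows(out)
}

merge_vertical_jumps <- function(v, t_tol) {
  if (nrow(v) == 0L) {
    return(tibble::tibble(t = double(0), S_start = double(0), S_end = double(0)))
  }
  v$t <- (v$t0 + v$t1) / 2
  v$lo <- pmin(v$S0, v$S1); v$hi <- pmax(v$S0, v$S1)
  v <- v[order(v$t), , drop = FALSE]
  v$grp <- cumsum(c(TRUE, diff(v$t) > t_tol))
  agg <- dplyr::summarise(dplyr::group_by(v, .data$grp),
                          t = mean(.data$t), lo = min(.data$lo),
                          hi = max(.data$hi), .groups = "drop")
  tibble::tibble(t = agg$t, S_start = agg$hi, S_end = agg$lo)
}

check_origin <- function(curve, noise_bound) {
  s0 <- curve$S[1]
  target <- if (curve_type(curve) == "survival") 1 else 0
  if (abs(s0 - target) > max(noise_bound, 1e-6) * 5) {
    warn(sprintf(
      "curve origin height %.6g differs from the expected %g for a %s curve; check calibration/curve_type",
      s0, target, curve_type(curve)))
  }
  invisible(curve)
}

#' Enforce monotonicity on a noisy step curve
#'
#' Coordinate rounding makes extracted heights very slightly non-monotone.
#' Provided every violation is within `noise_bound`, the heights are replaced
#' by their isotonic (pool-adjacent-violators) fit in the curve's monotone
#' direction — non-increasing for survival, non-decreasing otherwise.  A
#' violation beyond the bound aborts: that indicates a wrong `curve_type` or
#' a bad calibration rather than rounding noise.
#'
#' @param curve A `step_curve`.
#' @param noise_bound Largest tolerated single violation, in height units.
#' @return The snapped `step_curve`; attribute `snap_adjustment` holds the
#'   total absolute height adjustment applied.
#' @export
snap_monotone <- function(curve, noise_bound) {
  stopifnot(inherits(curve, "step_curve"))
  S <- curve$S
  sign <- if (curve_type(curve) == "survival") -1 else 1
  # wrong-direction increments
  viol <- pmax(0, -diff(S) * sign)
  if (any(viol > noise_bound)) {
    j <- which.max(viol)
    abort(sprintf(
      "monotonicity violation %.3g at t = %g exceeds noise bound %.3g; wrong curve_type or calibration?",
      max(viol), curve$t[j + 1], noise_bound),
      class = "kmrecover_monotonicity")
  }
  if (all(viol == 0)) return(curve)
  fit <- stats::isoreg(seq_along(S), sign * S)$yf * sign
  adj <- sum(abs(fit - S))
  out <- curve
  out$S <- fit
  attr(out, "snap_adjustment") <- adj
  out
}

#' Detect censoring marks on or around a step curve
#'
#' Two mark dialects are recognised.  *Ticks* are short vertical segments
#' crossing the curve height between jumps.  *Dots* are zero-length elements
#' lying on a horizontal run — how some packages silently record each
#' censored subject.  Marks coinciding with a jump time (within tolerance)
#' are excluded: a dot at a corner is part of the curve itself, and
#' censoring tied to an event is inferred downstream, not read off a mark.
#'
#' @param segments All candidate segments (the curve's own group plus any
#'   companion groups), device space with `calib` or data space.
#' @param curve The built `step_curve`.
#' @param calib Calibration for device-space input.
#' @param t_tol Time tolerance (defaults to the builder's convention via
#'   `decimals`).
#' @param decimals Source-coordinate rounding used for default tolerances.
#' @param max_tick_height Largest height extent (data units) accepted as a
#'   tick rather than a curve jump; default 0.15.
#' @return A tibble of class `censor_marks` with columns `t`, `S`, `kind`
#'   (`"tick"` or `"dot"`), possibly empty.
#' @export
detect_censor_marks <- function(segments, curve, calib = NULL,
                                t_tol = NULL, decimals = 3,
                                max_tick_height = 0.15) {
  segs <- as_data_segments(segments, calib)
  if (!is.null(calib)) {
    t_tol <- t_tol %||% (10^-decimals * abs(calib$x$slope) * 2)
    noise <- 2 * 10^-decimals * abs(calib$y$slope)
  } else {
    t_tol <- t_tol %||% (1e-6 * max(abs(c(segs$t0, segs$t1)), 1))
    noise <- 1e-6
  }
  jump_times <- curve$t[-1]

  marks <- list()
  # ticks: short verticals crossing the curve, away from jump times
  vseg <- segs[!segs$is_dot & abs(segs$t1 - segs$t0) <= t_tol, , drop = FALSE]
  if (nrow(vseg)) {
    tmid <- (vseg$t0 + vseg$t1) / 2
    lo <- pmin(vseg$S0, vseg$S1); hi <- pmax(vseg$S0, vseg$S1)
    on_curve <- step_height(curve, tmid)
    is_tick <- (hi - lo) <= max_tick_height &
      on_curve >= lo - noise - 1e-12 & on_curve <= hi + noise + 1e-12 &
      !near_any(tmid, jump_times, t_tol) &
      tmid >= curve$t[1] - t_tol & tmid <= attr(curve, "end_time") + t_tol
    if (any(is_tick)) {
      marks[[length(marks) + 1L]] <- tibble::tibble(
        t = tmid[is_tick], S = on_curve[is_tick], kind = "tick")
    }
  }
  # dots: zero-length elements sitting on a horizontal run, not at corners
  dseg <- segs[segs$is_dot, , drop = FALSE]
  if (nrow(dseg)) {
    td <- (dseg$t0 + dseg$t1) / 2
    Sd <- (dseg$S0 + dseg$S1) / 2
    on <- abs(Sd - step_height(curve, td)) <= max(noise * 3, 1e-9) &
      !near_any(td, jump_times, t_tol) &
      td >= curve$t[1] - t_tol & td <= attr(curve, "end_time") + t_tol
    if (any(on)) {
      marks[[length(marks) + 1L]] <- tibble::tibble(
        t = td[on], S = Sd[on], kind = "dot")
    }
  }
  out <- if (length(marks)) dplyr::arrange(dplyr::bind_rows(marks), .data$t) else
    tibble::tibble(t = double(0), S = double(0), kind = character(0))
  tibble::new_tibble(out, class = "censor_marks")
}

near_any <- function(x, targets, tol) {
  if (length(targets) == 0L) return(rep(FALSE, length(x)))
  vapply(x, function(xi) any(abs(xi - targets) <= tol), logical(1))
}

#' Read a digitizer-exported curve table
#'
#' Interoperability entry point for digitizer workflows: a CSV with columns
#' `t` and `S` (one row per clicked point on the curve, in data units) is
#' turned directly into a [step_curve()], bypassing PostScript extraction.
#'
#' @param file CSV path.
#' @inheritParams step_curve
#' @return A `step_curve`.
#' @export
read_digitizer_curve <- function(file,
                                 curve_type = c("survival",
                                                "cumulative_incidence",
                                                "cumulative_hazard"),
                                 end_time = NULL) {
  curve_type <- match.arg(curve_type)
  df <- utils::read.csv(file)
  if (!all(c("t", "S") %in% names(df))) abort("digitizer CSV needs columns t,S")
  step_curve(df, curve_type = curve_type, end_time = end_time,
             source = paste("digitizer:", file))
}
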