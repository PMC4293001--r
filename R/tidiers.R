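#' Tidy a fitted or recovered object
#'
#' Broom-style accessors.  `tidy()` returns the per-event-time table;
#' `glance()` a one-row summary.
#'
#' @param x A `km_fit`, `risk_set_table`, `step_curve` or
#'   `simulated_study`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.km_fit <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$table))
  out$S <- estimator_heights(out$n, out$d, curve_type(x$curve))
  out
}

#' @rdname tidiers
#' @export
glance.km_fit <- function(x, ...) {
  tibble::tibble(
    n0 = attr(x$table, "n0") %||% NA_integer_,
    n_event_times = nrow(x$table),
    events = sum(x$table$d),
    censored = sum(x$ipd$status == 0),
    end_time = attr(x$curve, "end_time"),
    curve_type = curve_type(x$curve))
}

#' @rdname tidiers
#' @export
tidy.risk_set_table <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidiers
#' @export
glance.risk_set_table <- function(x, ...) {
  tibble::tibble(
    n0 = attr(x, "n0") %||% (if (nrow(x)) x$n[1] else NA_integer_),
    n_event_times = nrow(x),
    events = sum(x$d),
    censored = sum(x$c) + (attr(x, "c0") %||% 0L),
    end_time = attr(x, "end_time") %||% (if (nrow(x)) max(x$t) else NA_real_),
    curve_type = attr(x, "curve_type") %||% NA_character_)
}

#' @rdname tidiers
#' @export
tidy.step_curve <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x))
  out$jump <- c(NA_real_, abs(diff(out$S)))
  out
}

#' @rdname tidiers
#' @export
glance.step_curve <- function(x, ...) {
  tibble::tibble(
    n_jumps = max(nrow(x) - 1L, 0L),
    S_start = x$S[1],
    S_end = x$S[nrow(x)],
    end_time = attr(x, "end_time"),
    curve_type = curve_type(x))
}

#' @rdname tidiers
#' @export
tidy.simulated_study <- function(x, ...) tidy(x$truth)

#' @rdname tidiers
#' @export
glance.simulated_study <- function(x, ...) glance(x$truth)
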