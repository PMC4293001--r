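#' Jumps and height ratios of a step curve
#'
#' For each jump time `t_j` of the curve, returns the jump magnitude
#' `J(t_j) = |S(t_{j-1}) - S(t_j)|` and, for survival curves, the ratio of
#' successive heights `S(t_j)/S(t_{j-1})` — the conditional survival
#' probability `1 - d_j/n_j` that the whole inversion rests on.
#'
#' @param curve A `step_curve` with at least one jump.
#' @return A tibble with columns `t`, `S_prev`, `S`, `jump`, and (survival
#'   curves) `ratio`.
#' @export
jumps_and_ratios <- function(curve) {
  stopifnot(inherits(curve, "step_curve"))
  if (nrow(curve) < 2L) abort("curve has no jumps")
  S_prev <- curve$S[-nrow(curve)]
  S <- curve$S[-1]
  out <- tibble::tibble(
    t = curve$t[-1],
    S_prev = S_prev,
    S = S,
    jump = abs(S_prev - S))
  if (curve_type(curve) == "survival") {
    if (any(S_prev <= 0)) {
      abort("curve reached 0 before a later jump; height ratio undefined")
    }
    out$ratio <- S / S_prev
  }
  out
}

#' Invert one jump of a product-limit (Kaplan-Meier) curve
#'
#' The Kaplan-Meier estimator multiplies conditional survival factors
#' `1 - d_j/n_j` at each event time, so the ratio of adjacent heights is
#' `S_j / S_{j-1} = 1 - d_j/n_j`, giving the simple inversion
#' `n_j = d_j / (1 - S_j/S_{j-1})`.
#'
#' @param S_prev,S_curr Heights just before and just after the jump
#'   (`0 <= S_curr < S_prev <= 1`).
#' @param d Number of events at the jump (default 1).
#' @return The (real-valued) number at risk implied by the jump.
#' @examples
#' infer_n_km(1, 10 / 11, 1)  # 11
#' @export
infer_n_km <- function(S_prev, S_curr, d = 1) {
  stopifnot(d >= 1)
  if (any(S_curr >= S_prev)) abort("no jump: S_curr must be below S_prev")
  if (any(S_prev <= 0)) abort("S_prev must be positive")
  d / (1 - S_curr / S_prev)
}

#' Invert one increment of a Nelson-Aalen cumulative-hazard curve
#'
#' The Nelson-Aalen estimator increments by exactly `d_j/n_j` at each event
#' time, so `n_j = d_j / (H_j - H_{j-1})` — exact, with no approximation.
#'
#' @param H_prev,H_curr Cumulative hazard before and after the jump
#'   (`H_curr > H_prev >= 0`).
#' @param d Number of events at the jump (default 1).
#' @return The implied number at risk.
#' @export
infer_n_na <- function(H_prev, H_curr, d = 1) {
  stopifnot(d >= 1)
  if (any(H_curr <= H_prev)) abort("non-positive cumulative-hazard increment")
  d / (H_curr - H_prev)
}

#' Invert one jump of a cumulative-incidence curve
#'
#' With `CI = 1 - S`, the product-limit ratio becomes
#' `n_j = d_j (1 - CI_{j-1}) / (CI_j - CI_{j-1})`.
#'
#' @param CI_prev,CI_curr Cumulative incidence before and after the jump
#'   (`0 <= CI_prev < CI_curr <= 1`).
#' @param d Number of events at the jump (default 1).
#' @return The implied number at risk.
#' @export
infer_n_ci <- function(CI_prev, CI_curr, d = 1) {
  stopifnot(d >= 1)
  if (any(CI_curr <= CI_prev)) abort("cumulative incidence must increase at a jump")
  d * (1 - CI_prev) / (CI_curr - CI_prev)
}

#' Resolve tied event counts from the pattern of inferred numbers at risk
#'
#' Following the d=1-first strategy: every jump is first inverted assuming a
#' single event.  True singleton jumps then trace out a monotonically
#' decreasing sequence of numbers at risk, while a jump with `d` tied events
#' yields a value at `1/d` of that backbone and stands out distinctly.  For
#' each entry, the multiplier `d in 1..d_max` whose product lands closest to
#' the local monotone reference (linear interpolation of neighbouring
#' backbone values, extrapolated at the ends) is chosen, scanning left to
#' right with ties broken toward smaller `d`.
#'
#' @details
#' Two pieces of structure sharpen the choice beyond the bare reference.
#' First, integrality: the raw value is `n_j/d_j` up to small measurement
#' noise, so only multipliers that land near a whole number of subjects are
#' admissible — a raw value of 2.5 can only be 5 subjects with 2 events,
#' never 2.5 subjects with one.  Second, the backbone and the corrections
#' are re-derived from the corrected sequence until they stabilise, which
#' resolves runs of consecutive tied-event times (common early in large
#' studies, where the inferred `n/d` can exceed every later singleton
#' value and would otherwise masquerade as backbone).
#'
#' @param raw_n Positive reals: numbers at risk inferred under `d = 1`.
#' @param d_max Largest multiplicity considered (default 5).
#' @param backbone_tol Count slack when identifying the monotone backbone
#'   (default 0.49: inferred values are expected within half a subject of
#'   truth for usable inputs).
#' @param max_iter Maximum backbone-refinement passes.
#' @return A tibble with columns `raw_n`, `d`, `n` (`= d * raw_n`) and
#'   `flagged` (`TRUE` when no candidate sat close to the reference).
#' @examples
#' detect_multiplicities(c(50, 49, 24, 47, 46))$d  # 1 1 2 1 1
#' @export
detect_multiplicities <- function(raw_n, d_max = 5, backbone_tol = 0.49,
                                  max_iter = 6) {
  stopifnot(is.numeric(raw_n), all(raw_n > 0), d_max >= 1)
  k <- length(raw_n)
  if (k == 0L) {
    return(tibble::tibble(raw_n = double(0), d = integer(0), n = double(0),
                          flagged = logical(0)))
  }
  # Backbone: the true n sequence is decreasing, so every d=1 entry equals
  # the running maximum of the remaining values (a d>=2 entry sits below).
  accept_set <- function(v) {
    env <- rev(cummax(rev(v)))
    acc <- v >= env - backbone_tol
    if (!any(acc)) acc[which.max(v)] <- TRUE
    acc
  }

  n <- raw_n
  d <- rep(1L, k)
  flagged <- logical(k)
  accepted <- accept_set(raw_n)
  choose <- function(j, refj, ub = Inf) {
    cand <- seq_len(d_max) * raw_n[j]
    # admissible multipliers must land near an integer count; the noise
    # allowance grows with the magnitude of the inferred count
    int_ok <- abs(cand - round(cand)) <= 0.25 + 0.002 * cand
    feas <- cand <= ub + 0.5
    pool <- which(int_ok & feas)
    if (length(pool) == 0L) pool <- which(feas)
    if (length(pool) == 0L) pool <- seq_len(d_max)
    resid <- abs(cand - refj)
    dj <- pool[which.min(resid[pool])]   # ties: first, i.e. smallest d
    list(d = dj, n = cand[dj], bad = resid[dj] > max(1, 0.05 * abs(refj)))
  }
  for (iter in seq_len(max_iter)) {
    ref <- interp_reference(which(accepted), n, k)
    # the envelope always accepts the endpoints, so their reference must
    # come from the other accepted values (leave-one-out extrapolation)
    for (jend in unique(c(1L, k))) {
      rest <- setdiff(which(accepted), jend)
      if (length(rest) >= 2L) {
        ref[jend] <- interp_reference(rest, n, k)[jend]
      }
    }
    changed <- FALSE
    for (j in seq_len(k)) {
      res <- choose(j, ref[j])
      if (res$d != d[j]) changed <- TRUE
      d[j] <- res$d; n[j] <- res$n; flagged[j] <- res$bad
    }
    acc2 <- accept_set(n)
    if (!changed && identical(acc2, accepted)) break
    accepted <- acc2
  }
  # feasibility sweep: the at-risk sequence can never rebound above what the
  # previous risk set leaves behind
  for (j in seq_len(k)[-1]) {
    ub <- n[j - 1] - d[j - 1]
    if (n[j] > ub + 0.5) {
      res <- choose(j, ref[j], ub = ub)
      d[j] <- res$d; n[j] <- res$n
    }
  }
  # a row is ambiguous when a second admissible multiple sits nearly as close
  # to the monotone reference as the chosen one (within one subject), or when
  # the choice still overshoots what the previous risk set leaves behind
  for (j in seq_len(k)) {
    ub <- if (j > 1) n[j - 1] - d[j - 1] else Inf
    if (n[j] > ub + 0.5) {
      flagged[j] <- TRUE
      next
    }
    cand <- seq_len(d_max) * raw_n[j]
    pool <- which(abs(cand - round(cand)) <= 0.25 + 0.002 * cand &
                    cand <= ub + 0.5)
    if (length(pool) == 0L) pool <- seq_len(d_max)
    rs <- sort(abs(cand[pool] - ref[j]))
    flagged[j] <- length(pool) > 1L && (rs[2] - rs[1]) < 1
  }
  if (any(flagged)) {
    warn(sprintf(
      "%d jump(s) had no multiplicity candidate close to the monotone reference; best guesses returned",
      sum(flagged)))
  }
  tibble::tibble(raw_n = raw_n, d = d, n = n, flagged = flagged)
}

# Linear interpolation of accepted values over index positions, with linear
# extrapolation beyond the first/last accepted entry.
interp_reference <- function(bidx, vals, k) {
  if (length(bidx) == 0L) return(rep(NA_real_, k))
  if (length(bidx) == 1L) return(rep(vals[bidx[1]], k))
  ref <- stats::approx(bidx, vals[bidx], xout = seq_len(k), rule = 2)$y
  b1 <- bidx[1]; b2 <- bidx[2]
  s <- (vals[b2] - vals[b1]) / (b2 - b1)
  before <- which(seq_len(k) < b1)
  ref[before] <- vals[b1] + s * (before - b1)
  bl <- bidx[length(bidx)]; bl1 <- bidx[length(bidx) - 1L]
  s <- (vals[bl] - vals[bl1]) / (bl - bl1)
  after <- which(seq_len(k) > bl)
  ref[after] <- vals[bl] + s * (after - bl)
  ref
}

#' Reconstruct the integer risk-set table from a step curve
#'
#' The package's core inversion: per-jump numbers at risk are inferred from
#' the estimator appropriate to the curve type (assuming one event per jump),
#' tied event counts are resolved with [detect_multiplicities()], the
#' corrected values are rounded to integers, and the censoring counts follow
#' by subtraction through the bookkeeping identity
#' `n_{j+1} = n_j - d_j - c_j`.  The final row's censoring count is the
#' number still at risk after its events (everyone remaining leaves
#' event-free).
#'
#' @param curve A (snapped, monotone) `step_curve`.
#' @param marks Optional `censor_marks` from [detect_censor_marks()].  Used
#'   downstream for censoring placement and, for the final event time only,
#'   to resolve a genuine ambiguity: a last jump can equally mean a small
#'   risk set after heavy censoring or a larger one with tied events, and
#'   only the number of visible marks just before it separates the two.
#' @param n0 Optional known initial sample size; adds `c_0 = n_0 - n_1`
#'   subjects censored before the first event.
#' @param reported_at_risk Optional data frame (`t`, `n`) of numbers at risk
#'   printed under the figure; each anchor overrides the inferred `n` at the
#'   nearest jump time and censoring is re-balanced around it.
#' @param d_max Largest tied-event multiplicity considered.
#' @param residue_warn Warn when a corrected `n` is farther than this from an
#'   integer (default 0.25); if more than 10% of rows exceed it the input is
#'   rejected as insufficiently precise.
#' @return A tibble of class `risk_set_table` with columns `t`, `n`, `d`,
#'   `c` and attributes `n0`, `c0`, `curve_type`, `end_time`.
#' @examples
#' curve <- km_curve(aml_maintained())$curve
#' reconstruct_risk_table(step_curve(curve[, c("t", "S")]))
#' @export
reconstruct_risk_table <- function(curve, marks = NULL, n0 = NULL,
                                   reported_at_risk = NULL, d_max = 5,
                                   residue_warn = 0.25) {
  jr <- jumps_and_ratios(curve)
  type <- curve_type(curve)
  raw_n <- switch(type,
    survival = infer_n_km(jr$S_prev, jr$S, 1),
    cumulative_hazard = infer_n_na(jr$S_prev, jr$S, 1),
    cumulative_incidence = infer_n_ci(jr$S_prev, jr$S, 1))
  mult <- detect_multiplicities(raw_n, d_max = d_max)

  n_int <- round(mult$n)
  residue <- abs(mult$n - n_int)
  if (any(residue > residue_warn)) {
    if (mean(residue > residue_warn) > 0.10) {
      abort(paste("insufficient precision: integer rounding residue exceeds",
                  residue_warn, "on more than 10% of rows; use a vector",
                  "(PostScript) source if available"),
            class = "kmrecover_insufficient_precision")
    }
    warn(sprintf("%d inferred n value(s) had rounding residue > %.2f",
                 sum(residue > residue_warn), residue_warn))
  }

  d <- mult$d
  k <- length(n_int)
  if (!is.null(marks) && k >= 2L) {
    # final-row disambiguation: match the implied censoring count in the
    # last inter-event interval to the visible marks there
    m_last <- sum(marks$t > jr$t[k - 1] & marks$t < jr$t[k])
    ub <- n_int[k - 1] - d[k - 1]
    cand <- seq_len(d_max) * mult$raw_n[k]
    ok <- abs(cand - round(cand)) <= 0.25 + 0.002 * cand & cand <= ub + 0.5
    if (any(ok)) {
      pool <- which(ok)
      imp_c <- ub - round(cand[pool])
      # marks undercount censoring (a "t+" censoring has no mark), so the
      # implied count must be at least the marks seen; take the smallest
      # admissible censoring, falling back to the closest
      geq <- pool[imp_c >= m_last]
      best <- if (length(geq)) {
        geq[order(imp_c[match(geq, pool)], geq)][1]
      } else pool[order(abs(imp_c - m_last), pool)][1]
      d[k] <- best
      n_int[k] <- round(cand[best])
    }
  }
  if (!is.null(marks)) {
    rep_res <- repair_with_marks(jr$t, n_int, d, mult$raw_n, marks, d_max)
    n_int <- rep_res$n
    d <- rep_res$d
  }
  if (!is.null(reported_at_risk)) {
    ra <- as.data.frame(reported_at_risk)
    for (i in seq_len(nrow(ra))) {
      j <- which.min(abs(jr$t - ra$t[i]))
      n_int[j] <- ra$n[i]
    }
  }

  k <- length(n_int)
  c_j <- c(n_int[-k] - d[-k] - n_int[-1], n_int[k] - d[k])
  if (any(c_j < 0)) {
    bad <- which(c_j < 0)
    abort(sprintf(
      "negative implied censoring count at t = %s; inconsistent heights or anchors",
      paste(signif(jr$t[bad], 6), collapse = ", ")),
      class = "kmrecover_negative_censoring")
  }
  if (any(n_int < d)) abort("inferred n below d; inconsistent curve")

  c0 <- if (!is.null(n0)) {
    if (n0 < n_int[1]) abort("supplied n0 is below the inferred number at the first event")
    n0 - n_int[1]
  } else 0L
  out <- tibble::new_tibble(
    tibble::tibble(t = jr$t, n = as.integer(n_int), d = as.integer(d),
                   c = as.integer(c_j)),
    class = "risk_set_table")
  attr(out, "n0") <- as.integer(n0 %||% n_int[1])
  attr(out, "c0") <- as.integer(c0)
  attr(out, "curve_type") <- type
  attr(out, "end_time") <- attr(curve, "end_time") %||% max(jr$t)
  attr(out, "marks") <- marks
  attr(out, "residue") <- residue
  out
}

# Enforce consistency between the implied censoring counts and the visible
# censor marks: c_j = n_j - d_j - n_{j+1} can never be smaller than the
# number of marks strictly inside (t_j, t_{j+1}) (marks only ever
# *undercount* censoring, since a "t+" censoring has no mark).  A violation
# means a jump was mis-attributed; re-choose among integer-admissible
# multiples, preferring the implied count closest to the marks seen, the
# fewest changes, and the smallest multiplicities.
repair_with_marks <- function(t, n, d, raw, marks, d_max, max_pass = 4) {
  k <- length(n)
  if (k == 0L) return(list(n = n, d = d))
  upper <- c(t[-1], Inf)
  m <- vapply(seq_len(k), function(j) {
    sum(marks$t > t[j] & marks$t < upper[j])
  }, double(1))
  cand_for <- function(j) {
    cand <- seq_len(d_max) * raw[j]
    ok <- abs(cand - round(cand)) <= 0.25 + 0.002 * cand
    if (!any(ok)) return(data.frame(d = d[j], n = n[j]))
    data.frame(d = which(ok), n = round(cand[ok]))
  }
  cands <- lapply(seq_len(k), cand_for)
  lex_lt <- function(a, b) {
    for (i in seq_along(a)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    FALSE
  }
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    for (j in seq_len(k)) {
      c_now <- if (j < k) n[j] - d[j] - n[j + 1] else n[j] - d[j]
      if (c_now >= m[j]) next
      cj <- cands[[j]]
      cj1 <- if (j < k) cands[[j + 1]] else data.frame(d = 0L, n = 0)
      best <- NULL; bestscore <- NULL
      for (a in seq_len(nrow(cj))) {
        for (b in seq_len(nrow(cj1))) {
          nj <- cj$n[a]; dj <- cj$d[a]
          nj1 <- cj1$n[b]; dj1 <- cj1$d[b]
          cc <- nj - dj - nj1
          if (cc < m[j]) next
          if (j > 1 && n[j - 1] - d[j - 1] - nj < m[j - 1]) next
          if (j < k - 1 && nj1 - dj1 - n[j + 2] < 0) next
          nch <- (nj != n[j]) + (j < k && nj1 != n[j + 1])
          score <- c(cc - m[j], nch, dj + dj1)
          if (is.null(bestscore) || lex_lt(score, bestscore)) {
            bestscore <- score
            best <- c(nj, dj, nj1, dj1)
          }
        }
      }
      if (is.null(best) && j > 1L) {
        # the violation may extend one row upstream (a run of consecutive
        # tied-event times): search the (j-1, j, j+1) window jointly
        cjm <- cands[[j - 1]]
        for (p in seq_len(nrow(cjm))) {
          njm <- cjm$n[p]; djm <- cjm$d[p]
          if (j > 2 && n[j - 2] - d[j - 2] - njm < m[j - 2]) next
          for (a in seq_len(nrow(cj))) {
            for (b in seq_len(nrow(cj1))) {
              nj <- cj$n[a]; dj <- cj$d[a]
              nj1 <- cj1$n[b]; dj1 <- cj1$d[b]
              ccm <- njm - djm - nj
              cc <- nj - dj - nj1
              if (ccm < m[j - 1] || cc < m[j]) next
              if (j < k - 1 && nj1 - dj1 - n[j + 2] < 0) next
              if (j == k && nj1 != 0) next
              nch <- (njm != n[j - 1]) + (nj != n[j]) +
                (j < k && nj1 != n[j + 1])
              score <- c(cc - m[j] + ccm - m[j - 1], nch, djm + dj + dj1)
              if (is.null(bestscore) || lex_lt(score, bestscore)) {
                bestscore <- score
                best <- c(nj, dj, nj1, dj1, njm, djm)
              }
            }
          }
        }
      }
      if (!is.null(best)) {
        if (best[1] != n[j] || best[2] != d[j]) changed <- TRUE
        n[j] <- best[1]; d[j] <- as.integer(best[2])
        if (j < k && (best[3] != n[j + 1] || best[4] != d[j + 1])) {
          changed <- TRUE
          n[j + 1] <- best[3]; d[j + 1] <- as.integer(best[4])
        }
        if (length(best) >= 6L &&
            (best[5] != n[j - 1] || best[6] != d[j - 1])) {
          changed <- TRUE
          n[j - 1] <- best[5]; d[j - 1] <- as.integer(best[6])
        }
      }
    }
    if (!changed) break
  }
  list(n = n, d = d)
}

#' @export
print.risk_set_table <- function(x, ...) {
  cat(sprintf("<risk_set_table: n0 = %d, %d event times, %d events, %d censored>\n",
              attr(x, "n0"), nrow(x), sum(x$d), sum(x$c) + attr(x, "c0")))
  NextMethod()
}

#' Lower bound on the initial sample size from the figure alone
#'
#' Every jump accounts for at least `d_j` subjects and every visible censor
#' mark for one more, so the initial number at risk is at least the sum of
#' jump multiplicities plus the mark count.  A lower bound only: censoring
#' tied to event times carries no mark.
#'
#' @param curve A `step_curve`.
#' @param marks Optional `censor_marks`.
#' @param d Optional integer vector of per-jump event counts (default: all 1,
#'   the pure what-you-see count).
#' @return Integer lower bound for `n_0`.
#' @export
infer_n0_lower_bound <- function(curve, marks = NULL, d = NULL) {
  n_jumps <- max(nrow(curve) - 1L, 0L)
  d <- d %||% rep(1L, n_jumps)
  sum(d) + (if (is.null(marks)) 0L else nrow(marks))
}

#' Reconstruct individual patient data from a risk-set table
#'
#' Emits `d_j` event records at each event time.  Censored subjects are
#' placed at their marked times when censor marks are available; censoring
#' detected with no mark in its interval is attributed to "immediately after"
#' the event (`t_j` plus a small epsilon), matching the convention that
#' packages record such times as `t+`.  Without marks, censored records are
#' spaced uniformly within their interval at `t_j + i/(c_j+1) * (t_{j+1} -
#' t_j)`.  Subjects censored after the last event are placed at marked times
#' beyond it, or at the curve's end of follow-up.
#'
#' @param table A `risk_set_table`.
#' @param marks Optional `censor_marks` (defaults to those attached to the
#'   table).
#' @param censor_placement `"marks"` (use marks where available, epsilon for
#'   unmarked, uniform as fallback) or `"uniform"`.
#' @param epsilon Offset for "immediately after an event" censoring; default
#'   `1e-9` times the time range.
#' @return A tibble of class `ipd` with columns `time` and `status`
#'   (1 event, 0 censored), one row per subject; `nrow` equals `n_0`.
#' @export
reconstruct_ipd <- function(table, marks = NULL,
                            censor_placement = c("marks", "uniform"),
                            epsilon = NULL) {
  stopifnot(inherits(table, "risk_set_table") || is.data.frame(table))
  censor_placement <- match.arg(censor_placement)
  marks <- marks %||% attr(table, "marks")
  if (censor_placement == "uniform") marks <- NULL
  end_time <- attr(table, "end_time") %||% max(table$t)
  c0 <- attr(table, "c0") %||% 0L
  eps <- epsilon %||% (1e-9 * max(end_time, max(table$t)))

  k <- nrow(table)
  rows <- list()
  if (c0 > 0) {
    # censored before the first event: uniform over (0, t_1)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      time = seq_len(c0) / (c0 + 1) * table$t[1], status = 0)
  }
  if (!is.null(marks) && nrow(marks) > 0 && sum(table$c) > 0) {
    marked_total <- sum(marks$t > 0)
    if (marked_total > sum(table$c)) {
      warn("more censor marks than inferred censored subjects; falling back to uniform placement")
      marks <- NULL
    }
  }
  for (j in seq_len(k)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(time = rep(table$t[j], table$d[j]),
                                                status = 1)
    cj <- table$c[j]
    if (cj == 0) next
    lo <- table$t[j]
    hi <- if (j < k) table$t[j + 1] else end_time
    placed <- NULL
    if (!is.null(marks) && nrow(marks) > 0) {
      in_int <- if (j < k) marks$t > lo & marks$t < hi else marks$t > lo
      mt <- sort(marks$t[in_int])
      if (length(mt) > cj) {
        warn(sprintf("more marks than censored subjects in (%g, %g); using uniform placement there",
                     lo, hi))
      } else {
        extra <- cj - length(mt)
        # unmarked censoring in a marked figure sits immediately after the event
        placed <- c(rep(lo + eps, extra), mt)
      }
    }
    if (is.null(placed)) {
      if (!is.null(marks)) {
        placed <- rep(lo + eps, cj)      # marks given but none here
        if (j == k) placed <- rep(end_time, cj)
      } else if (j == k) {
        placed <- rep(end_time, cj)   # trailing censored: end of follow-up
      } else {
        placed <- lo + seq_len(cj) / (cj + 1) * (hi - lo)
      }
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(time = placed, status = 0)
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$time, -.data$status)
  tibble::new_tibble(out, class = "ipd")
}

#' Person-time and event counts over a time grid
#'
#' Aggregates individual records (or a risk-set table, reconstructed on the
#' fly) into interval event counts and person-time: the integral of the
#' number at risk over each half-open interval `[a, b)`.  An event exactly on
#' a boundary counts in the interval that starts there.
#'
#' @param x An `ipd` tibble (`time`, `status`) or a `risk_set_table`.
#' @param boundaries Increasing time grid starting at 0; the last value caps
#'   follow-up for the table (times beyond it still contribute exposure up to
#'   the cap).
#' @return A tibble with columns `start`, `end`, `events`, `person_time`.
#' @examples
#' person_time(tibble::tibble(time = c(1, 2), status = c(1, 0)),
#'             boundaries = c(0, 2))
#' @export
person_time <- function(x, boundaries) {
  stopifnot(is.numeric(boundaries), length(boundaries) >= 2,
            all(diff(boundaries) > 0), boundaries[1] == 0)
  if (inherits(x, "risk_set_table")) x <- reconstruct_ipd(x)
  stopifnot(all(c("time", "status") %in% names(x)))
  a <- boundaries[-length(boundaries)]
  b <- boundaries[-1]
  events <- vapply(seq_along(a), function(i) {
    sum(x$status == 1 & x$time >= a[i] & x$time < b[i])
  }, double(1))
  pt <- vapply(seq_along(a), function(i) {
    sum(pmax(0, pmin(x$time, b[i]) - a[i]))
  }, double(1))
  tibble::tibble(start = a, end = b, events = as.integer(events),
                 person_time = pt)
}

#' Check a reconstruction against the curve it came from
#'
#' Recomputes the estimator implied by the table's `(n_j, d_j)` and reports
#' the maximum absolute height deviation from the input curve, plus any rows
#' violating the bookkeeping identity `n_{j+1} = n_j - d_j - c_j`.
#'
#' @param curve The input `step_curve`.
#' @param table The reconstructed `risk_set_table`.
#' @param noise_bound Height tolerance for the `pass` verdict (default
#'   `1e-6`).
#' @return A list with `max_deviation`, `deviation_by_time` (tibble `t`,
#'   `deviation`), `identity_violations` (row indices) and `pass`.
#' @export
validate_reconstruction <- function(curve, table, noise_bound = 1e-6) {
  if (nrow(table) == 0L || nrow(curve) < 2L) {
    return(list(max_deviation = 0, deviation_by_time = tibble::tibble(
      t = double(0), deviation = double(0)), identity_violations = integer(0),
      pass = TRUE))
  }
  S_hat <- estimator_heights(table$n, table$d, attr(table, "curve_type") %||%
                               curve_type(curve))
  S_obs <- curve$S[-1]
  m <- min(length(S_hat), length(S_obs))
  dev <- abs(S_hat[seq_len(m)] - S_obs[seq_len(m)])
  k <- nrow(table)
  viol <- which(table$n[-1] != table$n[-k] - table$d[-k] - table$c[-k])
  list(max_deviation = max(dev),
       deviation_by_time = tibble::tibble(t = table$t[seq_len(m)], deviation = dev),
       identity_violations = viol,
       pass = max(dev) <= noise_bound && length(viol) == 0L)
}

estimator_heights <- function(n, d, type) {
  switch(type,
    survival = cumprod(1 - d / n),
    cumulative_hazard = cumsum(d / n),
    cumulative_incidence = 1 - cumprod(1 - d / n))
}
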