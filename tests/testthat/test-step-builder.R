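test_that("the worked two-segment example builds one run and one jump", {
  cal <- worked_calibration()
  segs <- tibble::tibble(
    path_id = 1L,
    x0 = c(144, 146.88), y0 = c(300, 300),
    x1 = c(146.88, 146.88), y1 = c(300, 303),
    is_dot = FALSE)
  # a curve fragment: the origin-height check rightly warns
  curve <- suppressWarnings(build_step_curve(segs, cal, "survival",
                                             decimals = 3, snap = FALSE))
  jr <- jumps_and_ratios(curve)
  expect_equal(nrow(jr), 1L)
  expect_equal(jr$t, 2.6, tolerance = 1e-9)
  expect_equal(jr$S_prev, (360 - 300) / 108)
  expect_equal(jr$jump, 3 / 108, tolerance = 1e-9)
})

test_that("a horizontal run split into 40 collinear pieces merges to one", {
  cal <- worked_calibration()
  xs <- seq(72, 144, length.out = 41)
  split_run <- tibble::tibble(
    path_id = 1L, x0 = xs[-41], y0 = 252, x1 = xs[-1], y1 = 252,
    is_dot = FALSE)
  jump <- tibble::tibble(path_id = 1L, x0 = 144, y0 = 252, x1 = 144, y1 = 280,
                         is_dot = FALSE)
  whole <- tibble::tibble(path_id = 1L, x0 = 72, y0 = 252, x1 = 144, y1 = 252,
                          is_dot = FALSE)
  a <- build_step_curve(rbind(split_run, jump), cal, "survival", decimals = 3)
  b <- build_step_curve(rbind(whole, jump), cal, "survival", decimals = 3)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("build is idempotent on its own output's segments", {
  fit <- km_curve(aml_maintained())
  r <- render_postscript(fit, dialect = "segments", censor_style = "none")
  segs <- extract_paths(ps_tokenize(r$ps))
  g <- group_curves(segs)
  curve1 <- build_step_curve(g[[1]], r$calib, "survival")
  # redraw the built curve and rebuild
  r2 <- render_postscript(curve1, layout = r$layout, decimals = 6,
                          censor_style = "none")
  segs2 <- extract_paths(ps_tokenize(r2$ps))
  curve2 <- build_step_curve(group_curves(segs2)[[1]], r2$calib, "survival",
                             decimals = 6)
  expect_equal(curve2$t, curve1$t, tolerance = 1e-5)
  expect_equal(curve2$S, curve1$S, tolerance = 1e-5)
})

test_that("jump magnitudes sum exactly to the total drop after snapping", {
  sim <- simulate_study(40, hazard = 0.2, censoring = "uniform", seed = 3)
  p <- recover_pipeline(km_curve(sim$ipd))
  jr <- jumps_and_ratios(p$curve)
  expect_equal(sum(jr$jump), abs(p$curve$S[nrow(p$curve)] - p$curve$S[1]))
})

test_that("diagonal segments are rejected as not-a-step-function", {
  cal <- worked_calibration()
  segs <- tibble::tibble(path_id = 1L, x0 = c(72, 100), y0 = c(252, 252),
                         x1 = c(100, 140), y1 = c(252, 300), is_dot = FALSE)
  expect_error(build_step_curve(segs, cal, "survival"),
               class = "kmrecover_not_step")
})

test_that("group_curves separates arms by colour and warns on overlap", {
  red <- "1 0 0 setrgbcolor 0 10 moveto 5 10 lineto 5 8 lineto stroke"
  blue <- "0 0 1 setrgbcolor 0 9 moveto 4 9 lineto 4 6 lineto stroke"
  g <- group_curves(extract_paths(paste(red, blue)))
  expect_length(g, 2L)

  one <- group_curves(extract_paths(
    "0 10 moveto 5 10 lineto 5 8 lineto 9 8 lineto stroke"))
  expect_length(one, 1L)

  # two same-style arms sharing their origin: one group plus a warning
  overlapping <- paste(
    "0 10 moveto 6 10 lineto 6 8 lineto 12 8 lineto stroke",
    "0 9.5 moveto 8 9.5 lineto 8 5 lineto 12 5 lineto stroke")
  segs <- extract_paths(overlapping)
  segs$path_id <- 1L   # drawn as one stroked path
  expect_warning(group_curves(segs), "overlapping arms")
})

test_that("empty or segment-free input raises no-curve errors", {
  expect_error(group_curves(extract_paths("newpath")), "no curve-like path")
})

test_that("snap_monotone pools adjacent violators and guards large violations", {
  flat <- step_curve(tibble::tibble(t = 0:3, S = c(1, 0.8, 0.6, 0.4)))
  expect_identical(snap_monotone(flat, 1e-3), flat)

  noisy <- step_curve(tibble::tibble(t = 0:3, S = c(1, 0.90001, 0.90002, 0.85)))
  snapped <- snap_monotone(noisy, 1e-3)
  expect_equal(snapped$S, c(1, 0.900015, 0.900015, 0.85))
  expect_equal(attr(snapped, "snap_adjustment"), 1e-5, tolerance = 1e-9)

  bad <- step_curve(tibble::tibble(t = 0:3, S = c(1, 0.8, 0.85, 0.7)))
  expect_error(snap_monotone(bad, 1e-3), class = "kmrecover_monotonicity")
  expect_error(snap_monotone(bad, 1e-3), "t = 2")
})

test_that("AML tick rendering yields three censor marks", {
  p <- recover_pipeline(km_curve(aml_maintained()), censor_style = "tick")
  expect_equal(nrow(p$marks), 3L)
  expect_equal(sort(p$marks$t), c(28, 45, 161), tolerance = 1e-3)
  expect_true(all(p$marks$kind == "tick"))
})

test_that("per-observation dots off event corners are detected as marks", {
  p <- recover_pipeline(km_curve(aml_maintained()),
                        dialect = "per_observation_dots")
  # the subject censored at an event time ("13+") renders at a corner and is
  # classified as curve, not mark; the other three censored subjects show
  expect_equal(nrow(p$marks), 3L)
  expect_true(all(p$marks$kind == "dot"))
  expect_equal(sort(p$marks$t), c(28, 45, 161), tolerance = 1e-3)
})

test_that("a curve without censoring has no marks", {
  sim <- simulate_study(15, hazard = 0.3, censoring = "none", seed = 5)
  p <- recover_pipeline(km_curve(sim$ipd), censor_style = "tick")
  expect_equal(nrow(p$marks), 0L)
})

test_that("digitizer CSV input builds a curve directly", {
  f <- tempfile(fileext = ".csv")
  fit <- km_curve(aml_maintained())
  utils::write.csv(tidy(fit$curve)[, c("t", "S")], f, row.names = FALSE)
  curve <- read_digitizer_curve(f, "survival", end_time = 161)
  tab <- reconstruct_risk_table(curve)
  expect_equal(tab$n, c(11, 10, 8, 7, 5, 4, 2))
  unlink(f)
})
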