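# Shared fixtures: everything is generated in code at test time.

# The worked device geometry used in the documentation: 144-point x-axis for
# t in [0, 5], 108-point y-axis for S in [0, 1], heights measured downward
# from the top of the page.
worked_calibration <- function() {
  calibrate_axes(list(c(72, 0), c(216, 5)),
                 list(c(360, 0), c(252, 1)))
}

# Full recovery pipeline: render a fitted curve, extract, calibrate, build,
# detect marks, reconstruct.  Returns the pieces for inspection.
recover_pipeline <- function(fit, dialect = "segments", decimals = 3,
                             censor_style = "tick", d_max = 10) {
  r <- suppressWarnings(render_postscript(
    fit, dialect = dialect, decimals = decimals, censor_style = censor_style))
  segs <- extract_paths(ps_tokenize(r$ps))
  groups <- suppressWarnings(group_curves(segs))
  curve <- build_step_curve(groups[[1]], r$calib, "survival",
                            decimals = decimals)
  marks <- detect_censor_marks(segs, curve, r$calib, decimals = decimals)
  table <- suppressWarnings(
    reconstruct_risk_table(curve, marks = marks, d_max = d_max))
  list(render = r, segments = segs, curve = curve, marks = marks,
       table = table)
}

expect_table_equal <- function(rec, truth, t_tol = 0.05) {
  expect_equal(nrow(rec), nrow(truth))
  expect_equal(rec$n, truth$n)
  expect_equal(rec$d, truth$d)
  expect_equal(rec$c, truth$c)
  expect_lt(max(abs(rec$t - truth$t)), t_tol)
}
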