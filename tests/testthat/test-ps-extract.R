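test_that("tokenizer lexes numbers and operators, skipping comments and strings", {
  tk <- ps_tokenize("72 360 moveto")
  expect_equal(tk$value[1:2], c(72, 360))
  expect_equal(tk$text[3], "moveto")

  tk <- ps_tokenize("% comment\n1 2 lineto")
  expect_equal(tk$value[1:2], c(1, 2))
  expect_equal(tk$text[3], "lineto")

  tk <- ps_tokenize("(text) show 3 4 rlineto")
  expect_equal(tk$text, c("show", "3", "4", "rlineto"))
  expect_equal(tk$value[2:3], c(3, 4))

  # procedure bodies are retained as opaque blocks
  tk <- ps_tokenize("/f { 1 add } def 5 moveto")
  expect_true(any(tk$type == "proc"))
  expect_equal(tk$value[tk$type == "number"], 5)
})

test_that("binary input is rejected with the offending byte offset", {
  f <- tempfile(fileext = ".ps")
  writeBin(as.raw(c(0x25, 0x50, 0x44, 0x46, 0x00, 0x01)), f)
  expect_error(read_ps_segments(f), "not a PostScript text file",
               class = "kmrecover_binary_input")
  expect_error(read_ps_segments(f), "offset 4")
  unlink(f)
})

test_that("absolute and relative path operators produce the documented segments", {
  segs <- extract_paths("72 360 moveto 216 360 lineto stroke")
  expect_equal(nrow(segs), 1L)
  expect_equal(unlist(segs[1, c("x0", "y0", "x1", "y1")], use.names = FALSE),
               c(72, 360, 216, 360))

  segs <- extract_paths("0 0 moveto 10 0 rlineto 0 5 rlineto stroke")
  expect_equal(nrow(segs), 2L)
  expect_equal(unlist(segs[1, c("x0", "y0", "x1", "y1")], use.names = FALSE),
               c(0, 0, 10, 0))
  expect_equal(unlist(segs[2, c("x0", "y0", "x1", "y1")], use.names = FALSE),
               c(10, 0, 10, 5))
})

test_that("concat applies the affine map to path coordinates", {
  # oracle: independent hand application of (x,y) -> (2x + 10, 2y + 10)
  segs <- extract_paths("2 0 0 2 10 10 concat 1 1 moveto 2 1 lineto stroke")
  expect_equal(unlist(segs[1, c("x0", "y0", "x1", "y1")], use.names = FALSE),
               c(12, 12, 14, 12))
})

test_that("CTM composition equals post-hoc affine mapping of endpoints", {
  set.seed(41)
  base <- "3 7 moveto 20 7 lineto 20 30 lineto stroke"
  plain <- extract_paths(base)
  for (rep in 1:8) {
    m <- round(runif(6, -3, 3), 3)
    if (abs(m[1] * m[4] - m[2] * m[3]) < 0.1) next
    prog <- paste(paste(m, collapse = " "), "concat", base)
    got <- extract_paths(prog)
    fx <- function(x, y) m[1] * x + m[3] * y + m[5]
    fy <- function(x, y) m[2] * x + m[4] * y + m[6]
    expect_equal(got$x0, fx(plain$x0, plain$y0), tolerance = 1e-9)
    expect_equal(got$y0, fy(plain$x0, plain$y0), tolerance = 1e-9)
    expect_equal(got$x1, fx(plain$x1, plain$y1), tolerance = 1e-9)
    expect_equal(got$y1, fy(plain$x1, plain$y1), tolerance = 1e-9)
  }
})

test_that("translate, scale and rotate compose like the equivalent concat", {
  a <- extract_paths("10 20 translate 2 3 scale 1 1 moveto 4 1 lineto stroke")
  b <- extract_paths("2 0 0 3 10 20 concat 1 1 moveto 4 1 lineto stroke")
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
  r <- extract_paths("90 rotate 1 0 moveto 2 0 lineto stroke")
  expect_equal(unlist(r[1, c("x0", "y0", "x1", "y1")], use.names = FALSE),
               c(0, 1, 0, 2), tolerance = 1e-12)
})

test_that("gsave/grestore wrapping is a no-op and underflow is an error", {
  plain <- extract_paths("5 5 moveto 9 5 lineto stroke")
  wrapped <- extract_paths(
    "gsave 2 2 scale grestore 5 5 moveto 9 5 lineto stroke gsave grestore")
  expect_equal(as.data.frame(plain), as.data.frame(wrapped))
  expect_error(extract_paths("grestore"), "empty graphics-state stack",
               class = "kmrecover_parse_error")
  expect_error(extract_paths("1 1 moveto grestore"), "token 4")
})

test_that("unknown operators are skipped and counted, never fatal", {
  segs <- extract_paths("/Helvetica findfont 12 scalefont setfont 1 1 moveto 2 2 lineto stroke")
  expect_equal(nrow(segs), 1L)
  sk <- attr(segs, "skipped_ops")
  expect_true(all(c("findfont", "scalefont", "setfont") %in% names(sk)))
})

test_that("curveto is flattened to its chord with a warning", {
  expect_warning(
    segs <- extract_paths("0 0 moveto 1 2 3 2 4 0 curveto stroke"),
    "curveto")
  expect_equal(unlist(segs[1, c("x0", "y0", "x1", "y1")], use.names = FALSE),
               c(0, 0, 4, 0))
})

test_that("stroke attributes and dot flags are tracked per segment", {
  prog <- paste(
    "2 setlinewidth 1 0 0 setrgbcolor 0 0 moveto 1 0 lineto stroke",
    "0.5 setgray 5 5 moveto 5 5 lineto stroke")
  segs <- extract_paths(prog)
  expect_equal(segs$linewidth, c(2, 2))
  expect_equal(segs$red, c(1, 0.5))
  expect_equal(segs$is_dot, c(FALSE, TRUE))
  expect_equal(segs$path_id, c(1L, 2L))
})

test_that("segments_to_table keeps one row per segment and handles empties", {
  segs <- extract_paths("72 360 moveto 216 360 lineto stroke")
  tab <- segments_to_table(segs)
  expect_equal(nrow(tab), 1L)
  expect_named(tab, c("path_id", "x0", "y0", "x1", "y1", "is_dot", "length"))

  empty <- segments_to_table(extract_paths("newpath"))
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("path_id", "x0", "y0", "x1", "y1", "is_dot", "length"))
})

test_that("per-observation rendering yields one curve element per subject", {
  sim <- simulate_study(50, hazard = 0.2, censoring = "uniform", seed = 7)
  fit <- km_curve(sim$ipd)
  r <- render_postscript(fit, dialect = "per_observation_dots", decimals = 3)
  segs <- extract_paths(ps_tokenize(r$ps))
  curve_elements <- segs[segs$linewidth == 0.5, ]
  expect_equal(nrow(curve_elements), 50L)
})

test_that("renderer emits only operators the extractor interprets", {
  fit <- km_curve(aml_maintained())
  for (dial in c("segments", "per_observation_dots", "elaborate")) {
    r <- render_postscript(fit, dialect = dial, decimals = 3)
    segs <- extract_paths(ps_tokenize(r$ps))
    sk <- attr(segs, "skipped_ops")
    # the only uninterpreted tokens are the header's def/showpage scaffolding
    expect_true(all(names(sk) %in% c("def", "showpage", "pop")))
  }
})

test_that("renderer round-trip recovers segment coordinates to the rounding", {
  fit <- km_curve(aml_maintained())
  r <- render_postscript(fit, dialect = "segments", decimals = 3,
                         censor_style = "none")
  segs <- extract_paths(ps_tokenize(r$ps))
  curve_segs <- segs[segs$linewidth == 0.5, ]
  # corner coordinates, re-derived independently from the fitted curve,
  # all appear among the extracted endpoints to within the 3-decimal rounding
  v <- data_to_device(tidy(fit$curve)[, c("t", "S")], r$calib)
  ex <- c(curve_segs$x0, curve_segs$x1)
  ey <- c(curve_segs$y0, curve_segs$y1)
  for (i in seq_len(nrow(v))) {
    expect_lt(min(abs(v$x[i] - ex)), 5.5e-4)
    expect_lt(min(abs(v$y[i] - ey)), 5.5e-4)
  }
})
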