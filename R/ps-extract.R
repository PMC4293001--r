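#' Tokenize PostScript program text
#'
#' Splits PostScript source into numbers, executable names and opaque
#' procedure bodies.  Comments (`%` to end of line), string literals
#' (`(...)`, with nesting and backslash escapes) and hex strings (`<...>`)
#' are skipped: none of them can contribute path geometry.  Procedure
#' bodies `{ ... }` are retained as single opaque tokens so that the path
#' interpreter can step over them.
#'
#' @param text A character vector holding PostScript source (elements are
#'   joined with newlines), as produced by exporting a PDF page to
#'   PostScript.
#' @param max_bytes Maximum accepted input size in bytes (guards against
#'   accidentally feeding a whole print job); default 100 MB.
#' @return A tibble with one row per token: `text` (the token as written),
#'   `type` (`"number"`, `"operator"`, `"literal"` or `"proc"`) and `value`
#'   (the parsed number, `NA` otherwise).
#' @examples
#' ps_tokenize("72 360 moveto 216 360 lineto stroke")
#' @seealso [extract_paths()], [read_ps_segments()]
#' @export
ps_tokenize <- function(text, max_bytes = 1e8) {
  stopifnot(is.character(text))
  src <- paste(text, collapse = "\n")
  raw <- charToRaw(src)
  if (length(raw) > max_bytes) {
    abort(sprintf("input exceeds max_bytes (%d > %g)", length(raw), max_bytes))
  }
  assert_text_bytes(raw)

  chars <- strsplit(src, "", fixed = TRUE)[[1]]
  n <- length(chars)
  ws <- c(" ", "\t", "\n", "\r", "\f")
  delims <- c("(", ")", "<", ">", "[", "]", "{", "}", "/", "%")

  toks <- character(0)
  types <- character(0)
  buf_start <- 0L  # 0 = no word being accumulated

  push_word <- function(i_end) {
    if (buf_start > 0L) {
      word <- substr(src, buf_start, i_end)
      toks[[length(toks) + 1L]] <<- word
      types[[length(types) + 1L]] <<- classify_ps_word(word)
      buf_start <<- 0L
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (buf_start > 0L && (ch %in% ws || ch %in% delims)) push_word(i - 1L)
    if (ch %in% ws) {
      i <- i + 1L
    } else if (ch == "%") {
      while (i <= n && chars[[i]] != "\n") i <- i + 1L
    } else if (ch == "(") {
      depth <- 1L
      i <- i + 1L
      while (i <= n && depth > 0L) {
        if (chars[[i]] == "\\") i <- i + 1L
        else if (chars[[i]] == "(") depth <- depth + 1L
        else if (chars[[i]] == ")") depth <- depth - 1L
        i <- i + 1L
      }
    } else if (ch == "<") {
      # hex string or dict mark; skip to closing > (dict tokens are ignored
      # downstream anyway)
      i <- i + 1L
      if (i <= n && chars[[i]] == "<") {  # '<<' dict mark
        toks[[length(toks) + 1L]] <- "<<"
        types[[length(types) + 1L]] <- "operator"
        i <- i + 1L
      } else {
        while (i <= n && chars[[i]] != ">") i <- i + 1L
        i <- i + 1L
      }
    } else if (ch == ">") {
      i <- i + 1L
      if (i <= n && chars[[i]] == ">") i <- i + 1L
    } else if (ch == "{") {
      depth <- 1L
      j <- i + 1L
      while (j <= n && depth > 0L) {
        if (chars[[j]] == "{") depth <- depth + 1L
        if (chars[[j]] == "}") depth <- depth - 1L
        j <- j + 1L
      }
      toks[[length(toks) + 1L]] <- substr(src, i, j - 1L)
      types[[length(types) + 1L]] <- "proc"
      i <- j
    } else if (ch == "}") {
      i <- i + 1L  # stray close brace: ignore
    } else if (ch == "/") {
      j <- i + 1L
      while (j <= n && !(chars[[j]] %in% ws) && !(chars[[j]] %in% delims)) j <- j + 1L
      toks[[length(toks) + 1L]] <- substr(src, i, j - 1L)
      types[[length(types) + 1L]] <- "literal"
      i <- j
    } else if (ch %in% c("[", "]")) {
      toks[[length(toks) + 1L]] <- ch
      types[[length(types) + 1L]] <- "operator"
      i <- i + 1L
    } else {
      if (buf_start == 0L) buf_start <- i
      i <- i + 1L
    }
  }
  push_word(n)

  value <- rep(NA_real_, length(toks))
  is_num <- types == "number"
  value[is_num] <- as.numeric(unlist(toks)[is_num])
  tibble::tibble(text = unlist(toks) %||% character(0),
                 type = types %||% character(0),
                 value = value)
}

classify_ps_word <- function(word) {
  if (grepl("^[+-]?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?$", word)) "number"
  else "operator"
}

# Reject binary (e.g. PDF) input early, naming the first offending byte.
assert_text_bytes <- function(raw) {
  bad <- raw < as.raw(0x09) |
    (raw > as.raw(0x0d) & raw < as.raw(0x20) & raw != as.raw(0x1b))
  if (any(bad)) {
    abort(sprintf(
      "not a PostScript text file: binary byte 0x%02x at offset %d",
      as.integer(raw[which(bad)[1]]), which(bad)[1] - 1L),
      class = "kmrecover_binary_input")
  }
  invisible(TRUE)
}

#' Extract stroked line segments from PostScript tokens
#'
#' Interprets the path-construction and graphics-state subset of PostScript
#' (`moveto`, `lineto`, `rmoveto`, `rlineto`, `closepath`, `newpath`,
#' `stroke`, `gsave`/`grestore`, `translate`, `scale`, `rotate`, `concat`,
#' `setlinewidth`, `setrgbcolor`, `setgray`) and emits every stroked line
#' segment in device coordinates (printer points, 72 per inch), with the
#' current transformation matrix applied.  `curveto` is flattened to its
#' chord with a warning — genuine curves inside a step-function figure mean
#' the file needs manual inspection.  All other operators are skipped and
#' counted; unstroked path content is discarded.
#'
#' @param tokens A token tibble from [ps_tokenize()], or a character string
#'   of PostScript source (tokenized on the fly).
#' @param snap_tol Euclidean length at or below which a segment is classified
#'   as a dot (`is_dot`); default `1e-6` points.  Zero-length elements are
#'   how some packages draw censored subjects.
#' @return A tibble of class `ps_segments`, one row per stroked segment:
#'   `path_id` (1-based index of the stroke that produced it), `x0`, `y0`,
#'   `x1`, `y1`, `is_dot`, `length`, `linewidth`, `red`, `green`, `blue`.
#'   The attribute `skipped_ops` holds a named count of uninterpreted
#'   operators.
#' @examples
#' extract_paths("72 360 moveto 216 360 lineto stroke")
#' @export
extract_paths <- function(tokens, snap_tol = 1e-6) {
  if (is.character(tokens)) tokens <- ps_tokenize(tokens)
  stopifnot(is.data.frame(tokens))

  # CTM as a 6-vector (a b c d e f): device = (a x + c y + e, b x + d y + f)
  ctm <- c(1, 0, 0, 1, 0, 0)
  gstack <- list()
  attrs <- list(linewidth = 1, col = c(0, 0, 0))
  cp <- NULL                    # current point, device space
  subpaths <- list()            # completed subpaths (device-space matrices)
  cur <- NULL                   # open subpath
  path_id <- 0L
  stack <- numeric(0)
  skipped <- integer(0)
  n_curveto <- 0L
  out <- list()

  xf <- function(x, y) c(ctm[1] * x + ctm[3] * y + ctm[5],
                         ctm[2] * x + ctm[4] * y + ctm[6])
  inv_xf <- function(p) {
    det <- ctm[1] * ctm[4] - ctm[2] * ctm[3]
    u <- p[1] - ctm[5]; v <- p[2] - ctm[6]
    c((ctm[4] * u - ctm[3] * v) / det, (ctm[1] * v - ctm[2] * u) / det)
  }
  # row-vector convention: CTM' = A . CTM
  compose <- function(a) {
    c(a[1] * ctm[1] + a[2] * ctm[3],
      a[1] * ctm[2] + a[2] * ctm[4],
      a[3] * ctm[1] + a[4] * ctm[3],
      a[3] * ctm[2] + a[4] * ctm[4],
      a[5] * ctm[1] + a[6] * ctm[3] + ctm[5],
      a[5] * ctm[2] + a[6] * ctm[4] + ctm[6])
  }
  pop <- function(k) {
    if (length(stack) < k) return(NULL)
    v <- stack[(length(stack) - k + 1L):length(stack)]
    stack <<- stack[seq_len(length(stack) - k)]
    v
  }
  open_subpath <- function(p) {
    if (!is.null(cur) && nrow(cur) >= 2L) subpaths[[length(subpaths) + 1L]] <<- cur
    cur <<- matrix(p, ncol = 2)
  }
  add_point <- function(p) {
    if (is.null(cur)) cur <<- matrix(p, ncol = 2)
    else cur <<- rbind(cur, p)
  }
  clear_path <- function() { subpaths <<- list(); cur <<- NULL }

  for (k in seq_len(nrow(tokens))) {
    type <- tokens$type[k]
    if (type == "number") { stack <- c(stack, tokens$value[k]); next }
    if (type != "operator") next  # literals / procs carry no geometry
    op <- tokens$text[k]
    switch(op,
      "newpath" = { clear_path(); cp <- NULL },
      "moveto" = { v <- pop(2); if (!is.null(v)) { cp <- xf(v[1], v[2]); open_subpath(cp) } },
      "lineto" = { v <- pop(2); if (!is.null(v)) { cp <- xf(v[1], v[2]); add_point(cp) } },
      "rmoveto" = { v <- pop(2); if (!is.null(v) && !is.null(cp)) {
        cp <- xf(inv_xf(cp)[1] + v[1], inv_xf(cp)[2] + v[2]); open_subpath(cp) } },
      "rlineto" = { v <- pop(2); if (!is.null(v) && !is.null(cp)) {
        cp <- xf(inv_xf(cp)[1] + v[1], inv_xf(cp)[2] + v[2]); add_point(cp) } },
      "curveto" = { v <- pop(6); if (!is.null(v)) {
        n_curveto <- n_curveto + 1L; cp <- xf(v[5], v[6]); add_point(cp) } },
      "rcurveto" = { v <- pop(6); if (!is.null(v) && !is.null(cp)) {
        n_curveto <- n_curveto + 1L
        cp <- xf(inv_xf(cp)[1] + v[5], inv_xf(cp)[2] + v[6]); add_point(cp) } },
      "closepath" = { if (!is.null(cur) && nrow(cur) >= 2L) cur <- rbind(cur, cur[1, ]) },
      "stroke" = {
        if (!is.null(cur) && nrow(cur) >= 2L) subpaths[[length(subpaths) + 1L]] <- cur
        cur <- NULL
        if (length(subpaths)) {
          path_id <- path_id + 1L
          for (sp in subpaths) {
            dimnames(sp) <- NULL
            m <- nrow(sp)
            if (m < 2L) next
            out[[length(out) + 1L]] <- tibble::tibble(
              path_id = path_id,
              x0 = sp[-m, 1], y0 = sp[-m, 2],
              x1 = sp[-1, 1], y1 = sp[-1, 2],
              linewidth = attrs$linewidth,
              red = attrs$col[1], green = attrs$col[2], blue = attrs$col[3])
          }
        }
        clear_path(); cp <- NULL
      },
      "gsave" = { gstack[[length(gstack) + 1L]] <- list(ctm = ctm, attrs = attrs) },
      "grestore" = {
        if (length(gstack) == 0L) {
          abort(sprintf("grestore with empty graphics-state stack at token %d", k),
                class = "kmrecover_parse_error")
        }
        st <- gstack[[length(gstack)]]
        gstack[[length(gstack)]] <- NULL
        ctm <- st$ctm; attrs <- st$attrs
      },
      "translate" = { v <- pop(2); if (!is.null(v)) ctm <- compose(c(1, 0, 0, 1, v[1], v[2])) },
      "scale" = { v <- pop(2); if (!is.null(v)) ctm <- compose(c(v[1], 0, 0, v[2], 0, 0)) },
      "rotate" = { v <- pop(1); if (!is.null(v)) {
        th <- v * pi / 180
        ctm <- compose(c(cos(th), sin(th), -sin(th), cos(th), 0, 0)) } },
      "concat" = { v <- pop(6); if (!is.null(v)) ctm <- compose(v) },
      "setlinewidth" = { v <- pop(1); if (!is.null(v)) attrs$linewidth <- v },
      "setrgbcolor" = { v <- pop(3); if (!is.null(v)) attrs$col <- v },
      "setgray" = { v <- pop(1); if (!is.null(v)) attrs$col <- rep(v, 3) },
      {
        prev <- skipped[op]
        skipped[op] <- if (length(prev) == 0L || is.na(prev)) 1L else prev + 1L
      }
    )
  }

  if (n_curveto > 0L) {
    warn(sprintf(
      "%d curveto operator(s) flattened to chords; inspect the source figure",
      n_curveto))
  }

  segs <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    path_id = integer(0), x0 = double(0), y0 = double(0),
    x1 = double(0), y1 = double(0),
    linewidth = double(0), red = double(0), green = double(0), blue = double(0))
  segs$length <- sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2)
  segs$is_dot <- segs$length <= snap_tol
  segs <- segs[, c("path_id", "x0", "y0", "x1", "y1", "is_dot", "length",
                   "linewidth", "red", "green", "blue")]
  structure(segs,
            class = c("ps_segments", class(tibble::tibble())),
            skipped_ops = skipped)
}

#' Read a PostScript file and extract its stroked segments
#'
#' Convenience wrapper: reads the file, rejects binary (e.g. PDF) input,
#' tokenizes and runs [extract_paths()].
#'
#' @param file Path to a PostScript text file.
#' @inheritParams extract_paths
#' @inheritParams ps_tokenize
#' @return A `ps_segments` tibble; see [extract_paths()].
#' @export
read_ps_segments <- function(file, snap_tol = 1e-6, max_bytes = 1e8) {
  info <- file.info(file)
  if (is.na(info$size)) abort(sprintf("file not found: %s", file))
  if (info$size > max_bytes) {
    abort(sprintf("input exceeds max_bytes (%d > %g)", info$size, max_bytes))
  }
  raw <- readBin(file, "raw", n = info$size)
  assert_text_bytes(raw)
  extract_paths(ps_tokenize(rawToChar(raw), max_bytes = max_bytes),
                snap_tol = snap_tol)
}

#' Flatten a segment list to a plain exportable table
#'
#' Strips the extractor's stroke attributes down to the canonical
#' column set used for CSV interchange.
#'
#' @param segments A `ps_segments` tibble (or any data frame with the
#'   geometry columns).
#' @return A tibble with columns `path_id`, `x0`, `y0`, `x1`, `y1`,
#'   `is_dot`, `length`; one row per segment.
#' @export
segments_to_table <- function(segments) {
  cols <- c("path_id", "x0", "y0", "x1", "y1", "is_dot", "length")
  if (nrow(segments) == 0L) {
    return(tibble::tibble(path_id = integer(0), x0 = double(0), y0 = double(0),
                          x1 = double(0), y1 = double(0), is_dot = logical(0),
                          length = double(0)))
  }
  tibble::as_tibble(as.data.frame(segments)[, cols])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
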