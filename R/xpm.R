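#' Read a GROMACS .xpm matrix
#'
#' Parses the XPixMap dialect GROMACS writes for colour-coded matrices
#' (DSSP secondary-structure assignments, binned inter-residue distances).
#' The header line declares `ncols nrows ncolors chars_per_pixel`; the
#' following `ncolors` lines map each pixel code to a colour and a quoted
#' legend label; pixel rows follow, one quoted string per matrix row.
#' Optional `x-axis:` / `y-axis:` comment blocks are captured as tick values.
#'
#' @param path Path to an .xpm file.
#' @return An object of class `xpm_matrix`: a list with `ncols`, `nrows`,
#'   `chars_per_pixel`, `legend` (tibble: `code`, `label`, `lo`, `hi`,
#'   `value` — `lo`/`hi` from range labels such as `"0.1-0.2"`, `value` the
#'   midpoint or single number, `NA` for categorical labels), `codes` (an
#'   `nrows` x `ncols` character matrix in file row order), `x_ticks`,
#'   `y_ticks` and `title`.
#' @export
read_xpm <- function(path) {
  if (!file.exists(path)) {
    stop("xpm file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  title <- ""
  x_ticks <- numeric(0)
  y_ticks <- numeric(0)
  strings <- character(0)
  labels <- character(0)

  for (ln in lines) {
    t <- trimws(ln)
    if (startsWith(t, "/*")) {
      body <- sub("^/\\*", "", sub("\\*/$", "", t))
      if (grepl("^\\s*title:", body)) {
        m <- regmatches(body, regexpr('"[^"]*"', body))
        if (length(m)) title <- substr(m, 2L, nchar(m) - 1L)
      } else if (grepl("^\\s*x-axis:", body)) {
        x_ticks <- c(x_ticks, scan_ticks(body))
      } else if (grepl("^\\s*y-axis:", body)) {
        y_ticks <- c(y_ticks, scan_ticks(body))
      }
      next
    }
    qm <- regexpr('"[^"]*"', t)
    if (qm > 0L) {
      q <- regmatches(t, qm)
      strings <- c(strings, substr(q, 2L, nchar(q) - 1L))
      rest <- substr(t, qm + attr(qm, "match.length"), nchar(t))
      lm <- regmatches(rest, regexpr('/\\*\\s*"[^"]*"\\s*\\*/', rest))
      lab <- NA_character_
      if (length(lm)) {
        inner <- regmatches(lm, regexpr('"[^"]*"', lm))
        lab <- substr(inner, 2L, nchar(inner) - 1L)
      }
      labels <- c(labels, lab)
    }
  }
  if (length(strings) < 2L) {
    stop("not a parseable xpm file (no header/pixel strings): ", path,
         call. = FALSE)
  }
  hdr <- suppressWarnings(as.integer(strsplit(trimws(strings[1]), "\\s+")[[1]]))
  if (length(hdr) != 4L || anyNA(hdr) || any(hdr < 1L)) {
    stop("malformed xpm header line in ", path, ": ", strings[1], call. = FALSE)
  }
  ncols <- hdr[1]; nrows <- hdr[2]; ncolors <- hdr[3]; cpp <- hdr[4]
  if (length(strings) != 1L + ncolors + nrows) {
    stop(sprintf(
      "xpm %s declares %d colour + %d pixel rows but contains %d strings",
      path, ncolors, nrows, length(strings) - 1L), call. = FALSE)
  }
  color_strings <- strings[1L + seq_len(ncolors)]
  color_labels <- labels[1L + seq_len(ncolors)]
  legend <- parse_xpm_legend(color_strings, color_labels, cpp, path)
  pixel_strings <- strings[1L + ncolors + seq_len(nrows)]

  codes <- matrix(NA_character_, nrow = nrows, ncol = ncols)
  for (r in seq_len(nrows)) {
    row <- pixel_strings[r]
    if (nchar(row) != ncols * cpp) {
      stop(sprintf(
        "xpm pixel row %d in %s has %d characters, expected %d (ncols %d x %d chars/pixel)",
        r, path, nchar(row), ncols * cpp, ncols, cpp), call. = FALSE)
    }
    codes[r, ] <- substring(row, seq(1L, ncols * cpp, by = cpp),
                            seq(cpp, ncols * cpp, by = cpp))
  }
  unknown <- setdiff(unique(as.vector(codes)), legend$code)
  if (length(unknown)) {
    stop("xpm grid code(s) not declared in legend: ",
         paste(sprintf("'%s'", unknown), collapse = ", "),
         " (", path, ")", call. = FALSE)
  }
  structure(
    list(ncols = ncols, nrows = nrows, chars_per_pixel = cpp,
         legend = legend, codes = codes,
         x_ticks = x_ticks, y_ticks = y_ticks, title = title,
         source_path = path),
    class = "xpm_matrix"
  )
}

scan_ticks <- function(body) {
  payload <- sub("^\\s*[xy]-axis:\\s*", "", body)
  vals <- suppressWarnings(as.double(strsplit(trimws(payload), "\\s+")[[1]]))
  vals[!is.na(vals)]
}

parse_xpm_legend <- function(color_strings, color_labels, cpp, path) {
  n <- length(color_strings)
  code <- character(n); label <- character(n)
  lo <- rep(NA_real_, n); hi <- rep(NA_real_, n); value <- rep(NA_real_, n)
  num_re <- "[+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?"
  range_re <- sprintf("^\\s*(%s)\\s*[-–—]\\s*(%s)\\s*$", num_re, num_re)
  single_re <- sprintf("^\\s*(%s)\\s*$", num_re)
  for (i in seq_len(n)) {
    s <- color_strings[i]
    if (nchar(s) < cpp) {
      stop("xpm colour line shorter than chars_per_pixel in ", path,
           call. = FALSE)
    }
    code[i] <- substr(s, 1L, cpp)
    label[i] <- if (is.na(color_labels[i])) "" else color_labels[i]
    lab <- label[i]
    if (grepl(range_re, lab)) {
      lo[i] <- as.double(sub(range_re, "\\1", lab))
      hi[i] <- as.double(sub(range_re, "\\2", lab))
      value[i] <- (lo[i] + hi[i]) / 2
    } else if (grepl(single_re, lab)) {
      value[i] <- as.double(sub(single_re, "\\1", lab))
    }
  }
  if (anyDuplicated(code)) {
    stop("duplicate pixel codes in xpm legend: ", path, call. = FALSE)
  }
  tibble::tibble(code = code, label = label, lo = lo, hi = hi, value = value)
}

#' Convert an xpm matrix to numeric values
#'
#' Maps every grid cell to its legend value: range labels (`"lo-hi"`) map to
#' the range midpoint (GROMACS bins distances into colour levels; the midpoint
#' is the unbiased representative), single-number labels to that number.
#'
#' @param m An `xpm_matrix`.
#' @return A numeric `nrows` x `ncols` matrix (units as in the legend,
#'   typically nm for distance matrices).
#' @export
xpm_to_value_matrix <- function(m) {
  stopifnot(inherits(m, "xpm_matrix"))
  if (anyNA(m$legend$value)) {
    bad <- m$legend$label[is.na(m$legend$value)]
    stop("xpm legend is categorical, not numeric (labels: ",
         paste(sprintf("'%s'", bad), collapse = ", "),
         "); for DSSP assignments use classify_dssp()", call. = FALSE)
  }
  lut <- stats::setNames(m$legend$value, m$legend$code)
  matrix(lut[as.vector(m$codes)], nrow = m$nrows, ncol = m$ncols)
}

#' Write an xpm matrix in the GROMACS dialect
#'
#' Inverse of [read_xpm()]; used by the fixture generator and for round-trip
#' testing. Colours are synthesised from a grey ramp (the colour itself
#' carries no information; the legend label does).
#'
#' @param m An `xpm_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xpm <- function(m, path) {
  stopifnot(inherits(m, "xpm_matrix"))
  n <- nrow(m$legend)
  greys <- grDevices::grey(seq(0, 1, length.out = max(n, 2L)))[seq_len(n)]
  out <- c(
    "/* XPM */",
    sprintf('/* title:   "%s" */', m$title %||% ""),
    "static char *gromacs_xpm[] = {",
    sprintf('"%d %d   %d %d",', m$ncols, m$nrows, n, m$chars_per_pixel),
    sprintf('"%s  c %s " /* "%s" */,', m$legend$code, toupper(greys),
            m$legend$label)
  )
  if (length(m$x_ticks)) {
    out <- c(out, sprintf("/* x-axis:  %s */",
                          paste(format(m$x_ticks, trim = TRUE), collapse = " ")))
  }
  if (length(m$y_ticks)) {
    out <- c(out, sprintf("/* y-axis:  %s */",
                          paste(format(m$y_ticks, trim = TRUE), collapse = " ")))
  }
  rows <- apply(m$codes, 1L, paste, collapse = "")
  out <- c(out, sprintf('"%s",', rows[-length(rows)]),
           sprintf('"%s"', rows[length(rows)]), "};")
  writeLines(out, path)
  invisible(path)
}

#' @export
print.xpm_matrix <- function(x, ...) {
  cat(sprintf("<xpm_matrix> %d x %d, %d legend entr%s, %d char/pixel\n",
              x$nrows, x$ncols, nrow(x$legend),
              if (nrow(x$legend) == 1L) "y" else "ies", x$chars_per_pixel))
  if (nzchar(x$title %||% "")) cat("  title:", x$title, "\n")
  print(x$legend, ...)
  invisible(x)
}
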