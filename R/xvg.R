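#' Read a GROMACS .xvg table
#'
#' Parses the xmgrace-annotated two-or-more-column text format that GROMACS
#' analysis tools emit. Lines starting with `#` are comments and are skipped;
#' lines starting with `@` are grace plot directives, of which `title`,
#' `xaxis label`, `yaxis label` and `s<N> legend` are interpreted and every
#' other directive is preserved verbatim. Data rows are whitespace-delimited
#' floats (fixed or exponent notation); all columns, including frame indices,
#' are parsed as double.
#'
#' @param path Path to an .xvg file.
#' @return A tibble with one column per data column (`V1`, `V2`, ... or
#'   legend-derived names are *not* applied; columns stay positional), of class
#'   `xvg_tbl`, carrying attributes `title`, `xlab`, `ylab`, `legends`
#'   (character vector indexed by value-column number), `directives` (the
#'   uninterpreted `@` lines) and `source_path`.
#' @examples
#' p <- tempfile(fileext = ".xvg")
#' writeLines(c("@ title \"RMSD\"", "0 0.1", "10 0.2"), p)
#' read_xvg(p)
#' @export
read_xvg <- function(path) {
  if (!file.exists(path)) {
    stop("xvg file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(trimws(lines, "left"), "#")
  is_grace <- startsWith(trimws(lines, "left"), "@")
  meta <- parse_grace_directives(lines[is_grace])
  data_lines <- lines[!is_comment & !is_grace & nzchar(trimws(lines))]
  if (length(data_lines) == 0L) {
    stop("no data rows in xvg file: ", path, call. = FALSE)
  }
  cols <- parse_numeric_rows(data_lines, path)
  new_xvg_tbl(cols,
    title = meta$title, xlab = meta$xlab, ylab = meta$ylab,
    legends = meta$legends, directives = meta$directives,
    source_path = path
  )
}

#' Read a plain whitespace-delimited .dat table
#'
#' Same column contract as [read_xvg()] (`#` comments allowed, all columns
#' double) but with no grace metadata: CPPTRAJ-style or hand-made numeric
#' tables parse identically to an .xvg stripped of its `@` lines.
#'
#' @inheritParams read_xvg
#' @return An `xvg_tbl` with empty metadata.
#' @export
read_dat <- function(path) {
  if (!file.exists(path)) {
    stop("dat file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines, "left"), "#") & nzchar(trimws(lines))
  data_lines <- lines[keep]
  if (length(data_lines) == 0L) {
    stop("no data rows in dat file: ", path, call. = FALSE)
  }
  cols <- parse_numeric_rows(data_lines, path)
  new_xvg_tbl(cols, source_path = path)
}

#' Write an xvg table in the grace dialect
#'
#' Emits the interpreted metadata (`@ title`, axis labels, `s<N> legend`
#' lines), any preserved opaque directives, then whitespace-delimited rows at
#' 12 significant digits, so that [read_xvg()] round-trips both metadata and
#' values.
#'
#' @param table An `xvg_tbl` (or any data frame of equal-length numeric
#'   columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(table, path) {
  cols <- as.list(table)
  lens <- vapply(cols, length, integer(1))
  if (length(unique(lens)) > 1L) {
    stop("xvg columns must have identical length", call. = FALSE)
  }
  if (length(cols) == 0L || lens[1] == 0L) {
    stop("cannot write an empty xvg table", call. = FALSE)
  }
  hdr <- character(0)
  title <- attr(table, "title")
  if (!is.null(title) && nzchar(title)) hdr <- c(hdr, sprintf('@    title "%s"', title))
  xlab <- attr(table, "xlab")
  if (!is.null(xlab) && nzchar(xlab)) hdr <- c(hdr, sprintf('@    xaxis  label "%s"', xlab))
  ylab <- attr(table, "ylab")
  if (!is.null(ylab) && nzchar(ylab)) hdr <- c(hdr, sprintf('@    yaxis  label "%s"', ylab))
  legends <- attr(table, "legends")
  if (!is.null(legends)) {
    for (i in seq_along(legends)) {
      if (!is.na(legends[i]) && nzchar(legends[i])) {
        hdr <- c(hdr, sprintf('@ s%d legend "%s"', i - 1L, legends[i]))
      }
    }
  }
  directives <- attr(table, "directives")
  if (!is.null(directives)) hdr <- c(hdr, directives)
  mat <- vapply(cols, function(x) sprintf("%.12g", as.double(x)), character(lens[1]))
  if (lens[1] == 1L) mat <- matrix(mat, nrow = 1L)
  rows <- apply(mat, 1L, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

new_xvg_tbl <- function(cols, title = "", xlab = "", ylab = "",
                        legends = character(0), directives = character(0),
                        source_path = "") {
  names(cols) <- paste0("V", seq_along(cols))
  out <- tibble::as_tibble(cols)
  attr(out, "title") <- title %||% ""
  attr(out, "xlab") <- xlab %||% ""
  attr(out, "ylab") <- ylab %||% ""
  attr(out, "legends") <- legends %||% character(0)
  attr(out, "directives") <- directives %||% character(0)
  attr(out, "source_path") <- source_path
  class(out) <- c("xvg_tbl", class(out))
  out
}

# Interpret the small grace grammar the analyses need; keep the rest opaque.
parse_grace_directives <- function(grace_lines) {
  body <- sub("^\\s*@\\s*", "", grace_lines)
  title <- xlab <- ylab <- ""
  legends <- character(0)
  opaque <- character(0)
  quoted <- function(s) {
    m <- regmatches(s, regexpr('"[^"]*"', s))
    if (length(m) == 0L) "" else substr(m, 2L, nchar(m) - 1L)
  }
  for (i in seq_along(body)) {
    b <- body[i]
    if (grepl("^title\\s", b)) {
      title <- quoted(b)
    } else if (grepl("^xaxis\\s+label\\s", b)) {
      xlab <- quoted(b)
    } else if (grepl("^yaxis\\s+label\\s", b)) {
      ylab <- quoted(b)
    } else if (grepl("^s[0-9]+\\s+legend\\s", b)) {
      idx <- as.integer(sub("^s([0-9]+)\\s.*$", "\\1", b)) + 1L
      legends[idx] <- quoted(b)
    } else {
      opaque <- c(opaque, grace_lines[i])
    }
  }
  legends[is.na(legends)] <- ""
  list(title = title, xlab = xlab, ylab = ylab, legends = legends,
       directives = opaque)
}

# Split whitespace rows into equal-length double columns; reject ragged rows
# and non-numeric tokens with the offending line number.
parse_numeric_rows <- function(data_lines, path) {
  tokens <- strsplit(trimws(data_lines), "\\s+")
  nfield <- lengths(tokens)
  if (length(unique(nfield)) > 1L) {
    bad <- which(nfield != nfield[1])[1]
    stop(sprintf("ragged data row %d in %s: expected %d fields, found %d",
                 bad, path, nfield[1], nfield[bad]), call. = FALSE)
  }
  flat <- suppressWarnings(as.double(unlist(tokens)))
  if (anyNA(flat)) {
    bad_row <- ceiling(which(is.na(flat))[1] / nfield[1])
    stop(sprintf("non-numeric token in data row %d of %s", bad_row, path),
         call. = FALSE)
  }
  m <- matrix(flat, ncol = nfield[1], byrow = TRUE)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
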