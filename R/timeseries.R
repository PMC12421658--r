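#' Construct a time series from a parsed table
#'
#' Promotes an `xvg_tbl` (or any data frame) to a single-property time
#' series: column `time_col` becomes the axis, `value_col` the values. The
#' time unit is read from the table's x-axis label when it contains `(ps)`
#' or `(ns)`; absent a label, ps is assumed (the GROMACS default) unless
#' `unit` overrides it. For per-residue traces such as RMSF pass
#' `unit = "index"` — the axis is then a residue/atom index and is never
#' unit-converted.
#'
#' @param x An `xvg_tbl` or data frame with numeric columns.
#' @param value_col Index of the value column (default 2).
#' @param time_col Index of the axis column (default 1).
#' @param property Property name (e.g. `"RMSD"`); defaults to the table
#'   title, then the y-axis label.
#' @param replica Replica identifier string.
#' @param unit Time unit override: `"ps"`, `"ns"` or `"index"`.
#' @return A tibble with columns `time`, `value`, of class `time_series`,
#'   carrying attributes `property`, `replica` and `time_unit`.
#' @export
as_time_series <- function(x, value_col = 2L, time_col = 1L,
                           property = NULL, replica = "rep1", unit = NULL) {
  cols <- as.list(x)
  if (length(cols) < max(time_col, value_col)) {
    stop("table has fewer columns than requested indices", call. = FALSE)
  }
  time <- as.double(cols[[time_col]])
  value <- as.double(cols[[value_col]])
  if (length(time) < 1L) stop("empty time series", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("time axis must be strictly increasing to form a time series",
         call. = FALSE)
  }
  if (is.null(unit)) {
    xlab <- attr(x, "xlab") %||% ""
    unit <- if (grepl("\\(ns\\)", xlab)) "ns"
            else if (grepl("\\(ps\\)", xlab)) "ps"
            else "ps"
  }
  unit <- match.arg(unit, c("ps", "ns", "index"))
  if (is.null(property)) {
    property <- attr(x, "title") %||% ""
    if (!nzchar(property)) property <- attr(x, "ylab") %||% "value"
    if (!nzchar(property)) property <- "value"
  }
  out <- tibble::tibble(time = time, value = value)
  attr(out, "property") <- property
  attr(out, "replica") <- replica
  attr(out, "time_unit") <- unit
  class(out) <- c("time_series", class(out))
  out
}

#' Convert a time axis from picoseconds to nanoseconds
#'
#' GROMACS writes ps by default; plots use ns. A ps axis is divided by 1000
#' and retagged; an ns axis passes through unchanged; an index axis (RMSF)
#' is an error, as is any unknown unit tag.
#'
#' @param ts A `time_series` or `replica_set`.
#' @return The same object on an ns axis.
#' @export
to_nanoseconds <- function(ts) {
  unit <- attr(ts, "time_unit")
  if (is.null(unit) || !unit %in% c("ps", "ns")) {
    stop("cannot convert time unit '", unit %||% "<missing>",
         "' to nanoseconds (expected 'ps' or 'ns')", call. = FALSE)
  }
  if (unit == "ps") {
    ts$time <- ts$time / 1000
    attr(ts, "time_unit") <- "ns"
  }
  ts
}

# Internal inverse, used to verify the conversion round-trips.
to_picoseconds <- function(ts) {
  unit <- attr(ts, "time_unit")
  if (is.null(unit) || !unit %in% c("ps", "ns")) {
    stop("cannot convert time unit '", unit %||% "<missing>",
         "' to picoseconds", call. = FALSE)
  }
  if (unit == "ns") {
    ts$time <- ts$time * 1000
    attr(ts, "time_unit") <- "ps"
  }
  ts
}
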