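#' Canonical secondary-structure classes
#'
#' The six-class partition used throughout: alpha-helix, beta-sheet,
#' coil/loop, turn, bend, 3-helix.
#'
#' @export
ss_classes <- function() {
  c("alpha-helix", "beta-sheet", "coil/loop", "turn", "bend", "3-helix")
}

#' Default DSSP code to class mapping
#'
#' H -> alpha-helix; G -> 3-helix; E and B (isolated beta-bridge) ->
#' beta-sheet; T -> turn; S -> bend; C, `~`, blank and I (pi-helix) ->
#' coil/loop. B and I have no slot of their own in the six-class partition
#' and are folded into the nearest class to keep the partition exhaustive;
#' the mapping is user-overridable.
#'
#' @return A named character vector, code -> class.
#' @export
dssp_mapping <- function() {
  c(H = "alpha-helix", G = "3-helix", E = "beta-sheet", B = "beta-sheet",
    T = "turn", S = "bend", C = "coil/loop", "~" = "coil/loop",
    " " = "coil/loop", I = "coil/loop")
}

#' Classify a DSSP .xpm matrix into per-frame assignments
#'
#' Converts a GROMACS `do_dssp` colour matrix into a frame-major grid of the
#' six canonical classes. GROMACS puts residues on y and frames on x;
#' orientation is taken from the axis tick counts when present (the axis
#' whose tick count matches the frame count is the frame axis), else frames
#' are assumed on x, and the grid is transposed as needed so rows index
#' frames.
#'
#' @param m An `xpm_matrix` whose legend codes are DSSP codes.
#' @param mapping Named vector code -> class; default [dssp_mapping()].
#'   Codes are looked up first in the legend (via its code character), and
#'   any unmapped code is an error listing the known mapping.
#' @param frames_on Either `"auto"` (default), `"x"` or `"y"`.
#' @return An object of class `ss_assignments`: list with `classes` (an
#'   n_frames x n_residues character matrix of canonical classes),
#'   `frame_times` (numeric or NULL) and `n_residues`.
#' @export
classify_dssp <- function(m, mapping = dssp_mapping(), frames_on = "auto") {
  stopifnot(inherits(m, "xpm_matrix"))
  frames_on <- match.arg(frames_on, c("auto", "x", "y"))
  codes <- m$codes
  keys <- unique(as.vector(codes))
  unknown <- setdiff(keys, names(mapping))
  if (length(unknown)) {
    stop("DSSP code(s) with no class mapping: ",
         paste(sprintf("'%s'", unknown), collapse = ", "),
         "; known mapping: ",
         paste(sprintf("%s->%s", names(mapping), mapping), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(unname(mapping[keys])), ss_classes())
  if (length(bad)) {
    stop("mapping targets non-canonical class(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (frames_on == "auto") {
    frames_on <- "x"
    if (length(m$x_ticks) && length(m$y_ticks)) {
      # x ticks counting columns and y ticks counting rows is the GROMACS
      # frames-on-x layout; the reverse indicates a transposed grid
      if (length(m$y_ticks) == m$ncols && length(m$x_ticks) == m$nrows &&
          m$ncols != m$nrows) {
        frames_on <- "y"
      }
    }
  }
  # file rows are residues when frames run along x; transpose to frame-major
  cls <- matrix(unname(mapping[as.vector(codes)]),
                nrow = m$nrows, ncol = m$ncols)
  if (frames_on == "x") cls <- t(cls)
  frame_times <- NULL
  ticks <- if (frames_on == "x") m$x_ticks else m$y_ticks
  if (length(ticks) == nrow(cls)) frame_times <- ticks
  structure(
    list(classes = cls, frame_times = frame_times, n_residues = ncol(cls)),
    class = "ss_assignments"
  )
}

#' Per-frame secondary-structure probability (percent)
#'
#' For each frame i and class s the probability is the percentage of
#' residues adopting s: `P = N_is / N_total * 100`. The six classes
#' partition every frame, so the per-frame probabilities sum to 100.
#'
#' @param a An `ss_assignments`.
#' @return A tibble with columns `frame`, `time` (NA when the source had no
#'   tick times), `class` (factor over the six classes) and `probability`
#'   (percent), one row per frame per class.
#' @export
ss_probability <- function(a) {
  stopifnot(inherits(a, "ss_assignments"))
  counts <- ss_counts(a)
  counts$probability <- counts$count / a$n_residues * 100
  counts$count <- NULL
  counts
}

#' Per-frame secondary-structure fraction
#'
#' The proportion (0-1) of residues adopting each class per frame:
#' `F = N_is / N_total`, identically `probability / 100`.
#'
#' @param a An `ss_assignments`.
#' @return As [ss_probability()] but with a `fraction` column in 0-1.
#' @export
ss_fraction <- function(a) {
  stopifnot(inherits(a, "ss_assignments"))
  counts <- ss_counts(a)
  counts$fraction <- counts$count / a$n_residues
  counts$count <- NULL
  counts
}

ss_counts <- function(a) {
  lv <- ss_classes()
  n_frames <- nrow(a$classes)
  tab <- t(apply(a$classes, 1L, function(row) {
    tabulate(factor(row, levels = lv), nbins = length(lv))
  }))
  times <- if (is.null(a$frame_times)) rep(NA_real_, n_frames) else a$frame_times
  tidyr::expand_grid(frame = seq_len(n_frames), class = factor(lv, levels = lv)) |>
    dplyr::mutate(time = times[.data$frame],
                  count = as.vector(t(tab))) |>
    dplyr::select("frame", "time", "class", "count")
}

#' Five-number boxplot summary per group
#'
#' Median and quartiles (linear interpolation, type 7 by default), whiskers
#' at the most extreme observations within 1.5 IQR of the box, and the
#' observations beyond the whiskers as outliers — the numbers behind the
#' probability boxplots.
#'
#' @param data A data frame.
#' @param value Column holding the values (unquoted).
#' @param ... Grouping columns (unquoted), e.g. `class`.
#' @param quartile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return A tibble with one row per group: `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`, `n`, and `outliers` (list column).
#' @export
boxplot_summary <- function(data, value, ..., quartile_type = 7) {
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      stats = list(five_number({{ value }}, quartile_type)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("stats")
}

five_number <- function(x, quartile_type = 7) {
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = quartile_type))
  iqr <- q[3] - q[1]
  inside <- x[x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr]
  list(
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_lo = min(inside), whisker_hi = max(inside),
    n = length(x),
    outliers = list(sort(x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr]))
  )
}

#' Export per-frame secondary-structure fractions
#'
#' Writes the per-frame fraction table of one or more simulation groups in
#' wide form — first column the frame index (and time when known), then one
#' column per class per group — as a spreadsheet workbook plus a CSV twin.
#' The workbook uses the single-file SpreadsheetML XML format, which Excel
#' and LibreOffice open natively.
#'
#' @param profiles A named list of [ss_fraction()] tibbles (names are group
#'   labels), or a single tibble.
#' @param path Output stem or CSV path; `.csv` and `.xml` siblings are
#'   written.
#' @return Invisibly, a character vector of the two paths written.
#' @export
export_ss_fractions <- function(profiles, path) {
  if (is.data.frame(profiles)) profiles <- list(group = profiles)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- paste0("group", seq_along(profiles))
  }
  wides <- purrr::imap(profiles, function(p, label) {
    stopifnot(all(c("frame", "class", "fraction") %in% names(p)))
    w <- tidyr::pivot_wider(p, id_cols = c("frame", "time"),
                            names_from = "class", values_from = "fraction")
    # all six class columns always present, even when a class never occurs
    for (cl in setdiff(ss_classes(), names(w))) w[[cl]] <- 0
    names(w)[-(1:2)] <- paste(label, names(w)[-(1:2)], sep = ".")
    w
  })
  out <- purrr::reduce(wides, dplyr::full_join, by = c("frame", "time"))
  out <- dplyr::arrange(out, .data$frame)
  if (all(is.na(out$time))) out$time <- NULL
  stem <- sub("\\.(csv|xml|xlsx)$", "", path)
  csv_path <- paste0(stem, ".csv")
  xml_path <- paste0(stem, ".xml")
  utils::write.csv(format_num_df(out), csv_path, row.names = FALSE,
                   quote = FALSE)
  write_spreadsheetml(out, xml_path, sheet = "ss_fractions")
  invisible(c(csv = csv_path, workbook = xml_path))
}

format_num_df <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.12g", col) else col
  })
  df
}

# Minimal SpreadsheetML 2003 writer: one worksheet, typed cells.
write_spreadsheetml <- function(df, path, sheet = "Sheet1") {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  cell <- function(v) {
    if (is.numeric(v) && is.finite(v)) {
      sprintf('<Cell><Data ss:Type="Number">%.12g</Data></Cell>', v)
    } else {
      sprintf('<Cell><Data ss:Type="String">%s</Data></Cell>',
              esc(as.character(v)))
    }
  }
  header_row <- paste0("<Row>", paste(vapply(names(df), cell, character(1)),
                                      collapse = ""), "</Row>")
  body_rows <- vapply(seq_len(nrow(df)), function(i) {
    paste0("<Row>",
           paste(vapply(seq_along(df), function(j) cell(df[[j]][i]),
                        character(1)), collapse = ""),
           "</Row>")
  }, character(1))
  doc <- c(
    '<?xml version="1.0"?>',
    '<?mso-application progid="Excel.Sheet"?>',
    '<Workbook xmlns="urn:schemas-microsoft-com:office:spreadsheet"',
    ' xmlns:ss="urn:schemas-microsoft-com:office:spreadsheet">',
    sprintf('<Worksheet ss:Name="%s">', esc(sheet)),
    "<Table>", header_row, body_rows, "</Table>",
    "</Worksheet>", "</Workbook>"
  )
  writeLines(doc, path)
  invisible(path)
}

#' @export
print.ss_assignments <- function(x, ...) {
  cat(sprintf("<ss_assignments> %d frames x %d residues\n",
              nrow(x$classes), x$n_residues))
  tab <- sort(table(x$classes), decreasing = TRUE)
  cat("  overall composition:",
      paste(sprintf("%s %.1f%%", names(tab), 100 * tab / sum(tab)),
            collapse = ", "), "\n")
  invisible(x)
}
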