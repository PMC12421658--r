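#' Ligand occupancy map over the simulation-box XY plane
#'
#' Pools the (x, y) positions of every ligand atom in every frame (the z
#' coordinate is discarded — projection onto the XY plane), bins them on a
#' regular grid spanning the full box X and Y dimensions, and normalises the
#' counts by their maximum so the hottest bin has relative density 1.
#' Coordinates outside the box are wrapped modulo the box length (periodic
#' images) with a warning.
#'
#' @param coords A data frame with numeric columns `x`, `y` (a `z` column is
#'   allowed and ignored), in nm.
#' @param box_xy Box lengths `c(Lx, Ly)` in nm; bin ranges are the box
#'   dimensions, not the data range.
#' @param n_bins Bin counts `c(nx, ny)` (default `c(50, 50)`).
#' @return An object of class `occupancy_map`: list with `x_edges`,
#'   `y_edges`, `counts` (ny x nx integer matrix, `counts[j, i]` = bin
#'   (x_i, y_j)), `density` (counts / max), `n_samples`.
#' @export
occupancy_map <- function(coords, box_xy, n_bins = c(50L, 50L)) {
  if (!all(c("x", "y") %in% names(coords))) {
    stop("coords needs x and y columns", call. = FALSE)
  }
  x <- as.double(coords$x); y <- as.double(coords$y)
  if (length(x) == 0L) stop("occupancy_map: no coordinates", call. = FALSE)
  if (length(box_xy) != 2L || any(box_xy <= 0)) {
    stop("box_xy must be two positive lengths (nm)", call. = FALSE)
  }
  n_bins <- rep_len(as.integer(n_bins), 2L)
  if (any(n_bins < 1L)) stop("n_bins must be >= 1", call. = FALSE)
  if (any(x < 0 | x > box_xy[1] | y < 0 | y > box_xy[2])) {
    warning("coordinates outside the box were wrapped by the box length",
            call. = FALSE)
    x <- x %% box_xy[1]
    y <- y %% box_xy[2]
  }
  x_edges <- seq(0, box_xy[1], length.out = n_bins[1] + 1L)
  y_edges <- seq(0, box_xy[2], length.out = n_bins[2] + 1L)
  ix <- pmin(pmax(findInterval(x, x_edges, rightmost.closed = TRUE), 1L), n_bins[1])
  iy <- pmin(pmax(findInterval(y, y_edges, rightmost.closed = TRUE), 1L), n_bins[2])
  counts <- matrix(0L, nrow = n_bins[2], ncol = n_bins[1])
  tab <- table(factor(iy, levels = seq_len(n_bins[2])),
               factor(ix, levels = seq_len(n_bins[1])))
  counts[] <- as.integer(tab)
  density <- counts / max(max(counts), 1L)
  structure(
    list(x_edges = x_edges, y_edges = y_edges, counts = counts,
         density = density, n_samples = length(x)),
    class = "occupancy_map"
  )
}

#' @export
#' @importFrom generics tidy
tidy.occupancy_map <- function(x, ...) {
  nx <- length(x$x_edges) - 1L
  ny <- length(x$y_edges) - 1L
  xm <- (x$x_edges[-1] + x$x_edges[-(nx + 1L)]) / 2
  ym <- (x$y_edges[-1] + x$y_edges[-(ny + 1L)]) / 2
  cnt <- as.vector(t(x$counts))
  den <- as.vector(t(x$density))
  out <- tidyr::expand_grid(y = ym, x = xm)
  out$count <- cnt
  out$density <- den
  out[c("x", "y", "count", "density")]
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> %d x %d bins, %d samples, peak count %d\n",
              ncol(x$counts), nrow(x$counts), x$n_samples, max(x$counts)))
  invisible(x)
}

#' Inter-residue distance matrix with CSV sidecar
#'
#' Wraps a numeric pairwise-distance matrix (nm; typically
#' `xpm_to_value_matrix()` of a `gmx mdmat` .xpm) for heatmap display, with
#' both axes indexing residues along the sequence. When `sidecar` is given,
#' the matrix is written as CSV so the rendered figure is always backed by
#' its exact numbers.
#'
#' @param m A square numeric matrix.
#' @param residue_start First residue index (default 1); axis labels run
#'   `residue_start, residue_start + 1, ...`.
#' @param sidecar Optional CSV path to write the matrix to.
#' @return An object of class `distance_matrix` (list: `values`,
#'   `residues`).
#' @export
distance_heatmap <- function(m, residue_start = 1L, sidecar = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) {
    stop("distance matrix must be square, got ", nrow(m), " x ", ncol(m),
         call. = FALSE)
  }
  residues <- seq.int(residue_start, length.out = nrow(m))
  if (!is.null(sidecar)) {
    df <- as.data.frame(m)
    names(df) <- as.character(residues)
    utils::write.csv(cbind(residue = residues, format_num_df(df)), sidecar,
                     row.names = FALSE, quote = FALSE)
  }
  structure(list(values = m, residues = residues), class = "distance_matrix")
}

#' @export
#' @importFrom generics tidy
tidy.distance_matrix <- function(x, ...) {
  d <- as.vector(t(x$values))
  out <- tidyr::expand_grid(res_i = x$residues, res_j = x$residues)
  out$distance <- d
  out
}

#' Adopt a 2D PCA projection from a parsed table
#'
#' The principal components are computed upstream (e.g. `gmx anaeig -2d`);
#' this adopts the projection columns for the conformational-landscape
#' scatter. A 2-column table is read as (PC1, PC2); with 3+ columns the
#' first column is treated as time and dropped, columns 2-3 become PC1/PC2.
#' Temporal progression is encoded as `frame_order` in input order, the
#' colour axis of the scatter.
#'
#' @param table An `xvg_tbl` or data frame of numeric columns.
#' @return A tibble with columns `pc1`, `pc2`, `frame_order` (0-based), of
#'   class `pca_projection`.
#' @export
pca_scatter <- function(table) {
  cols <- as.list(table)
  if (length(cols) < 2L) {
    stop("PCA projection table needs at least 2 columns", call. = FALSE)
  }
  if (length(cols) >= 3L) cols <- cols[2:3]
  out <- tibble::tibble(pc1 = as.double(cols[[1]]),
                        pc2 = as.double(cols[[2]]),
                        frame_order = seq_along(cols[[1]]) - 1L)
  class(out) <- c("pca_projection", class(out))
  out
}
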