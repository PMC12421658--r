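#' Silverman's rule-of-thumb bandwidth
#'
#' `0.9 * min(sd, IQR/1.349) * n^(-1/5)`, the standard unopinionated default
#' for a Gaussian kernel. Degenerate samples (all observations identical, so
#' both spread measures vanish) fall back to a bandwidth of 1 with a warning.
#'
#' @param x Numeric observations.
#' @return A positive bandwidth.
#' @export
bw_silverman <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  iqr <- stats::IQR(x, type = 7) / 1.349
  spread <- if (n >= 2L) min(c(s, iqr)[c(s, iqr) > 0], Inf) else Inf
  if (!is.finite(spread)) {
    warning("observations have no spread; falling back to bandwidth h = 1",
            call. = FALSE)
    return(1)
  }
  0.9 * spread * n^(-1 / 5)
}

#' Gaussian kernel density estimate (1D)
#'
#' Each observation contributes a Gaussian kernel of width `h`; the estimate
#' at `x` is
#' `f(x) = 1/(n h sqrt(2 pi)) * sum_i exp(-(x - x_i)^2 / (2 h^2))`,
#' evaluated on `grid` (default: 512 evenly spaced points spanning the
#' observations plus/minus 4 bandwidths, so the estimate integrates to ~1).
#'
#' @param obs Numeric observations (n >= 1).
#' @param h Bandwidth; default Silverman's rule ([bw_silverman()]).
#' @param grid Evaluation points; default as above.
#' @param n_grid Grid size when `grid` is derived (default 512).
#' @return A tibble with columns `grid`, `density`, of class
#'   `density_estimate`, carrying `bandwidth` and `n_obs` attributes.
#' @examples
#' kde_1d(c(-1, 1), h = 1)
#' @export
kde_1d <- function(obs, h = NULL, grid = NULL, n_grid = 512L) {
  obs <- as.double(obs)
  n <- length(obs)
  if (n == 0L) stop("kde_1d: no observations", call. = FALSE)
  if (anyNA(obs)) stop("kde_1d: NA observations", call. = FALSE)
  if (is.null(h)) h <- bw_silverman(obs)
  if (!is.finite(h) || h <= 0) stop("kde_1d: bandwidth must be > 0", call. = FALSE)
  if (is.null(grid)) {
    grid <- seq(min(obs) - 4 * h, max(obs) + 4 * h, length.out = n_grid)
  }
  # outer() materialises the full grid x obs kernel matrix; fine at the
  # problem sizes here (<= a few 1e6 cells)
  z <- outer(grid, obs, "-") / h
  dens <- rowSums(exp(-z^2 / 2)) / (n * h * sqrt(2 * pi))
  out <- tibble::tibble(grid = grid, density = dens)
  attr(out, "bandwidth") <- h
  attr(out, "n_obs") <- n
  class(out) <- c("density_estimate", class(out))
  out
}

#' Product-Gaussian kernel density estimate (2D)
#'
#' The 2D analogue with a per-axis bandwidth:
#' `f(x, y) = 1/(n hx hy 2 pi) * sum_i exp(-(x-x_i)^2/(2 hx^2) - (y-y_i)^2/(2 hy^2))`,
#' evaluated on the tensor grid `x_grid` x `y_grid` (default: 128 points per
#' axis spanning the data plus/minus 4 per-axis bandwidths). Used for
#' Ramachandran (phi/psi), rotamer (chi1/chi2) and time-resolved dihedral
#' densities.
#'
#' @param xs,ys Paired observations (equal length, n >= 1).
#' @param hx,hy Per-axis bandwidths; default Silverman per axis.
#' @param x_grid,y_grid Evaluation grids; defaults as above.
#' @param n_grid Per-axis grid size when grids are derived (default 128).
#' @return An object of class `density_2d`: list with `x`, `y` (grid
#'   vectors), `z` (length(y) x length(x) density matrix, `z[j, i]` =
#'   density at `(x[i], y[j])`), `bandwidths`, `n_obs`.
#' @export
kde_2d <- function(xs, ys, hx = NULL, hy = NULL,
                   x_grid = NULL, y_grid = NULL, n_grid = 128L) {
  xs <- as.double(xs); ys <- as.double(ys)
  if (length(xs) != length(ys)) {
    stop("kde_2d: xs and ys must be paired (equal length)", call. = FALSE)
  }
  n <- length(xs)
  if (n == 0L) stop("kde_2d: no observations", call. = FALSE)
  if (is.null(hx)) hx <- bw_silverman(xs)
  if (is.null(hy)) hy <- bw_silverman(ys)
  if (hx <= 0 || hy <= 0) stop("kde_2d: bandwidths must be > 0", call. = FALSE)
  if (is.null(x_grid)) x_grid <- seq(min(xs) - 4 * hx, max(xs) + 4 * hx, length.out = n_grid)
  if (is.null(y_grid)) y_grid <- seq(min(ys) - 4 * hy, max(ys) + 4 * hy, length.out = n_grid)
  kx <- exp(-(outer(x_grid, xs, "-") / hx)^2 / 2)  # |x_grid| x n
  ky <- exp(-(outer(y_grid, ys, "-") / hy)^2 / 2)  # |y_grid| x n
  z <- ky %*% t(kx) / (n * hx * hy * 2 * pi)
  structure(
    list(x = x_grid, y = y_grid, z = z,
         bandwidths = c(hx = hx, hy = hy), n_obs = n),
    class = "density_2d"
  )
}

#' Augment angular observations with periodic images
#'
#' Optional edge correction for densities of angles near the +/-180 degree
#' seam: each observation is replicated at +360 and -360 degrees so a
#' non-periodic Gaussian kernel sees its wrap-around neighbours. The density
#' is then read off the central window only.
#'
#' @param angles Angles in degrees.
#' @return A vector of length `3 * length(angles)`.
#' @export
augment_periodic <- function(angles) {
  c(angles - 360, angles, angles + 360)
}

#' Trapezoidal integral of a 1D density estimate
#'
#' @param d A `density_estimate`.
#' @return The trapezoid-rule integral over its grid.
#' @export
kde_integral <- function(d) {
  stopifnot(inherits(d, "density_estimate"))
  g <- d$grid; f <- d$density
  sum(diff(g) * (f[-1] + f[-length(f)]) / 2)
}

#' @export
#' @importFrom generics glance
glance.density_estimate <- function(x, ...) {
  tibble::tibble(
    n_obs = attr(x, "n_obs"),
    bandwidth = attr(x, "bandwidth"),
    n_grid = nrow(x),
    integral = kde_integral(x),
    mode = x$grid[which.max(x$density)],
    peak = max(x$density)
  )
}

#' @export
#' @importFrom generics tidy
tidy.density_2d <- function(x, ...) {
  den <- as.vector(t(x$z))
  out <- tidyr::expand_grid(y = x$y, x = x$x)
  out$density <- den
  out[c("x", "y", "density")]
}

#' @export
print.density_2d <- function(x, ...) {
  cat(sprintf("<density_2d> %d x %d grid, n = %d, h = (%.4g, %.4g)\n",
              length(x$x), length(x$y), x$n_obs,
              x$bandwidths[["hx"]], x$bandwidths[["hy"]]))
  invisible(x)
}
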