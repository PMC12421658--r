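#' Wrap angles to the canonical interval [-180, 180)
#'
#' Dihedral angles are periodic (0 degrees is equivalent to 360), so every
#' angle is reduced modulo 360 into the Ramachandran convention
#' `[-180, 180)`; 180 maps to -180.
#'
#' @param deg Angles in degrees (finite).
#' @return Wrapped angles, congruent to the input modulo 360.
#' @export
wrap_angle <- function(deg) {
  if (any(!is.finite(deg))) {
    stop("wrap_angle: angles must be finite", call. = FALSE)
  }
  ((deg + 180) %% 360) - 180
}

#' Circular mean of angles in degrees
#'
#' The mean direction: `atan2(mean(sin), mean(cos))`, converted back to
#' degrees and wrapped to `[-180, 180)`. Required for dihedral data because
#' the arithmetic mean of e.g. 10 and 350 degrees (which straddle the seam)
#' is meaningless. The mean resultant length
#' `R = sqrt(mean(sin)^2 + mean(cos)^2)` measures concentration; when the
#' resultant (nearly) vanishes — e.g. \{0, 180\} — the mean direction is
#' undefined and `NaN` is returned with a warning, never a silent arbitrary
#' angle.
#'
#' @param angles Angles in degrees (n >= 1; any representatives, wrapped
#'   internally).
#' @param min_resultant Resultant length below which the mean is declared
#'   undefined (default 1e-9).
#' @return The mean direction in degrees, with attribute
#'   `resultant_length` (R in 0-1).
#' @examples
#' circular_mean(c(10, 350)) # 0
#' @export
circular_mean <- function(angles, min_resultant = 1e-9) {
  if (length(angles) == 0L) {
    stop("circular_mean: need at least one angle", call. = FALSE)
  }
  rad <- angles * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  r <- sqrt(s^2 + c^2)
  if (r < min_resultant) {
    warning("circular mean undefined: resultant length ",
            format(r, digits = 3), " < ", min_resultant, call. = FALSE)
    out <- NaN
  } else {
    out <- wrap_angle(atan2(s, c) * 180 / pi)
  }
  attr(out, "resultant_length") <- r
  out
}

#' Construct an angle series
#'
#' A dihedral angle sampled along simulation time, wrapped to `[-180, 180)`.
#'
#' @param time Time axis (strictly increasing).
#' @param angles Angles in degrees.
#' @param angle_name Name of the dihedral (e.g. `"phi"`, `"chi1"`,
#'   `"ligand"`).
#' @param replica Replica identifier.
#' @return A tibble with columns `time`, `angle`, of class `angle_series`,
#'   carrying `angle_name` and `replica` attributes.
#' @export
angle_series <- function(time, angles, angle_name = "dihedral",
                         replica = "rep1") {
  if (length(time) != length(angles)) {
    stop("angle_series: time and angles must have equal length", call. = FALSE)
  }
  if (length(time) >= 2L && is.unsorted(time, strictly = TRUE)) {
    stop("angle_series: time must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(time = as.double(time),
                        angle = wrap_angle(as.double(angles)))
  attr(out, "angle_name") <- angle_name
  attr(out, "replica") <- replica
  class(out) <- c("angle_series", class(out))
  out
}

#' Per-timepoint circular mean across replicas
#'
#' Averages a dihedral across replicas on a common time grid using the
#' circular mean at every timepoint; a single replica passes through
#' unchanged. Timepoints whose resultant vanishes yield `NaN` (see
#' [circular_mean()]).
#'
#' @param replicas A list of `angle_series` on identical time grids.
#' @return An `angle_series` of per-timepoint circular means (replica
#'   `"circular-mean"`).
#' @export
circular_mean_trace <- function(replicas) {
  if (inherits(replicas, "angle_series")) replicas <- list(replicas)
  if (length(replicas) == 0L) {
    stop("circular_mean_trace: need at least one replica", call. = FALSE)
  }
  t0 <- replicas[[1]]$time
  for (r in replicas) {
    if (length(r$time) != length(t0) || any(r$time != t0)) {
      stop("circular_mean_trace: replica time grids differ; align first",
           call. = FALSE)
    }
  }
  if (length(replicas) == 1L) return(replicas[[1]])
  mat <- vapply(replicas, `[[`, double(length(t0)), "angle")
  mat <- matrix(mat, nrow = length(t0))
  means <- apply(mat, 1L, function(a) suppressWarnings(as.double(circular_mean(a))))
  out <- angle_series(t0, ifelse(is.nan(means), 0, means),
                      angle_name = attr(replicas[[1]], "angle_name"),
                      replica = "circular-mean")
  out$angle[is.nan(means)] <- NaN
  out
}

#' Pool phi/psi observations across replicas
#'
#' Ramachandran densities are built by concatenating, not averaging, the
#' (phi, psi) pairs of every replica of a simulation group: pooling keeps
#' every sampled conformation and so depicts the whole conformational space
#' rather than a washed-out average.
#'
#' @param pairs A list of data frames with columns `phi` and `psi` (degrees),
#'   one per replica; each replica's columns must be equal length.
#' @return A tibble with columns `phi`, `psi`, `replica`; `nrow` equals the
#'   summed replica lengths.
#' @export
concat_replicas <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- list(pairs)
  if (length(pairs) == 0L) stop("concat_replicas: no replicas", call. = FALSE)
  purrr::imap(pairs, function(p, i) {
    if (!all(c("phi", "psi") %in% names(p))) {
      stop("concat_replicas: each replica needs phi and psi columns",
           call. = FALSE)
    }
    if (length(p$phi) != length(p$psi)) {
      stop("concat_replicas: phi/psi length mismatch in replica ", i,
           call. = FALSE)
    }
    tibble::tibble(phi = wrap_angle(p$phi), psi = wrap_angle(p$psi),
                   replica = if (is.character(i)) i else paste0("rep", i))
  }) |>
    dplyr::bind_rows()
}

#' Restrict a series to a time window
#'
#' Keeps the samples with `t0 <= time <= t1` (closed interval), for focused
#' analysis of a simulation interval (e.g. the equilibrated tail of a
#' rotamer trace). An empty result is returned as an empty series with a
#' warning.
#'
#' @param s An `angle_series`, `time_series`, or any data frame with a
#'   `time` column.
#' @param t0,t1 Window bounds (same unit as the series axis), `t0 <= t1`.
#' @return The filtered object, attributes preserved.
#' @export
time_window <- function(s, t0, t1) {
  if (t0 > t1) stop("time_window: t0 must be <= t1", call. = FALSE)
  keep <- s$time >= t0 & s$time <= t1
  if (!any(keep)) {
    warning("time_window [", t0, ", ", t1, "] contains no samples",
            call. = FALSE)
  }
  out <- s[keep, , drop = FALSE]
  for (a in setdiff(names(attributes(s)), c("row.names", "names", "class"))) {
    attr(out, a) <- attr(s, a)
  }
  class(out) <- class(s)
  out
}

#' Histogram of angles over the canonical circle
#'
#' Equal-width bins over `[-180, 180)`; every angle falls in exactly one
#' bin, so counts sum to the input length.
#'
#' @param angles Angles in degrees (wrapped internally).
#' @param n_bins Number of bins (>= 1; default 36, i.e. 10-degree bins).
#' @return A tibble with columns `bin_lo`, `bin_hi`, `mid`, `count`.
#' @export
angle_histogram <- function(angles, n_bins = 36L) {
  if (n_bins < 1L) stop("angle_histogram: n_bins must be >= 1", call. = FALSE)
  a <- wrap_angle(angles)
  width <- 360 / n_bins
  idx <- pmin(floor((a + 180) / width), n_bins - 1L)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  lo <- -180 + width * (seq_len(n_bins) - 1L)
  tibble::tibble(bin_lo = lo, bin_hi = lo + width, mid = lo + width / 2,
                 count = counts)
}
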