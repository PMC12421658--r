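#' Bundle replica time series of one simulation group
#'
#' A replica set holds every independent repetition of one simulation
#' condition for one property, in long form. There is no restriction on the
#' number of replicas; a single replica is a valid (degenerate) set.
#'
#' @param series A list of `time_series` objects sharing a property, or a
#'   single `time_series`.
#' @param group_label Label for the simulation group.
#' @return A long tibble with columns `replica`, `time`, `value`, of class
#'   `replica_set`, carrying `group_label`, `property` and `time_unit`
#'   attributes.
#' @export
replica_set <- function(series, group_label = "group") {
  if (inherits(series, "time_series")) series <- list(series)
  if (length(series) == 0L) {
    stop("a replica set needs at least one series", call. = FALSE)
  }
  props <- unique(vapply(series, function(s) attr(s, "property"), character(1)))
  if (length(props) > 1L) {
    stop("replicas mix properties: ", paste(props, collapse = ", "),
         call. = FALSE)
  }
  units <- unique(vapply(series, function(s) attr(s, "time_unit"), character(1)))
  if (length(units) > 1L) {
    stop("replicas mix time units (", paste(units, collapse = ", "),
         "); convert with to_nanoseconds() first", call. = FALSE)
  }
  ids <- vapply(seq_along(series), function(i) {
    r <- attr(series[[i]], "replica")
    if (is.null(r) || !nzchar(r)) paste0("rep", i) else r
  }, character(1))
  if (anyDuplicated(ids)) ids <- paste0(ids, "_", seq_along(ids))
  out <- dplyr::bind_rows(
    purrr::map2(series, ids, function(s, id) {
      tibble::tibble(replica = id, time = s$time, value = s$value)
    })
  )
  attr(out, "group_label") <- group_label
  attr(out, "property") <- props
  attr(out, "time_unit") <- units
  class(out) <- c("replica_set", class(out))
  out
}

rs_split <- function(rs) {
  split(rs[c("time", "value")], factor(rs$replica, unique(rs$replica)))
}

rs_rebuild <- function(parts, template) {
  out <- dplyr::bind_rows(purrr::imap(parts, function(p, id) {
    tibble::tibble(replica = id, time = p$time, value = p$value)
  }))
  for (a in c("group_label", "property", "time_unit")) {
    attr(out, a) <- attr(template, a)
  }
  class(out) <- c("replica_set", class(out))
  out
}

#' Align replicas onto a common axis
#'
#' Every downstream mean/SD needs replicas sampled on one grid. If all
#' replica axes already agree pointwise (within `rel_tol` of the sampling
#' interval, after truncation to the shortest series), the first replica's
#' axis is adopted. Otherwise all series are truncated to their overlapping
#' axis range and resampled onto the coarsest replica's grid by
#' nearest-neighbour lookup.
#'
#' @param rs A `replica_set`.
#' @param rel_tol Pointwise axis agreement tolerance, as a fraction of the
#'   median sampling interval (default 0.01).
#' @return A `replica_set` in which every replica shares one axis.
#' @export
align_replicas <- function(rs, rel_tol = 0.01) {
  stopifnot(inherits(rs, "replica_set"))
  parts <- rs_split(rs)
  if (length(parts) == 1L) return(rs)
  for (p in parts) {
    if (is.unsorted(p$time, strictly = TRUE)) {
      stop("replica axes must be strictly increasing", call. = FALSE)
    }
  }
  n_min <- min(vapply(parts, nrow, integer(1)))
  step <- stats::median(diff(parts[[1]]$time[seq_len(n_min)]))
  if (!is.finite(step) || step <= 0) step <- 1
  agree <- all(vapply(parts, function(p) {
    max(abs(p$time[seq_len(n_min)] - parts[[1]]$time[seq_len(n_min)])) <=
      rel_tol * step
  }, logical(1)))
  if (agree) {
    axis <- parts[[1]]$time[seq_len(n_min)]
    parts <- lapply(parts, function(p) {
      tibble::tibble(time = axis, value = p$value[seq_len(n_min)])
    })
    return(rs_rebuild(parts, rs))
  }
  lo <- max(vapply(parts, function(p) min(p$time), double(1)))
  hi <- min(vapply(parts, function(p) max(p$time), double(1)))
  if (lo > hi) {
    spans <- vapply(parts, function(p)
      sprintf("[%g, %g]", min(p$time), max(p$time)), character(1))
    stop("replica axes do not overlap: ",
         paste(names(parts), spans, collapse = "; "), call. = FALSE)
  }
  steps <- vapply(parts, function(p) stats::median(diff(p$time)), double(1))
  coarse <- parts[[which.max(steps)]]
  axis <- coarse$time[coarse$time >= lo & coarse$time <= hi]
  if (length(axis) == 0L) {
    stop("replica axis overlap contains no sample of the coarsest grid",
         call. = FALSE)
  }
  parts <- lapply(parts, function(p) {
    idx <- vapply(axis, function(t) which.min(abs(p$time - t)), integer(1))
    tibble::tibble(time = axis, value = p$value[idx])
  })
  rs_rebuild(parts, rs)
}

#' Mean and standard deviation across replicas
#'
#' The central descriptive statistic of every time-dependent analysis: the
#' per-timepoint arithmetic mean of the property across replicas, with the
#' sample standard deviation (n-1 denominator) as the uncertainty band. A
#' single replica yields its own values with an identically-zero band.
#'
#' @param rs A `replica_set` whose replicas share an axis (see
#'   [align_replicas()]).
#' @return A tibble with columns `time`, `mean`, `sd`, of class
#'   `summary_trace`, carrying `n_replicas`, `group_label`, `property` and
#'   `time_unit` attributes.
#' @export
summarize_replicas <- function(rs) {
  stopifnot(inherits(rs, "replica_set"))
  parts <- rs_split(rs)
  axes <- lapply(parts, `[[`, "time")
  same <- all(vapply(axes, function(a) {
    length(a) == length(axes[[1]]) && all(a == axes[[1]])
  }, logical(1)))
  if (!same) {
    stop("replica axes differ; run align_replicas() first", call. = FALSE)
  }
  vals <- vapply(parts, `[[`, double(length(axes[[1]])), "value")
  vals <- matrix(vals, nrow = length(axes[[1]]))
  n <- ncol(vals)
  m <- rowMeans(vals)
  s <- if (n >= 2L) apply(vals, 1L, stats::sd) else rep(0, nrow(vals))
  out <- tibble::tibble(time = axes[[1]], mean = m, sd = s)
  attr(out, "n_replicas") <- n
  attr(out, "group_label") <- attr(rs, "group_label")
  attr(out, "property") <- attr(rs, "property")
  attr(out, "time_unit") <- attr(rs, "time_unit")
  class(out) <- c("summary_trace", class(out))
  out
}

#' @export
#' @importFrom generics glance
glance.summary_trace <- function(x, ...) {
  tibble::tibble(
    group = attr(x, "group_label") %||% NA_character_,
    property = attr(x, "property") %||% NA_character_,
    n_replicas = attr(x, "n_replicas") %||% NA_integer_,
    n_points = nrow(x),
    mean_overall = mean(x$mean),
    sd_overall = stats::sd(x$mean)
  )
}

#' @export
#' @importFrom generics tidy
tidy.summary_trace <- function(x, ...) {
  tibble::tibble(time = x$time, mean = x$mean, sd = x$sd,
                 group = attr(x, "group_label") %||% NA_character_)
}
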