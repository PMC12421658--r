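#' Names of the available analyses
#' @return Character vector of valid `run_analysis()` names.
#' @export
analysis_names <- function() {
  c("rmsd", "rmsf", "gyrate", "sasa", "hbond", "saltbridge", "contacts",
    "hydrophobic", "mindist", "ss-probability", "ss-fraction", "pca",
    "occupancy", "dihedral", "distmat", "phipsi", "rotamers",
    "temperature", "pressure", "density")
}

#' Read an analysis configuration profile
#'
#' One declarative YAML file per run. Typical keys: `groups` (list of
#' `label` + `files`, plus analysis-specific entries), `colors`, `alpha`,
#' `bandwidth`, `bins`, `selection`, `time_window`, `box`, `n_bins`,
#' `figure` (`width`/`height`), `xlab`, `ylab`.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Run one analysis end to end
#'
#' Parses the configured input files, aggregates replicas per the analysis
#' contract (mean/SD summary, frame pooling, circular means, or
#' concatenation), and writes figure files (PNG + SVG), numeric CSV
#' sidecars, and a run log to `out_dir`. Time-dependent analyses also emit
#' their kernel-density companion. The returned (invisible) list carries
#' the computed objects so results can be checked against direct module
#' calls.
#'
#' @param name One of [analysis_names()].
#' @param config A configuration list (see [read_analysis_config()]), or a
#'   path to a YAML profile.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `files` (paths written) and `results`
#'   (the computed objects).
#' @export
run_analysis <- function(name, config, out_dir = ".") {
  if (!name %in% analysis_names()) {
    stop("unknown analysis '", name, "'; valid names: ",
         paste(analysis_names(), collapse = ", "), call. = FALSE)
  }
  if (is.character(config) && length(config) == 1L) {
    config <- read_analysis_config(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ctx <- new.env(parent = emptyenv())
  ctx$files <- character(0)
  ctx$log <- file.path(out_dir, paste0(gsub("[^a-z0-9]+", "_", name), ".log"))
  unlink(ctx$log)
  log_line(ctx, "analysis=%s version=%s", name,
           as.character(utils::packageVersion("mdspectra")))
  log_line(ctx, "out_dir=%s", normalizePath(out_dir))
  for (g in config$groups %||% list()) {
    log_line(ctx, "group=%s files=%s", g$label %||% "?",
             paste(unlist(g$files), collapse = ","))
  }
  results <- switch(
    name,
    "rmsf" = run_timeseries_analysis(name, config, out_dir, ctx, unit = "index"),
    "contacts" = ,
    "hbond" = ,
    "saltbridge" = run_timeseries_analysis(name, config, out_dir, ctx,
                                           nonneg = TRUE),
    "mindist" = run_mindist(config, out_dir, ctx),
    "hydrophobic" = run_hydrophobic(config, out_dir, ctx),
    "ss-probability" = run_ss(config, out_dir, ctx, what = "probability"),
    "ss-fraction" = run_ss(config, out_dir, ctx, what = "fraction"),
    "pca" = run_pca(config, out_dir, ctx),
    "occupancy" = run_occupancy(config, out_dir, ctx),
    "dihedral" = run_dihedral(config, out_dir, ctx),
    "distmat" = run_distmat(config, out_dir, ctx),
    "phipsi" = run_phipsi(config, out_dir, ctx),
    "rotamers" = run_rotamers(config, out_dir, ctx),
    run_timeseries_analysis(name, config, out_dir, ctx)
  )
  log_line(ctx, "status=ok files_written=%d", length(ctx$files))
  invisible(list(files = ctx$files, results = results, log = ctx$log))
}

log_line <- function(ctx, fmt, ...) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              sprintf(fmt, ...)),
      file = ctx$log, append = TRUE)
}

record_file <- function(ctx, path) {
  ctx$files <- c(ctx$files, path)
  path
}

write_figure <- function(ctx, plot, stem, config = list()) {
  fig <- config$figure %||% list()
  w <- fig$width %||% 7
  h <- fig$height %||% 4.5
  for (ext in c("png", "svg")) {
    path <- paste0(stem, ".", ext)
    ok <- tryCatch({
      if (ext == "svg") {
        grDevices::svg(path, width = w, height = h)
      } else {
        grDevices::png(path, width = w, height = h, units = "in", res = 150)
      }
      print(plot)
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      try(grDevices::dev.off(), silent = TRUE)
      warning("could not write figure ", path, ": ", conditionMessage(e),
              call. = FALSE)
      FALSE
    })
    if (ok) record_file(ctx, path)
  }
}

write_sidecar <- function(ctx, df, path) {
  utils::write.csv(format_num_df(as.data.frame(df)), path,
                   row.names = FALSE, quote = FALSE)
  record_file(ctx, path)
}

config_groups <- function(config) {
  groups <- config$groups
  if (is.null(groups) || length(groups) == 0L) {
    stop("config must define at least one group with replica files",
         call. = FALSE)
  }
  groups
}

read_group_series <- function(g, unit = NULL, value_col = 2L) {
  files <- unlist(g$files)
  if (length(files) == 0L) {
    stop("group '", g$label %||% "?", "' has no replica files", call. = FALSE)
  }
  prop <- NULL  # replicas of one group are one property; adopt the first's
  series <- lapply(seq_along(files), function(i) {
    tbl <- if (grepl("\\.dat$", files[i])) read_dat(files[i]) else read_xvg(files[i])
    s <- as_time_series(tbl, value_col = value_col, replica = paste0("rep", i),
                        unit = unit, property = prop)
    if (is.null(prop)) prop <<- attr(s, "property")
    s
  })
  replica_set(series, group_label = g$label %||% "group")
}

summarize_group <- function(g, unit = NULL, to_ns = TRUE, nonneg = FALSE) {
  rs <- read_group_series(g, unit = unit)
  if (nonneg && any(rs$value < 0)) {
    stop("group '", attr(rs, "group_label"),
         "': counts must be non-negative", call. = FALSE)
  }
  if (to_ns && attr(rs, "time_unit") %in% c("ps", "ns")) {
    rs <- to_nanoseconds(rs)
  }
  summarize_replicas(align_replicas(rs))
}

kde_companion <- function(ctx, name, groups_rs, config, out_dir) {
  kdes <- lapply(groups_rs, function(rs) {
    kde_1d(rs$value, h = config$bandwidth %||% NULL)
  })
  names(kdes) <- vapply(groups_rs, function(rs)
    attr(rs, "group_label") %||% "group", character(1))
  df <- dplyr::bind_rows(purrr::imap(kdes, function(k, lab) {
    tibble::tibble(group = lab, grid = k$grid, density = k$density)
  }))
  write_sidecar(ctx, df, file.path(out_dir, paste0(name, "_kde.csv")))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$grid, y = .data$density,
                                        colour = .data$group,
                                        fill = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_area(alpha = 0.3, position = "identity") +
    ggplot2::labs(x = config$xlab %||% "Value", y = "Density",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  write_figure(ctx, p, file.path(out_dir, paste0(name, "_kde")), config)
  kdes
}

summary_sidecars <- function(ctx, name, traces, config, out_dir) {
  df <- dplyr::bind_rows(lapply(traces, tidy))
  write_sidecar(ctx, df, file.path(out_dir, paste0(name, "_summary.csv")))
  p <- plot_summary_traces(traces, alpha = config$alpha %||% 0.25,
                           colors = unlist(config$colors))
  if (!is.null(config$xlab)) p <- p + ggplot2::xlab(config$xlab)
  if (!is.null(config$ylab)) p <- p + ggplot2::ylab(config$ylab)
  write_figure(ctx, p, file.path(out_dir, name), config)
}

run_timeseries_analysis <- function(name, config, out_dir, ctx,
                                    unit = NULL, nonneg = FALSE) {
  groups <- config_groups(config)
  rss <- lapply(groups, function(g) {
    rs <- read_group_series(g, unit = unit)
    if (nonneg && any(rs$value < 0)) {
      stop("group '", attr(rs, "group_label"),
           "': counts must be non-negative", call. = FALSE)
    }
    if (is.null(unit) && attr(rs, "time_unit") %in% c("ps", "ns")) {
      rs <- to_nanoseconds(rs)
    }
    align_replicas(rs)
  })
  traces <- lapply(rss, summarize_replicas)
  summary_sidecars(ctx, name, traces, config, out_dir)
  kdes <- kde_companion(ctx, name, rss, config, out_dir)
  list(traces = traces, kdes = kdes)
}

run_mindist <- function(config, out_dir, ctx) {
  groups <- config_groups(config)
  rss <- lapply(groups, function(g) {
    align_replicas(to_nanoseconds(read_group_series(g)))
  })
  traces <- min_distance_summary(rss, dissociation_nm =
                                   config$dissociation_nm %||% 0.6)
  for (tr in traces) {
    fl <- attr(tr, "dissociation_frames")
    log_line(ctx, "group=%s dissociation_frames=%d/%d",
             attr(tr, "group_label"), length(fl), nrow(tr))
  }
  summary_sidecars(ctx, "mindist", traces, config, out_dir)
  kdes <- kde_companion(ctx, "mindist", rss, config, out_dir)
  list(traces = traces, kdes = kdes)
}

run_hydrophobic <- function(config, out_dir, ctx) {
  groups <- config_groups(config)
  selection <- unlist(config$selection)
  if (is.null(selection)) {
    stop("hydrophobic analysis requires config$selection (residue names)",
         call. = FALSE)
  }
  traces <- lapply(groups, function(g) {
    if (is.null(g$residue_files)) {
      stop("group '", g$label %||% "?",
           "' needs residue_files: residue -> per-replica contact files",
           call. = FALSE)
    }
    per_residue <- purrr::imap(g$residue_files, function(files, res) {
      read_group_series(list(label = g$label %||% "group",
                             files = unlist(files)))
    })
    tr <- hydrophobic_contacts(per_residue, selection)
    attr(tr, "group_label") <- g$label %||% "group"
    tr
  })
  log_line(ctx, "selection=%s", paste(selection, collapse = ","))
  summary_sidecars(ctx, "hydrophobic", traces, config, out_dir)
  list(traces = traces)
}

read_group_ss <- function(g) {
  files <- unlist(g$files)
  probs <- lapply(files, function(f) classify_dssp(read_xpm(f)))
  # frames of every replica of a group are pooled before summarising
  cls <- do.call(rbind, lapply(probs, `[[`, "classes"))
  structure(list(classes = cls, frame_times = NULL,
                 n_residues = ncol(cls)),
            class = "ss_assignments")
}

run_ss <- function(config, out_dir, ctx, what = "probability") {
  groups <- config_groups(config)
  assigns <- lapply(groups, read_group_ss)
  labels <- vapply(groups, function(g) g$label %||% "group", character(1))
  names(assigns) <- labels
  if (what == "probability") {
    probs <- lapply(assigns, ss_probability)
    box <- dplyr::bind_rows(
      purrr::imap(probs, function(p, lab) {
        dplyr::mutate(boxplot_summary(p, .data$probability, .data$class),
                      group = lab)
      })
    )
    box$outliers <- vapply(box$outliers, function(o)
      paste(sprintf("%.6g", unlist(o)), collapse = ";"), character(1))
    write_sidecar(ctx, box, file.path(out_dir, "ss_probability_boxstats.csv"))
    write_figure(ctx, plot_ss_boxplot(probs),
                 file.path(out_dir, "ss_probability"), config)
    list(assignments = assigns, probability = probs, boxstats = box)
  } else {
    fracs <- lapply(assigns, ss_fraction)
    out <- export_ss_fractions(fracs, file.path(out_dir, "ss_fractions"))
    for (p in out) record_file(ctx, p)
    write_figure(ctx, plot_ss_fractions(fracs[[1]]),
                 file.path(out_dir, "ss_fraction"), config)
    list(assignments = assigns, fraction = fracs, exports = out)
  }
}

run_pca <- function(config, out_dir, ctx) {
  groups <- config_groups(config)
  projs <- lapply(groups, function(g) {
    f <- unlist(g$files)[1]
    pca_scatter(if (grepl("\\.dat$", f)) read_dat(f) else read_xvg(f))
  })
  labels <- vapply(groups, function(g) g$label %||% "group", character(1))
  df <- dplyr::bind_rows(purrr::map2(projs, labels, function(p, lab) {
    tibble::tibble(group = lab, pc1 = p$pc1, pc2 = p$pc2,
                   frame_order = p$frame_order)
  }))
  write_sidecar(ctx, df, file.path(out_dir, "pca_projection.csv"))
  p <- autoplot(projs[[1]])
  write_figure(ctx, p, file.path(out_dir, "pca"), config)
  list(projections = projs)
}

run_occupancy <- function(config, out_dir, ctx) {
  groups <- config_groups(config)
  box <- unlist(config$box %||% c(6, 6))
  n_bins <- unlist(config$n_bins %||% c(50, 50))
  maps <- lapply(groups, function(g) {
    coords <- dplyr::bind_rows(lapply(unlist(g$files), function(f) {
      tbl <- read_dat(f)
      tibble::tibble(x = tbl[[1]], y = tbl[[2]],
                     z = if (length(tbl) >= 3L) tbl[[3]] else 0)
    }))
    occupancy_map(coords, box_xy = box[1:2], n_bins = n_bins)
  })
  df <- tidy(maps[[1]])
  write_sidecar(ctx, df, file.path(out_dir, "occupancy.csv"))
  write_figure(ctx, autoplot(maps[[1]]), file.path(out_dir, "occupancy"),
               config)
  list(maps = maps)
}

read_group_angles <- function(g) {
  files <- unlist(g$files)
  lapply(seq_along(files), function(i) {
    tbl <- read_xvg(files[i])
    angle_series(tbl[[1]], tbl[[2]],
                 angle_name = attr(tbl, "title") %||% "dihedral",
                 replica = paste0("rep", i))
  })
}

run_dihedral <- function(config, out_dir, ctx) {
  groups <- config_groups(config)
  out <- lapply(groups, function(g) {
    reps <- read_group_angles(g)
    trace <- circular_mean_trace(reps)
    pooled <- unlist(lapply(reps, `[[`, "angle"))
    k2 <- kde_2d(trace$time[!is.nan(trace$angle)],
                 trace$angle[!is.nan(trace$angle)])
    k1 <- kde_1d(pooled, h = config$bandwidth %||% NULL)
    list(label = g$label %||% "group", trace = trace, kde2d = k2, kde1d = k1)
  })
  df <- dplyr::bind_rows(lapply(out, function(o) {
    tibble::tibble(group = o$label, time = o$trace$time,
                   circular_mean = o$trace$angle)
  }))
  write_sidecar(ctx, df, file.path(out_dir, "dihedral_circular_mean.csv"))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$circular_mean,
                                        colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time", y = "Circular mean (degrees)", colour = NULL) +
    ggplot2::theme_minimal()
  write_figure(ctx, p, file.path(out_dir, "dihedral_trace"), config)
  write_figure(ctx, autoplot(out[[1]]$kde2d),
               file.path(out_dir, "dihedral_kde2d"), config)
  kdf <- dplyr::bind_rows(lapply(out, function(o) {
    tibble::tibble(group = o$label, grid = o$kde1d$grid,
                   density = o$kde1d$density)
  }))
  write_sidecar(ctx, kdf, file.path(out_dir, "dihedral_kde.csv"))
  list(groups = out)
}

run_distmat <- function(config, out_dir, ctx) {
  groups <- config_groups(config)
  mats <- lapply(groups, function(g) {
    m <- read_xpm(unlist(g$files)[1])
    vals <- xpm_to_value_matrix(m)
    sidecar <- file.path(out_dir,
                         sprintf("distmat_%s.csv", g$label %||% "group"))
    dm <- distance_heatmap(vals, sidecar = sidecar)
    record_file(ctx, sidecar)
    dm
  })
  write_figure(ctx, autoplot(mats[[1]]), file.path(out_dir, "distmat"),
               config)
  list(matrices = mats)
}

read_phipsi_files <- function(files) {
  lapply(unlist(files), function(f) {
    tbl <- read_xvg(f)
    if (length(tbl) >= 3L) {
      # time phi psi layout
      tibble::tibble(phi = wrap_angle(tbl[[2]]), psi = wrap_angle(tbl[[3]]))
    } else {
      tibble::tibble(phi = wrap_angle(tbl[[1]]), psi = wrap_angle(tbl[[2]]))
    }
  })
}

run_phipsi <- function(config, out_dir, ctx) {
  groups <- config_groups(config)
  out <- lapply(groups, function(g) {
    reps <- read_phipsi_files(g$files)
    pooled <- concat_replicas(reps)
    per_rep <- lapply(reps, function(p) kde_2d(p$phi, p$psi))
    combined <- kde_2d(pooled$phi, pooled$psi)
    list(label = g$label %||% "group", replicas = reps, pooled = pooled,
         per_replica_kde = per_rep, combined_kde = combined)
  })
  g1 <- out[[1]]
  write_sidecar(ctx, g1$pooled, file.path(out_dir, "phipsi_pooled.csv"))
  for (i in seq_along(g1$per_replica_kde)) {
    write_figure(ctx, autoplot(g1$per_replica_kde[[i]]) +
                   ggplot2::labs(x = "Phi (degrees)", y = "Psi (degrees)"),
                 file.path(out_dir, sprintf("phipsi_rep%d", i)), config)
  }
  write_figure(ctx, autoplot(g1$combined_kde) +
                 ggplot2::labs(x = "Phi (degrees)", y = "Psi (degrees)"),
               file.path(out_dir, "phipsi_combined"), config)
  list(groups = out)
}

run_rotamers <- function(config, out_dir, ctx) {
  groups <- config_groups(config)
  tw <- unlist(config$time_window)
  out <- lapply(groups, function(g) {
    chi1 <- read_group_angles(list(label = g$label, files = g$files))
    chi2 <- read_group_angles(list(label = g$label,
                                   files = g$files2 %||% g$files))
    if (!is.null(tw)) {
      chi1 <- lapply(chi1, time_window, t0 = tw[1], t1 = tw[2])
      chi2 <- lapply(chi2, time_window, t0 = tw[1], t1 = tw[2])
    }
    m1 <- circular_mean_trace(chi1)
    m2 <- circular_mean_trace(chi2)
    ok <- !is.nan(m1$angle) & !is.nan(m2$angle)
    k2 <- kde_2d(m1$angle[ok], m2$angle[ok])
    h1 <- angle_histogram(m1$angle[ok], n_bins = config$bins %||% 36L)
    h2 <- angle_histogram(m2$angle[ok], n_bins = config$bins %||% 36L)
    list(label = g$label %||% "group", chi1 = m1, chi2 = m2, kde2d = k2,
         hist_chi1 = h1, hist_chi2 = h2)
  })
  g1 <- out[[1]]
  df <- tibble::tibble(time = g1$chi1$time, chi1 = g1$chi1$angle,
                       chi2 = g1$chi2$angle)
  write_sidecar(ctx, df, file.path(out_dir, "rotamers_means.csv"))
  dot <- ggplot2::ggplot(df, ggplot2::aes(.data$chi1, .data$chi2,
                                          colour = .data$time)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "Chi1 (degrees)", y = "Chi2 (degrees)",
                  colour = "Time") +
    ggplot2::theme_minimal()
  write_figure(ctx, dot, file.path(out_dir, "rotamers_dot"), config)
  write_figure(ctx, autoplot(g1$kde2d) +
                 ggplot2::labs(x = "Chi1 (degrees)", y = "Chi2 (degrees)"),
               file.path(out_dir, "rotamers_kde2d"), config)
  write_figure(ctx, plot_angle_histogram(g1$hist_chi1),
               file.path(out_dir, "rotamers_hist_chi1"), config)
  write_sidecar(ctx, g1$hist_chi1,
                file.path(out_dir, "rotamers_hist_chi1.csv"))
  write_sidecar(ctx, g1$hist_chi2,
                file.path(out_dir, "rotamers_hist_chi2.csv"))
  list(groups = out)
}

#' Generate a fixture directory tree
#'
#' Emits seeded synthetic inputs for one fixture kind (or all of them) in a
#' per-simulation/per-replica layout, ready to be referenced from analysis
#' configuration profiles.
#'
#' @param kind One of `"timeseries"`, `"dssp_xpm"`, `"distance_xpm"`,
#'   `"dihedral"`, `"phipsi"`, `"coords"`, `"pca2d"`, `"all"`.
#' @param out Output directory.
#' @param seed Integer seed.
#' @return Invisibly, a named list of generator truth records.
#' @export
generate_fixtures <- function(kind = "all", out = "fixtures", seed = 1L) {
  kinds <- c("timeseries", "dssp_xpm", "distance_xpm", "dihedral",
             "phipsi", "coords", "pca2d")
  kind <- match.arg(kind, c(kinds, "all"))
  todo <- if (kind == "all") kinds else kind
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  for (k in todo) {
    res[[k]] <- switch(
      k,
      timeseries = gen_timeseries(file.path(out, "sim1"), seed = seed),
      dssp_xpm = gen_dssp_xpm(file.path(out, "dssp.xpm"), seed = seed),
      distance_xpm = gen_distance_xpm(file.path(out, "distmat.xpm"),
                                      seed = seed),
      dihedral = gen_dihedral(file.path(out, "sim1"), seed = seed),
      phipsi = gen_phipsi(file.path(out, "sim1"), seed = seed),
      coords = gen_coords(file.path(out, "ligand_xyz.dat"), seed = seed),
      pca2d = gen_pca2d(file.path(out, "pca2d.xvg"), seed = seed)
    )
  }
  invisible(res)
}
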