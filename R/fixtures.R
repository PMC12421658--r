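#' @name fixtures
#' @title Synthetic GROMACS-dialect fixture generators
#' @description
#' Every analysis in the package can be exercised without running a
#' simulation: these generators emit files in the exact dialects GROMACS
#' writes (.xvg with grace headers, .xpm with legend lines, plain .dat)
#' from known statistical ground truth — deterministic trends with Gaussian
#' noise, categorical secondary-structure draws with known class
#' probabilities, von Mises dihedral draws with known circular mean, ligand
#' coordinates clustered at known hot spots. Each generator returns the
#' paths written together with its truth record, and is bit-reproducible
#' for a fixed seed: each fixture kind derives its own pseudo-random stream
#' from (seed, kind), so replica files regenerate identically in isolation.
#' Headers deliberately vary (with/without title and legends) to harden the
#' parsers. The synthetic data emulate the statistical shape of
#' post-processed MD output, not its physics.
NULL

# One stream per (seed, kind): deterministic, isolated between fixture kinds.
fixture_seed <- function(seed, kind) {
  h <- sum(utf8ToInt(kind) * seq_along(utf8ToInt(kind)))
  (as.integer(seed) %% 100000L) * 10007L + (h %% 10007L)
}

with_fixture_seed <- function(seed, kind, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(fixture_seed(seed, kind))
  force(code)
}

#' Generate replica .xvg time series with known trend
#'
#' Values are a deterministic trend plus iid Gaussian noise with standard
#' deviation `noise_sd`; each replica gets an independent noise draw. Files
#' carry a grace header with the property title and a `(ps)` time axis (the
#' GROMACS default); legend/title presence alternates across replicas to
#' exercise the parser.
#'
#' @param dir Output directory (created if needed).
#' @param property Property title (e.g. `"RMSD"`).
#' @param n_points Samples per replica.
#' @param n_replicas Number of replica files.
#' @param trend Deterministic trend: a constant, a vector of length
#'   `n_points`, or a function of time (ps).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param dt_ps Sampling interval in ps (default 10).
#' @param seed Integer seed.
#' @param ylab y-axis label written to the header.
#' @return A list: `paths` (character), `truth` (tibble `time_ps`, `trend`),
#'   `noise_sd`.
#' @export
gen_timeseries <- function(dir, property = "RMSD", n_points = 500L,
                           n_replicas = 3L, trend = 0.2, noise_sd = 0.02,
                           dt_ps = 10, seed = 1L, ylab = "RMSD (nm)") {
  stopifnot(n_points >= 1L, n_replicas >= 1L, noise_sd >= 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  time_ps <- seq(0, by = dt_ps, length.out = n_points)
  mu <- if (is.function(trend)) trend(time_ps) else rep_len(trend, n_points)
  paths <- with_fixture_seed(seed, paste0("timeseries:", property), {
    vapply(seq_len(n_replicas), function(r) {
      vals <- mu + stats::rnorm(n_points, 0, noise_sd)
      tbl <- new_xvg_tbl(
        list(time_ps, vals),
        title = if (r %% 2L == 1L) property else "",
        xlab = "Time (ps)", ylab = ylab,
        legends = if (r == 1L) c("", property) else character(0),
        directives = if (r == 1L) "@ TYPE xy" else character(0)
      )
      p <- file.path(dir, sprintf("%s_rep%d.xvg", tolower(property), r))
      write_xvg(tbl, p)
      p
    }, character(1))
  })
  list(paths = paths,
       truth = tibble::tibble(time_ps = time_ps, trend = mu),
       noise_sd = noise_sd)
}

#' Generate a DSSP-style .xpm with known class probabilities
#'
#' Each residue x frame cell is drawn categorically over the DSSP codes
#' with the given probabilities; the file uses the GROMACS do_dssp layout
#' (residues on y, frames on x, tick comments for both axes). The truth
#' record stores the exact per-frame class counts realised in the draw.
#'
#' @param path Output .xpm path.
#' @param n_frames,n_residues Grid dimensions.
#' @param probs Named probabilities over DSSP codes (subset of
#'   `names(dssp_mapping())`), summing to 1 within 1e-9.
#' @param seed Integer seed.
#' @return A list: `path`, `truth_counts` (tibble `frame`, `class`,
#'   `count` over the six canonical classes), `probs`.
#' @export
gen_dssp_xpm <- function(path, n_frames = 100L, n_residues = 30L,
                         probs = c(H = 0.4, E = 0.25, "~" = 0.2,
                                   T = 0.08, S = 0.05, G = 0.02),
                         seed = 1L) {
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("class probabilities must sum to 1 (got ", sum(probs), ")",
         call. = FALSE)
  }
  codes_used <- names(probs)
  unknown <- setdiff(codes_used, names(dssp_mapping()))
  if (length(unknown)) {
    stop("probabilities name unknown DSSP code(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  draw <- with_fixture_seed(seed, "dssp_xpm", {
    matrix(sample(codes_used, n_frames * n_residues, replace = TRUE,
                  prob = probs),
           nrow = n_residues, ncol = n_frames)  # residues on y, frames on x
  })
  labels <- c(H = "A-Helix", G = "3-Helix", E = "B-Sheet", B = "B-Bridge",
              T = "Turn", S = "Bend", "~" = "Coil", C = "Coil",
              I = "5-Helix")[codes_used]
  legend <- tibble::tibble(code = codes_used, label = unname(labels),
                           lo = NA_real_, hi = NA_real_, value = NA_real_)
  m <- structure(
    list(ncols = n_frames, nrows = n_residues, chars_per_pixel = 1L,
         legend = legend, codes = draw,
         x_ticks = seq_len(n_frames) - 1L, y_ticks = seq_len(n_residues),
         title = "Secondary structure", source_path = ""),
    class = "xpm_matrix"
  )
  write_xpm(m, path)
  mapping <- dssp_mapping()
  lv <- ss_classes()
  counts <- t(apply(draw, 2L, function(col) {
    tabulate(factor(unname(mapping[col]), levels = lv), nbins = length(lv))
  }))
  truth <- tidyr::expand_grid(frame = seq_len(n_frames),
                              class = factor(lv, levels = lv))
  truth$count <- as.vector(t(counts))
  list(path = path, truth_counts = truth, probs = probs)
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution.
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (!is.finite(kappa) || kappa <= 0) {
    stop("von Mises concentration kappa must be > 0", call. = FALSE)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- double(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 64L)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5) * acos(pmax(pmin(f, 1), -1))
    out <- c(out, theta[ok])
  }
  wrap_angle(out[seq_len(n)] * 180 / pi + mu_deg)
}

#' Generate dihedral-angle .xvg replicas with known circular mean
#'
#' Angles are von Mises draws concentrated around `mu_deg` with
#' concentration `kappa`, written as time + angle columns; the circular mean
#' of the generating distribution is `mu_deg` exactly.
#'
#' @param dir Output directory.
#' @param angle_name Dihedral name used in file names and headers.
#' @param n_points Samples per replica.
#' @param n_replicas Number of replica files.
#' @param mu_deg True mean direction (degrees).
#' @param kappa Concentration (> 0).
#' @param dt_ps Sampling interval (ps).
#' @param seed Integer seed.
#' @return A list: `paths`, `mu_deg`, `kappa`.
#' @export
gen_dihedral <- function(dir, angle_name = "dihedral", n_points = 1000L,
                         n_replicas = 3L, mu_deg = 45, kappa = 4,
                         dt_ps = 10, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  time_ps <- seq(0, by = dt_ps, length.out = n_points)
  paths <- with_fixture_seed(seed, paste0("dihedral:", angle_name), {
    vapply(seq_len(n_replicas), function(rr) {
      ang <- rvonmises_deg(n_points, mu_deg, kappa)
      tbl <- new_xvg_tbl(list(time_ps, ang),
                         title = angle_name, xlab = "Time (ps)",
                         ylab = "Angle (degrees)")
      p <- file.path(dir, sprintf("%s_rep%d.xvg", angle_name, rr))
      write_xvg(tbl, p)
      p
    }, character(1))
  })
  list(paths = paths, mu_deg = mu_deg, kappa = kappa)
}

#' Generate phi/psi replica .xvg files (Ramachandran input)
#'
#' Each replica holds paired (phi, psi) von Mises draws around the given
#' conformational centres (mixed with the given weights), in the two-column
#' `gmx rama`-like layout phi psi.
#'
#' @param dir Output directory.
#' @param n_points Pairs per replica.
#' @param n_replicas Number of replicas.
#' @param centers A data frame with columns `phi`, `psi`, `weight` (weights
#'   renormalised); default: alpha-helical and beta-sheet basins.
#' @param kappa Concentration of each basin.
#' @param seed Integer seed.
#' @return A list: `paths`, `centers`.
#' @export
gen_phipsi <- function(dir, n_points = 1000L, n_replicas = 3L,
                       centers = data.frame(phi = c(-63, -120),
                                            psi = c(-43, 130),
                                            weight = c(0.6, 0.4)),
                       kappa = 8, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- centers$weight / sum(centers$weight)
  paths <- with_fixture_seed(seed, "phipsi", {
    vapply(seq_len(n_replicas), function(rr) {
      comp <- sample(nrow(centers), n_points, replace = TRUE, prob = w)
      phi <- psi <- double(n_points)
      for (k in seq_len(nrow(centers))) {
        idx <- which(comp == k)
        if (length(idx)) {
          phi[idx] <- rvonmises_deg(length(idx), centers$phi[k], kappa)
          psi[idx] <- rvonmises_deg(length(idx), centers$psi[k], kappa)
        }
      }
      tbl <- new_xvg_tbl(list(phi, psi), title = "Ramachandran",
                         xlab = "Phi", ylab = "Psi")
      p <- file.path(dir, sprintf("rama_rep%d.xvg", rr))
      write_xvg(tbl, p)
      p
    }, character(1))
  })
  list(paths = paths, centers = centers)
}

#' Generate a binned distance-matrix .xpm with known cell values
#'
#' Builds a symmetric inter-residue distance matrix (zero diagonal, distance
#' growing with sequence separation plus noise), quantises it into
#' `n_levels` equal-width bins, and writes an .xpm whose legend labels are
#' the bin ranges — so `xpm_to_value_matrix()` must recover each cell's bin
#' midpoint exactly. The truth record stores the midpoint matrix.
#'
#' @param path Output .xpm path.
#' @param n_residues Matrix dimension.
#' @param n_levels Number of legend bins (<= 26).
#' @param max_nm Largest distance before binning (nm).
#' @param seed Integer seed.
#' @return A list: `path`, `truth_values` (midpoint matrix, nm), `raw`
#'   (pre-quantisation matrix).
#' @export
gen_distance_xpm <- function(path, n_residues = 20L, n_levels = 10L,
                             max_nm = 3, seed = 1L) {
  stopifnot(n_levels >= 1L, n_levels <= 26L)
  raw <- with_fixture_seed(seed, "distance_xpm", {
    sep <- abs(outer(seq_len(n_residues), seq_len(n_residues), "-"))
    d <- max_nm * sep / max(sep)
    jitter <- matrix(stats::runif(n_residues^2, 0, max_nm * 0.1),
                     n_residues, n_residues)
    jitter <- (jitter + t(jitter)) / 2
    d <- pmin(d + jitter, max_nm)
    diag(d) <- 0
    d
  })
  width <- max_nm / n_levels
  level <- pmin(floor(raw / width), n_levels - 1L)
  lo <- level * width
  codes <- matrix(LETTERS[level + 1L], n_residues, n_residues)
  used <- sort(unique(as.vector(level)))
  legend <- tibble::tibble(
    code = LETTERS[used + 1L],
    label = sprintf("%.3f-%.3f", used * width, (used + 1L) * width),
    lo = used * width, hi = (used + 1L) * width,
    value = (used + 0.5) * width
  )
  m <- structure(
    list(ncols = n_residues, nrows = n_residues, chars_per_pixel = 1L,
         legend = legend, codes = codes,
         x_ticks = seq_len(n_residues), y_ticks = seq_len(n_residues),
         title = "Mean minimum distance", source_path = ""),
    class = "xpm_matrix"
  )
  write_xpm(m, path)
  # label is printed at 3 decimals, so the recoverable truth is the midpoint
  # of the printed (rounded) bounds
  plo <- round(lo, 3); phi <- round((level + 1L) * width, 3)
  list(path = path, truth_values = (plo + phi) / 2, raw = raw)
}

#' Generate ligand coordinates clustered at known hot spots
#'
#' Writes a 3-column whitespace .dat of (x, y, z) positions inside the box:
#' a mixture of isotropic Gaussians at the given hot spots (truncated to the
#' box) or a uniform cloud when `hotspots` is NULL.
#'
#' @param path Output .dat path.
#' @param n_points Number of positions.
#' @param box Box lengths `c(Lx, Ly, Lz)` (nm).
#' @param hotspots Data frame with columns `x`, `y`, `sd`, `weight`, or NULL
#'   for uniform.
#' @param seed Integer seed.
#' @return A list: `path`, `hotspots`, `box`.
#' @export
gen_coords <- function(path, n_points = 5000L, box = c(6, 6, 6),
                       hotspots = data.frame(x = 2, y = 4, sd = 0.15,
                                             weight = 1),
                       seed = 1L) {
  xyz <- with_fixture_seed(seed, "coords", {
    if (is.null(hotspots)) {
      cbind(stats::runif(n_points, 0, box[1]),
            stats::runif(n_points, 0, box[2]),
            stats::runif(n_points, 0, box[3]))
    } else {
      w <- hotspots$weight / sum(hotspots$weight)
      comp <- sample(nrow(hotspots), n_points, replace = TRUE, prob = w)
      x <- stats::rnorm(n_points, hotspots$x[comp], hotspots$sd[comp])
      y <- stats::rnorm(n_points, hotspots$y[comp], hotspots$sd[comp])
      cbind(pmin(pmax(x, 0), box[1]), pmin(pmax(y, 0), box[2]),
            stats::runif(n_points, 0, box[3]))
    }
  })
  rows <- sprintf("%.6f %.6f %.6f", xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c("# synthetic ligand positions (nm)", rows), path)
  list(path = path, hotspots = hotspots, box = box)
}

#' Generate a 2D PCA-projection .xvg with known point clouds
#'
#' Writes a two-column (PC1, PC2) table drawn from a mixture of Gaussian
#' clusters, emulating `gmx anaeig -2d` output.
#'
#' @param path Output .xvg path.
#' @param n_points Number of frames.
#' @param clusters Data frame with columns `pc1`, `pc2`, `sd`, `weight`.
#' @param seed Integer seed.
#' @return A list: `path`, `clusters`, `points` (the tibble written).
#' @export
gen_pca2d <- function(path, n_points = 500L,
                      clusters = data.frame(pc1 = c(-1, 2), pc2 = c(0, 1),
                                            sd = c(0.3, 0.5),
                                            weight = c(0.5, 0.5)),
                      seed = 1L) {
  pts <- with_fixture_seed(seed, "pca2d", {
    w <- clusters$weight / sum(clusters$weight)
    comp <- sample(nrow(clusters), n_points, replace = TRUE, prob = w)
    tibble::tibble(pc1 = stats::rnorm(n_points, clusters$pc1[comp],
                                      clusters$sd[comp]),
                   pc2 = stats::rnorm(n_points, clusters$pc2[comp],
                                      clusters$sd[comp]))
  })
  tbl <- new_xvg_tbl(list(pts$pc1, pts$pc2), title = "2D projection",
                     xlab = "projection on eigenvector 1 (nm)",
                     ylab = "projection on eigenvector 2 (nm)")
  write_xvg(tbl, path)
  list(path = path, clusters = clusters, points = pts)
}
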