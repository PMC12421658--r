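setup_group <- function(dir, label = "apo", trend = 0.2, seed = 1,
                        n_points = 40, n_replicas = 2) {
  fx <- gen_timeseries(file.path(dir, label), n_points = n_points,
                       n_replicas = n_replicas, trend = trend, seed = seed)
  list(label = label, files = as.list(fx$paths))
}

test_that("run_analysis rejects unknown names and empty configs", {
  expect_error(run_analysis("frobnicate", list()), "unknown analysis")
  expect_error(run_analysis("rmsd", list(groups = list()), tempfile()),
               "at least one group")
})

test_that("rmsd run writes figure, summary sidecar, KDE companion and log", {
  d <- local_fixture_dir()
  out <- file.path(d, "out")
  cfg <- list(groups = list(setup_group(d)))
  r <- run_analysis("rmsd", cfg, out)
  base <- basename(r$files)
  expect_true(all(c("rmsd.png", "rmsd.svg", "rmsd_summary.csv",
                    "rmsd_kde.csv", "rmsd_kde.png") %in% base))
  expect_true(file.exists(r$log))
  lg <- readLines(r$log)
  expect_true(any(grepl("analysis=rmsd", lg)))
  expect_true(any(grepl("group=apo", lg)))
  expect_true(any(grepl("status=ok", lg)))
})

test_that("sidecar values equal direct module-level computation", {
  d <- local_fixture_dir()
  out <- file.path(d, "out")
  g <- setup_group(d, n_points = 60, n_replicas = 3, seed = 5)
  run_analysis("sasa", list(groups = list(g)), out)
  side <- utils::read.csv(file.path(out, "sasa_summary.csv"))

  rs <- to_nanoseconds(read_replicas(unlist(g$files)))
  st <- summarize_replicas(align_replicas(rs))
  # sidecars print 12 significant digits; compare at that precision
  expect_equal(side$time, st$time, tolerance = 1e-10)
  expect_equal(side$mean, st$mean, tolerance = 1e-10)
  expect_equal(side$sd, st$sd, tolerance = 1e-10)

  kde_side <- utils::read.csv(file.path(out, "sasa_kde.csv"))
  k <- kde_1d(rs$value)
  expect_equal(kde_side$grid, k$grid, tolerance = 1e-10)
  expect_equal(kde_side$density, k$density, tolerance = 1e-10)
})

test_that("identical config and inputs give byte-identical sidecars", {
  d <- local_fixture_dir()
  cfg <- list(groups = list(setup_group(d, seed = 2)))
  out1 <- file.path(d, "o1"); out2 <- file.path(d, "o2")
  run_analysis("gyrate", cfg, out1)
  run_analysis("gyrate", cfg, out2)
  expect_identical(readLines(file.path(out1, "gyrate_summary.csv")),
                   readLines(file.path(out2, "gyrate_summary.csv")))
})

test_that("ss runs produce workbook, CSV and box statistics from one xpm", {
  d <- local_fixture_dir()
  out <- file.path(d, "out")
  fx <- gen_dssp_xpm(file.path(d, "s.xpm"), n_frames = 40, n_residues = 12,
                     seed = 3)
  cfg <- list(groups = list(list(label = "apo",
                                 files = list(file.path(d, "s.xpm")))))
  rf <- run_analysis("ss-fraction", cfg, out)
  expect_true(file.exists(file.path(out, "ss_fractions.csv")))
  expect_true(file.exists(file.path(out, "ss_fractions.xml")))
  back <- utils::read.csv(file.path(out, "ss_fractions.csv"),
                          check.names = FALSE)
  f <- ss_fraction(classify_dssp(read_xpm(fx$path)))
  expect_equal(back[["apo.alpha-helix"]],
               f$fraction[f$class == "alpha-helix"], tolerance = 1e-9)

  rp <- run_analysis("ss-probability", cfg, out)
  bx <- utils::read.csv(file.path(out, "ss_probability_boxstats.csv"))
  direct <- boxplot_summary(ss_probability(classify_dssp(read_xpm(fx$path))),
                            probability, class)
  expect_equal(bx$median, direct$median, tolerance = 1e-9)
  expect_equal(bx$q1, direct$q1, tolerance = 1e-9)
})

test_that("replica frames pool before the ss summary", {
  d <- local_fixture_dir()
  out <- file.path(d, "out")
  f1 <- gen_dssp_xpm(file.path(d, "r1.xpm"), n_frames = 10, n_residues = 8,
                     probs = c(H = 1), seed = 1)
  f2 <- gen_dssp_xpm(file.path(d, "r2.xpm"), n_frames = 10, n_residues = 8,
                     probs = c(E = 1), seed = 2)
  cfg <- list(groups = list(list(label = "apo",
                                 files = list(f1$path, f2$path))))
  r <- run_analysis("ss-fraction", cfg, out)
  frac <- r$results$fraction$apo
  expect_equal(nrow(frac), 20L * 6L)
  expect_equal(mean(frac$fraction[frac$class == "alpha-helix"]), 0.5)
  expect_equal(mean(frac$fraction[frac$class == "beta-sheet"]), 0.5)
})

test_that("dihedral, rotamer, phipsi, occupancy, pca and distmat runs agree with module calls", {
  d <- local_fixture_dir()
  out <- file.path(d, "out")
  dh <- gen_dihedral(file.path(d, "dh"), n_points = 80, n_replicas = 2,
                     mu_deg = 60, kappa = 8, seed = 4)
  cfg <- list(groups = list(list(label = "apo", files = as.list(dh$paths))))
  r <- run_analysis("dihedral", cfg, out)
  side <- utils::read.csv(file.path(out, "dihedral_circular_mean.csv"))
  reps <- lapply(seq_along(dh$paths), function(i) {
    tbl <- read_xvg(dh$paths[i])
    angle_series(tbl[[1]], tbl[[2]], replica = paste0("r", i))
  })
  tr <- circular_mean_trace(reps)
  expect_equal(side$circular_mean, tr$angle, tolerance = 1e-9)

  rr <- run_analysis("rotamers", cfg, out)
  hist_side <- utils::read.csv(file.path(out, "rotamers_hist_chi1.csv"))
  expect_equal(sum(hist_side$count), 80L)

  pp <- gen_phipsi(file.path(d, "pp"), n_points = 120, n_replicas = 2,
                   seed = 5)
  rp <- run_analysis("phipsi",
                     list(groups = list(list(label = "apo",
                                             files = as.list(pp$paths)))),
                     out)
  pooled_side <- utils::read.csv(file.path(out, "phipsi_pooled.csv"))
  expect_equal(nrow(pooled_side), 240L)

  co <- gen_coords(file.path(d, "lig.dat"), n_points = 400, seed = 6)
  ro <- run_analysis("occupancy",
                     list(groups = list(list(label = "apo",
                                             files = list(co$path))),
                          box = c(6, 6), n_bins = c(10, 10)), out)
  occ_side <- utils::read.csv(file.path(out, "occupancy.csv"))
  expect_equal(sum(occ_side$count), 400L)

  dx <- gen_distance_xpm(file.path(d, "m.xpm"), n_residues = 10, seed = 7)
  rd <- run_analysis("distmat",
                     list(groups = list(list(label = "apo",
                                             files = list(dx$path)))), out)
  mat_side <- utils::read.csv(file.path(out, "distmat_apo.csv"),
                              check.names = FALSE)
  expect_equal(as.matrix(mat_side[, -1]), dx$truth_values,
               ignore_attr = TRUE, tolerance = 1e-9)

  px <- gen_pca2d(file.path(d, "p.xvg"), n_points = 100, seed = 8)
  rx <- run_analysis("pca",
                     list(groups = list(list(label = "apo",
                                             files = list(px$path)))), out)
  pca_side <- utils::read.csv(file.path(out, "pca_projection.csv"))
  expect_equal(pca_side$pc1, signif(px$points$pc1, 12), tolerance = 1e-12)
})

test_that("configuration profiles round-trip through YAML", {
  d <- local_fixture_dir()
  g <- setup_group(d)
  cfg_path <- file.path(d, "rmsd_config.yaml")
  yaml::write_yaml(list(groups = list(list(label = "apo",
                                           files = unlist(g$files))),
                        alpha = 0.2, xlab = "Time (ns)"), cfg_path)
  cfg <- read_analysis_config(cfg_path)
  expect_equal(cfg$alpha, 0.2)
  r <- run_analysis("rmsd", cfg_path, file.path(d, "out"))
  expect_true(file.exists(file.path(d, "out", "rmsd_summary.csv")))
  expect_error(read_analysis_config(tempfile()), "not found")
})
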