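test_that("gen_timeseries writes parseable replicas around its trend", {
  d <- local_fixture_dir()
  fx <- gen_timeseries(d, n_points = 50, n_replicas = 3, trend = 0.25,
                       noise_sd = 0, seed = 3)
  expect_length(fx$paths, 3L)
  for (p in fx$paths) {
    tbl <- read_xvg(p)
    expect_equal(nrow(tbl), 50L)
    expect_equal(tbl[[2]], rep(0.25, 50))
  }
  expect_equal(attr(read_xvg(fx$paths[1]), "xlab"), "Time (ps)")
})

test_that("fixture generation is bit-reproducible for a fixed seed", {
  d1 <- local_fixture_dir(); d2 <- local_fixture_dir()
  a <- gen_timeseries(d1, n_points = 30, seed = 9)
  b <- gen_timeseries(d2, n_points = 30, seed = 9)
  for (i in seq_along(a$paths)) {
    expect_identical(readLines(a$paths[i]), readLines(b$paths[i]))
  }
  c1 <- gen_dssp_xpm(file.path(d1, "s.xpm"), n_frames = 20, n_residues = 8,
                     seed = 4)
  c2 <- gen_dssp_xpm(file.path(d2, "s.xpm"), n_frames = 20, n_residues = 8,
                     seed = 4)
  expect_identical(readLines(c1$path), readLines(c2$path))
  h1 <- gen_dihedral(d1, n_points = 40, seed = 5)
  h2 <- gen_dihedral(d2, n_points = 40, seed = 5)
  expect_identical(readLines(h1$paths[1]), readLines(h2$paths[1]))
})

test_that("replica summary recovers the generating trend within CLT bounds", {
  d <- local_fixture_dir()
  n <- 2000L; reps <- 5L; sd0 <- 0.05
  fx <- gen_timeseries(d, n_points = n, n_replicas = reps, trend = 0.3,
                       noise_sd = sd0, seed = 12)
  rs <- read_replicas(fx$paths)
  st <- summarize_replicas(align_replicas(rs))
  grand_mean <- mean(st$mean)
  expect_lt(abs(grand_mean - 0.3), 4 * sd0 / sqrt(reps * n))
  expect_equal(mean(st$sd), sd0, tolerance = 0.15)
})

test_that("gen_dssp_xpm truth counts equal the parsed per-frame counting", {
  d <- local_fixture_dir()
  fx <- gen_dssp_xpm(file.path(d, "s.xpm"), n_frames = 100, n_residues = 30,
                     seed = 7)
  a <- classify_dssp(read_xpm(fx$path))
  expect_equal(nrow(a$classes), 100L)
  expect_equal(a$n_residues, 30L)
  f <- ss_fraction(a)
  joined <- merge(as.data.frame(f), as.data.frame(fx$truth_counts),
                  by = c("frame", "class"))
  expect_equal(joined$fraction, joined$count / 30, tolerance = 1e-15)
})

test_that("degenerate all-helix probabilities give 100 % alpha-helix", {
  d <- local_fixture_dir()
  fx <- gen_dssp_xpm(file.path(d, "h.xpm"), n_frames = 10, n_residues = 6,
                     probs = c(H = 1), seed = 1)
  p <- ss_probability(classify_dssp(read_xpm(fx$path)))
  expect_true(all(p$probability[p$class == "alpha-helix"] == 100))
  expect_true(all(p$probability[p$class != "alpha-helix"] == 0))
  expect_error(gen_dssp_xpm(tempfile(), probs = c(H = 0.5, E = 0.4)),
               "sum to 1")
})

test_that("gen_dihedral recovers mu in the high-concentration limit and wraps", {
  d <- local_fixture_dir()
  tight <- gen_dihedral(d, angle_name = "chiX", n_points = 500,
                        n_replicas = 1, mu_deg = 100, kappa = 1e6, seed = 2)
  a <- read_xvg(tight$paths[1])[[2]]
  expect_lt(abs(as.double(circular_mean(a)) - 100), 0.1)

  seam <- gen_dihedral(d, angle_name = "seam", n_points = 500,
                       n_replicas = 1, mu_deg = 179, kappa = 50, seed = 3)
  b <- read_xvg(seam$paths[1])[[2]]
  expect_true(all(b >= -180 & b < 180))
  expect_error(gen_dihedral(d, kappa = 0), "kappa")
})

test_that("gen_coords hot spot dominates the occupancy map", {
  d <- local_fixture_dir()
  fx <- gen_coords(file.path(d, "lig.dat"), n_points = 2000,
                   box = c(6, 6, 6),
                   hotspots = data.frame(x = 2, y = 4, sd = 0.1, weight = 1),
                   seed = 8)
  tbl <- read_dat(fx$path)
  om <- occupancy_map(data.frame(x = tbl[[1]], y = tbl[[2]]), c(6, 6),
                      c(12, 12))
  td <- tidy(om)
  peak <- td[which.max(td$density), ]
  expect_equal(peak$density, 1)
  expect_lt(abs(peak$x - 2), 0.5)
  expect_lt(abs(peak$y - 4), 0.5)
})

test_that("gen_pca2d writes the exact points it reports as truth", {
  d <- local_fixture_dir()
  fx <- gen_pca2d(file.path(d, "p.xvg"), n_points = 300, seed = 6)
  pr <- pca_scatter(read_xvg(fx$path))
  expect_equal(pr$pc1, signif(fx$points$pc1, 12), tolerance = 1e-12)
  expect_equal(pr$pc2, signif(fx$points$pc2, 12), tolerance = 1e-12)
  expect_equal(pr$frame_order, 0:299)
})

test_that("every generated file parses cleanly through the io layer", {
  d <- local_fixture_dir()
  res <- generate_fixtures("all", out = d, seed = 10)
  expect_named(res, c("timeseries", "dssp_xpm", "distance_xpm", "dihedral",
                      "phipsi", "coords", "pca2d"))
  for (p in res$timeseries$paths) expect_s3_class(read_xvg(p), "xvg_tbl")
  expect_s3_class(read_xpm(res$dssp_xpm$path), "xpm_matrix")
  expect_s3_class(read_xpm(res$distance_xpm$path), "xpm_matrix")
  for (p in res$dihedral$paths) expect_s3_class(read_xvg(p), "xvg_tbl")
  for (p in res$phipsi$paths) expect_s3_class(read_xvg(p), "xvg_tbl")
  expect_s3_class(read_dat(res$coords$path), "xvg_tbl")
  expect_s3_class(read_xvg(res$pca2d$path), "xvg_tbl")
})
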