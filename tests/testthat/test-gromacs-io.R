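test_that("read_xvg parses grace metadata, comments and data columns", {
  p <- write_lines_tmp(c(
    "# GROMACS comment",
    '@    title "RMSD"',
    '@    xaxis  label "Time (ps)"',
    '@    yaxis  label "RMSD (nm)"',
    '@ s0 legend "backbone"',
    "@ TYPE xy",
    "0 0.1",
    "10 0.2"
  ))
  tbl <- read_xvg(p)
  expect_equal(dim(tbl), c(2L, 2L))
  expect_equal(tbl[[1]], c(0, 10))
  expect_equal(tbl[[2]], c(0.1, 0.2))
  expect_equal(attr(tbl, "title"), "RMSD")
  expect_equal(attr(tbl, "xlab"), "Time (ps)")
  expect_equal(attr(tbl, "ylab"), "RMSD (nm)")
  expect_equal(attr(tbl, "legends")[1], "backbone")
  expect_equal(attr(tbl, "directives"), "@ TYPE xy")
})

test_that("read_xvg rejects files without data, ragged rows, bad tokens", {
  empty <- write_lines_tmp(c("# only", "@ title \"x\""))
  expect_error(read_xvg(empty), "no data rows")
  ragged <- write_lines_tmp(c("0 1 2", "3 4"))
  expect_error(read_xvg(ragged), "ragged")
  bad <- write_lines_tmp(c("0 1", "2 oops"))
  expect_error(read_xvg(bad), "non-numeric token in data row 2")
  expect_error(read_xvg(tempfile()), "does not exist")
})

test_that("read_xvg accepts exponent notation and negative values", {
  p <- write_lines_tmp(c("0 1.0e-3", "1 -2.5E+2", "2 3e4"))
  tbl <- read_xvg(p)
  expect_equal(tbl[[2]], c(1e-3, -250, 3e4))
})

test_that("write_xvg / read_xvg round-trips metadata and values to 12 significant digits", {
  set.seed(42)
  n <- 1000L
  cols <- list(sort(runif(n, 0, 1e4)), rnorm(n), rexp(n), runif(n, -1, 1),
               rnorm(n, 1e6, 10))
  tbl <- mdspectra:::new_xvg_tbl(cols, title = "Random table",
                                 xlab = "Time (ps)", ylab = "value",
                                 legends = c("", "a", "b", "c", "d"),
                                 directives = "@ TYPE xy")
  p <- tempfile(fileext = ".xvg")
  write_xvg(tbl, p)
  back <- read_xvg(p)
  expect_equal(attr(back, "title"), "Random table")
  expect_equal(attr(back, "xlab"), "Time (ps)")
  expect_equal(attr(back, "legends")[2:5], c("a", "b", "c", "d"))
  expect_equal(attr(back, "directives"), "@ TYPE xy")
  for (j in 1:5) expect_identical(signif(back[[j]], 12), signif(cols[[j]], 12))
})

test_that("write_xvg rejects unequal column lengths and empty tables", {
  bad <- list(V1 = 1:3, V2 = 1:2)
  expect_error(write_xvg(bad, tempfile()), "identical length")
})

test_that("read_dat parses plain tables and matches an xvg stripped of @ lines", {
  p <- write_lines_tmp(c("# header", "0 1.0", "1 2.0"), ext = ".dat")
  tbl <- read_dat(p)
  expect_equal(dim(tbl), c(2L, 2L))
  expect_equal(tbl[[2]], c(1, 2))
  expect_equal(attr(tbl, "title"), "")

  set.seed(7)
  vals <- cbind(0:49, rnorm(50))
  rows <- sprintf("%.10g %.10g", vals[, 1], vals[, 2])
  xvg <- write_lines_tmp(c('@ title "t"', rows))
  dat <- write_lines_tmp(rows, ext = ".dat")
  a <- read_xvg(xvg)
  b <- read_dat(dat)
  expect_equal(as.list(b)[1:2], as.list(a)[1:2], ignore_attr = TRUE)
})

test_that("read_xpm parses a handcrafted matrix with legend labels", {
  p <- write_lines_tmp(c(
    "/* XPM */",
    '/* title:   "demo" */',
    "static char *gromacs_xpm[] = {",
    '"2 2   2 1",',
    '"A  c #FFFFFF " /* "0.0-0.2" */,',
    '"B  c #000000 " /* "0.2-0.4" */,',
    "/* x-axis:  1 2 */",
    "/* y-axis:  1 2 */",
    '"AB",',
    '"BA"',
    "};"
  ), ext = ".xpm")
  m <- read_xpm(p)
  expect_equal(m$ncols, 2L)
  expect_equal(m$nrows, 2L)
  expect_equal(m$codes, matrix(c("A", "B", "B", "A"), 2, byrow = TRUE))
  expect_equal(m$legend$label, c("0.0-0.2", "0.2-0.4"))
  expect_equal(m$x_ticks, c(1, 2))
  expect_equal(m$title, "demo")
  vals <- xpm_to_value_matrix(m)
  expect_equal(vals, matrix(c(0.1, 0.3, 0.3, 0.1), 2, byrow = TRUE))
})

test_that("read_xpm rejects undeclared codes and dimension mismatches", {
  bad_code <- write_lines_tmp(c(
    '"2 2   1 1",',
    '"A  c #FFFFFF " /* "0" */,',
    '"AB",', '"AA"'
  ), ext = ".xpm")
  expect_error(read_xpm(bad_code), "not declared in legend.*'B'")

  bad_row <- write_lines_tmp(c(
    '"3 2   1 1",',
    '"A  c #FFFFFF " /* "0" */,',
    '"AAA",', '"AA"'
  ), ext = ".xpm")
  expect_error(read_xpm(bad_row), "pixel row 2")

  bad_count <- write_lines_tmp(c(
    '"2 3   1 1",',
    '"A  c #FFFFFF " /* "0" */,',
    '"AA",', '"AA"'
  ), ext = ".xpm")
  expect_error(read_xpm(bad_count), "declares")
})

test_that("xpm round-trips through write_xpm with chars_per_pixel = 2", {
  legend <- tibble::tibble(code = c("AA", "BB", "C "),
                           label = c("0.0-1.0", "1.0-2.0", "2.0-3.0"),
                           lo = c(0, 1, 2), hi = c(1, 2, 3),
                           value = c(0.5, 1.5, 2.5))
  codes <- matrix(c("AA", "BB", "C ", "BB", "AA", "C "), nrow = 2,
                  byrow = TRUE)
  m <- structure(list(ncols = 3L, nrows = 2L, chars_per_pixel = 2L,
                      legend = legend, codes = codes,
                      x_ticks = 1:3, y_ticks = 1:2, title = "cpp2",
                      source_path = ""),
                 class = "xpm_matrix")
  p <- tempfile(fileext = ".xpm")
  write_xpm(m, p)
  back <- read_xpm(p)
  expect_equal(back$codes, codes)
  expect_equal(back$legend$value, legend$value)
  expect_equal(back$chars_per_pixel, 2L)
  expect_equal(back$x_ticks, c(1, 2, 3))
})

test_that("xpm_to_value_matrix maps single-number legends and refuses categorical ones", {
  p <- write_lines_tmp(c(
    '"2 1   2 1",',
    '"A  c #FFFFFF " /* "0.75" */,',
    '"B  c #000000 " /* "1.25" */,',
    '"AB"'
  ), ext = ".xpm")
  m <- read_xpm(p)
  expect_equal(xpm_to_value_matrix(m), matrix(c(0.75, 1.25), 1))

  ss <- write_lines_tmp(c(
    '"2 1   2 1",',
    '"H  c #FFFFFF " /* "A-Helix" */,',
    '"E  c #000000 " /* "B-Sheet" */,',
    '"HE"'
  ), ext = ".xpm")
  expect_error(xpm_to_value_matrix(read_xpm(ss)), "classify_dssp")
})

test_that("uniform single-code grid maps to a constant matrix", {
  p <- write_lines_tmp(c(
    '"3 3   1 1",',
    '"A  c #FFFFFF " /* "0.4-0.6" */,',
    '"AAA",', '"AAA",', '"AAA"'
  ), ext = ".xpm")
  expect_equal(xpm_to_value_matrix(read_xpm(p)), matrix(0.5, 3, 3))
})
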