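make_assignments <- function(rows) {
  # rows: list of character vectors of DSSP codes, one per frame
  codes <- do.call(rbind, rows)
  m <- structure(
    list(ncols = nrow(codes), nrows = ncol(codes), chars_per_pixel = 1L,
         legend = tibble::tibble(code = unique(as.vector(codes)),
                                 label = "", lo = NA_real_, hi = NA_real_,
                                 value = NA_real_),
         # GROMACS layout: residues on y, frames on x
         codes = t(codes), x_ticks = numeric(0), y_ticks = numeric(0),
         title = "", source_path = ""),
    class = "xpm_matrix"
  )
  classify_dssp(m, frames_on = "x")
}

test_that("classify_dssp applies the default code mapping", {
  a <- make_assignments(list(c("H", "H", "E", "C")))
  expect_equal(a$classes[1, ],
               c("alpha-helix", "alpha-helix", "beta-sheet", "coil/loop"))
  b <- make_assignments(list(c("~", "~", "~")))
  expect_true(all(b$classes == "coil/loop"))
  # B and I fold into beta-sheet and coil/loop
  d <- make_assignments(list(c("B", "I", "G", "S", "T")))
  expect_equal(a$n_residues, 4L)
  expect_equal(d$classes[1, ],
               c("beta-sheet", "coil/loop", "3-helix", "bend", "turn"))
})

test_that("classify_dssp rejects unmapped codes, naming them", {
  m <- structure(
    list(ncols = 1L, nrows = 1L, chars_per_pixel = 1L,
         legend = tibble::tibble(code = "X", label = "", lo = NA_real_,
                                 hi = NA_real_, value = NA_real_),
         codes = matrix("X"), x_ticks = numeric(0), y_ticks = numeric(0),
         title = "", source_path = ""),
    class = "xpm_matrix"
  )
  expect_error(classify_dssp(m), "'X'")
})

test_that("per-frame probability implements N_is / N_total * 100", {
  a <- make_assignments(list(
    c(rep("H", 5), rep("C", 35)),   # 5 of 40 helical -> 12.5 %
    rep("C", 40)
  ))
  p <- ss_probability(a)
  p1 <- p[p$frame == 1, ]
  expect_equal(p1$probability[p1$class == "alpha-helix"], 12.5)
  p2 <- p[p$frame == 2, ]
  expect_equal(p2$probability[p2$class == "coil/loop"], 100)
  expect_equal(sum(p2$probability[p2$class != "coil/loop"]), 0)
})

test_that("probabilities partition each frame (sum 100) and match brute-force counts", {
  set.seed(31)
  codes <- c("H", "G", "E", "B", "T", "S", "C", "~", "I")
  rows <- lapply(1:100, function(i) sample(codes, 30, replace = TRUE))
  a <- make_assignments(rows)
  p <- ss_probability(a)
  f <- ss_fraction(a)
  sums <- tapply(p$probability, p$frame, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_equal(f$fraction, p$probability / 100, tolerance = 1e-15)

  map <- dssp_mapping()
  for (i in c(1, 50, 100)) {
    truth <- table(factor(unname(map[rows[[i]]]), levels = ss_classes()))
    pi <- p[p$frame == i, ]
    expect_equal(pi$probability[match(names(truth), as.character(pi$class))],
                 as.vector(truth) / 30 * 100)
  }
})

test_that("probability is invariant under residue permutation within frames", {
  set.seed(32)
  row <- sample(c("H", "E", "C"), 25, replace = TRUE)
  a1 <- make_assignments(list(row))
  a2 <- make_assignments(list(sample(row)))
  expect_equal(ss_probability(a1)$probability, ss_probability(a2)$probability)
})

test_that("boxplot_summary reproduces interpolated quartiles and whiskers", {
  df <- data.frame(g = "a", v = c(10, 20, 30, 40, 50))
  bs <- boxplot_summary(df, v, g)
  expect_equal(bs$median, 30)
  expect_equal(bs$q1, 20)
  expect_equal(bs$q3, 40)
  expect_equal(bs$whisker_lo, 10)
  expect_equal(bs$whisker_hi, 50)
  expect_length(unlist(bs$outliers), 0L)

  const <- boxplot_summary(data.frame(g = "a", v = rep(4, 10)), v, g)
  expect_equal(const$median, 4)
  expect_equal(const$q1, 4)
  expect_equal(const$q3, 4)
})

test_that("boxplot_summary matches an independent sort-and-index quartile computation", {
  set.seed(33)
  x <- rnorm(1000)
  bs <- boxplot_summary(data.frame(v = x), v)
  # independent type-7 quartiles: linear interpolation of the sorted sample
  xs <- sort(x)
  q7 <- function(p) {
    hh <- (length(xs) - 1) * p
    lo <- floor(hh) + 1
    xs[lo] + (hh - floor(hh)) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(bs$median, q7(0.5), tolerance = 1e-12)
  expect_equal(bs$q1, q7(0.25), tolerance = 1e-12)
  expect_equal(bs$q3, q7(0.75), tolerance = 1e-12)
  iqr <- bs$q3 - bs$q1
  inside <- x[x >= bs$q1 - 1.5 * iqr & x <= bs$q3 + 1.5 * iqr]
  expect_equal(bs$whisker_lo, min(inside))
  expect_equal(bs$whisker_hi, max(inside))
  expect_equal(sort(unlist(bs$outliers)),
               sort(x[x < bs$q1 - 1.5 * iqr | x > bs$q3 + 1.5 * iqr]))
  expect_true(bs$median >= min(x) && bs$median <= max(x))
})

test_that("export_ss_fractions writes a CSV twin that round-trips values", {
  set.seed(34)
  rows <- lapply(1:3, function(i) sample(c("H", "E", "C"), 12, replace = TRUE))
  a <- make_assignments(rows)
  f <- ss_fraction(a)
  stem <- tempfile()
  paths <- export_ss_fractions(list(apo = f), stem)
  expect_true(all(file.exists(paths)))

  back <- utils::read.csv(paths[["csv"]], check.names = FALSE)
  expect_equal(nrow(back), 3L)
  # one frame column + six class columns
  expect_equal(ncol(back), 7L)
  expect_true(all(paste("apo", ss_classes(), sep = ".") %in% names(back)))
  for (cl in ss_classes()) {
    want <- f$fraction[f$class == cl]
    expect_equal(back[[paste("apo", cl, sep = ".")]], want,
                 tolerance = 1e-9)
  }
  # empty classes present as zero columns
  expect_equal(back[["apo.3-helix"]], rep(0, 3))
  # the workbook twin is well-formed XML with one row per frame + header
  wb <- readLines(paths[["workbook"]])
  expect_equal(sum(grepl("<Row>", wb)), 4L)
})
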