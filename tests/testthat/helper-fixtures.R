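# Shared helpers: build tiny GROMACS-dialect files in tempdirs.

local_fixture_dir <- function(env = parent.frame()) {
  d <- tempfile("fix")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

write_lines_tmp <- function(lines, ext = ".xvg", dir = tempdir()) {
  p <- tempfile(fileext = ext, tmpdir = dir)
  writeLines(lines, p)
  p
}

# Read a replica group of xvg files into an aligned replica_set.
read_replicas <- function(paths, group = "g", property = "prop",
                          unit = NULL) {
  series <- lapply(seq_along(paths), function(i) {
    as_time_series(read_xvg(paths[i]), replica = paste0("r", i),
                   property = property, unit = unit)
  })
  replica_set(series, group_label = group)
}

# Independent circular mean via complex arithmetic (not atan2 of means).
oracle_circular_mean <- function(deg) {
  z <- mean(exp(1i * deg * pi / 180))
  Arg(z) * 180 / pi
}
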