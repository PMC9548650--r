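test_that("compute_fc matches a brute-force Pearson computation", {
  cf <- cohort_config(n_subjects = 1, regions_per_hemisphere = 5,
                      submodule_pairs = c(primary = 5), n_timepoints = 50,
                      seed = 11)
  ts <- generate_cohort(cf)$timeseries[[1L]]
  fc <- compute_fc(ts)
  expect_lt(max(abs(unclass(fc) - brute_fc(ts$data))), 1e-12)
  expect_equal(fc_scale(fc), "pearson_r")
  expect_true(isSymmetric(unclass(fc)))
  expect_equal(unname(diag(fc)), rep(1, 10L))
  expect_true(all(abs(fc) <= 1))
})

test_that("perfectly dependent columns give correlations of +/-1 and the
           4-point example matches the defining formula", {
  sc <- minimal_scheme()
  s <- rnorm(30)
  ts <- roi_timeseries("S1", unname(cbind(s, s, -s, rnorm(30))), sc)
  fc <- compute_fc(ts)
  expect_equal(fc[1L, 2L], 1)
  expect_equal(fc[1L, 3L], -1)

  x <- c(1, 2, 3, 5); y <- c(2, 1, 4, 6)
  ts4 <- roi_timeseries("S1", unname(cbind(x, y, rev(x), rev(y))), sc)
  expect_lt(abs(compute_fc(ts4)[1L, 2L] - brute_pearson(x, y)), 1e-12)
})

test_that("a region made constant by GSR is reported by name", {
  sc <- minimal_scheme()
  s <- sin(seq_len(50))
  same <- roi_timeseries("S1", matrix(rep(s, 4L), 50L, 4L), sc)
  expect_error(compute_fc(same, gsr = TRUE), "zero-variance region")
})

test_that("fisher_z is the clipped atanh, odd, increasing, diagonal-masked", {
  sc <- minimal_scheme()
  s <- rnorm(40)
  ts <- roi_timeseries("S1", unname(cbind(s, s + rnorm(40), -s + rnorm(40),
                                          rnorm(40))), sc)
  fc <- compute_fc(ts)
  z <- fisher_z(fc)
  expect_equal(fc_scale(z), "fisher_z")
  expect_true(all(is.na(diag(z))))
  off <- upper.tri(fc)
  expect_equal(unclass(z)[off], atanh(unclass(fc)[off]), tolerance = 1e-12)

  # closed forms and clipping at |r| = 1
  ts1 <- roi_timeseries("S1",
                        unname(cbind(s, s, -s + 1e-8 * rnorm(40), rnorm(40))),
                        sc)
  z1 <- fisher_z(compute_fc(ts1))
  expect_true(is.finite(z1[1L, 2L]))
  expect_equal(z1[1L, 2L], atanh(1 - 1e-7))

  r <- seq(-0.95, 0.95, by = 0.05)
  zq <- atanh(r)
  expect_true(all(diff(zq) > 0))          # strictly increasing
  expect_equal(atanh(-r), -zq)            # odd
  expect_equal(atanh(0.5), 0.5 * log(3))  # z(0.5) = ln(3)/2
  expect_error(fisher_z(z), "pearson_r")
})

test_that("split_hemispheres performs the hand-traced index mapping", {
  sc <- interleaved_scheme()   # rows: L2, R1, L1, R2
  ts <- random_timeseries(sc, t = 60L)
  fc <- compute_fc(ts)
  hem <- split_hemispheres(fc, sc)

  # L rows in pair order are scheme rows (3, 1); R rows are (2, 4)
  expect_equal(unclass(hem$L), unclass(fc)[c(3L, 1L), c(3L, 1L)],
               ignore_attr = TRUE)
  expect_equal(unclass(hem$R), unclass(fc)[c(2L, 4L), c(2L, 4L)],
               ignore_attr = TRUE)
  expect_equal(rownames(hem$L), c("L1", "L2"))
  expect_equal(rownames(hem$R), c("R1", "R2"))
  expect_true(isSymmetric(unclass(hem$L)) && isSymmetric(unclass(hem$R)))

  expect_error(split_hemispheres(fc, two_module_scheme()), "does not match")
})

test_that("hemisphere splitting keeps exactly the intra-hemispheric edges", {
  cf <- cohort_config(n_subjects = 1, seed = 2)
  co <- generate_cohort(cf)
  fc <- compute_fc(co$timeseries[[1L]])
  hem <- split_hemispheres(fc, co$scheme)
  half <- n_pairs(co$scheme)
  expect_equal(length(vectorize_upper(hem$L)) + length(vectorize_upper(hem$R)),
               2L * half * (half - 1L) / 2L)
})

test_that("extract_submodule selects the labelled block by index bookkeeping", {
  sc <- two_module_scheme()    # pairs 1,2,4 primary; 3,5,6 unimodal
  ts <- random_timeseries(sc, t = 80L)
  hem <- split_hemispheres(compute_fc(ts), sc)

  prim <- extract_submodule(hem$L, "primary")
  expect_equal(dim(prim), c(3L, 3L))
  expect_equal(unclass(prim), unclass(hem$L)[c(1L, 2L, 4L), c(1L, 2L, 4L)],
               ignore_attr = TRUE)
  expect_equal(rownames(prim), c("L1", "L2", "L4"))

  # scheme where every pair carries the module: block equals the hemisphere
  sc1 <- minimal_scheme()
  hem1 <- split_hemispheres(compute_fc(random_timeseries(sc1)), sc1)
  expect_equal(unclass(extract_submodule(hem1$L, "primary")),
               unclass(hem1$L), ignore_attr = TRUE)

  expect_error(extract_submodule(hem$L, "paralimbic"), "need >= 2")
})

test_that("vectorize_upper is row-major, of length n(n-1)/2, and invertible", {
  m <- matrix(c(1, 2, 3, 2, 1, 4, 3, 4, 1), 3L)
  expect_equal(vectorize_upper(m), c(2, 3, 4))   # (m12, m13, m23)

  n <- 192L
  v <- rnorm(n * (n - 1L) / 2L)
  expect_equal(length(v), 18336L)
  M <- devectorize_upper(v, diag_value = 0)
  expect_equal(vectorize_upper(M), v)
  expect_true(isSymmetric(M))
  expect_error(vectorize_upper(1:3), "square")
  expect_error(devectorize_upper(rnorm(4L)), "not n\\(n-1\\)/2")
})

test_that("FC matrices round-trip through TSV and bad files are rejected", {
  sc <- two_module_scheme()
  fc <- compute_fc(random_timeseries(sc, t = 40L, seed = 9))
  path <- withr::local_tempfile(fileext = ".tsv")

  write_matrix(fc, path)
  back <- read_matrix(path, sc)
  expect_lt(max(abs(unclass(back) - unclass(fc))), 1e-12)
  expect_equal(fc_scale(back), "pearson_r")

  z <- fisher_z(fc)
  write_matrix(z, path)
  backz <- read_matrix(path, sc)
  expect_equal(fc_scale(backz), "fisher_z")
  offd <- !diag(nrow(z))
  expect_lt(max(abs(unclass(backz)[offd] - unclass(z)[offd])), 1e-12)

  # asymmetric entry
  lines <- readLines(path)
  row1 <- strsplit(lines[3L], "\t")[[1L]]   # first matrix row
  row1[2L] <- "0.5"                         # m[1,2] only: breaks symmetry
  lines[3L] <- paste(row1, collapse = "\t")
  writeLines(lines, path)
  expect_error(read_matrix(path), "not symmetric")

  # pearson matrix with an out-of-range entry
  m <- unclass(fc)
  m[1L, 2L] <- m[2L, 1L] <- 1.2
  fake <- fc; fake[] <- m
  write_matrix(fake, path)
  expect_error(read_matrix(path), "outside")
})
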