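test_that("per-base and bedGraph depth dialects parse identically", {
  iv <- data.frame(chrom = "chrY", start = 100, end = 103)
  perbase <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrY\t101\t7", "chrY\t102\t7", "chrY\t103\t7"), perbase)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chrY\t100\t103\t7", bg)
  p1 <- read_depth_table(perbase, iv)
  p2 <- read_depth_table(bg, iv)
  expect_equal(p1$depth, p2$depth)
  expect_equal(p1$depth[[1]], c(7, 7, 7))

  # absent rows inside a requested interval default to depth 0
  gap <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrY\t101\t10", "chrY\t103\t30"), gap)
  expect_equal(read_depth_table(gap, iv)$depth[[1]], c(10, 0, 30))
  expect_equal(read_depth_table(gap, iv, missing_as = NA)$depth[[1]],
               c(10, NA, 30))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrY\t101\t10", "chrY\toops\t30"), bad)
  expect_error(read_depth_table(bad, iv), "line 2")
  other <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrY\t101\t10", "chr1\t101\t10"), other)
  expect_warning(read_depth_table(other, iv), "chr1")
})

test_that("depth table round-trips through the writer", {
  prof <- simulate_depth(toy_map, m498_vector, 25, noise = "poisson", seed = 7)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_depth_table(prof, out)
  again <- read_depth_table(out, prof$intervals, sample_id = prof$sample_id)
  expect_equal(again$depth, prof$depth)
  out2 <- withr::local_tempfile(fileext = ".bedGraph")
  write_depth_table(prof, out2, format = "bedGraph")
  expect_equal(read_depth_table(out2, prof$intervals)$depth, prof$depth)
})

test_that("mean depth averages the union of intervals", {
  iv <- data.frame(chrom = "chrY", start = 0, end = 8)
  prof <- azfcnahr:::new_depth_profile("x", iv, list(c(10, 20, 30, 40, 5, 5, 5, 5)))
  expect_equal(mean_depth(prof, data.frame(chrom = "chrY", start = 0, end = 4)), 25)
  two <- data.frame(chrom = "chrY", start = c(0, 4), end = c(4, 8))
  expect_equal(mean_depth(prof, two), mean(c(25, 5)))
  # overlapping queries count each base once
  ovl <- data.frame(chrom = "chrY", start = c(0, 2), end = c(4, 4))
  expect_equal(mean_depth(prof, ovl), 25)
  expect_error(mean_depth(prof, iv[0, ]), "at least one")
  expect_error(mean_depth(prof, data.frame(chrom = "chrY", start = 6, end = 10)),
               "not fully covered")
})

test_that("normalized depth divides by the single-copy mean", {
  iv <- data.frame(chrom = "chrY", start = c(0, 100), end = c(10, 110))
  prof <- azfcnahr:::new_depth_profile("x", iv, list(rep(60, 10), rep(30, 10)))
  amp <- iv[1, ]; nrm <- iv[2, ]
  expect_equal(normalized_depth(prof, amp, nrm), 2)
  expect_equal(normalized_depth(prof, nrm, nrm), 1)
  zero <- azfcnahr:::new_depth_profile("z", iv, list(rep(60, 10), rep(0, 10)))
  expect_error(normalized_depth(zero, amp, nrm), "degenerate")
})

test_that("expected normalized depth is copies over reference copies", {
  expect_equal(expected_normalized_depth(2, 2), 1)
  expect_equal(expected_normalized_depth(1, 2), 0.5)
  expect_equal(expected_normalized_depth(0, 2), 0)
  expect_equal(expected_normalized_depth(5, 3), 5 / 3)
  expect_equal(expected_normalized_depth(6, 4), 1.5)
  expect_error(expected_normalized_depth(2, 0), "reference")
  expect_error(expected_normalized_depth(-1, 2), ">= 0")
})

test_that("midpoint calling reproduces the published thresholds and ratios", {
  expect_equal(calling_thresholds(1, 2), c(lower = 0.25, upper = 0.75))
  expect_equal(calling_thresholds(0, 2)[["upper"]], 0.25)
  expect_equal(call_copy_number(1.962, 2), 4L)
  expect_equal(call_copy_number(0.076, 2), 0L)
  expect_equal(call_copy_number(1.589, 3), 5L)
  expect_equal(call_copy_number(1.475, 4), 6L)
  expect_equal(call_copy_number(0.022, 1), 0L)
  # boundaries are lower-inclusive
  expect_equal(call_copy_number(0.75, 2), 2L)
  expect_equal(call_copy_number(0.25, 2), 1L)
  expect_error(call_copy_number(-0.1, 2), "non-negative")
  expect_warning(k <- call_copy_number(5, 2, k_max = 6), "clamping")
  expect_equal(k, 6L)
})

test_that("calling inverts expected depth and is monotone", {
  for (ref in c(1L, 2L, 3L, 4L)) {
    k_max <- 3L * ref
    for (k in 0:k_max)
      expect_equal(call_copy_number(expected_normalized_depth(k, ref), ref, k_max), k)
    nd <- seq(0, (k_max + 0.4) / ref, by = 0.01)
    calls <- vapply(nd, call_copy_number, integer(1), ref = ref, k_max = k_max)
    expect_true(all(diff(calls) >= 0))
  }
})

test_that("Table-style printed normalized depths call the printed ratios", {
  res <- call_from_normalized(table1_nd[["M4-98"]], full_map)
  expect_identical(as.integer(res$vector), as.integer(m498_vector))
  for (ctl in c("W043", "W005")) {
    res <- call_from_normalized(table1_nd[[ctl]], full_map)
    expect_identical(as.integer(res$vector),
                     as.integer(reference_copy_vector(full_map)))
  }
  expect_error(call_from_normalized(c(b = 1, t = 1), full_map), "missing")
})

test_that("call_all recovers generating vectors from noiseless simulations", {
  vectors <- list(
    reference_copy_vector(toy_map),
    m498_vector,
    copy_vector(6, 2, 6, 8, 4, 2, 1),   # after the duplication alone
    copy_vector(2, 2, 0, 2, 2, 2, 1),   # large deletion product
    copy_vector(0, 0, 0, 0, 0, 0, 0))
  for (v in vectors) {
    prof <- simulate_depth(toy_map, v, 30, noise = "none")
    expect_identical(as.integer(call_all(prof, toy_map)$vector), as.integer(v))
  }
  ref <- simulate_depth(toy_map, noise = "none")
  expect_equal(call_all(ref, toy_map)$calls$normalized_depth, rep(1, 7))
})

test_that("Poisson noise at 30x does not disturb calls on toy-scale intervals", {
  prof <- simulate_depth(toy_map, base_coverage = 30, noise = "poisson", seed = 11)
  expect_identical(as.integer(call_all(prof, toy_map)$vector),
                   as.integer(reference_copy_vector(toy_map)))
  # control invariance: a control called against itself is exactly 1
  res <- call_all(prof, toy_map)
  nd_self <- normalized_depth(prof, azfcnahr:::norm_interval(toy_map),
                              azfcnahr:::norm_interval(toy_map))
  expect_equal(nd_self, 1)
})
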