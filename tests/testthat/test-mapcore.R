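test_that("contact_map validates shape, symmetrizes, and masks missing bins", {
  m <- contact_map(matrix(0, 4, 4), bin_size_bp = 2048)
  expect_s3_class(m, "contact_map")
  expect_equal(n_bins(m), 4)
  expect_true(all(m$valid_mask))

  V <- matrix(rnorm(16), 4, 4)
  m2 <- contact_map(V, 2048)
  expect_equal(m2$values, (V + t(V)) / 2)

  V3 <- matrix(rnorm(16), 4, 4); V3 <- (V3 + t(V3)) / 2
  V3[2, ] <- NaN; V3[, 2] <- NaN
  m3 <- contact_map(V3, 2048, symmetrize = FALSE)
  expect_equal(unname(m3$valid_mask), c(TRUE, FALSE, TRUE, TRUE))
  expect_true(all(is.nan(m3$values[2, ])))

  expect_error(contact_map(matrix(0, 3, 4)), class = "format_error")
  expect_error(contact_map(matrix(NaN, 3, 3)), class = "empty_map_error")
})

test_that("one-triangle storage is recovered by missing-aware symmetrization", {
  V <- matrix(NaN, 4, 4)
  full <- matrix(rnorm(16), 4, 4); full <- (full + t(full)) / 2
  V[upper.tri(V, diag = TRUE)] <- full[upper.tri(full, diag = TRUE)]
  m <- contact_map(V, 2048)
  expect_equal(m$values, full)
})

test_that("TSV and RDS round trips preserve values", {
  m <- rand_map(12, seed = 1, na_frac = 0.05)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  rds <- withr::local_tempfile(fileext = ".rds")
  save_map(m, tsv)
  save_map(m, rds)
  m_tsv <- load_map(tsv, bin_size_bp = 2048)
  m_rds <- load_map(rds)
  expect_equal(m_tsv$values, m$values, tolerance = 1e-9)
  expect_identical(m_rds$values, m$values)   # binary round trip is bit-exact
  expect_identical(m_rds$bin_size_bp, m$bin_size_bp)
  expect_error(load_map("no/such/file.tsv"), class = "io_error")
  writeLines(c("0\t1\t2", "1\t0\t1"), tsv)
  expect_error(load_map(tsv, bin_size_bp = 2048), class = "format_error")
})

test_that("align_and_mask retains the upper triangle where both maps are defined", {
  a <- rand_map(10, seed = 2)
  b <- rand_map(10, seed = 3)
  mp <- align_and_mask(a, b)
  expect_equal(mp$n_retained, 55)   # n(n+1)/2

  a2 <- a
  a2$values[3, 6] <- NaN; a2$values[6, 3] <- NaN
  a2 <- contact_map(a2$values, 2048, symmetrize = FALSE)
  mp2 <- align_and_mask(a2, b)
  expect_equal(mp2$n_retained, 54)
  expect_false(any(mp2$i == 3 & mp2$j == 6))

  a3 <- rand_map(10, seed = 2, invalid_bins = 3)
  mp3 <- align_and_mask(a3, b)
  expect_equal(mp3$n_retained, 45)  # 55 - 10 positions touching bin 3
  expect_false(any(mp3$i == 3 | mp3$j == 3))

  expect_error(align_and_mask(a, rand_map(9, seed = 4)),
               class = "alignment_error")
  expect_error(align_and_mask(a, rand_map(10, seed = 4, bin_size_bp = 4096)),
               class = "alignment_error")
})

test_that("align_and_mask matches the brute-force enumeration and is symmetric", {
  for (seed in 1:10) {
    a <- rand_map(9, seed = seed, na_frac = 0.1,
                  invalid_bins = if (seed %% 3 == 0) c(2L, 7L) else integer())
    b <- rand_map(9, seed = seed + 100, na_frac = 0.1)
    mp <- align_and_mask(a, b)
    nv <- naive_masked_view(a, b)
    expect_equal(mp$x, nv$x)
    expect_equal(mp$y, nv$y)
    swapped <- align_and_mask(b, a)
    expect_equal(swapped$x, mp$y)
    expect_equal(swapped$y, mp$x)
  }
})

test_that("downsample pools valid block means and composes multiplicatively", {
  m <- rand_map(8, seed = 5)
  expect_identical(downsample(m, 1), m)

  const <- contact_map(matrix(1.5, 4, 4), 2048)
  d <- downsample(const, 2)
  expect_equal(d$values, matrix(1.5, 2, 2))
  expect_equal(d$bin_size_bp, 4096L)

  m9 <- rand_map(9, seed = 6, na_frac = 0.1)
  d9 <- downsample(m9, 2)
  expect_equal(n_bins(d9), 4)
  expect_equal(d9$values, naive_block_mean(m9$values, 2))

  m12 <- rand_map(12, seed = 7)
  expect_equal(downsample(downsample(m12, 2), 3)$values,
               downsample(m12, 6)$values)
  expect_error(downsample(m, 20), class = "degenerate_size_error")
})

test_that("smooth_map is identity for sigma 0 and constants, and conserves mass", {
  m <- rand_map(20, seed = 8)
  expect_identical(smooth_map(m, 0), m)

  const <- contact_map(matrix(2, 16, 16), 2048)
  expect_equal(smooth_map(const, 1.5)$values, const$values, tolerance = 1e-12)

  # mass conservation of the normalized kernel, checked on a map whose total
  # signal dominates its edge band
  big <- contact_map(1 + rand_map(64, seed = 10, sd = 0.05)$values, 2048,
                     symmetrize = FALSE)
  sb <- smooth_map(big, 1.5)
  expect_lt(abs(sum(sb$values) - sum(big$values)) / abs(sum(big$values)), 1e-3)
  expect_equal(sb$values, t(sb$values))
})

test_that("clip_values forces values to the nearest bound and records the range", {
  m <- rand_map(6, seed = 9, sd = 0.1)
  c1 <- clip_values(m, -2, 2)
  expect_equal(c1$values, m$values)   # already in range
  expect_equal(c1$clip_range, c(-2, 2))

  V <- matrix(c(3.5, 0, 0, -9), 2, 2); V <- (V + t(V)) / 2
  V[1, 1] <- 3.5; V[2, 2] <- -9
  m2 <- contact_map(V, 2048, symmetrize = FALSE)
  c2 <- clip_values(m2, -2, 2)
  expect_equal(c2$values[1, 1], 2)
  expect_equal(c2$values[2, 2], -2)
  expect_error(clip_values(m, 2, -2), class = "format_error")
})

test_that("genomic writers emit 0-based half-open plain-text records", {
  dir <- withr::local_tempdir()
  tr <- bin_track(c(NaN, 0.5, -0.25, NaN), 2048)
  p1 <- file.path(dir, "t.bedGraph")
  write_bedgraph(tr, p1, chrom = "chr3", start = 1000)
  lines <- readLines(p1)
  expect_length(lines, 2)   # NaN bins skipped
  expect_equal(lines[1], "chr3\t3048\t5096\t0.5")

  m <- make_template(n_bins = 128, seed = 50)
  b <- call_boundaries(m)
  p2 <- file.path(dir, "b.bed")
  write_bed(b, p2)
  expect_length(readLines(p2), nrow(b))
  expect_match(readLines(p2)[1], "^chr0\t\\d+\t\\d+\t[-0-9.e]+$")

  lp <- planted_peak_map(120, 30, 80)
  calls <- call_loops(lp)
  p3 <- file.path(dir, "l.bedpe")
  write_bedpe(calls, p3)
  expect_length(readLines(p3), nrow(calls))
  expect_equal(length(strsplit(readLines(p3)[1], "\t")[[1]]), 7)

  ts <- triangle_summary(rand_map(8, seed = 51))
  p4 <- file.path(dir, "tri.tsv")
  write_triangle_tsv(ts, p4)
  tab <- read.table(p4, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), sum(!is.na(ts$means)))
  expect_equal(tab$mean[tab$start_bin == 1 & tab$end_bin == 8],
               ts$means[1, 8], tolerance = 1e-6)
})
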