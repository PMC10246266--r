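test_that("insulation matches the naive diamond oracle and flags edges", {
  const <- contact_map(matrix(0.7, 20, 20), 2048, symmetrize = FALSE)
  tr <- insulation_track(const, 3)
  expect_true(all(is.nan(tr[c(1:3, 18:20)])))
  expect_true(all(abs(tr[4:17] - 0.7) < 1e-12))

  for (seed in 1:8) {
    m <- rand_map(20, seed = seed, na_frac = if (seed > 4) 0.1 else 0)
    tr <- as.numeric(insulation_track(m, 3))
    expect_equal(tr, naive_insulation(m$values, 3), tolerance = 1e-12)
  }
  expect_error(insulation_track(rand_map(10, 1), 5), class = "format_error")
})

test_that("insulation dips at the template's TAD boundaries", {
  m <- make_template(n_bins = 128, seed = 2)
  tr <- as.numeric(insulation_track(m, 5))
  q1 <- 128 / 4; q3 <- 3 * 128 / 4
  # local minima of the defined track
  mins <- which(diff(sign(diff(tr))) == 2) + 1
  expect_true(any(abs(mins - q1) <= 2))
  expect_true(any(abs(mins - q3) <= 2))
})

test_that("directionality index follows the signed chi-square form", {
  # bin 2 of a 3-bin map: A = exp(v[2,1]), B = exp(v[2,3]); set A=1, B=3
  V <- matrix(0, 3, 3)
  V[2, 3] <- V[3, 2] <- log(3)
  V[1, 3] <- V[3, 1] <- 0
  m <- contact_map(V, 2048, symmetrize = FALSE)
  tr <- di_track(m, window_resolution = 2048, replace_ends = FALSE)
  # E = 2, DI = +((1-2)^2/2 + (3-2)^2/2) = 1
  expect_equal(tr[2], 1, tolerance = 1e-12)

  # locally symmetric bin: A == B => 0
  sym <- contact_map(matrix(0.4, 5, 5), 2048, symmetrize = FALSE)
  trs <- di_track(sym, window_resolution = 2048, replace_ends = FALSE)
  expect_equal(trs[3], 0)

  # sign flips when upstream dominates: reverse the bin order
  tr2 <- di_track(contact_map(V[3:1, 3:1], 2048, symmetrize = FALSE),
                  window_resolution = 2048, replace_ends = FALSE)
  expect_equal(tr2[2], -1, tolerance = 1e-12)
})

test_that("directionality track ends are replaced with zeros", {
  m <- make_template(n_bins = 448, seed = 3)
  tr <- di_track(m)   # defaults: 10 kb window, replace_ends, buffer 50
  expect_true(all(tr[1:50] == 0))
  expect_true(all(tr[399:448] == 0))
  expect_true(any(tr[51:398] != 0))
})

test_that("eigenvector track separates a two-block map and is scale invariant", {
  n <- 16
  blk <- rep(c(TRUE, FALSE), each = n / 2)
  V <- outer(blk, blk, "==") * 1 - outer(blk, blk, "!=") * 1
  V <- V + diag(0.5, n)
  set.seed(20)
  V <- V + matrix(rnorm(n * n, 0, 0.01), n, n)
  m <- contact_map(V, 2048)
  e <- as.numeric(eigenvector_track(m))
  expect_true(all(sign(e[blk]) != sign(e[!blk])) ||
                all(sign(e[blk]) == -sign(e[!blk])))
  expect_equal(sum(e^2), 1, tolerance = 1e-9)

  scaled <- contact_map(m$values * 3, 2048, symmetrize = FALSE)
  expect_equal(as.numeric(eigenvector_track(scaled)), e, tolerance = 1e-9)

  # eigen residual against the correlation matrix it came from
  C <- cor(m$values)
  lam <- eigen(C, symmetric = TRUE)$values[1]
  expect_lt(sqrt(sum((C %*% e - lam * e)^2)), 1e-8)
})

test_that("orient_eigenvectors flips only anti-correlated pairs", {
  e1 <- bin_track(c(1, 2, 3, -1, -2), 2048)
  flipped <- orient_eigenvectors(e1, bin_track(-unclass(e1), 2048))
  expect_equal(as.numeric(flipped[[2]]), as.numeric(e1))
  same <- orient_eigenvectors(e1, e1)
  expect_equal(as.numeric(same[[2]]), as.numeric(e1))
  # exactly zero correlation: the tie-break is "no flip"
  orth <- bin_track(c(1, 1, -1, -1), 2048)
  kept <- orient_eigenvectors(bin_track(c(1, -1, 1, -1), 2048), orth)
  expect_equal(as.numeric(kept[[2]]), as.numeric(orth))
})

test_that("contact decay equals per-offset means, exactly on Toeplitz maps", {
  n <- 10
  v_s <- seq(1, 0.1, length.out = n)
  V <- outer(seq_len(n), seq_len(n), function(i, j) v_s[abs(i - j) + 1])
  m <- contact_map(V, 2048, symmetrize = FALSE)
  dc <- contact_decay_curve(m)
  expect_equal(dc$values, v_s)

  const <- contact_map(matrix(0.3, 8, 8), 2048, symmetrize = FALSE)
  expect_true(all(contact_decay_curve(const)$values == 0.3))

  m2 <- rand_map(12, seed = 21, invalid_bins = 5L)
  expect_equal(contact_decay_curve(m2)$values, naive_decay(m2),
               tolerance = 1e-12)
})

test_that("triangle summary equals the O(n^4) enumeration oracle", {
  const <- contact_map(matrix(1.2, 10, 10), 2048, symmetrize = FALSE)
  ts <- triangle_summary(const)
  expect_true(all(abs(ts$means[!is.na(ts$means)] - 1.2) < 1e-12))

  for (seed in 22:26) {
    m <- rand_map(15, seed = seed, na_frac = if (seed %% 2) 0.1 else 0)
    ts <- triangle_summary(m, min_size = 3)
    expect_equal(ts$means, naive_triangle(m$values, 3), tolerance = 1e-10)
    # full-map entry is the mean of the upper triangle
    mp <- align_and_mask(m, m)
    expect_equal(ts$means[1, 15], mean(mp$x), tolerance = 1e-12)
  }
  expect_error(triangle_summary(rand_map(2, 1), 3), class = "format_error")
})

test_that("compare_tracks handles both modes and interleaved NaN", {
  x <- bin_track(c(1, 2, NaN, 4, 5, 6), 2048)
  expect_identical(compare_tracks(x, x, "mse"), 0)
  expect_identical(compare_tracks(x, x, "spearman"), 0)

  y <- bin_track(c(10, 20, 30, NaN, 50, 60), 2048)   # monotone transform
  expect_identical(compare_tracks(x, y, "spearman"), 0)

  shared <- c(1, 2, 5, 6)
  expect_equal(compare_tracks(x, y, "mse"),
               mean((shared - 10 * shared)^2), tolerance = 1e-12)

  expect_error(compare_tracks(x, bin_track(rep(1, 6), 2048), "spearman"),
               class = "undefined_correlation_error")
  expect_error(compare_tracks(x, bin_track(1:5, 2048), "mse"),
               class = "alignment_error")
  expect_error(compare_tracks(x, contact_decay_curve(rand_map(6, 1)), "mse"),
               class = "format_error")
})

test_that("every map-informed self-comparison is exactly zero", {
  m <- make_template(n_bins = 160, seed = 30)
  expect_identical(compare_tracks(insulation_track(m), insulation_track(m), "mse"), 0)
  expect_identical(compare_tracks(di_track(m), di_track(m), "spearman"), 0)
  expect_identical(compare_tracks(contact_decay_curve(m), contact_decay_curve(m), "mse"), 0)
  expect_identical(compare_tracks(triangle_summary(m), triangle_summary(m), "spearman"), 0)
})
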