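test_that("the template is a valid TAD canvas and deterministic", {
  m <- make_template(n_bins = 128, seed = 11)
  n <- 128; q1 <- m$sim_params$q1; q3 <- m$sim_params$q3
  inb <- seq_len(n) >= q1 & seq_len(n) <= q3
  expect_gt(mean(m$values[outer(inb, inb, "&")]),
            mean(m$values[outer(!inb, !inb, "&")]))
  expect_equal(m$values, t(m$values))
  expect_true(all(m$values >= -2 & m$values <= 2))
  expect_true(all(m$valid_mask))
  expect_identical(m$values, make_template(n_bins = 128, seed = 11)$values)
  expect_false(identical(m$values, make_template(n_bins = 128, seed = 12)$values))
})

test_that("the substructure variant adds a mid-TAD boundary and matches elsewhere", {
  m <- make_template(n_bins = 128, seed = 13)
  s <- make_substructure_template(m)
  it_m <- as.numeric(insulation_track(m, 5))
  it_s <- as.numeric(insulation_track(s, 5))
  mid <- 64
  # insulation dips at n/2 only in the variant
  expect_lt(it_s[mid] - it_m[mid], -0.2)
  # identical outside the affected block (smoothing spreads a few bins)
  outside <- c(1:20, 110:128)
  expect_equal(m$values[outside, outside], s$values[outside, outside])
  expect_identical(make_substructure_template(m)$values, s$values)
})

test_that("every perturbation kind is the identity at its no-op degree", {
  m <- make_template(n_bins = 96, seed = 14)
  noop <- list(noise = 0, resolution = 2048, contrast = 1, intensity = 0,
               size = 1, substructure = 0)
  for (kind in names(noop)) {
    out <- perturb(m, perturbation_spec(kind, seed = 1), noop[[kind]], seed = 5)
    expect_identical(out$values, m$values)
  }
  expect_error(perturb(m, perturbation_spec("noise"), 0.5, 1),
               class = "format_error")
})

test_that("contrast and intensity perturbations obey their exact algebra", {
  m <- make_template(n_bins = 96, seed = 15)
  mp <- align_and_mask(m, m)
  b <- perturb(m, perturbation_spec("contrast"), 1.6, 1)
  expect_equal(mse(m, b), (1.6 - 1)^2 * mean(mp$x^2), tolerance = 1e-10)
  b2 <- perturb(m, perturbation_spec("intensity"), 0.13, 1)
  expect_equal(mse(m, b2), 0.13^2, tolerance = 1e-10)
})

test_that("the noise field is symmetric with per-entry variance sd^2", {
  m <- make_template(n_bins = 96, seed = 16)
  spec <- perturbation_spec("noise", seed = 3)
  b <- perturb(m, spec, 0.2, seed = 21)
  expect_equal(b$values, t(b$values))
  expect_identical(perturb(m, spec, 0.2, seed = 21)$values, b$values)
  # Monte-Carlo mean MSE against the analytic expectation sigma^2
  v <- vapply(1:60, function(s) mse(m, perturb(m, spec, 0.2, seed = s)),
              numeric(1))
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 0.04), 3 * se)
})

test_that("resolution perturbation renders block means on the original grid", {
  m <- make_template(n_bins = 96, seed = 17)
  b <- perturb(m, perturbation_spec("resolution"), 5 * 2048, 1)
  expect_equal(n_bins(b), 96)
  # block-constant: value at (1,1) equals the 5x5 block mean
  expect_equal(b$values[1, 1], mean(m$values[1:5, 1:5]), tolerance = 1e-12)
  expect_equal(b$values[3, 4], b$values[1, 1])
  # downsample() proper shrinks: factor at the 50,972 bp endpoint is 25
  expect_equal(n_bins(downsample(make_template(seed = 18),
                                 round(50972 / 2048))), floor(448 / 25))
})

test_that("size perturbation grows the domain toward the origin anchor", {
  m <- make_template(n_bins = 128, seed = 19)
  b <- perturb(m, perturbation_spec("size"), 1.1, 1)
  expect_equal(n_bins(b), 128)
  # boundaries move outward: insulation minima shift right
  bnd_m <- call_boundaries(m)$bin
  bnd_b <- call_boundaries(b)$bin
  expect_true(all(bnd_b >= bnd_m - 1))
  expect_gt(max(bnd_b), max(bnd_m))
})

test_that("ladders follow the degree grid and regenerate bit-identically", {
  m <- make_template(n_bins = 96, seed = 20)
  spec <- perturbation_spec("noise", n_degrees = 12, seed = 7)
  lad <- make_ladder(m, spec)
  expect_length(lad$maps, 12)
  expect_equal(lad$degrees, seq(0, 0.2, length.out = 12))
  expect_true(all(diff(lad$degrees) > 0))
  expect_identical(lad$maps[[1]]$values, m$values)   # identity endpoint
  lad2 <- make_ladder(m, spec)
  for (d in c(1, 5, 12)) {
    expect_identical(lad2$maps[[d]]$values, lad$maps[[d]]$values)
  }
})

test_that("variant pairs isolate the named structural edit", {
  pr <- make_variant_pair("contrast_only", magnitude = 0.8, seed = 21,
                          n_bins = 96)
  expect_identical(spearman_disruption(pr$a, pr$b), 0)
  expect_gt(mse(pr$a, pr$b), 0)

  lp <- make_variant_pair("loop_change", magnitude = 1, seed = 22,
                          n_bins = 128)
  expect_equal(nrow(call_loops(lp$a)), 0)
  expect_gte(nrow(call_loops(lp$b)), 1)

  bc <- make_variant_pair("boundary_change", magnitude = 1, seed = 23,
                          n_bins = 128)
  expect_gt(nrow(call_boundaries(bc$b)), nrow(call_boundaries(bc$a)))

  sp <- make_variant_pair("stripe_change", magnitude = 0.5, seed = 24,
                          n_bins = 128)
  expect_gt(mse(sp$a, sp$b), 0)
  expect_equal(sp$a$values, make_template(n_bins = 128, seed = 24)$values)
})

test_that("small-deletion analogs barely perturb the map", {
  m <- make_template(n_bins = 128, seed = 25)
  d <- simulate_small_deletion(m, del_bp = 100, at_bin = 40)
  expect_equal(n_bins(d), 128)
  expect_gt(mse(m, d), 0)
  expect_lt(mse(m, d), 1e-3)
  # upstream of the deletion the map is unchanged
  expect_equal(d$values[1:38, 1:38], m$values[1:38, 1:38], tolerance = 1e-12)
})
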