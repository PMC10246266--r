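# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive loops/enumeration so they share no code path with the package
# implementations they check.

# Random symmetric contact map; optional missing entries and invalid bins.
rand_map <- function(n, seed, sd = 0.3, na_frac = 0, invalid_bins = integer(),
                     bin_size_bp = 2048) {
  set.seed(seed)
  V <- matrix(rnorm(n * n, 0, sd), n, n)
  V <- (V + t(V)) / 2
  if (na_frac > 0) {
    up <- which(upper.tri(V, diag = TRUE))
    drop <- sample(up, ceiling(na_frac * length(up)))
    V[drop] <- NaN
    V <- ifelse(is.nan(V) | is.nan(t(V)), NaN, V)
  }
  if (length(invalid_bins)) {
    V[invalid_bins, ] <- NaN
    V[, invalid_bins] <- NaN
  }
  contact_map(V, bin_size_bp = bin_size_bp, symmetrize = FALSE)
}

# Enumerate the retained masked-pair positions by explicit double loop.
naive_masked_view <- function(a, b) {
  n <- nrow(a$values)
  xs <- c(); ys <- c()
  for (i in seq_len(n)) for (j in i:n) {
    if (a$valid_mask[i] && a$valid_mask[j] && b$valid_mask[i] &&
        b$valid_mask[j] && is.finite(a$values[i, j]) &&
        is.finite(b$values[i, j])) {
      xs <- c(xs, a$values[i, j]); ys <- c(ys, b$values[i, j])
    }
  }
  list(x = xs, y = ys)
}

# Block means by explicit loops.
naive_block_mean <- function(V, f) {
  k <- nrow(V) %/% f
  out <- matrix(NaN, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    blk <- V[((a - 1) * f + 1):(a * f), ((b - 1) * f + 1):(b * f)]
    blk <- blk[is.finite(blk)]
    if (length(blk)) out[a, b] <- mean(blk)
  }
  out
}

# Diamond means by explicit loops (1-based i, half-width w).
naive_insulation <- function(V, w) {
  n <- nrow(V)
  out <- rep(NaN, n)
  for (i in (w + 1):(n - w)) {
    blk <- V[(i - w):(i - 1), (i + 1):(i + w)]
    blk <- blk[is.finite(blk)]
    if (length(blk)) out[i] <- mean(blk)
  }
  out
}

# O(n^4) enumeration of every diagonal-anchored submatrix upper-triangle mean.
naive_triangle <- function(V, min_size) {
  n <- nrow(V)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1 < min_size) next
    s <- 0; k <- 0
    for (a in i:j) for (b in a:j) {
      if (is.finite(V[a, b])) { s <- s + V[a, b]; k <- k + 1 }
    }
    out[i, j] <- if (k > 0) s / k else NaN
  }
  out
}

# Background map with a planted focal peak: a (2p+1)-square block of elevated
# log contact around (pi, pj), mirrored below the diagonal.
planted_peak_map <- function(n, pi, pj, height = log(2), p = 2,
                             background = 0) {
  V <- matrix(background, n, n)
  V[(pi - p):(pi + p), (pj - p):(pj + p)] <- background + height
  V[(pj - p):(pj + p), (pi - p):(pi + p)] <- background + height
  contact_map(V, 2048, symmetrize = FALSE)
}

# Per-diagonal Pearson + weighted average, straight from the definition.
naive_scc <- function(a, b, max_offset = NULL) {
  n <- nrow(a$values)
  if (is.null(max_offset)) max_offset <- n - 1
  num <- 0; den <- 0
  for (k in 0:max_offset) {
    xs <- c(); ys <- c()
    for (i in seq_len(n - k)) {
      x <- a$values[i, i + k]; y <- b$values[i, i + k]
      if (a$valid_mask[i] && a$valid_mask[i + k] && b$valid_mask[i] &&
          b$valid_mask[i + k] && is.finite(x) && is.finite(y)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    if (length(xs) >= 3 && sd(xs) > 0 && sd(ys) > 0) {
      w <- length(xs) * sd(xs) * sd(ys)
      num <- num + w * cor(xs, ys)
      den <- den + w
    }
  }
  1 - num / den
}

# Mean contact per diagonal offset by explicit loops.
naive_decay <- function(a) {
  n <- nrow(a$values)
  out <- rep(NaN, n)
  for (k in 0:(n - 1)) {
    vals <- c()
    for (i in seq_len(n - k)) {
      x <- a$values[i, i + k]
      if (is.finite(x)) vals <- c(vals, x)
    }
    if (length(vals)) out[k + 1] <- mean(vals)
  }
  out
}

# Windowed SSIM by explicit per-pixel loops over full (2r+1)^2 Gaussian
# windows; border pixels without full support are skipped, matching the
# implementation's crop.
naive_ssim <- function(a, b, window = 7, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                       L = 4) {
  va <- a$values; vb <- b$values
  va[!is.finite(va)] <- 0; vb[!is.finite(vb)] <- 0
  n <- nrow(va)
  r <- (window - 1) %/% 2
  g <- exp(-0.5 * ((-r:r) / sigma)^2); g <- g / sum(g)
  W <- outer(g, g)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  vals <- c()
  for (i in (r + 1):(n - r)) for (j in (r + 1):(n - r)) {
    wa <- va[(i - r):(i + r), (j - r):(j + r)]
    wb <- vb[(i - r):(i + r), (j - r):(j + r)]
    ua <- sum(W * wa); ub <- sum(W * wb)
    s2a <- sum(W * wa * wa) - ua^2
    s2b <- sum(W * wb * wb) - ub^2
    sab <- sum(W * wa * wb) - ua * ub
    vals <- c(vals, ((2 * ua * ub + C1) * (2 * sab + C2)) /
                ((ua^2 + ub^2 + C1) * (s2a + s2b + C2)))
  }
  mean(vals)
}
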