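# Internal helpers shared across modules.

# Classed error so callers can distinguish failure modes with tryCatch().
cm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "contactdiff_error", "error", "condition")))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user scripts.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Normalized 1D Gaussian kernel with radius ceiling(truncate * sigma).
gaussian_kernel <- function(sigma, truncate = 3, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- seq.int(-radius, radius)
  g <- exp(-0.5 * (x / sigma)^2)
  g / sum(g)
}

# Banded convolution matrix K with K[i, j] = kernel[|i - j|]; K %*% X %*% K is
# the separable zero-padded 2D convolution of X with the kernel.
band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  half <- kernel[(r + 1L):length(kernel)]   # kernel is symmetric
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- matrix(0, n, n)
  sel <- D <= r
  K[sel] <- half[D[sel] + 1L]
  K
}

# Summed-area table with a zero top row/left column: rectangle sums in O(1).
sat <- function(M) {
  n <- nrow(M); m <- ncol(M)
  S <- matrix(0, n + 1L, m + 1L)
  S[-1L, -1L] <- t(apply(apply(M, 2L, cumsum), 1L, cumsum))
  S
}

# Sum of M over rows r1..r2, cols c1..c2 (inclusive, 1-based); vectorized.
# Linear indexing into the padded table avoids per-call index-matrix
# allocation on large candidate grids.
rect_sum <- function(S, r1, r2, c1, c2) {
  np <- nrow(S)
  S[c2 * np + r2 + 1L] - S[c2 * np + r1] -
    S[(c1 - 1L) * np + r2 + 1L] + S[(c1 - 1L) * np + r1]
}

# Linear interpolation matrix A (length(g) x n): (A %*% M %*% t(A)) samples a
# matrix bilinearly at target coordinates g (in [1, n]) along both axes.
interp_matrix <- function(n, g) {
  stopifnot(all(g >= 1 - 1e-9), all(g <= n + 1e-9))
  g <- pmin(pmax(g, 1), n)
  i0 <- pmin(floor(g), n - 1L)
  f <- g - i0
  A <- matrix(0, length(g), n)
  A[cbind(seq_along(g), i0)] <- 1 - f
  A[cbind(seq_along(g), i0 + 1L)] <- f
  A
}

# NaN-aware mean of a numeric vector; NaN when nothing is finite.
fin_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) NaN else mean(x)
}
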