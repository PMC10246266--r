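# Basic (whole-matrix) comparison scores. All operate on the masked pair view
# of the two maps: upper triangle including the diagonal, positions finite and
# valid in both maps. Disruption variants are oriented so 0 = identical and
# larger = more different.

#' Mean squared error between two contact maps
#'
#' @param a,b Alignable `contact_map`s.
#' @return Nonnegative mean of squared differences over the masked pair view.
#' @export
mse <- function(a, b) {
  mp <- align_and_mask(a, b)
  mean((mp$x - mp$y)^2)
}

# Correlation of the masked pair view, with the preconditions shared by the
# rank/linear variants: at least 3 retained positions, neither sequence
# constant (a constant sequence has no defined correlation and must error
# rather than silently return 0).
.masked_cor <- function(a, b, method) {
  mp <- align_and_mask(a, b)
  if (mp$n_retained < 3L) {
    cm_stop("fewer than 3 retained positions", "empty_overlap_error")
  }
  if (stats::sd(mp$x) == 0 || stats::sd(mp$y) == 0) {
    cm_stop(sprintf("%s correlation undefined: constant input", method),
            "undefined_correlation_error")
  }
  # identical sequences have correlation exactly 1; floating-point summation
  # in cor() can land an ulp short, so enforce the identity explicitly
  # (for the rank variant, on the ranks: a monotone transform then scores
  # exactly 0 disruption, as it should)
  if (method == "spearman") {
    rx <- rank(mp$x); ry <- rank(mp$y)
    if (identical(rx, ry)) return(1)
    return(stats::cor(rx, ry))
  }
  if (identical(mp$x, mp$y)) return(1)
  stats::cor(mp$x, mp$y, method = method)
}

#' Spearman disruption score
#'
#' `1 -` Spearman rank correlation of the masked pair view (average ranks for
#' ties), so identical maps score 0 and anti-correlated maps score 2. Errors
#' on constant input rather than returning a silent 0.
#'
#' @inheritParams mse
#' @return Value in `[0, 2]`.
#' @export
spearman_disruption <- function(a, b) 1 - .masked_cor(a, b, "spearman")

#' Pearson disruption score
#'
#' `1 -` Pearson correlation of the masked pair view. Kept as an optional
#' method; it behaves almost identically to the Spearman variant on smoothed
#' log(observed/expected) maps and is excluded from the default method suite.
#'
#' @inheritParams mse
#' @return Value in `[0, 2]`.
#' @export
pearson_disruption <- function(a, b) 1 - .masked_cor(a, b, "pearson")

# Mean local SSIM over the pair, Gaussian-windowed. Missing values are filled
# with 0 (the observed/expected-neutral value in log space) for the windowed
# pass only; the window is a width-`win` Gaussian (sigma 1.5 by default) and
# the dynamic range is fixed (default 4, the span of the conventional (-2, 2)
# clip) so scores are comparable across pairs. Border bins whose window
# extends outside the matrix are cropped from the mean.
.ssim_mean <- function(a, b, window = 7, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                       dynamic_range = 4) {
  mp <- align_and_mask(a, b)   # validates alignability / nonempty overlap
  va <- a$values; vb <- b$values
  va[!is.finite(va)] <- 0
  vb[!is.finite(vb)] <- 0
  n <- nrow(va)
  r <- (window - 1L) %/% 2L
  if (n < window) cm_stop("map smaller than the SSIM window", "format_error")
  K <- band_matrix(n, gaussian_kernel(sigma, radius = r))
  conv <- function(X) K %*% X %*% K
  ua <- conv(va); ub <- conv(vb)
  va2 <- conv(va * va) - ua * ua
  vb2 <- conv(vb * vb) - ub * ub
  cab <- conv(va * vb) - ua * ub
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  S <- ((2 * ua * ub + C1) * (2 * cab + C2)) /
    ((ua * ua + ub * ub + C1) * (va2 + vb2 + C2))
  core <- S[(r + 1L):(n - r), (r + 1L):(n - r)]
  mean(core)
}

#' SSIM disruption score
#'
#' `1 -` mean local structural similarity between the two maps, computed with
#' a Gaussian window and a fixed dynamic range so that scores are comparable
#' across map pairs. Identical maps score exactly 0.
#'
#' @inheritParams mse
#' @param window Odd window width in bins.
#' @param sigma Gaussian window standard deviation in bins.
#' @param K1,K2 SSIM stability constants.
#' @param dynamic_range Fixed dynamic range of the values (4 spans the
#'   conventional (-2, 2) log clip).
#' @return Value in `[0, 2]`.
#' @export
ssim_disruption <- function(a, b, window = 7, sigma = 1.5, K1 = 0.01,
                            K2 = 0.03, dynamic_range = 4) {
  1 - .ssim_mean(a, b, window, sigma, K1, K2, dynamic_range)
}

# Per-stratum (diagonal offset) statistics backing the SCC: retained pair
# count, Pearson correlation and the two standard deviations per offset.
# Strata with < 3 pairs or zero variance in either map are unusable.
.scc_strata <- function(a, b, max_offset = NULL) {
  mp <- align_and_mask(a, b)
  off <- mp$j - mp$i
  if (!is.null(max_offset)) {
    keep <- off <= max_offset
    if (!any(keep)) cm_stop("no strata within max_offset", "degenerate_stratum_error")
    mp$x <- mp$x[keep]; mp$y <- mp$y[keep]; off <- off[keep]
  }
  groups <- split(seq_along(off), off)
  ng <- length(groups)
  offset <- integer(ng); n <- integer(ng)
  r <- rep(NA_real_, ng); sd_a <- numeric(ng); sd_b <- numeric(ng)
  w <- numeric(ng); usable <- logical(ng)
  for (g in seq_len(ng)) {
    ix <- groups[[g]]
    x <- mp$x[ix]; y <- mp$y[ix]
    nk <- length(ix)
    offset[g] <- off[ix[1L]]; n[g] <- nk
    sda <- if (nk >= 2L) stats::sd(x) else 0
    sdb <- if (nk >= 2L) stats::sd(y) else 0
    sd_a[g] <- sda; sd_b[g] <- sdb
    if (nk >= 3L && sda > 0 && sdb > 0) {
      usable[g] <- TRUE
      # identical strata have correlation exactly 1, see .masked_cor
      r[g] <- if (identical(x, y)) 1 else stats::cor(x, y)
      w[g] <- nk * sda * sdb
    }
  }
  data.frame(offset = offset, n = n, r = r, sd_a = sd_a, sd_b = sd_b,
             w = w, usable = usable)
}

#' Stratum-adjusted correlation disruption score
#'
#' `1 - SCC`, where the stratum-adjusted correlation coefficient is the
#' weighted mean of per-diagonal-offset Pearson correlations,
#' `SCC = sum_k w_k r_k / sum_k w_k` with HiCRep-style weights
#' `w_k = N_k sd_k(a) sd_k(b)`. Strata with fewer than 3 retained pairs or
#' zero variance in either map are skipped. No additional 2D smoothing is
#' applied (inputs are assumed already smoothed).
#'
#' @inheritParams mse
#' @param max_offset Largest diagonal offset (genomic distance in bins) to
#'   include; `NULL` uses the full map.
#' @return Value in `[0, 2]`.
#' @export
scc_disruption <- function(a, b, max_offset = NULL) {
  st <- .scc_strata(a, b, max_offset)
  st <- st[st$usable, , drop = FALSE]
  if (nrow(st) == 0L) {
    cm_stop("no usable stratum (all have < 3 pairs or zero variance)",
            "degenerate_stratum_error")
  }
  1 - sum(st$w * st$r) / sum(st$w)
}
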