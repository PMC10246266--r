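# Map-informed methods: transform each map into a 1D summary (per-bin track,
# per-distance decay curve, or triangle table), then compare the pair of
# summaries with MSE or Spearman.

#' Per-bin track aligned to contact map bins
#'
#' A classed numeric vector of per-bin values; `NaN` marks bins where the
#' statistic is undefined (edges within a method's window, invalid bins).
#' Edge bins are never extrapolated.
#'
#' @param values Numeric vector, one value per map bin.
#' @param bin_size_bp Bin size in bp.
#' @param method Label of the generating method.
#' @return A `bin_track`.
#' @export
bin_track <- function(values, bin_size_bp, method = "track") {
  structure(as.numeric(values), bin_size_bp = as.integer(bin_size_bp),
            method = method, class = "bin_track")
}

#' @export
print.bin_track <- function(x, ...) {
  cat(sprintf("bin_track (%s): %d bins, %d defined\n",
              attr(x, "method"), length(x), sum(is.finite(x))))
  invisible(x)
}

#' Insulation score track
#'
#' `track[i]` is the mean contact of the diamond-shaped window straddling bin
#' `i`: rows `i-w .. i-1` by columns `i+1 .. i+w` (w = `window_size`), over
#' valid finite entries. Bins within `w` of either edge are `NaN`. Because
#' inputs are already observed/expected-normalized, the raw diamond mean is
#' returned without the log2-to-genome-mean normalization used on raw counts.
#'
#' @param m A `contact_map`.
#' @param window_size Diamond half-width in bins.
#' @param scale `"log"` (default) computes the diamond mean on the stored
#'   log(observed/expected) values; `"ratio"` exponentiates first.
#' @return A `bin_track` of length `n_bins(m)`; local minima mark insulating
#'   boundaries.
#' @export
insulation_track <- function(m, window_size = 10, scale = c("log", "ratio")) {
  stopifnot(inherits(m, "contact_map"))
  scale <- match.arg(scale)
  w <- as.integer(window_size)
  n <- n_bins(m)
  if (w < 1L || n <= 2L * w) {
    cm_stop("window_size too large for this map", "format_error")
  }
  V <- m$values
  if (scale == "ratio") V <- exp(V)
  fin <- is.finite(V)
  Sv <- sat(ifelse(fin, V, 0))
  Sc <- sat(fin + 0)
  out <- rep(NaN, n)
  i <- (w + 1L):(n - w)
  s <- rect_sum(Sv, i - w, i - 1L, i + 1L, i + w)
  cnt <- rect_sum(Sc, i - w, i - 1L, i + 1L, i + w)
  out[i] <- ifelse(cnt > 0, s / cnt, NaN)
  out[!m$valid_mask] <- NaN
  bin_track(out, m$bin_size_bp, "insulation")
}

#' Directionality index track
#'
#' For each bin, `A` is the summed contact to the `W` upstream bins and `B`
#' to the `W` downstream bins (`W = round(window_resolution / bin_size_bp)`),
#' on a strictly positive scale; with `E = (A + B) / 2`, the statistic is
#' `sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)`, and 0 when `A == B`.
#' Its sign flips at domain boundaries. Because the chi-square-style
#' denominators require nonnegative sums, the default exponentiates the
#' stored log(observed/expected) values.
#'
#' @param m A `contact_map`.
#' @param window_resolution Sliding-window width in bp.
#' @param replace_ends Replace the track ends with 0s (default).
#' @param buffer How many bins at each end to replace with 0.
#' @param scale `"ratio"` (default) exponentiates to observed/expected
#'   ratios; `"log"` uses the stored values and errors if a window sum is
#'   not positive.
#' @return A `bin_track` of length `n_bins(m)`.
#' @export
di_track <- function(m, window_resolution = 10000, replace_ends = TRUE,
                     buffer = 50, scale = c("ratio", "log")) {
  stopifnot(inherits(m, "contact_map"))
  scale <- match.arg(scale)
  n <- n_bins(m)
  W <- as.integer(round(window_resolution / m$bin_size_bp))
  if (W < 1L) cm_stop("window_resolution below one bin", "format_error")
  if (n <= 2L * W) cm_stop("window too large for this map", "format_error")
  V <- m$values
  if (scale == "ratio") V <- exp(V)
  V0 <- ifelse(is.finite(V), V, 0)
  A <- numeric(n); B <- numeric(n)
  idx <- seq_len(n)
  for (d in seq_len(W)) {
    up <- idx - d
    ok <- up >= 1L
    A[ok] <- A[ok] + V0[cbind(idx[ok], up[ok])]
    dn <- idx + d
    ok <- dn <= n
    B[ok] <- B[ok] + V0[cbind(idx[ok], dn[ok])]
  }
  E <- (A + B) / 2
  if (scale == "log" && any(E <= 0 & A != B)) {
    cm_stop("window sums must be positive on the log scale; use scale='ratio'",
            "format_error")
  }
  di <- ifelse(A == B, 0,
               sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E))
  if (isTRUE(replace_ends) && buffer > 0L) {
    b <- min(as.integer(buffer), n)
    di[seq_len(b)] <- 0
    di[(n - b + 1L):n] <- 0
  }
  di[!m$valid_mask] <- NaN
  bin_track(di, m$bin_size_bp, "directionality_index")
}

#' Compartment eigenvector track
#'
#' Leading eigenvector of the Pearson correlation matrix of the map's
#' columns, the conventional compartment statistic. Invalid and constant
#' bins are excluded and reinserted as `NaN`; the vector is unit-normalized
#' and its (arbitrary) sign is canonicalized so the largest-magnitude entry
#' is positive. Use [orient_eigenvectors()] to co-orient a pair of tracks
#' before comparison.
#'
#' @param m A `contact_map`.
#' @return A `bin_track` of length `n_bins(m)`.
#' @export
eigenvector_track <- function(m) {
  stopifnot(inherits(m, "contact_map"))
  n <- n_bins(m)
  use <- m$valid_mask
  V <- m$values[use, use, drop = FALSE]
  sds <- apply(V, 2L, function(col) stats::sd(col[is.finite(col)]))
  nonconst <- is.finite(sds) & sds > 0
  if (sum(nonconst) < 2L) {
    cm_stop("correlation matrix undefined: fewer than 2 non-constant bins",
            "undefined_correlation_error")
  }
  V <- V[nonconst, nonconst, drop = FALSE]
  C <- if (anyNA(V)) {
    suppressWarnings(stats::cor(V, use = "pairwise.complete.obs"))
  } else {
    stats::cor(V)   # complete maps take the fast path
  }
  if (any(!is.finite(C))) {
    cm_stop("correlation matrix undefined for some bin pairs",
            "undefined_correlation_error")
  }
  e <- eigen(C, symmetric = TRUE)
  v1 <- e$vectors[, 1L]
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  out <- rep(NaN, n)
  out[which(use)[nonconst]] <- v1
  bin_track(out, m$bin_size_bp, "eigenvector")
}

#' Co-orient two eigenvector tracks
#'
#' The sign of an eigenvector is arbitrary; this flips the second track iff
#' the Pearson correlation between the two (over shared defined bins) is
#' negative, returning a pair with nonnegative correlation. Zero correlation
#' leaves both unchanged.
#'
#' @param e1,e2 `bin_track`s of equal length.
#' @return `list(e1, e2)` with `e2` possibly sign-flipped.
#' @export
orient_eigenvectors <- function(e1, e2) {
  stopifnot(length(e1) == length(e2))
  ok <- is.finite(e1) & is.finite(e2)
  if (sum(ok) >= 2L && stats::sd(e1[ok]) > 0 && stats::sd(e2[ok]) > 0) {
    r <- stats::cor(e1[ok], e2[ok])
    if (is.finite(r) && r < 0) e2 <- bin_track(-unclass(e2),
                                               attr(e2, "bin_size_bp"),
                                               attr(e2, "method"))
  }
  list(e1, e2)
}

#' Contact decay curve P(s)
#'
#' Mean contact as a function of genomic separation: for each diagonal offset
#' `s = 0 .. n-1`, the mean of finite entries at that offset over bins valid
#' at both ends. Offsets with no valid pairs are `NaN`.
#'
#' @param m A `contact_map`.
#' @return A `decay_curve`: list with `values` (length `n`, index `s + 1`),
#'   `counts`, and `bin_size_bp`.
#' @export
contact_decay_curve <- function(m) {
  stopifnot(inherits(m, "contact_map"))
  n <- n_bins(m)
  V <- m$values
  ri <- row(V); ci <- col(V)
  keep <- ri <= ci
  off <- ci[keep] - ri[keep]
  val <- V[keep]
  fin <- is.finite(val)
  sums <- rep(0, n); cnts <- rep(0L, n)
  t1 <- tapply(val[fin], off[fin] + 1L, sum)
  t2 <- tapply(rep(1L, sum(fin)), off[fin] + 1L, sum)
  ix <- as.integer(names(t1))
  sums[ix] <- t1; cnts[ix] <- t2
  structure(list(values = ifelse(cnts > 0, sums / cnts, NaN),
                 counts = cnts, bin_size_bp = m$bin_size_bp),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("decay_curve: %d offsets, %d defined\n",
              length(x$values), sum(is.finite(x$values))))
  invisible(x)
}

#' Triangle summary of all diagonal-anchored submatrices
#'
#' For every diagonal-anchored square submatrix spanning bins `i .. j`
#' (inclusive, side length `j - i + 1 >= min_size`), the mean contact over
#' its upper triangle including the diagonal. Computed with 2D prefix sums in
#' O(n^2) total; invalid entries are excluded through a parallel prefix sum
#' of validity counts.
#'
#' @param m A `contact_map`.
#' @param min_size Smallest submatrix side length in bins.
#' @return A `triangle_summary`: list with `means` (n x n matrix, entry
#'   `[i, j]` the mean for the submatrix spanning bins `i .. j`; `NA` below
#'   `min_size` or under the diagonal), `min_size`, `bin_size_bp`.
#' @export
triangle_summary <- function(m, min_size = 3) {
  stopifnot(inherits(m, "contact_map"))
  min_size <- as.integer(min_size)
  n <- n_bins(m)
  if (n < min_size) cm_stop("map smaller than min_size", "format_error")
  V <- m$values
  fin <- is.finite(V) & row(V) <= col(V)   # upper triangle incl. diagonal
  V0 <- ifelse(fin, V, 0)
  colcum_v <- apply(V0, 2L, cumsum)        # colcum_v[a, j] = sum_{a' <= a} V0[a', j]
  colcum_c <- apply(fin + 0, 2L, cumsum)
  diag_v <- colcum_v[cbind(seq_len(n), seq_len(n))]
  diag_c <- colcum_c[cbind(seq_len(n), seq_len(n))]
  means <- matrix(NA_real_, n, n)
  for (i in seq_len(n - min_size + 1L)) {
    js <- i:n
    seg_v <- diag_v[js] - if (i > 1L) colcum_v[i - 1L, js] else 0
    seg_c <- diag_c[js] - if (i > 1L) colcum_c[i - 1L, js] else 0
    sums <- cumsum(seg_v)
    cnts <- cumsum(seg_c)
    sel <- (i + min_size - 1L):n
    k <- sel - i + 1L
    means[i, sel] <- ifelse(cnts[k] > 0, sums[k] / cnts[k], NaN)
  }
  structure(list(means = means, min_size = min_size,
                 bin_size_bp = m$bin_size_bp),
            class = "triangle_summary")
}

#' @export
print.triangle_summary <- function(x, ...) {
  cat(sprintf("triangle_summary: %d bins, min_size %d, %d submatrices\n",
              nrow(x$means), x$min_size, sum(!is.na(x$means))))
  invisible(x)
}

# Flatten any 1D summary to a plain numeric vector for pairwise comparison.
.summary_values <- function(x) {
  if (inherits(x, "bin_track")) return(as.numeric(x))
  if (inherits(x, "decay_curve")) return(x$values)
  if (inherits(x, "triangle_summary")) return(as.numeric(x$means))
  if (is.numeric(x)) return(as.numeric(x))
  cm_stop("unsupported summary type", "format_error")
}

.summary_type <- function(x) {
  if (inherits(x, "bin_track")) "bin_track"
  else if (inherits(x, "decay_curve")) "decay_curve"
  else if (inherits(x, "triangle_summary")) "triangle_summary"
  else "numeric"
}

#' Compare two 1D map summaries
#'
#' Collapses a pair of tracks, decay curves, or triangle summaries into a
#' single disruption value: `mode = "mse"` gives the mean squared difference,
#' `mode = "spearman"` gives `1 -` rank correlation. Positions undefined
#' (`NaN`/`NA`) in either summary are excluded pairwise; zeros (e.g. the
#' replaced ends of a directionality track) are retained.
#'
#' @param x,y Summaries of the same type and shape.
#' @param mode `"mse"` or `"spearman"`.
#' @return Nonnegative disruption value.
#' @export
compare_tracks <- function(x, y, mode = c("mse", "spearman")) {
  mode <- match.arg(mode)
  if (.summary_type(x) != .summary_type(y)) {
    cm_stop("summaries have different types", "format_error")
  }
  xv <- .summary_values(x); yv <- .summary_values(y)
  if (length(xv) != length(yv)) {
    cm_stop("summaries have different lengths", "alignment_error")
  }
  ok <- is.finite(xv) & is.finite(yv)
  if (!any(ok)) cm_stop("no shared defined positions", "empty_overlap_error")
  xv <- xv[ok]; yv <- yv[ok]
  if (mode == "mse") return(mean((xv - yv)^2))
  if (length(xv) < 3L) cm_stop("fewer than 3 shared positions",
                               "empty_overlap_error")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    cm_stop("spearman comparison undefined: constant summary",
            "undefined_correlation_error")
  }
  rx <- rank(xv); ry <- rank(yv)
  if (identical(rx, ry)) return(0)   # exact rank identity, see .masked_cor
  1 - stats::cor(rx, ry)
}
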