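# Feature-informed methods: call loops (donut filter) and TAD boundaries
# (insulation minima), match features between two maps, and score the ratio
# of changed features.

.feature_set <- function(df, kind, n_bins, bin_size_bp) {
  structure(df, kind = kind, n_bins = n_bins, bin_size_bp = bin_size_bp,
            class = c("feature_set", "data.frame"))
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set (%s): %d features on %d bins\n",
              attr(x, "kind"), nrow(x), attr(x, "n_bins")))
  if (nrow(x)) print.data.frame(utils::head(x, 10L))
  invisible(x)
}

#' Call chromatin loops with a donut filter
#'
#' Local-background loop calling in the HiCCUPS style, parameterized by the
#' printed ratio thresholds rather than Poisson statistics (inputs are
#' smoothed log(observed/expected) maps, not raw counts; values are
#' exponentiated internally so ratios are well defined). Candidates are
#' strict off-diagonal local maxima of the `(2p+1)`-square center-window
#' mean; a candidate is retained iff the center mean exceeds `ther` times the
#' donut and lower-left background means, `ther_H` times the horizontal
#' stripe mean and `ther_V` times the vertical stripe mean. Overlapping
#' candidates within `radius` bins are resolved by keeping the higher center
#' mean (ties: smaller `(i, j)`).
#'
#' The filter geometry follows the HiCCUPS convention with outer half-width
#' `w = p + width`: the donut is the outer square minus the center box and
#' the row/column cross through the peak; the lower-left block spans rows
#' `i+1 .. i+w` by columns `j-w .. j-1` minus the center box; the horizontal
#' and vertical stripes are the center-height (resp. width) bands across the
#' outer square minus the center box. The lower-left filter is what rejects
#' domain-corner artifacts that are not focal enrichments.
#'
#' @param m A `contact_map`.
#' @param p Center-window half-width in bins.
#' @param width Donut annulus width in bins.
#' @param ther Threshold for center/donut and center/lower-left ratios.
#' @param ther_H,ther_V Thresholds for center/horizontal and center/vertical.
#' @param radius Suppression radius: calls closer than this (Euclidean, bins)
#'   are merged keeping the stronger.
#' @return A `feature_set` with columns `i`, `j` (1-based bin pair, `i < j`),
#'   `center_mean`, and the four background ratios.
#' @export
call_loops <- function(m, p = 2, width = 5, ther = 1.1, ther_H = 1.1,
                       ther_V = 1.1, radius = 5) {
  stopifnot(inherits(m, "contact_map"))
  p <- as.integer(p); width <- as.integer(width)
  w <- p + width
  n <- n_bins(m)
  if (n <= 2L * w) cm_stop("map too small for the filter geometry",
                           "format_error")
  V <- exp(m$values)
  fin <- is.finite(V)
  Sv <- sat(ifelse(fin, V, 0))
  Sc <- sat(fin + 0)

  # Center-window mean everywhere it fits, for local-maximum detection.
  C <- matrix(-Inf, n, n)
  ii <- (p + 1L):(n - p)
  gi <- rep(ii, times = length(ii))
  gj <- rep(ii, each = length(ii))
  cs <- rect_sum(Sv, gi - p, gi + p, gj - p, gj + p)
  ck <- rect_sum(Sc, gi - p, gi + p, gj - p, gj + p)
  C[cbind(gi, gj)] <- ifelse(ck > 0, cs / ck, -Inf)

  # Strict 3x3 local maxima among positions with full filter support,
  # restricted to the upper triangle at distance > w from the diagonal.
  pad <- matrix(-Inf, n + 2L, n + 2L)
  pad[2:(n + 1L), 2:(n + 1L)] <- C
  core <- 2:(n + 1L)
  ismax <- is.finite(C)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    ismax <- ismax & (C > pad[core + di, core + dj])
  }
  ri <- row(C); ci <- col(C)
  cand <- which(ismax & ci - ri > w &
                  ri > w & ci > w & ri <= n - w & ci <= n - w)
  if (length(cand) == 0L) {
    return(.feature_set(data.frame(i = integer(), j = integer(),
                                   center_mean = numeric(),
                                   ratio_donut = numeric(),
                                   ratio_ll = numeric(),
                                   ratio_h = numeric(),
                                   ratio_v = numeric()),
                        "loop", n, m$bin_size_bp))
  }
  i <- ri[cand]; j <- ci[cand]
  center_s <- rect_sum(Sv, i - p, i + p, j - p, j + p)
  center_k <- rect_sum(Sc, i - p, i + p, j - p, j + p)
  center <- center_s / center_k

  outer_s <- rect_sum(Sv, i - w, i + w, j - w, j + w)
  outer_k <- rect_sum(Sc, i - w, i + w, j - w, j + w)
  row_s <- rect_sum(Sv, i, i, j - w, j + w)
  row_k <- rect_sum(Sc, i, i, j - w, j + w)
  col_s <- rect_sum(Sv, i - w, i + w, j, j)
  col_k <- rect_sum(Sc, i - w, i + w, j, j)
  rowc_s <- rect_sum(Sv, i, i, j - p, j + p)    # cross within center box
  rowc_k <- rect_sum(Sc, i, i, j - p, j + p)
  colc_s <- rect_sum(Sv, i - p, i + p, j, j)
  colc_k <- rect_sum(Sc, i - p, i + p, j, j)
  donut_s <- outer_s - center_s - (row_s - rowc_s) - (col_s - colc_s)
  donut_k <- outer_k - center_k - (row_k - rowc_k) - (col_k - colc_k)
  donut <- ifelse(donut_k > 0, donut_s / donut_k, NaN)

  ll_s <- rect_sum(Sv, i + 1L, i + w, j - w, j - 1L) -
    rect_sum(Sv, i + 1L, i + p, j - p, j - 1L)
  ll_k <- rect_sum(Sc, i + 1L, i + w, j - w, j - 1L) -
    rect_sum(Sc, i + 1L, i + p, j - p, j - 1L)
  ll <- ifelse(ll_k > 0, ll_s / ll_k, NaN)

  h_s <- rect_sum(Sv, i - p, i + p, j - w, j + w) - center_s
  h_k <- rect_sum(Sc, i - p, i + p, j - w, j + w) - center_k
  hor <- ifelse(h_k > 0, h_s / h_k, NaN)

  v_s <- rect_sum(Sv, i - w, i + w, j - p, j + p) - center_s
  v_k <- rect_sum(Sc, i - w, i + w, j - p, j + p) - center_k
  ver <- ifelse(v_k > 0, v_s / v_k, NaN)

  rd <- center / donut; rl <- center / ll; rh <- center / hor; rv <- center / ver
  pass <- is.finite(rd) & is.finite(rl) & is.finite(rh) & is.finite(rv) &
    rd >= ther & rl >= ther & rh >= ther_H & rv >= ther_V
  df <- data.frame(i = i[pass], j = j[pass], center_mean = center[pass],
                   ratio_donut = rd[pass], ratio_ll = rl[pass],
                   ratio_h = rh[pass], ratio_v = rv[pass])
  # Greedy suppression: strongest center mean first, lexicographic tie-break.
  if (nrow(df) > 1L) {
    ord <- order(-df$center_mean, df$i, df$j)
    df <- df[ord, , drop = FALSE]
    keep <- logical(nrow(df))
    for (k in seq_len(nrow(df))) {
      if (!any(keep)) { keep[k] <- TRUE; next }
      d2 <- (df$i[keep] - df$i[k])^2 + (df$j[keep] - df$j[k])^2
      keep[k] <- all(d2 > radius^2)
    }
    df <- df[keep, , drop = FALSE]
    df <- df[order(df$i, df$j), , drop = FALSE]
  }
  rownames(df) <- NULL
  .feature_set(df, "loop", n, m$bin_size_bp)
}

#' Call TAD boundaries from insulation minima
#'
#' Computes the insulation track with the given diamond window and calls
#' boundaries at local minima whose prominence (the smaller of the drops from
#' the nearest flanking local maxima, or from the track extreme on a side
#' with no interior maximum) exceeds `ther`. Minima closer than `radius`
#' bins are merged keeping the stronger.
#'
#' @param m A `contact_map`.
#' @param window_size Diamond half-width in bins.
#' @param ther Minimum boundary strength (prominence, in track units).
#' @param radius Merge radius in bins.
#' @return A `feature_set` with columns `bin` (1-based) and `strength`.
#' @export
call_boundaries <- function(m, window_size = 5, ther = 0.2, radius = 5) {
  tr <- as.numeric(insulation_track(m, window_size))
  n <- length(tr)
  def <- which(is.finite(tr))
  is_min <- function(k) {
    k > 1L && k < n && is.finite(tr[k - 1L]) && is.finite(tr[k + 1L]) &&
      tr[k] < tr[k - 1L] && tr[k] < tr[k + 1L]
  }
  is_max <- function(k) {
    k > 1L && k < n && is.finite(tr[k - 1L]) && is.finite(tr[k + 1L]) &&
      tr[k] > tr[k - 1L] && tr[k] > tr[k + 1L]
  }
  minima <- def[vapply(def, is_min, logical(1L))]
  maxima <- def[vapply(def, is_max, logical(1L))]
  strength <- vapply(minima, function(k) {
    lm <- maxima[maxima < k]
    rm_ <- maxima[maxima > k]
    left <- if (length(lm)) tr[max(lm)] else max(tr[def[def < k]], tr[k])
    right <- if (length(rm_)) tr[min(rm_)] else max(tr[def[def > k]], tr[k])
    min(left - tr[k], right - tr[k])
  }, numeric(1L))
  keep <- strength > ther
  df <- data.frame(bin = minima[keep], strength = strength[keep])
  if (nrow(df) > 1L) {
    ord <- order(-df$strength, df$bin)
    df <- df[ord, , drop = FALSE]
    take <- logical(nrow(df))
    for (k in seq_len(nrow(df))) {
      if (!any(take)) { take[k] <- TRUE; next }
      take[k] <- all(abs(df$bin[take] - df$bin[k]) > radius)
    }
    df <- df[take, , drop = FALSE]
    df <- df[order(df$bin), , drop = FALSE]
  }
  rownames(df) <- NULL
  .feature_set(df, "boundary", n, m$bin_size_bp)
}

.feature_coords <- function(fs) {
  if (attr(fs, "kind") == "loop") cbind(fs$i, fs$j) else cbind(fs$bin)
}

#' Match features between two maps
#'
#' Greedy one-to-one matching in ascending Euclidean bin distance (1D for
#' boundaries, 2D for loops); candidate pairs farther than `radius` are never
#' matched. Ties are broken by lexicographic feature coordinates for
#' determinism.
#'
#' @param fa,fb `feature_set`s of the same kind from maps of the same shape.
#' @param radius Maximum distance (bins) for two features to count as the
#'   same.
#' @return A `feature_matching`: matched index pairs with distances, and the
#'   unmatched indices on each side.
#' @export
match_features <- function(fa, fb, radius = 5) {
  stopifnot(inherits(fa, "feature_set"), inherits(fb, "feature_set"))
  if (attr(fa, "kind") != attr(fb, "kind")) {
    cm_stop("feature sets have different kinds", "format_error")
  }
  if (attr(fa, "n_bins") != attr(fb, "n_bins")) {
    cm_stop("feature sets come from maps of different shape", "alignment_error")
  }
  ca <- .feature_coords(fa); cb <- .feature_coords(fb)
  na <- nrow(ca); nb <- nrow(cb)
  matched <- data.frame(ia = integer(), ib = integer(), dist = numeric())
  if (na > 0L && nb > 0L) {
    d2 <- outer(seq_len(na), seq_len(nb), function(x, y) {
      rowSums((ca[x, , drop = FALSE] - cb[y, , drop = FALSE])^2)
    })
    cand <- which(d2 <= radius^2, arr.ind = TRUE)
    if (nrow(cand)) {
      key <- do.call(order, c(list(d2[cand]),
                              lapply(seq_len(ncol(ca)), function(k) ca[cand[, 1L], k]),
                              lapply(seq_len(ncol(cb)), function(k) cb[cand[, 2L], k])))
      cand <- cand[key, , drop = FALSE]
      useda <- logical(na); usedb <- logical(nb)
      for (k in seq_len(nrow(cand))) {
        ia <- cand[k, 1L]; ib <- cand[k, 2L]
        if (!useda[ia] && !usedb[ib]) {
          useda[ia] <- TRUE; usedb[ib] <- TRUE
          matched <- rbind(matched,
                           data.frame(ia = ia, ib = ib,
                                      dist = sqrt(d2[ia, ib])))
        }
      }
    }
  }
  structure(list(matched = matched,
                 unmatched_a = setdiff(seq_len(na), matched$ia),
                 unmatched_b = setdiff(seq_len(nb), matched$ib),
                 n_a = na, n_b = nb, radius = radius,
                 kind = attr(fa, "kind")),
            class = "feature_matching")
}

#' @export
print.feature_matching <- function(x, ...) {
  cat(sprintf("feature_matching (%s): %d matched, %d + %d unmatched (radius %g)\n",
              x$kind, nrow(x$matched), length(x$unmatched_a),
              length(x$unmatched_b), x$radius))
  invisible(x)
}

#' Ratio of changed features
#'
#' `(unmatched in A + unmatched in B) / (|A| + |B|)`: the fraction of
#' features added or lost between the two maps. Defined as 0 when both sets
#' are empty ("no change detectable"); note that feature scores can be
#' artificial on maps without strong TADs or loops.
#'
#' @param matching A `feature_matching` from [match_features()].
#' @return Value in `[0, 1]`.
#' @export
changed_ratio <- function(matching) {
  stopifnot(inherits(matching, "feature_matching"))
  tot <- matching$n_a + matching$n_b
  if (tot == 0L) return(0)
  (length(matching$unmatched_a) + length(matching$unmatched_b)) / tot
}
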