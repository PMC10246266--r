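#' Contact map objects
#'
#' A `contact_map` holds a square, symmetric matrix of log(observed/expected)
#' contact frequencies together with its genomic bin size, an optional genomic
#' anchor, and a per-bin validity mask. It is the universal input to every
#' comparison method in the package.
#'
#' Construction enforces the container's invariants: the matrix must be
#' square; symmetry is enforced by averaging the matrix with its transpose
#' (missing-aware, so dialects that store a single triangle are handled);
#' bins whose row is entirely missing are marked invalid and their rows and
#' columns are set to `NaN`, the single missing-value sentinel. Bins are
#' 0-based in genomic coordinate terms; intervals are 0-based half-open.
#'
#' @param values Square numeric matrix of log(observed/expected) values.
#'   Non-finite entries are treated as missing.
#' @param bin_size_bp Positive integer, genomic width of one bin in bp.
#' @param anchor Optional `list(chrom =, start =)` genomic anchor of bin 0
#'   (0-based bp).
#' @param clip_range Optional length-2 numeric `(low, high)`; when set, all
#'   finite values must lie within it (as produced by [clip_values()]).
#' @param symmetrize Average `values` with its transpose (default). Set to
#'   `FALSE` only for inputs already exactly symmetric.
#'
#' @return An object of class `contact_map` with fields `values`,
#'   `bin_size_bp`, `anchor`, `valid_mask`, `clip_range`.
#' @seealso [load_map()], [align_and_mask()], [downsample()], [smooth_map()],
#'   [clip_values()]
#' @examples
#' m <- contact_map(matrix(0, 4, 4), bin_size_bp = 2048)
#' n_bins(m)
#' @export
contact_map <- function(values, bin_size_bp = 2048, anchor = NULL,
                        clip_range = NULL, symmetrize = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) {
    cm_stop(sprintf("contact map values must be square, got %d x %d",
                    nrow(values), ncol(values)), "format_error")
  }
  if (!is.numeric(bin_size_bp) || length(bin_size_bp) != 1L || bin_size_bp <= 0) {
    cm_stop("bin_size_bp must be a single positive number", "format_error")
  }
  values[!is.finite(values)] <- NaN
  if (all(is.nan(values))) {
    cm_stop("contact map has no finite values", "empty_map_error")
  }
  if (symmetrize) {
    tv <- t(values)
    fa <- !is.nan(values)
    fb <- !is.nan(tv)
    num <- ifelse(fa, values, 0) + ifelse(fb, tv, 0)
    den <- fa + fb
    values <- ifelse(den > 0L, num / den, NaN)
  }
  valid <- rowSums(!is.nan(values)) > 0L
  if (!all(valid)) {
    values[!valid, ] <- NaN
    values[, !valid] <- NaN
  }
  if (!is.null(clip_range)) {
    stopifnot(length(clip_range) == 2L, clip_range[1] < clip_range[2])
    fin <- values[is.finite(values)]
    if (length(fin) && (min(fin) < clip_range[1] || max(fin) > clip_range[2])) {
      cm_stop("values fall outside the declared clip_range", "format_error")
    }
  }
  structure(
    list(values = values, bin_size_bp = as.integer(bin_size_bp),
         anchor = anchor, valid_mask = valid, clip_range = clip_range),
    class = "contact_map"
  )
}

#' Number of bins in a contact map
#' @param m A `contact_map`.
#' @return Integer bin count (side length of the matrix).
#' @export
n_bins <- function(m) nrow(m$values)

#' @export
dim.contact_map <- function(x) dim(x$values)

#' @export
print.contact_map <- function(x, ...) {
  fin <- x$values[is.finite(x$values)]
  cat(sprintf("contact_map: %d x %d bins, %d bp/bin\n",
              n_bins(x), n_bins(x), x$bin_size_bp))
  if (!is.null(x$anchor)) {
    cat(sprintf("  anchor: %s:%d\n", x$anchor$chrom, x$anchor$start))
  }
  cat(sprintf("  valid bins: %d/%d\n", sum(x$valid_mask), n_bins(x)))
  if (length(fin)) {
    cat(sprintf("  value range: [%.3f, %.3f]\n", min(fin), max(fin)))
  }
  if (!is.null(x$clip_range)) {
    cat(sprintf("  clip range: (%g, %g)\n", x$clip_range[1], x$clip_range[2]))
  }
  invisible(x)
}

#' @export
plot.contact_map <- function(x, main = NULL, zlim = NULL, ...) {
  v <- x$values
  if (is.null(zlim)) {
    fin <- v[is.finite(v)]
    zlim <- range(fin)
    if (zlim[1] == zlim[2]) zlim <- zlim + c(-0.5, 0.5)
  }
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  n <- n_bins(x)
  graphics::image(seq_len(n), seq_len(n), t(v[n:1, , drop = FALSE]),
                  col = pal, zlim = zlim, xlab = "bin", ylab = "bin",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Read a contact map from a file
#'
#' Supported dense dialects: whitespace/tab TSV of the matrix values
#' (`format = "tsv"`; bin size must be supplied), and RDS serialization of a
#' `contact_map` (`format = "rds"`, a binary container carrying
#' values/bin_size/anchor/mask). The format is inferred from the file
#' extension when not given.
#'
#' @param path File path.
#' @param format `"tsv"`, `"rds"`, or `NULL` to infer from the extension.
#' @param bin_size_bp Bin size in bp (required for TSV input).
#' @param anchor Optional genomic anchor, see [contact_map()].
#' @return A validated `contact_map`.
#' @export
load_map <- function(path, format = NULL, bin_size_bp = NULL, anchor = NULL) {
  if (!file.exists(path)) cm_stop(paste("no such file:", path), "io_error")
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, rds = "rds", tsv = , txt = , mat = "tsv",
                     cm_stop(paste("cannot infer format from extension:", ext),
                             "format_error"))
  }
  format <- match.arg(format, c("tsv", "rds"))
  if (format == "rds") {
    obj <- readRDS(path)
    if (inherits(obj, "contact_map")) {
      return(contact_map(obj$values, obj$bin_size_bp, obj$anchor,
                         obj$clip_range, symmetrize = FALSE))
    }
    if (is.list(obj) && !is.null(obj$values)) {
      return(contact_map(obj$values,
                         bin_size_bp = obj$bin_size %||% obj$bin_size_bp %||%
                           bin_size_bp %||% cm_stop("no bin size in file",
                                                    "format_error"),
                         anchor = obj$anchor))
    }
    if (is.matrix(obj)) {
      if (is.null(bin_size_bp)) cm_stop("bin_size_bp required", "format_error")
      return(contact_map(obj, bin_size_bp, anchor))
    }
    cm_stop("unrecognized RDS payload", "format_error")
  }
  tab <- utils::read.table(path, header = FALSE,
                           colClasses = "numeric",
                           na.strings = c("NA", "NaN", "nan"))
  if (is.null(bin_size_bp)) {
    cm_stop("bin_size_bp must be provided for TSV input", "format_error")
  }
  V <- unname(as.matrix(tab))
  contact_map(V, bin_size_bp, anchor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a contact map to a file
#'
#' TSV output stores values at full double precision (round trips to 1e-9 or
#' better); RDS output is bit-exact.
#'
#' @param m A `contact_map`.
#' @param path Output path.
#' @param format `"tsv"`, `"rds"`, or `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
save_map <- function(m, path, format = NULL) {
  stopifnot(inherits(m, "contact_map"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "rds") "rds" else "tsv"
  }
  format <- match.arg(format, c("tsv", "rds"))
  if (format == "rds") {
    saveRDS(m, path)
  } else {
    txt <- apply(m$values, 1L, function(r) {
      paste(formatC(r, format = "g", digits = 17), collapse = "\t")
    })
    writeLines(txt, path)
  }
  invisible(path)
}

#' Align two contact maps and mask missing positions
#'
#' Flattens the upper triangle (including the diagonal) of both maps in
#' row-major order, keeping only positions where both entries are finite and
#' both bins are valid in both maps. All elementwise comparison methods
#' operate on this view, so symmetric entries are never double-counted and
#' missing bins are never considered.
#'
#' @param a,b `contact_map`s with identical bin count and bin size.
#' @return An object of class `masked_pair`: `x`, `y` (aligned value
#'   sequences), `i`, `j` (1-based bin indices of each retained position),
#'   `n_retained`, `n_bins`.
#' @export
align_and_mask <- function(a, b) {
  stopifnot(inherits(a, "contact_map"), inherits(b, "contact_map"))
  if (n_bins(a) != n_bins(b) || a$bin_size_bp != b$bin_size_bp) {
    cm_stop(sprintf(
      "maps are not alignable: %d bins @ %d bp vs %d bins @ %d bp",
      n_bins(a), a$bin_size_bp, n_bins(b), b$bin_size_bp), "alignment_error")
  }
  n <- n_bins(a)
  valid <- a$valid_mask & b$valid_mask
  ri <- row(a$values); ci <- col(a$values)
  keep <- ri <= ci & is.finite(a$values) & is.finite(b$values) &
    valid[ri] & valid[ci]
  idx <- which(keep)
  if (length(idx) == 0L) {
    cm_stop("no overlapping finite positions", "empty_overlap_error")
  }
  ord <- order(ri[idx], ci[idx])   # row-major within the upper triangle
  idx <- idx[ord]
  structure(list(x = a$values[idx], y = b$values[idx],
                 i = ri[idx], j = ci[idx],
                 n_retained = length(idx), n_bins = n),
            class = "masked_pair")
}

#' @export
print.masked_pair <- function(x, ...) {
  cat(sprintf("masked_pair: %d retained upper-triangle positions (n = %d)\n",
              x$n_retained, x$n_bins))
  invisible(x)
}

#' Downsample a contact map by an integer factor
#'
#' Each output entry is the mean over valid finite entries of the
#' corresponding `factor` x `factor` block; trailing partial bins are
#' dropped and the bin size is multiplied by `factor`. Blocks with no valid
#' entries become `NaN`.
#'
#' @param m A `contact_map`.
#' @param factor Positive integer pooling factor.
#' @return A `contact_map` with `floor(n / factor)` bins.
#' @export
downsample <- function(m, factor) {
  stopifnot(inherits(m, "contact_map"))
  factor <- as.integer(factor)
  if (factor < 1L) cm_stop("factor must be >= 1", "format_error")
  n <- n_bins(m)
  if (factor > n) cm_stop("factor exceeds the number of bins",
                          "degenerate_size_error")
  if (factor == 1L) return(m)
  k <- n %/% factor
  V <- m$values[seq_len(k * factor), seq_len(k * factor), drop = FALSE]
  fin <- is.finite(V)
  V0 <- ifelse(fin, V, 0)
  grp <- rep(seq_len(k), each = factor)
  pool <- function(X) t(rowsum(t(rowsum(X, grp)), grp))
  s <- pool(V0)
  cnt <- pool(fin + 0)
  out <- ifelse(cnt > 0, s / cnt, NaN)
  dimnames(out) <- NULL
  contact_map(out, bin_size_bp = m$bin_size_bp * factor, anchor = m$anchor,
              symmetrize = FALSE)
}

#' Gaussian smoothing of a contact map
#'
#' 2D Gaussian convolution with missing-aware normalization: the kernel
#' weight falling on `NaN` positions (or outside the matrix) is redistributed
#' over the observed positions, so a constant map is left unchanged and total
#' signal is conserved away from missing data. Invalid bins stay `NaN`.
#'
#' @param m A `contact_map`.
#' @param sigma Gaussian standard deviation in bins; `0` returns the map
#'   unchanged.
#' @return A smoothed `contact_map`.
#' @export
smooth_map <- function(m, sigma) {
  stopifnot(inherits(m, "contact_map"), sigma >= 0)
  if (sigma == 0) return(m)
  V <- m$values
  n <- nrow(V)
  K <- band_matrix(n, gaussian_kernel(sigma))
  fin <- is.finite(V)
  num <- K %*% ifelse(fin, V, 0) %*% K
  den <- K %*% (fin + 0) %*% K
  out <- ifelse(den > 0, num / den, NaN)
  out[!m$valid_mask, ] <- NaN
  out[, !m$valid_mask] <- NaN
  out <- (out + t(out)) / 2   # symmetry can drift at the last ulp
  contact_map(out, m$bin_size_bp, m$anchor, symmetrize = FALSE)
}

#' Clip contact map values to a range
#'
#' Finite values outside `[low, high]` are set to the nearest bound and the
#' range is recorded in the map's `clip_range` field.
#'
#' @param m A `contact_map`.
#' @param low,high Clip bounds, `low < high`.
#' @return A clipped `contact_map`.
#' @export
clip_values <- function(m, low, high) {
  stopifnot(inherits(m, "contact_map"))
  if (!(low < high)) cm_stop("low must be < high", "format_error")
  V <- m$values
  fin <- is.finite(V)
  V[fin] <- pmin(pmax(V[fin], low), high)
  out <- contact_map(V, m$bin_size_bp, m$anchor, clip_range = c(low, high),
                     symmetrize = FALSE)
  out
}
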