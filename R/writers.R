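# Plain-text genomic writers for tracks and feature sets. Intervals are
# 0-based half-open, matching the bedGraph/BED conventions.

.anchor_or_default <- function(obj_anchor, chrom, start) {
  if (!is.null(obj_anchor)) list(chrom = obj_anchor$chrom,
                                 start = obj_anchor$start)
  else list(chrom = chrom, start = start)
}

#' Write a per-bin track as bedGraph
#'
#' Four columns (chrom, start, end, value), 0-based half-open; bins with
#' undefined values are skipped.
#'
#' @param track A `bin_track` (or plain numeric vector).
#' @param path Output path.
#' @param bin_size_bp Bin size (taken from the track when available).
#' @param chrom,start Genomic anchor of bin 0.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, bin_size_bp = NULL, chrom = "chr0",
                           start = 0) {
  v <- as.numeric(track)
  bs <- bin_size_bp %||% attr(track, "bin_size_bp") %||%
    cm_stop("bin_size_bp required", "format_error")
  keep <- which(is.finite(v))
  s <- start + (keep - 1L) * bs
  lines <- sprintf("%s\t%d\t%d\t%s", chrom, s, s + bs,
                   sprintf("%.10g", v[keep]))
  writeLines(lines, path)
  invisible(path)
}

#' Write boundary calls as BED
#'
#' Columns: chrom, start, end, score (boundary strength).
#'
#' @param boundaries A boundary `feature_set` from [call_boundaries()].
#' @param path Output path.
#' @param chrom,start Genomic anchor of bin 0.
#' @return `path`, invisibly.
#' @export
write_bed <- function(boundaries, path, chrom = "chr0", start = 0) {
  stopifnot(inherits(boundaries, "feature_set"),
            attr(boundaries, "kind") == "boundary")
  bs <- attr(boundaries, "bin_size_bp")
  s <- start + (boundaries$bin - 1L) * bs
  lines <- sprintf("%s\t%d\t%d\t%s", chrom, s, s + bs,
                   sprintf("%.6g", boundaries$strength))
  writeLines(lines, path)
  invisible(path)
}

#' Write loop calls as BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, score (center-window
#' mean on the observed/expected scale).
#'
#' @param loops A loop `feature_set` from [call_loops()].
#' @param path Output path.
#' @param chrom,start Genomic anchor of bin 0.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path, chrom = "chr0", start = 0) {
  stopifnot(inherits(loops, "feature_set"), attr(loops, "kind") == "loop")
  bs <- attr(loops, "bin_size_bp")
  s1 <- start + (loops$i - 1L) * bs
  s2 <- start + (loops$j - 1L) * bs
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s", chrom, s1, s1 + bs,
                   chrom, s2, s2 + bs,
                   sprintf("%.6g", loops$center_mean))
  writeLines(lines, path)
  invisible(path)
}

#' Write a triangle summary as TSV
#'
#' Long format: start_bin, end_bin (1-based inclusive), mean.
#'
#' @param ts A `triangle_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triangle_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "triangle_summary"))
  idx <- which(!is.na(ts$means), arr.ind = TRUE)
  df <- data.frame(start_bin = idx[, 1L], end_bin = idx[, 2L],
                   mean = ts$means[idx])
  df <- df[order(df$start_bin, df$end_bin), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
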