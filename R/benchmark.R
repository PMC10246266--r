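# Benchmarking layer: method concordance (correlation matrix, PCA,
# top-percentile overlap) across a scored pair collection, and sensitivity
# curves along graded perturbation ladders.

#' Score matrix container
#'
#' Pairs-by-methods matrix of normalized disruption scores with optional
#' per-pair annotations (perturbation kind, degree) and per-method
#' annotations (family). `NA` entries flag per-pair method failures; each
#' analysis excludes incomplete pairs listwise and reports how many it
#' dropped.
#'
#' @param scores Numeric matrix, rows = pairs (rownames = pair ids),
#'   columns = methods.
#' @param pair_info Optional data frame of per-pair annotations.
#' @param method_info Optional data frame of per-method annotations.
#' @return A `score_matrix`.
#' @export
score_matrix <- function(scores, pair_info = NULL, method_info = NULL) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) rownames(scores) <- seq_len(nrow(scores))
  structure(list(scores = scores, pair_info = pair_info,
                 method_info = method_info),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d pairs x %d methods (%d NA entries)\n",
              nrow(x$scores), ncol(x$scores), sum(is.na(x$scores))))
  invisible(x)
}

#' Build a score matrix from a long score table
#'
#' @param df Output of [score_batch()] or row-bound [score_pair()] calls.
#' @param value Which score column to spread (default `"normalized"`).
#' @return A `score_matrix`.
#' @export
scores_to_matrix <- function(df, value = "normalized") {
  pairs <- unique(df$pair_id)
  methods <- unique(df$method)
  M <- matrix(NA_real_, length(pairs), length(methods),
              dimnames = list(pairs, methods))
  M[cbind(match(df$pair_id, pairs), match(df$method, methods))] <- df[[value]]
  fam <- df$family[match(methods, df$method)]
  score_matrix(M, method_info = data.frame(method = methods, family = fam))
}

.complete_rows <- function(sm, context) {
  S <- sm$scores
  ok <- stats::complete.cases(S)
  if (!all(ok)) {
    message(sprintf("%s: excluding %d/%d pairs with failed scores listwise",
                    context, sum(!ok), nrow(S)))
  }
  S[ok, , drop = FALSE]
}

#' Inter-method score correlation matrix
#'
#' Spearman correlation between every pair of method score vectors across
#' the scored pairs. Methods with constant scores yield `NA` rows/columns
#' with a warning (their rank correlation is undefined). A hierarchical
#' ordering (average linkage on `1 - correlation`) is attached for heatmap
#' display.
#'
#' @param sm A `score_matrix` with at least 3 pairs.
#' @return Symmetric method-by-method correlation matrix with attribute
#'   `"order"`.
#' @export
method_correlation <- function(sm) {
  S <- .complete_rows(sm, "method_correlation")
  if (nrow(S) < 3L) cm_stop("need at least 3 scored pairs", "format_error")
  sds <- apply(S, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("constant score vector(s): ",
            paste(colnames(S)[sds == 0], collapse = ", "),
            "; correlation undefined (NA)")
  }
  C <- suppressWarnings(stats::cor(S, method = "spearman"))
  usable <- sds > 0
  ord <- seq_len(ncol(S))
  if (sum(usable) >= 2L) {
    D <- stats::as.dist(1 - C[usable, usable, drop = FALSE])
    hc <- stats::hclust(D, method = "average")
    ord <- c(which(usable)[hc$order], which(!usable))
  }
  attr(C, "order") <- colnames(S)[ord]
  C
}

#' PCA of method score profiles
#'
#' Projects each method (observation = its standardized score profile across
#' pairs) onto the leading principal components; methods that score pairs
#' alike land close together. Score vectors are z-scored per method first
#' because methods live on different native scales. Component signs are
#' fixed by the largest-loading-positive convention for determinism.
#'
#' @param sm A `score_matrix` with at least 3 methods and 3 pairs.
#' @param n_components Components to report (capped at the available rank).
#' @return List with `coords` (methods x components), `explained`
#'   (variance fractions, all components), `dropped` (constant methods,
#'   excluded with a warning), and the full `prcomp` fit.
#' @export
method_pca <- function(sm, n_components = 2) {
  S <- .complete_rows(sm, "method_pca")
  if (nrow(S) < 3L || ncol(S) < 3L) {
    cm_stop("need at least 3 pairs and 3 methods", "format_error")
  }
  sds <- apply(S, 2L, stats::sd)
  dropped <- colnames(S)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant method(s) before standardization: ",
            paste(dropped, collapse = ", "))
    S <- S[, sds > 0, drop = FALSE]
  }
  Z <- scale(S)                    # standardize per method
  X <- t(Z)                        # methods as observations
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(fit$rotation))) {
    lead <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[lead, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  ev <- fit$sdev^2
  nz <- sum(ev > max(ev) * 1e-12)
  if (nz < n_components) {
    warning(sprintf("rank-deficient input: only %d informative component(s)",
                    nz))
  }
  keep <- seq_len(min(n_components, ncol(fit$x)))
  list(coords = fit$x[, keep, drop = FALSE],
       explained = ev / sum(ev), dropped = dropped, fit = fit)
}

#' Top-percentile ranking overlap between methods
#'
#' For each ordered method pair (X, Y): the fraction of X's top-`q`% most
#' disrupted pairs that are also in Y's top-`q`%. Both top sets have size
#' `ceiling(q * n_pairs / 100)`, so the denominator is the set size and the
#' matrix is symmetric up to ties; ties in scores are broken by pair
#' identifier for determinism.
#'
#' @param sm A `score_matrix`.
#' @param q Percentile (percent of pairs in each top set).
#' @return Method-by-method matrix of overlap fractions in `[0, 1]`.
#' @export
top_percentile_overlap <- function(sm, q = 5) {
  S <- .complete_rows(sm, "top_percentile_overlap")
  k <- ceiling(q * nrow(S) / 100)
  if (k < 1L) cm_stop("top percentile is empty at this q / pair count",
                      "format_error")
  ids <- rownames(S)
  tops <- lapply(seq_len(ncol(S)), function(m) {
    ids[order(-S[, m], ids)][seq_len(k)]
  })
  nm <- colnames(S)
  out <- matrix(0, ncol(S), ncol(S), dimnames = list(nm, nm))
  for (x in seq_len(ncol(S))) for (y in seq_len(ncol(S))) {
    out[x, y] <- length(intersect(tops[[x]], tops[[y]])) / k
  }
  out
}

#' Sensitivity curves along perturbation ladders
#'
#' Scores `(template, ladder map)` at every degree of every ladder and
#' summarizes each method's response with a monotonicity statistic: the
#' Spearman rank correlation between score and degree (`NA` when the score
#' is constant along the ladder, i.e. the method is blind to that axis).
#' Per-point method failures are recorded and the curve continues.
#'
#' @param ladders List of `perturbation_ladder`s (see [make_ladder()]).
#' @param methods Registry ids.
#' @param config Parameter table.
#' @param baseline Optional `baseline_set` for normalized scores.
#' @return A `sensitivity_curves` object: `curves` (long data frame with
#'   kind, degree, method, family, flipped, normalized, status) and
#'   `monotonicity` (kind x method data frame of rank correlations).
#' @export
sensitivity_curves <- function(ladders, methods = default_methods(),
                               config = default_config(), baseline = NULL) {
  if (inherits(ladders, "perturbation_ladder")) ladders <- list(ladders)
  curves <- do.call(rbind, lapply(ladders, function(lad) {
    kind <- lad$spec$kind
    do.call(rbind, lapply(seq_along(lad$degrees), function(d) {
      df <- score_pair(lad$template, lad$maps[[d]], methods, config,
                       baseline,
                       pair_id = sprintf("%s_%03d", kind, d))
      df$kind <- kind
      df$degree <- lad$degrees[d]
      df
    }))
  }))
  mono <- do.call(rbind, lapply(split(curves, curves[c("kind", "method")]),
                                function(g) {
    ok <- g$status == "ok" & is.finite(g$normalized)
    # a curve flat to within floating-point dust carries no ordering signal
    spread <- if (any(ok)) diff(range(g$normalized[ok])) else 0
    rho <- if (sum(ok) >= 3L && spread > 1e-12) {
      stats::cor(g$normalized[ok], g$degree[ok], method = "spearman")
    } else NA_real_
    data.frame(kind = g$kind[1L], method = g$method[1L],
               family = g$family[1L], monotonicity = rho,
               n_ok = sum(ok), stringsAsFactors = FALSE)
  }))
  rownames(mono) <- NULL
  structure(list(curves = curves, monotonicity = mono),
            class = "sensitivity_curves")
}

#' @export
print.sensitivity_curves <- function(x, ...) {
  cat(sprintf("sensitivity_curves: %d kinds x %d methods\n",
              length(unique(x$curves$kind)),
              length(unique(x$curves$method))))
  print(x$monotonicity)
  invisible(x)
}

#' @export
plot.sensitivity_curves <- function(x, value = "normalized", ...) {
  kinds <- unique(x$curves$kind)
  methods <- unique(x$curves$method)
  cols <- grDevices::hcl.colors(length(methods), "Dark 3")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(kinds)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (k in kinds) {
    g <- x$curves[x$curves$kind == k, ]
    ylim <- range(g[[value]][is.finite(g[[value]])], 0)
    graphics::plot(NA, xlim = range(g$degree), ylim = ylim,
                   xlab = paste(k, "degree"), ylab = value, main = k)
    for (mi in seq_along(methods)) {
      gm <- g[g$method == methods[mi], ]
      graphics::lines(gm$degree, gm[[value]], col = cols[mi])
    }
  }
  invisible(x)
}

#' Invariance classes of the registered methods
#'
#' Classifies each method variant by its exact algebraic behavior under
#' global contrast (multiplying all log-contact values by a scalar) and
#' intensity (adding a scalar) changes:
#' * `rank_invariant` — score is exactly 0 under both: rank or affine
#'   invariant statistics (Spearman, Pearson, SCC) and map-informed
#'   Spearman-mode comparisons whose tracks transform linearly
#'   (insulation, decay, triangle) or are scale-free (eigenvector);
#' * `quadratic_mse` — score grows strictly and quadratically under both:
#'   MSE and the map-informed MSE-mode comparisons with linearly
#'   transforming tracks;
#' * `other` — methods whose response is neither (SSIM's luminance and
#'   contrast terms react to both changes under a fixed dynamic range;
#'   the directionality index exponentiates, so log-space contrast deforms
#'   its track nonlinearly; the eigenvector MSE score is identically 0 on
#'   both axes; feature ratios are discrete).
#'
#' @return Data frame with columns `method` and `invariance_class`.
#' @export
method_invariance_classes <- function() {
  data.frame(
    method = c("mse", "spearman", "pearson", "ssim", "scc",
               "eigenvector_mse", "eigenvector_spearman",
               "di_mse", "di_spearman",
               "insulation_mse", "insulation_spearman",
               "decay_mse", "decay_spearman",
               "triangle_mse", "triangle_spearman",
               "loops", "tads"),
    invariance_class = c("quadratic_mse", "rank_invariant", "rank_invariant",
                         "other", "rank_invariant",
                         "other", "rank_invariant",
                         "other", "other",
                         "quadratic_mse", "rank_invariant",
                         "quadratic_mse", "rank_invariant",
                         "quadratic_mse", "rank_invariant",
                         "other", "other"),
    stringsAsFactors = FALSE
  )
}
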