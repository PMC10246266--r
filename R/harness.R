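# Uniform method harness: registry of the 11 comparison methods (plus the
# optional Pearson variant), score flipping ("higher = more disrupted"),
# baseline normalization, single-pair and batch scoring, and configuration.

#' Default method parameters
#'
#' Flat parameter table grouped by method, with the conventional defaults:
#' insulation `window_size = 10`; directionality index
#' `window_resolution = 10000`, `replace_ends = TRUE`, `buffer = 50`; loop
#' caller `p = 2`, `width = 5`, `ther = ther_H = ther_V = 1.1`,
#' `radius = 5`; TAD caller `window_size = 5`, `ther = 0.2`, `radius = 5`;
#' SSIM window 7 / sigma 1.5 / K1 0.01 / K2 0.03 / dynamic range 4; SCC full
#' map; triangle `min_size = 3` on maps pooled to ~10 kb bins (computationally
#' intensive methods are evaluated at reduced resolution).
#'
#' @return A nested named list of parameters.
#' @export
default_config <- function() {
  list(
    insulation = list(window_size = 10, scale = "log"),
    di = list(window_resolution = 10000, replace_ends = TRUE, buffer = 50),
    loops = list(p = 2, width = 5, ther = 1.1, ther_H = 1.1, ther_V = 1.1,
                 radius = 5),
    tads = list(window_size = 5, ther = 0.2, radius = 5),
    ssim = list(window = 7, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                dynamic_range = 4),
    scc = list(max_offset = NULL),
    triangle = list(min_size = 3, target_bin_bp = 10240)
  )
}

#' Read a method configuration file
#'
#' YAML document with the same nesting and parameter names as
#' [default_config()]; values present in the file override the defaults,
#' everything else keeps its default.
#'
#' @param path YAML file path.
#' @return A full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (grp in names(user)) {
    if (!grp %in% names(cfg)) cfg[[grp]] <- list()
    for (key in names(user[[grp]])) cfg[[grp]][[key]] <- user[[grp]][[key]]
  }
  cfg
}

# Pool a map to approximately the configured working resolution before the
# computationally heavy triangle summary.
.triangle_input <- function(m, config) {
  f <- max(1L, as.integer(round(config$triangle$target_bin_bp / m$bin_size_bp)))
  if (f > 1L && n_bins(m) %/% f >= config$triangle$min_size) downsample(m, f)
  else m
}

#' The method registry
#'
#' One entry per registered comparison method variant. Each entry carries
#' the method family used for score flipping (`correlation`: flipped score
#' is `1 - raw`; `mse` and `feature_ratio`: flipped equals raw) and a
#' function computing the raw score from two maps and a configuration.
#' Map-informed methods appear as `<name>_mse` / `<name>_spearman` variant
#' pairs; [default_methods()] selects the canonical 11.
#'
#' @return Named list of registry entries.
#' @export
method_registry <- function() {
  track_pair <- function(track_fun) {
    list(
      mse = function(a, b, config) {
        compare_tracks(track_fun(a, config), track_fun(b, config), "mse")
      },
      cor = function(a, b, config) {
        # raw = rank correlation, so the correlation-family flip applies
        1 - compare_tracks(track_fun(a, config), track_fun(b, config),
                           "spearman")
      }
    )
  }
  ins <- track_pair(function(m, cfg) {
    insulation_track(m, cfg$insulation$window_size, cfg$insulation$scale)
  })
  di <- track_pair(function(m, cfg) {
    di_track(m, cfg$di$window_resolution, cfg$di$replace_ends, cfg$di$buffer)
  })
  dec <- track_pair(function(m, cfg) contact_decay_curve(m))
  tri <- track_pair(function(m, cfg) {
    triangle_summary(.triangle_input(m, cfg), cfg$triangle$min_size)
  })
  eig_tracks <- function(a, b) {
    e <- orient_eigenvectors(eigenvector_track(a), eigenvector_track(b))
    e
  }
  list(
    mse = list(family = "mse",
               fun = function(a, b, config) mse(a, b)),
    spearman = list(family = "correlation",
                    fun = function(a, b, config) .masked_cor(a, b, "spearman")),
    pearson = list(family = "correlation",
                   fun = function(a, b, config) .masked_cor(a, b, "pearson")),
    ssim = list(family = "correlation",
                fun = function(a, b, config) {
                  s <- config$ssim
                  .ssim_mean(a, b, s$window, s$sigma, s$K1, s$K2,
                             s$dynamic_range)
                }),
    scc = list(family = "correlation",
               fun = function(a, b, config) {
                 1 - scc_disruption(a, b, config$scc$max_offset)
               }),
    eigenvector_mse = list(family = "mse",
                           fun = function(a, b, config) {
                             e <- eig_tracks(a, b)
                             compare_tracks(e[[1]], e[[2]], "mse")
                           }),
    eigenvector_spearman = list(family = "correlation",
                                fun = function(a, b, config) {
                                  e <- eig_tracks(a, b)
                                  1 - compare_tracks(e[[1]], e[[2]], "spearman")
                                }),
    di_mse = list(family = "mse", fun = di$mse),
    di_spearman = list(family = "correlation", fun = di$cor),
    insulation_mse = list(family = "mse", fun = ins$mse),
    insulation_spearman = list(family = "correlation", fun = ins$cor),
    decay_mse = list(family = "mse", fun = dec$mse),
    decay_spearman = list(family = "correlation", fun = dec$cor),
    triangle_mse = list(family = "mse", fun = tri$mse),
    triangle_spearman = list(family = "correlation", fun = tri$cor),
    loops = list(family = "feature_ratio",
                 fun = function(a, b, config) {
                   l <- config$loops
                   fa <- call_loops(a, l$p, l$width, l$ther, l$ther_H,
                                    l$ther_V, l$radius)
                   fb <- call_loops(b, l$p, l$width, l$ther, l$ther_H,
                                    l$ther_V, l$radius)
                   changed_ratio(match_features(fa, fb, l$radius))
                 }),
    tads = list(family = "feature_ratio",
                fun = function(a, b, config) {
                  t <- config$tads
                  fa <- call_boundaries(a, t$window_size, t$ther, t$radius)
                  fb <- call_boundaries(b, t$window_size, t$ther, t$radius)
                  changed_ratio(match_features(fa, fb, t$radius))
                })
  )
}

#' The canonical 11-method suite
#'
#' The default method list: MSE, Spearman, SSIM, SCC, eigenvector,
#' directionality index, insulation, contact decay, triangle (map-informed
#' methods in their MSE mode; `_spearman` variants are registered
#' separately), loop difference, and TAD difference. Pearson is registered
#' but excluded from the default suite because it behaves almost identically
#' to Spearman on these maps.
#'
#' @return Character vector of 11 registry ids.
#' @export
default_methods <- function() {
  c("mse", "spearman", "ssim", "scc", "eigenvector_mse", "di_mse",
    "insulation_mse", "decay_mse", "triangle_mse", "loops", "tads")
}

#' All registered method variants
#' @return Character vector of registry ids (both modes of every
#'   map-informed method, plus Pearson).
#' @export
all_methods <- function() names(method_registry())

#' Flip a raw score to disruption orientation
#'
#' Correlation-family scores (raw in `[-1, 1]`, 1 = identical) become
#' `1 - raw`, so a perfect correlation maps to 0 disruption; MSE-family and
#' feature-ratio scores are already oriented and pass through unchanged.
#'
#' @param raw Raw method score.
#' @param method_family `"correlation"`, `"mse"`, or `"feature_ratio"`.
#' @return Flipped score (larger = more disrupted).
#' @export
flip_score <- function(raw, method_family = c("correlation", "mse",
                                              "feature_ratio")) {
  method_family <- match.arg(method_family)
  if (method_family == "correlation") {
    if (!is.finite(raw) || raw < -1 - 1e-12 || raw > 1 + 1e-12) {
      cm_stop("correlation-family raw score outside [-1, 1]", "format_error")
    }
    return(1 - raw)
  }
  raw
}

#' Normalize a flipped score by a baseline mean
#'
#' Divides a flipped disruption score by the mean flipped score of a
#' reference perturbation collection, so a normalized score of 2 reads as
#' "twice the average disruption of the reference perturbation" regardless
#' of the method's native scale.
#'
#' @param flipped Flipped disruption score.
#' @param baseline_mean Positive per-method baseline mean.
#' @return Normalized score.
#' @export
normalize_score <- function(flipped, baseline_mean) {
  if (!is.finite(baseline_mean) || baseline_mean <= 0) {
    cm_stop("baseline mean must be positive", "degenerate_baseline_error")
  }
  flipped / baseline_mean
}

#' Compute a baseline set from reference map pairs
#'
#' Per-method arithmetic mean of flipped scores over a declared reference
#' collection of map pairs. A zero mean is rejected (it would make
#' normalization degenerate), naming the offending method.
#'
#' @param pairs List of `list(a =, b =)` map pairs.
#' @param methods Registry ids to include.
#' @param config Parameter table, see [default_config()].
#' @param provenance Label describing the reference collection.
#' @return A `baseline_set`: `means` (named numeric), `provenance`,
#'   `n_pairs`.
#' @export
compute_baseline <- function(pairs, methods = default_methods(),
                             config = default_config(),
                             provenance = "user-supplied reference pairs") {
  stopifnot(length(pairs) >= 1L)
  reg <- method_registry()
  unknown <- setdiff(methods, names(reg))
  if (length(unknown)) {
    cm_stop(paste("unknown methods:", paste(unknown, collapse = ", ")),
            "format_error")
  }
  acc <- matrix(NA_real_, length(pairs), length(methods),
                dimnames = list(NULL, methods))
  for (k in seq_along(pairs)) {
    for (meth in methods) {
      raw <- reg[[meth]]$fun(pairs[[k]]$a, pairs[[k]]$b, config)
      acc[k, meth] <- flip_score(raw, reg[[meth]]$family)
    }
  }
  means <- colMeans(acc)
  zero <- names(means)[means == 0]
  if (length(zero)) {
    cm_stop(paste("degenerate baseline (mean flipped score is 0) for:",
                  paste(zero, collapse = ", ")), "degenerate_baseline_error")
  }
  structure(list(means = means, provenance = provenance,
                 n_pairs = length(pairs)),
            class = "baseline_set")
}

#' @export
print.baseline_set <- function(x, ...) {
  cat(sprintf("baseline_set: %d methods over %d pairs\n  provenance: %s\n",
              length(x$means), x$n_pairs, x$provenance))
  print(signif(x$means, 4))
  invisible(x)
}

#' Default simulator-derived baseline
#'
#' The reference collection emulates random 100 bp deletions directly in map
#' space: each pair is the TAD template versus the template with a sub-bin
#' coordinate shift (`del_bp / bin_size_bp` bins, ~0.05 bins) applied
#' downstream of a seeded random position — a small structural perturbation
#' with minimal impact, like the sequence deletions it stands in for.
#' Feature-ratio methods are excluded by default: a sub-bin shift never
#' changes a feature call, so their baseline mean would be the (rejected)
#' degenerate 0; their scores are interpretable unnormalized on `[0, 1]`.
#'
#' @param template Template map; built with `seed` when absent.
#' @param methods Registry ids to include.
#' @param config Parameter table.
#' @param n_pairs Number of reference pairs.
#' @param seed RNG seed (template texture and deletion positions).
#' @param del_bp Emulated deletion size in bp.
#' @return A `baseline_set`.
#' @export
default_baseline <- function(template = NULL,
                             methods = setdiff(default_methods(),
                                               c("loops", "tads")),
                             config = default_config(), n_pairs = 100,
                             seed = 1, del_bp = 100) {
  if (is.null(template)) template <- make_template(seed = seed)
  n <- n_bins(template)
  pos <- with_seed(seed + 7L,
                   sample.int(n - 2L, n_pairs, replace = TRUE) + 1L)
  pairs <- lapply(seq_len(n_pairs), function(k) {
    list(a = template, b = simulate_small_deletion(template, del_bp, pos[k]))
  })
  compute_baseline(pairs, methods, config,
                   provenance = sprintf(
                     "simulated %d bp deletions (sub-bin shift), %d seeded pairs, seed %d",
                     del_bp, n_pairs, seed))
}

#' Save / load a baseline set as JSON
#' @param baseline A `baseline_set`.
#' @param path JSON file path.
#' @return `path` (save) or a `baseline_set` (load).
#' @export
save_baseline <- function(baseline, path) {
  jsonlite::write_json(list(means = as.list(baseline$means),
                            provenance = baseline$provenance,
                            n_pairs = baseline$n_pairs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_baseline
#' @export
load_baseline <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(means = unlist(obj$means), provenance = obj$provenance,
                 n_pairs = obj$n_pairs),
            class = "baseline_set")
}

#' Score one pair of maps with multiple methods
#'
#' Applies each requested method and returns one disruption-score record per
#' method: the raw score, the flipped score (larger = more disrupted), and
#' the normalized score (flipped divided by the method's baseline mean when
#' a baseline is supplied and covers the method; otherwise the flipped score
#' is carried through). A method's failure (e.g. undefined correlation on
#' constant input) is recorded as a per-method status without aborting the
#' remaining methods. Output is deterministic given inputs and
#' configuration.
#'
#' @param a,b Alignable `contact_map`s.
#' @param methods Registry ids, see [all_methods()].
#' @param config Parameter table, see [default_config()].
#' @param baseline Optional `baseline_set`.
#' @param pair_id Identifier copied into the output rows.
#' @return A data frame with columns `pair_id`, `method`, `family`, `raw`,
#'   `flipped`, `normalized`, `status`, `message`.
#' @export
score_pair <- function(a, b, methods = default_methods(),
                       config = default_config(), baseline = NULL,
                       pair_id = "pair") {
  reg <- method_registry()
  unknown <- setdiff(methods, names(reg))
  if (length(unknown)) {
    cm_stop(paste("unknown methods:", paste(unknown, collapse = ", ")),
            "format_error")
  }
  rows <- lapply(methods, function(meth) {
    fam <- reg[[meth]]$family
    res <- tryCatch({
      raw <- reg[[meth]]$fun(a, b, config)
      flipped <- flip_score(raw, fam)
      normalized <- if (!is.null(baseline) && meth %in% names(baseline$means))
        normalize_score(flipped, baseline$means[[meth]]) else flipped
      list(raw = raw, flipped = flipped, normalized = normalized,
           status = "ok", message = "")
    }, contactdiff_error = function(e) {
      list(raw = NA_real_, flipped = NA_real_, normalized = NA_real_,
           status = "failed", message = conditionMessage(e))
    })
    data.frame(pair_id = pair_id, method = meth, family = fam,
               raw = res$raw, flipped = res$flipped,
               normalized = res$normalized, status = res$status,
               message = res$message, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score a manifest of map pairs
#'
#' Long-format batch scoring: one row per pair and method. Pairs that fail
#' to load or score are isolated as failure rows; the run continues.
#'
#' @param manifest Data frame with columns `pair_id`, `path_a`, `path_b`
#'   (and optionally `bin_size_bp` for TSV inputs).
#' @param methods,config,baseline As in [score_pair()].
#' @param bin_size_bp Fallback bin size for TSV inputs without a manifest
#'   column.
#' @param progress Log per-pair progress via `message()`.
#' @return A data frame in the [score_pair()] layout.
#' @export
score_batch <- function(manifest, methods = default_methods(),
                        config = default_config(), baseline = NULL,
                        bin_size_bp = NULL, progress = FALSE) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1L,
            all(c("pair_id", "path_a", "path_b") %in% names(manifest)))
  out <- lapply(seq_len(nrow(manifest)), function(k) {
    pid <- manifest$pair_id[k]
    if (progress) message(sprintf("[%d/%d] %s", k, nrow(manifest), pid))
    bs <- if ("bin_size_bp" %in% names(manifest)) manifest$bin_size_bp[k]
    else bin_size_bp
    tryCatch({
      a <- load_map(manifest$path_a[k], bin_size_bp = bs)
      b <- load_map(manifest$path_b[k], bin_size_bp = bs)
      score_pair(a, b, methods, config, baseline, pair_id = pid)
    }, error = function(e) {
      reg <- method_registry()
      data.frame(pair_id = pid, method = methods,
                 family = vapply(methods, function(m) reg[[m]]$family, ""),
                 raw = NA_real_, flipped = NA_real_, normalized = NA_real_,
                 status = "failed", message = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
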