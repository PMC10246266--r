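# Synthetic contact-map simulator: a TAD-template canvas, a substructure
# variant, six graded perturbation ladders, and matched structural-variant
# pairs. All outputs are deterministic under a fixed seed.

# Symmetric Gaussian noise field: the upper triangle (including the diagonal)
# is drawn and mirrored, so every retained position of the masked pair view
# has variance sd^2 and the expected MSE against the unperturbed map is
# exactly sd^2.
.sym_noise <- function(n, sd, seed) {
  with_seed(seed, {
    up <- which(upper.tri(matrix(0, n, n), diag = TRUE))
    M <- matrix(0, n, n)
    M[up] <- stats::rnorm(length(up), 0, sd)
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  })
}

#' Simulated TAD template map
#'
#' Builds the simulation canvas directly in log(observed/expected) map space:
#' a zero background with seeded low-amplitude texture, a square block of
#' elevated contact spanning bins `[n/4, 3n/4)` (the TAD formed by a
#' convergent boundary pair), depleted contact between the TAD and its
#' flanks (so insulation dips at the boundaries, as cross-boundary contact
#' does in real maps), Gaussian smoothing, symmetrization, and a (-2, 2)
#' clip.
#'
#' @param n_bins Map side length in bins.
#' @param bin_size_bp Bin size in bp.
#' @param tad_strength Log-contact elevation inside the TAD block.
#' @param boundary_depletion Log-contact depletion of cross-boundary pairs.
#' @param texture_sd Standard deviation of the pre-smoothing background
#'   texture.
#' @param smooth_sigma Gaussian smoothing sigma in bins.
#' @param seed RNG seed; the same seed reproduces the map bit-exactly.
#' @return A `contact_map` with simulation parameters stored in
#'   `$sim_params`.
#' @export
make_template <- function(n_bins = 448, bin_size_bp = 2048,
                          tad_strength = 0.6, boundary_depletion = 0.4,
                          texture_sd = 0.05, smooth_sigma = 1, seed = 1) {
  n <- as.integer(n_bins)
  if (n < 16L) cm_stop("n_bins must be at least 16", "format_error")
  q1 <- n %/% 4L + 1L          # first bin of the TAD (0-based n/4)
  q3 <- (3L * n) %/% 4L        # last bin of the TAD (0-based 3n/4 exclusive)
  inb <- seq_len(n) >= q1 & seq_len(n) <= q3
  V <- with_seed(seed, matrix(stats::rnorm(n * n, 0, texture_sd), n, n))
  V <- (V + t(V)) / 2
  block <- outer(inb, inb, "&")
  V[block] <- V[block] + tad_strength
  cross <- outer(inb, !inb, "&") | outer(!inb, inb, "&")
  V[cross] <- V[cross] - boundary_depletion
  m <- contact_map(V, bin_size_bp, symmetrize = FALSE)
  m <- smooth_map(m, smooth_sigma)
  m <- clip_values(m, -2, 2)
  m$sim_params <- list(n_bins = n, tad_strength = tad_strength,
                       boundary_depletion = boundary_depletion,
                       texture_sd = texture_sd, smooth_sigma = smooth_sigma,
                       seed = seed, q1 = q1, q3 = q3)
  m
}

#' Substructure variant of a template
#'
#' Adds one extra boundary at `n/2`, splitting the TAD block into two
#' sub-blocks: within-TAD pairs that straddle the midpoint are depleted by
#' the template's boundary depletion (smoothed with the template's sigma).
#' Texture is matched exactly — the variant equals the template everywhere
#' outside the affected block region.
#'
#' @param template A map from [make_template()].
#' @param seed Unused (the variant shares the template's texture); kept for
#'   interface symmetry with the other generators.
#' @return A `contact_map` with an additional insulating boundary at `n/2`.
#' @export
make_substructure_template <- function(template, seed = NULL) {
  stopifnot(inherits(template, "contact_map"), !is.null(template$sim_params))
  p <- template$sim_params
  n <- n_bins(template)
  n2 <- n %/% 2L
  inb <- seq_len(n) >= p$q1 & seq_len(n) <= p$q3
  left <- inb & seq_len(n) <= n2
  right <- inb & seq_len(n) > n2
  D <- matrix(0, n, n)
  crossmid <- outer(left, right, "&") | outer(right, left, "&")
  D[crossmid] <- -p$boundary_depletion
  Dm <- contact_map(D, template$bin_size_bp, symmetrize = FALSE)
  Dm <- smooth_map(Dm, p$smooth_sigma)
  V <- template$values + Dm$values
  m <- contact_map(pmin(pmax(V, -2), 2), template$bin_size_bp,
                   clip_range = c(-2, 2), symmetrize = FALSE)
  m$sim_params <- c(p, list(substructure = TRUE, n2 = n2))
  m
}

#' Perturbation specification
#'
#' Declares one graded perturbation axis with its degree range. Printed
#' default ranges: noise sd 0 to 0.2; resolution 2,048 to 50,972 bp;
#' contrast scalar 1 to 2; intensity additive 0 to 0.2; size factor 1 to
#' 1.1; substructure blend 0 to 1. The degree grid is linear with
#' `n_degrees` points including both endpoints.
#'
#' @param kind One of `"noise"`, `"resolution"`, `"contrast"`,
#'   `"intensity"`, `"size"`, `"substructure"`.
#' @param min,max Degree range; defaults are the printed ranges per kind.
#' @param n_degrees Number of grid points.
#' @param seed Base RNG seed for the ladder.
#' @return A `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("noise", "resolution", "contrast",
                                       "intensity", "size", "substructure"),
                              min = NULL, max = NULL, n_degrees = 100,
                              seed = 1) {
  kind <- match.arg(kind)
  defaults <- list(noise = c(0, 0.2), resolution = c(2048, 50972),
                   contrast = c(1, 2), intensity = c(0, 0.2),
                   size = c(1, 1.1), substructure = c(0, 1))
  rng <- defaults[[kind]]
  if (is.null(min)) min <- rng[1]
  if (is.null(max)) max <- rng[2]
  stopifnot(min <= max, n_degrees >= 1)
  structure(list(kind = kind, min = min, max = max,
                 n_degrees = as.integer(n_degrees), seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat(sprintf("perturbation_spec: %s, degrees [%g, %g] x %d, seed %d\n",
              x$kind, x$min, x$max, x$n_degrees, x$seed))
  invisible(x)
}

#' Apply one perturbation at a given degree
#'
#' The six axes and their degree semantics:
#' * `noise` — add a seeded symmetric Gaussian field with sd = degree;
#' * `resolution` — mean-pool by `round(degree / bin_size_bp)` and render
#'   the block means back on the original grid (block-constant map), so the
#'   degraded map stays alignable with the original;
#' * `contrast` — multiply all values by the degree;
#' * `intensity` — add the degree to all values;
#' * `size` — rescale the matrix about its origin by the degree with
#'   bilinear interpolation and trim bottom/right back to the original
#'   dimensions (the domain grows);
#' * `substructure` — blend `(1 - degree) * map + degree *` the substructure
#'   variant.
#'
#' Every axis is the identity at its no-op degree (sd 0, 2,048 bp, scalar 1,
#' additive 0, factor 1, blend 0). The output is re-symmetrized but not
#' re-clipped, so the algebraic relations between the original and perturbed
#' map (e.g. MSE under contrast or intensity) hold exactly.
#'
#' @param m The map to perturb (the template, for `substructure`).
#' @param spec A [perturbation_spec()].
#' @param degree_value Degree within the spec's range.
#' @param seed RNG seed for stochastic axes; defaults to the spec's seed.
#' @param substructure_template Optional precomputed substructure variant;
#'   computed from `m` when absent.
#' @return A perturbed `contact_map`.
#' @export
perturb <- function(m, spec, degree_value, seed = spec$seed,
                    substructure_template = NULL) {
  stopifnot(inherits(m, "contact_map"), inherits(spec, "perturbation_spec"))
  eps <- 1e-9
  if (degree_value < spec$min - eps || degree_value > spec$max + eps) {
    cm_stop(sprintf("degree %g outside spec range [%g, %g]",
                    degree_value, spec$min, spec$max), "format_error")
  }
  n <- n_bins(m)
  out_values <- switch(
    spec$kind,
    noise = {
      if (degree_value == 0) return(m)
      m$values + .sym_noise(n, degree_value, seed)
    },
    resolution = {
      f <- max(1L, as.integer(round(degree_value / m$bin_size_bp)))
      if (f == 1L) return(m)
      grp <- rep(seq_len(ceiling(n / f)), each = f)[seq_len(n)]
      fin <- is.finite(m$values)
      V0 <- ifelse(fin, m$values, 0)
      s <- t(rowsum(t(rowsum(V0, grp)), grp))
      k <- t(rowsum(t(rowsum(fin + 0, grp)), grp))
      blk <- ifelse(k > 0, s / k, NaN)
      blk[grp, grp]
    },
    contrast = {
      if (degree_value == 1) return(m)
      m$values * degree_value
    },
    intensity = {
      if (degree_value == 0) return(m)
      m$values + degree_value
    },
    size = {
      if (degree_value == 1) return(m)
      g <- (seq_len(n) - 1) / degree_value + 1
      A <- interp_matrix(n, g)
      A %*% m$values %*% t(A)
    },
    substructure = {
      if (degree_value == 0) return(m)
      if (is.null(substructure_template)) {
        substructure_template <- make_substructure_template(m)
      }
      (1 - degree_value) * m$values + degree_value * substructure_template$values
    }
  )
  out_values <- (out_values + t(out_values)) / 2
  out <- contact_map(out_values, m$bin_size_bp, m$anchor, symmetrize = FALSE)
  out
}

#' Build a graded perturbation ladder
#'
#' Generates one perturbed map per degree on the linear grid of the spec
#' (default 100 degrees including both endpoints). The first map is
#' identical to the template for axes whose minimum is the identity.
#' Regeneration with the same spec is bit-identical: the map at degree index
#' `d` uses seed `spec$seed + d`.
#'
#' @param template The template `contact_map`.
#' @param spec A [perturbation_spec()].
#' @return A `perturbation_ladder`: list with `template`, `degrees`, `maps`,
#'   `spec`.
#' @export
make_ladder <- function(template, spec) {
  degrees <- if (spec$n_degrees == 1L) spec$min else
    seq(spec$min, spec$max, length.out = spec$n_degrees)
  sub <- if (spec$kind == "substructure") {
    make_substructure_template(template)
  }
  maps <- lapply(seq_along(degrees), function(d) {
    perturb(template, spec, degrees[d], seed = spec$seed + d,
            substructure_template = sub)
  })
  structure(list(template = template, degrees = degrees, maps = maps,
                 spec = spec),
            class = "perturbation_ladder")
}

#' @export
print.perturbation_ladder <- function(x, ...) {
  cat(sprintf("perturbation_ladder: %s, %d degrees in [%g, %g]\n",
              x$spec$kind, length(x$degrees), min(x$degrees), max(x$degrees)))
  invisible(x)
}

#' Matched structural-variant map pair
#'
#' Produces a pair of maps differing only by one named structural edit, for
#' probing which comparison methods see which kind of change:
#' * `boundary_change` — substructure blend at `magnitude` (clamped to 1);
#' * `loop_change` — a focal Gaussian peak of log-amplitude `magnitude`
#'   planted at the TAD corner;
#' * `stripe_change` — a band of elevated contact emanating from the first
#'   boundary along the TAD (log-amplitude `magnitude`);
#' * `contrast_only` — scalar multiplication by `1 + magnitude` (structure
#'   identical, dynamic range changed).
#'
#' @param kind Edit type.
#' @param magnitude Positive edit size (log-contact units, or scalar excess
#'   for `contrast_only`).
#' @param seed Seed for the underlying template.
#' @param n_bins,bin_size_bp Template dimensions.
#' @return `list(a =, b =)` of `contact_map`s.
#' @export
make_variant_pair <- function(kind = c("boundary_change", "loop_change",
                                       "stripe_change", "contrast_only"),
                              magnitude = 1, seed = 1, n_bins = 448,
                              bin_size_bp = 2048) {
  kind <- match.arg(kind)
  stopifnot(magnitude > 0)
  a <- make_template(n_bins = n_bins, bin_size_bp = bin_size_bp, seed = seed)
  p <- a$sim_params
  n <- n_bins(a)
  b <- switch(
    kind,
    boundary_change = {
      spec <- perturbation_spec("substructure", seed = seed)
      perturb(a, spec, min(magnitude, 1), seed = seed + 1L)
    },
    loop_change = {
      ci <- p$q1; cj <- p$q3   # TAD corner
      # symmetric Gaussian dot at (ci, cj) and its mirror (cj, ci)
      g1 <- exp(-0.5 * ((seq_len(n) - ci) / 1.5)^2)
      g2 <- exp(-0.5 * ((seq_len(n) - cj) / 1.5)^2)
      dot <- magnitude * (outer(g1, g2) + outer(g2, g1))
      vb <- a$values + dot
      out <- contact_map(vb, bin_size_bp, symmetrize = FALSE)
      out$sim_params <- p
      out
    },
    stripe_change = {
      anchor <- p$q1
      band <- seq_len(n) %in% anchor:(anchor + 1L)
      along <- seq_len(n) >= p$q1 & seq_len(n) <= p$q3
      S <- matrix(0, n, n)
      S[band, along] <- magnitude
      S <- (S + t(S)) / 2 * 2   # symmetric band, full magnitude both arms
      S[S > magnitude] <- magnitude
      vb <- a$values + S
      out <- contact_map(vb, bin_size_bp, symmetrize = FALSE)
      out$sim_params <- p
      out
    },
    contrast_only = {
      spec <- perturbation_spec("contrast", max = 1 + magnitude, seed = seed)
      perturb(a, spec, 1 + magnitude, seed = seed)
    }
  )
  list(a = a, b = b)
}

#' Sub-bin deletion analog
#'
#' Emulates the map-space effect of deleting `del_bp` of sequence at a given
#' position: coordinates downstream of the position shift toward the
#' diagonal by `del_bp / bin_size_bp` bins (a fraction of a bin for a 100 bp
#' deletion at 2 kb resolution), implemented by bilinear resampling; the
#' final fraction of a bin is filled by edge clamping. Used to build the
#' default normalization baseline.
#'
#' @param m A `contact_map`.
#' @param del_bp Deleted length in bp.
#' @param at_bin 1-based bin from which the shift applies.
#' @return A `contact_map` of the same shape.
#' @export
simulate_small_deletion <- function(m, del_bp = 100, at_bin) {
  stopifnot(inherits(m, "contact_map"))
  n <- n_bins(m)
  at_bin <- as.integer(at_bin)
  stopifnot(at_bin >= 1L, at_bin <= n)
  shift <- del_bp / m$bin_size_bp
  g <- seq_len(n) + ifelse(seq_len(n) >= at_bin, shift, 0)
  g <- pmin(g, n)
  A <- interp_matrix(n, g)
  V <- A %*% m$values %*% t(A)
  V <- (V + t(V)) / 2
  contact_map(V, m$bin_size_bp, m$anchor, symmetrize = FALSE)
}
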