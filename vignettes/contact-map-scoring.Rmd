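---
title: "Scoring differences between chromatin contact maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring differences between chromatin contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 5)
library(contactdiff)
```

## The problem

Chromosome-conformation assays (Hi-C, Micro-C) and sequence-based predictors
summarize the 3D folding of a genomic region as a square *contact map*: bin
`(i, j)` holds the interaction frequency between two genomic intervals,
conventionally normalized to log(observed/expected), so that 0 means
background-level contact at that genomic separation. Comparing two maps of
the same region — across cell types, genotypes, species, or a predicted
wild-type/mutant pair — is the basic operation behind most downstream
biology, yet there is no single agreed-upon difference score. Simple global
statistics (mean squared error, rank correlation) are cheap but conflate
dynamic-range artifacts with structural change; feature callers (TAD
boundaries, loops) are interpretable but discrete and parameter-hungry.

`contactdiff` implements eleven comparison methods spanning three
strategies, a uniform *disruption score* harness that makes their outputs
comparable, a synthetic-map simulator that perturbs one property of a map
at a time, and a benchmarking layer that quantifies when methods agree and
what each one can and cannot see.

## The methods and their assumptions

All methods consume a pair of `contact_map` objects with the same bin count
and bin size. Elementwise comparisons use the upper triangle including the
diagonal (symmetric entries are never double-counted) and exclude any
position that is missing or belongs to an invalid bin in either map.

**Basic methods** compare the matrices directly:

* `mse` — mean squared difference. Sensitive to everything, including pure
  intensity or contrast changes.
* `spearman_disruption`, `pearson_disruption` — `1 - correlation`, so 0
  means identical ordering. Rank/affine invariant; Pearson behaves nearly
  identically to Spearman on smoothed log-ratio maps and is excluded from
  the default suite.
* `ssim_disruption` — `1 -` mean local structural similarity with a
  width-7 Gaussian window (sigma 1.5, K1 = 0.01, K2 = 0.03). The dynamic
  range is fixed at 4 (the span of the conventional (-2, 2) log clip)
  rather than estimated per pair, so scores are comparable across pairs;
  the price is that SSIM reacts to global intensity and contrast changes,
  which a data-driven range would partly absorb. Missing values are filled
  with 0 (the observed/expected-neutral value) for the windowed pass only,
  and border pixels whose window leaves the matrix are cropped from the
  mean.
* `scc_disruption` — `1 -` stratum-adjusted correlation: a per-diagonal
  Pearson correlation combined with weights `N_k sd_k(a) sd_k(b)`. Strata
  with fewer than 3 pairs or zero variance are skipped; no extra 2D
  smoothing is applied because inputs are assumed already smoothed. The
  maximum genomic distance is exposed as `max_offset` (default: full map).

**Map-informed methods** reduce each map to a 1D summary, then compare the
pair of summaries with MSE or `1 -` Spearman (`compare_tracks`):

* `insulation_track` — mean contact in a diamond window (half-width 10
  bins) straddling each bin; local minima mark insulating boundaries.
  Because inputs are already observed/expected-normalized, the raw diamond
  mean is used without the log2-to-genome-mean normalization applied to
  raw counts (that would double-normalize).
* `di_track` — the directionality index, a signed chi-square-style
  contrast between a bin's upstream and downstream contact sums over a
  10 kb window. The statistic requires nonnegative sums, so it is computed
  on `exp(values)` (observed/expected ratios); a consequence worth knowing
  is that a *multiplicative* change in log space becomes a *power*
  transform of the ratios, so the DI track is not invariant under contrast
  scaling. Track ends (50 bins by default) are replaced with zeros.
* `eigenvector_track` — the leading eigenvector of the map's column
  correlation matrix, the conventional compartment statistic, computed
  here on the full window even though true compartments are larger.
  Eigenvector signs are arbitrary; pairs are co-oriented with
  `orient_eigenvectors` before comparison.
* `contact_decay_curve` — mean contact per diagonal offset, P(s).
* `triangle_summary` — the mean contact of *every* diagonal-anchored
  square submatrix at least 3 bins wide, computed with 2D prefix sums in
  O(n^2). This is the richest summary and the slowest method, so the
  harness pools maps to ~10 kb bins (`target_bin_bp = 10240`) before
  summarizing, mirroring the usual practice of degrading resolution for
  expensive statistics.

**Feature-informed methods** call discrete structures and score the ratio
of changed features, `(|unmatched A| + |unmatched B|) / (|A| + |B|)`
(0 when both sets are empty — "no change detectable" — a convention that
avoids NaN in score tables but means featureless map pairs always look
identical to these methods):

* `call_loops` — a donut-filter caller: candidates are strict local maxima
  of the 5x5 center-window mean, kept when the center exceeds 1.1x the
  donut, lower-left, horizontal, and vertical background means. The
  lower-left filter is what rejects domain corners that are bright only
  because two domain edges meet there. Thresholding uses the printed
  ratios rather than Poisson statistics because inputs are smoothed
  log-ratios, not raw counts.
* `call_boundaries` — local minima of a half-width-5 insulation track
  whose prominence (drop to the nearest flanking maxima, min of the two
  sides) exceeds 0.2. Prominence was chosen as the "boundary strength"
  definition; a caller using a different strength statistic would rank
  weak boundaries differently.
* `match_features` — greedy one-to-one matching in ascending Euclidean bin
  distance with radius 5, ties broken lexicographically for determinism.

## The disruption-score harness

Raw method outputs live on incompatible scales and orientations.
`score_pair` applies each requested method and records three values per
method: the raw score; the *flipped* score (correlation-family scores
become `1 - r` so larger always means more disrupted; MSE-family and
feature-ratio scores pass through); and the *normalized* score, the
flipped score divided by the method's mean flipped score over a reference
collection of minimally perturbed pairs. A normalized score of 2 therefore
reads as "twice the average disruption of the reference perturbation"
regardless of the method.

The shipped reference collection (`default_baseline`) emulates random
100 bp deletions directly in map space: each pair is the template versus
the template with a sub-bin coordinate shift (100 bp / 2048 bp per bin ≈
0.049 bins) applied downstream of a seeded random position. A deletion
moves all downstream sequence toward the breakpoint, which is exactly a
small structural edit, not white noise; this distinction matters because a
noise-only baseline would scale every quadratically-responding method by
the same factor and erase the contrast between basic and track-summarizing
methods that normalization is meant to reveal. Feature-ratio methods are
excluded from the default baseline (a sub-bin shift never changes a
feature call, so their reference mean is zero, which normalization
rejects); their scores are carried through unnormalized on their natural
[0, 1] scale, and the baseline's provenance string records the
substitution.

```{r harness-example}
template <- make_template(n_bins = 128, seed = 1)
noisy <- perturb(template, perturbation_spec("noise", seed = 2), 0.1,
                 seed = 3)
score_pair(template, noisy, c("mse", "spearman", "insulation_mse"))[
  , c("method", "raw", "flipped", "status")]
```

## What the simulator emulates

`make_template` synthesizes the test canvas directly in map space: a
448-bin (2,048 bp/bin, ~1 Mb) log(observed/expected) map with a TAD — a
square of elevated contact (+0.6) between boundaries at 1/4 and 3/4 of the
window — depleted cross-boundary contact (-0.4, which is what makes
insulation dip *at* the boundaries, as it does in real maps), low-amplitude
seeded texture (sd 0.05), Gaussian smoothing (sigma 1), and a (-2, 2)
clip. `make_substructure_template` adds one more boundary at the midpoint,
splitting the TAD. The template deliberately contains no corner dot, so
the loop caller finds nothing on it and planted-loop experiments
(`make_variant_pair("loop_change", ...)`) have an unambiguous negative
control.

Six graded perturbation axes (`perturbation_spec`, `make_ladder`) each
span 100 linearly spaced degrees from an identity endpoint: Gaussian noise
(sd 0 to 0.2, drawn on the upper triangle and mirrored so every entry has
the nominal variance and the expected MSE against the original is exactly
sd^2); resolution (2,048 to 50,972 bp — for ladders the pooled block means
are rendered back on the original grid so that every rung stays alignable
with the template, while `downsample()` proper shrinks the matrix);
contrast (scalar 1 to 2); intensity (additive 0 to 0.2); domain size
(origin-anchored bilinear rescale by 1 to 1.1, trimmed back to the
original dimensions — the anchor is a convention; trimming from the
bottom/right keeps bin 0 fixed); and substructure (linear blend 0 to 1
with the extra-boundary variant). Perturbed maps are re-symmetrized but
*not* re-clipped: leaving the clip off preserves the exact algebraic
relations (contrast MSE `= (c-1)^2 mean(A^2)`, intensity MSE `= delta^2`)
that the test suite verifies, and template values sit far enough inside
(-2, 2) that clipping would almost never engage anyway.

What the simulator does **not** emulate: read-depth-dependent sparsity,
distance-decay miscalibration, translocations, compartment-scale
(multi-Mb) structure, and the rich heterogeneity of real loci. Tests that
pass on these canvases demonstrate that each method responds to the axis
it is supposed to respond to under controlled conditions — not that its
scores are well calibrated on any particular experimental dataset.

## Benchmarking and what each method can see

`sensitivity_curves` scores (template, rung) pairs along each ladder and
summarizes each method with a monotonicity statistic: the Spearman
correlation between score and degree. Curves that are flat to within
1e-12 are reported as `NA` ("blind to this axis") rather than letting
floating-point dust masquerade as signal.

The exact invariances partition the registry into classes
(`method_invariance_classes`), derived from the algebra rather than from
the flip families:

* *rank/affine-invariant*: Spearman, Pearson, SCC, and the
  Spearman-mode track comparisons whose summaries transform linearly
  under contrast and shift (insulation, decay, triangle) or are
  scale-free (eigenvector). These score exactly 0 along the contrast and
  intensity ladders.
* *strictly quadratic MSE*: MSE and the MSE-mode comparisons with
  linearly transforming summaries. Their contrast/intensity curves are
  exact quadratics, hence monotonicity 1.0.
* *other*: SSIM (the fixed dynamic range makes its luminance and contrast
  terms react to both axes); DI in either mode (the exponentiation makes
  its track nonlinear under log-space contrast); eigenvector (MSE mode
  is identically zero on both axes — invariant, not monotone); and the
  feature ratios (discrete).

Two structural limits of the feature-informed scores are worth stating
plainly, because they show up in any ladder analysis. First, a
changed-feature ratio is a step function of the perturbation degree: with
a couple of features per map, the score jumps from 0 to 0.5 to 1 at the
degrees where a feature's displacement crosses the matching radius, and a
step function's rank correlation with the degree is bounded well below 1
(a single step at position k of a 100-degree grid gives
`sqrt(3k(100-k)/9999) <= 0.87`). Second, on a canvas with no loops the
loop score is constant zero along every axis. Neither is a bug; both are
the discrete nature of the scores, and both are reasons the field treats
feature-informed scores as hypothesis generators rather than ranking
statistics.

The directionality index deserves one more caveat: it is excellent at
flagging a *new* boundary (a localized sign flip appears where the track
was flat) but its chi-square-style spikes simply translate when an
existing boundary *moves*. Once the displacement exceeds the DI window
the track comparison saturates, and for large displacements — the size
ladder moves the far boundary by up to 34 bins — the whole-track
stretching dominates, so DI's response to a large size change can exceed
its response to a new mid-TAD boundary. Interpreting a high DI score
therefore requires looking at the track, which is exactly what the 1D
intermediate representation is for.

```{r sensitivity, eval = FALSE}
template <- make_template(seed = 1)
ladders <- lapply(c("noise", "contrast", "size", "substructure"),
                  function(k) make_ladder(template,
                                          perturbation_spec(k, seed = 2)))
sc <- sensitivity_curves(ladders, methods = default_methods())
plot(sc)
sc$monotonicity
```

For scored collections, `method_correlation` (Spearman between method
score vectors, with average-linkage ordering attached for heatmaps),
`method_pca` (methods projected onto the leading components of their
z-scored profiles; z-scoring per method because methods live on different
scales, with component signs fixed largest-loading-positive), and
`top_percentile_overlap` (the fraction of one method's top-q% most
disrupted pairs shared with another's; both sets have size
`ceiling(q n / 100)`, so the denominator is the set size rather than a
Jaccard union, matching the symmetric reading of "ranked in the top
percentile for both") reproduce the standard concordance analyses.

## Numerical choices

* `NaN` is the single missing-value sentinel; symmetrization at load time
  is missing-aware, so single-triangle files are recovered rather than
  destroyed.
* Correlations of *identical* sequences (and identical rank vectors) are
  returned as exactly 1 without summation: floating-point `cor` can land
  one ulp short of 1, and an identity comparison must score exactly 0.
* Undefined statistics (constant input under a correlation, no usable
  stratum) raise classed errors rather than returning 0 — silent zeros
  corrupt rankings at scale. The harness converts per-method errors into
  `status = "failed"` rows without aborting the remaining methods.
* Greedy procedures (feature matching, loop suppression) order ties
  lexicographically so outputs are bit-reproducible.
* Smoothing uses zero-padded separable Gaussian convolution with
  missing-aware renormalization: constants are preserved exactly and mass
  is conserved up to edge effects.
* All simulator randomness flows through explicit seeds, with the
  caller's RNG state saved and restored.

## Problem sizes in the test suite

The automated suite exercises the full 448-bin study conditions where the
claims depend on them (identity of all methods, the 100-degree ladder
analyses, feature recall at the printed parameters, the 200-seed
Monte-Carlo noise check) and smaller canvases (64–160 bins) plus
8–30-bin random instances for the brute-force oracle comparisons, where
exhaustive enumeration is the point and the size is irrelevant to the
property.

## Known limitations

* No cooler/HDF5 reader: dense TSV and RDS dialects only. Balancing,
  expected-model fitting, and interpolation of missing bins are upstream
  concerns and out of scope.
* No significance thresholds: every score is a ranking statistic, and
  turning a score into a "significant difference" call is deliberately
  left to the caller.
* One TAD caller and one loop caller, with the printed default
  parameters; alternative callers would produce different feature ratios.
* The simulator's canvas is a single-TAD idealization; conclusions about
  method sensitivity transfer to real data only to the extent that the
  perturbation axes capture the variation present there.
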