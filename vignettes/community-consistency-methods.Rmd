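---
title: "Methods: community-structure consistency and distance regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community-structure consistency and distance regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the modeling choices behind `sinet`: what each stage
assumes, which knobs matter, what the synthetic generator does and does not
emulate, and where the design was genuinely open.

## The question the pipeline answers

Given one node × time functional series per subject per condition, the
pipeline asks whether subjects who differ more on a continuous phenotype
(binocular log contrast sensitivity, CS) also differ more in the spatial
layout of their network communities. The unit of inference is the subject
*pair*: community structure lives in a label space with no natural
alignment across subjects, so instead of comparing raw maps we compare
pairwise distances between per-subject scaled-inclusivity (SI) maps, and
regress those on pairwise covariate distances.

## Signal cleaning

Framewise displacement uses Power's formulation — the sum of absolute
frame-to-frame translations plus rotations converted to arc length. The
head radius is not dictated by the method's description, so the
conventional 50 mm is the default. DVARS is the RMS frame-to-frame change
over nodes in percent of the global mean signal; the percent scale is why
`dvars()` refuses series without a positive mean. Scrubbing drops the
union of FD and DV exceedances.

The band-pass (0.009–0.08 Hz) is realized in the Fourier domain: bins
outside the band are zeroed and the series inverted back. This is
zero-phase by construction, has exactly unit passband gain and removes the
DC component; the testable contract (passband gain within 10%, one-octave
stopband attenuation over 90%, zero mean) is the stated surface, not a
filter family. Spectral leakage of non-bin-aligned components is the known
trade-off; for passband tones more than a few bins from the edges the
retained amplitude error is well under the 10% contract.

Stage order is scrub → filter → regress. Filtering the concatenated kept
frames treats them as contiguous, which distorts frequencies near gaps;
the alternative (filter full series, then drop flagged frames) is
available via `clean_series(scrub_first = FALSE)`. Confound regressors
are passed through the identical scrub and filter before regression so
the regression cannot reintroduce removed frequencies; the intercept is
appended after filtering.

## Network construction

The density rule `S = log N / log K` is inverted to `K = N^(1/S)` and the
top `floor(N·K/2)` off-diagonal correlations become edges, so every
subject has an identical edge count — equalizing density rather than the
correlation threshold value. `S` defaults to 2.5 (the source analysis
determined its value empirically without publishing it; 2.5 gives
K ≈ 12.9 at N = 600 and K ≈ 53 at N = 20,000, a typical sparse-connectome
regime) and is configurable everywhere. Ranking is on signed r — the
binarization keeps "values above the threshold", i.e. the positive tail —
and ties break lexicographically by node pair, making the operation a
pure function of the correlation ranking (hence invariant to monotone
transforms). Graph connectivity is deliberately not enforced; downstream
code tolerates disconnected graphs and isolated nodes.

## Community detection

The quantity optimized is Newman modularity Q. The "stability" framing of
the source method is reconciled by the identity that the discrete-time
Markov stability of a partition at time 1 equals Q; `markov_stability()`
implements the random-walk autocovariance form and the suite checks the
identity numerically, so maximizing Q *is* maximizing one-step stability.
The optimizer is a Louvain-type greedy run with an explicitly permuted
node order per restart (100 restarts by default), keeping the best
recomputed Q. Restarts share one seeded RNG stream, so the best Q is
non-decreasing in the restart count and results are exactly reproducible
from `(network, n_runs, seed)`. Singleton communities are permitted.

## Scaled inclusivity

For template `T` and the subject community `C` containing template node
`n`, `SI(n) = |C∩T|²/(|C|·|T|)`. The quadratic-overlap form is the
standard scaled-inclusivity definition (the method's sources cite it
without printing it); a double-loop reference implementation is the test
oracle. Each node is scored against the single community containing it —
no best-match search — because node-wise maps are the required output.
SI is relabel-invariant, equals 1 only under perfect alignment, and for
fixed overlap strictly decreases as `C` grows (dilution). Group maps are
node-wise means; tertile maps (upper vs lower covariate tertile, extras
assigned to lower tertiles first, ties resolved by stable order) are a
visualization aid only and feed no statistics.

## Distance regression and inference

Brain distances are `1 − Σmin/Σmax` (Ružička complement) between SI
maps; numeric covariates use absolute differences, sex uses mismatch
coding, and head motion enters as the absolute difference in
volumes-removed counts. The model regresses the unrolled upper-triangle
pair distances on the covariate distances plus subject fixed effects
(indicator columns for both members of each pair, one dropped;
covariate estimates are invariant to which, and the suite checks this).

Parametric p-values use the standard-normal reference on T = estimate/SE.
This matches the published convention: across all 16 printed (T, p) pairs
of the bundled reference table the two-sided normal p agrees with the
printed raw p to within 1e-4, which is printed precision (the printed
T-scores are themselves rounded to 4 decimals, so exact 4-decimal
round-matching is not attainable for every row — e.g. T = 0.0688 gives
0.94513, printing as 0.9451 vs the published 0.9452). Because the
M(M−1)/2 pairs sharing a subject are dependent, the normal reference is
anticonservative in principle; the package therefore also provides a
subject-relabeling permutation test for the focal term. Permuting subject
labels of the covariate and rebuilding its distance matrix are the same
operation (a joint row/column permutation), which preserves the
dependence structure of the distances. Only the focal covariate is
permuted (Draper–Stoneman); under the generator's null the focal
covariate is independent of everything, making the test exact, and the
calibration block confirms a rejection rate near the nominal 5%. The
permuted refits use the Frisch–Waugh–Lovell identity — outcome and focal
column residualized once against all other columns — which reproduces the
full-refit T exactly (asserted via `t_perm_obs`) at a fraction of the
cost; B = 10,000 is a sensible default for real analyses, B = 1,000 is
used in the automated calibration for runtime.

"Adapted FDR" is Benjamini–Hochberg step-up over the family of CS terms
only (8 networks × 2 conditions = 16 models), which reproduces the
published adjusted column: exactly for the 0.5224 and 0.9805 entries, and
to ≤ 1.3e-4 for entries limited by the 4-decimal rounding of the raw-p
inputs. Motion and sex p-values are not adjusted, mirroring the published
table. A two-stage adaptive variant is behind `method = "two-stage"`.

## The synthetic cohort: what it emulates

The generator plants `k` disjoint communities over `N` nodes, draws per
subject CS ~ N(1.71, 0.14²) — the published cohort's distribution —
truncated to [0, 2.4] (the physical range of a 48-letter Pelli-Robson
chart at 0.05 log units per letter, which is also the scoring rule
`pelli_robson_to_logcs()` adopts; the source describes conversion to log
CS without printing the rule, and letter-by-letter 0.05 scoring is the
chart's published convention). Each subject's target community is
degraded by reassigning its nodes elsewhere with probability
`g(cs) = clamp(0.35 − slope·(cs − 1.71), 0, 1)`: the link is linear with
clamping because the source implies only a direction (lower CS ↔ more
degraded structure), not a functional form. Signals follow a
one-factor-per-community Gaussian model (`√ρ·latent + √(1−ρ)·noise`),
giving exact expected within/cross correlations of ρ and 0; series are
scaled to 0.25% fluctuations on a baseline of 100 so DVARS has a
realistic percent scale. Motion traces are Gaussian jitter with 1 mm
Bernoulli spikes whose FD exceedances define the volumes-removed
covariate.

Deliberately not emulated: spatial smoothness, hemodynamic spectra,
anatomical geometry, voxel grids, global signal structure, or
condition-specific task activation (conditions differ only via jitter
parameters, matching an analysis that fits conditions separately). A
green calibration therefore establishes that the statistics behave as
designed under the stated generative model — not that the model captures
every property of real BOLD data.

Default scale choices made once: N = 600 nodes (desk-scale; all formulas
are size-agnostic), 4 communities of 150, T = 120–200 frames, TR = 2 s.
The effect size `jitter_slope = 1.2, jitter_intercept = 0.35` spans
jitter rates ≈ 0–0.7 across ±2 SD of CS — strong but not degenerate,
sized (as the design requires) so the upper/lower tertile maps visibly
separate.

## Numerical choices and degenerate inputs

* Thresholding uses a partial-sort cutoff plus exact lexicographic
  ordering of the candidate set, so tie handling is deterministic.
* Correlations are computed via centered cross-products and clamped to
  [−1, 1]; constant rows raise an error naming the offending nodes.
* `dvars()` errors on non-positive global means; `scrub_volumes()` errors
  when no frame survives; `regress_confounds()` errors on rank-deficient
  confound matrices, naming the collinear columns.
* `ruzicka_similarity()` errors on two all-zero vectors (0/0).
* All stochastic operations take explicit seeds, restore the caller's RNG
  state, and serialize deterministically (fixed formatting), so identical
  configs yield byte-identical artifacts.

## Known limitations

* The fixed-effects normal-reference p ignores pair dependence; use the
  permutation p for confirmatory claims.
* The FFT band-pass assumes approximately stationary, regularly sampled
  input; heavy scrubbing before filtering (the default order) violates
  regular sampling near gaps.
* Real-mode image ingestion (4D volumes + masks) is out of scope; the
  pipeline consumes node × time matrices in delimited text.
* Fixed-seed Monte-Carlo band assertions are themselves statistical: a
  200-replicate check that a nominal-0.05 rejection rate lies in
  [0.03, 0.08] has roughly a 7% false-alarm probability even when the
  test is exactly calibrated (binomial noise), so a red band at one seed
  set must be read together with the larger calibration property test,
  which verifies uniformity of the null permutation p-values directly.
* Louvain-type greedy search is not guaranteed to reach the global Q
  optimum on adversarial graphs, though on ≤ 8-node graphs it attains the
  enumerated optimum in ≥ 95% of seeds and planted structures are
  recovered with ARI > 0.9 in the suite's regimes.
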