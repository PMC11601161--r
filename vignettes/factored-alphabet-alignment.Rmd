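---
title: "Structure alignment with a factored structural alphabet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure alignment with a factored structural alphabet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strataln)
```

This vignette is the package's own account of the method it implements: the
model, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, the numerical choices, and the design
decisions that were genuinely open. Everything quantitative shown here is
computed by the code below or by the package's tests; nothing is quoted
from elsewhere.

## The model

### Per-residue features

Each residue is represented only by its C-alpha coordinates and amino-acid
letter. From the coordinate trace we compute, per residue *i*:

* **aa** — the amino-acid letter (20-letter alphabet; nonstandard residues
  map to `X`, which is assigned to the `A` slot at discretization time with
  a warning rather than widening the alphabet to 21 letters).
* **NEN / REN** — the nearest Euclidean neighbour of *i* subject to a chain
  separation of at least `min_chain_sep` residues, and the nearest
  neighbour on the *opposite* chain side of *i* from the NEN. We record
  their distances (`dist_nen`, `dist_ren`), their signed chain offsets
  clipped to ±`offset_clip`, and the distance to the second-nearest
  eligible neighbour (`dist_n2`).
* **Conf windows** — all pairwise C-alpha distances among the 2κ+1
  positions centred at *i*, excluding the 2κ adjacent pairs whose spacing
  is fixed by the virtual C-alpha bond; with κ = 3 this is a 15-dimensional
  vector. The same window is evaluated at the NEN and at the REN, giving
  three vector features (`conf_self`, `conf_nen`, `conf_ren`).

All features are functions of inter-atomic distances only, hence invariant
under rigid motion of the chain — the tests assert this to 1e-9 Å under
random rotations and translations.

Defaults and their units: `kappa = 3` (residues; window of 7), `min_chain_sep
= 2` (residues; excludes i±1 whose proximity is uninformative),
`offset_clip = 32` (residues; the offset tail beyond ±32 is rare and
carries little alignment signal), `sentinel_dist = 20` Å (recorded when a
residue has no eligible neighbour, e.g. at the termini of very short
chains; a bounded sentinel keeps the scalar bins stable). Terminal
conformation windows are mirror-padded (indices reflected across the
terminus) so the window vectors have constant dimension for K-means; the
alternative — variable-dimension or dropped terminal windows — would have
complicated both clustering and scoring for no accuracy benefit at this
scale. Sentinel values participate in alphabet training, so the letters
they map to are well-defined at assignment time.

### Alphabets

Scalar features are discretized into `L = 16` equal-frequency bins: the
sorted training values are split into L contiguous bins whose sizes differ
by at most one, and the threshold between bins is the mean of the adjacent
extreme values. Equal frequency maximizes the entropy of the alphabet and
hence the information per letter. A value exactly on a threshold falls in
the lower bin. When ties in the training data would collapse thresholds
(offsets are integers, so this can happen), the same rule is re-applied to
the *distinct* values — strictly increasing thresholds are kept at the cost
of exact equal frequency. If fewer distinct values than letters exist the
alphabet is refused as degenerate rather than silently shrunk, because the
factored state count is part of the model's contract.

Vector features are discretized by K-means with K = 16. We use the
stats built-in (Hartigan–Wong, 10 restarts, 300 iterations) under an
explicit seed; letters are assigned by nearest centroid with ties to the
smallest index. When K equals the number of training vectors the exact
solution (every point its own centroid) is returned directly.

The per-residue tuple of letters is one state in the factored alphabet of

```{r}
mega_alphabet_size(c(20, rep(16, 8)))
```

states. The point of factoring is that each 16×16 (or 20×20) log-odds
matrix is trainable from realistic amounts of data while the product space
is astronomically larger than any alphabet one could train directly.

### Scoring, alignment, quality

Per-feature log-odds matrices are trained from reference alignments by
counting aligned letter pairs (both orders, so the matrix is exactly
symmetric and the independence case gives an exactly zero matrix), adding a
Jeffreys-style pseudocount of 0.5 to every joint cell, and taking
`log2(P/(p p'))` in bits. The pseudocount is the minimal fix for the
sparse-counts problem that motivates factoring in the first place; with it,
rare letter pairs get finite, conservative scores. Feature weights default
to 1 and are stored in the tables, so a weight search can be layered on
without touching the scoring path.

Alignment is affine-gap local dynamic programming (three-state Gotoh) over
the pair-score matrix, with a gap of length `len` costing
`G_open + (len − 1) G_ext` and terminal gaps free. Defaults `G_open = 3`,
`G_ext = 0.5` bits were chosen on the simulated benchmark: they are small
relative to the ~7 bits/column of a confident homolog alignment, so indels
are bridged, yet large enough that unrelated chains cannot stitch together
scattered matches. Traceback ties break deterministically (diagonal, then
gap-in-target, then gap-in-query). The DP kernel is the one piece of
compiled code in the package; an independent re-evaluation of the returned
alignment from its columns is used as an invariant in the tests, and the DP
is checked exhaustively against an enumeration oracle over *all* sequence
pairs of length ≤ 6 on a 2-letter alphabet.

Alignment quality combines four ingredients:

* `D`, a symmetrized local-distance-difference score of the alignment:
  reference pairs are aligned columns within 15 Å in the reference
  structure at chain separation ≥ 2; a pair is preserved at tolerance τ if
  the two structures' distances differ by less than τ; the preserved
  fraction is averaged over τ ∈ {0.5, 1, 2, 4} Å, over columns, and over
  both choices of reference structure. The both-references symmetrization
  matches the quality statistic's own Q↔T symmetry. Columns with no
  reference pair contribute 0 (conservative). The exact constants are the
  standard LDDT choices; the measure as a whole is a documented stand-in
  for the variant used by the method's reference implementation, which is
  specified elsewhere.
* `s`, the alignment score in bits;
* `s_rev`, the score of the query against its own coordinate-reversed copy
  — features are *recomputed* on the reversed coordinates, not copied — a
  per-query null correction for composition-driven score inflation;
* `L`, the mean chain length, damped by `lambda`.

Then `t = delta·D + (alpha·s − beta·s_rev)/(L + lambda)` and
`AQ = 1/(1 + 0.5·10^{(a + b·t)/10})`. The grouping of the length term (the
denominator reading `(αs − βs_rev)/(L + λ)`) is the one under which
`lambda` actually damps the statistic for anomalously short queries, which
is its stated purpose. A constant `gamma` is sometimes listed alongside
these parameters in descriptions of the method but appears in no formula we
implement; it is deliberately unhoused here.

Defaults `delta = 10, alpha = 0.2, beta = 0.2, lambda = 10, a = 14, b = −2`
were calibrated once on the package's simulated training benchmark and
frozen: with them, simulated homolog pairs land at t ≈ 8–9 and unrelated
pairs at t ≈ 2–5, the sigmoid midpoint `t = (a − 10·log10 2)/(−b) ≈ 5.5`
sits between the two populations, and AQ < 0.5 marks spurious alignments as
intended. These constants are properties of the shipped configuration, not
of the mathematics; retraining them for a different data regime is a
one-liner grid search over `run_benchmark()` output.

### E-values

The null model is reversed-chain decoys built from the search database
itself: every query is aligned against the reversed copies of the other
chains, and the upper half of the resulting AQ distribution (≥ 50 points,
≥ 100 decoys required) is fitted by a linear model of log10 exceedance
probability against AQ. `E(aq) = N · P_null(AQ ≥ aq)`, clamped to
`[0, N]`, with the exceedance floored at 0.5 below the decoy median so the
reported E-value is monotone and never pretends to resolution the fit does
not have. Reversal preserves length, composition and local window geometry
while destroying homologous correspondence, so no labels are needed — the
same recipe works on a real database. Two properties follow by
construction and are tested: E scales exactly linearly in database size,
and E is non-increasing in AQ.

The linear tail is deliberately conservative: extrapolated far beyond the
decoy range (AQ ≈ 0.8 for a true homolog) it *over*-estimates E, so
homologs of interest get E-values like 0.3 rather than 1e-10. Conversely,
measured against real unrelated chains the reversed-decoy null is slightly
thin at stringent thresholds — the acceptance measurement on 60 unrelated
chains finds FPEPQ/E ratios of roughly 1.5–3 at E = 0.1 and near 1 at
E ∈ {1, 10}, within the factor-of-three band the package's tests demand.

### Benchmarking

`search_all_vs_all()` scores every ordered pair (self-hits excluded;
standard practice, and the only choice under which FPEPQ is a per-query
error count). Homology is same family/superfamily label, strictly: a
same-fold different-superfamily pair counts as a false positive unless the
caller relabels. The CVE curve sweeps the observed E-values (an exact step
curve, not a grid) and reports TPR over *ordered* homolog pairs — the
normalization consistent with per-query FPEPQ — against FPEPQ; the CatE
curve does the same for top-hit category assignment; `sens_at_fpepq()`
reads the step function without interpolation. `evalue_vs_fpepq()` measures
calibration directly. Hits, curves and labels are plain tibbles, so the
dplyr/ggplot2 ecosystem applies; `autoplot()` methods give the
conventional log-error layouts.

## The synthetic-data generator

`synth_chain()` builds idealized C-alpha traces from helix (100°/residue,
1.5 Å rise, 2.3 Å radius), strand (3.3 Å-rise zig-zag) and coil
(self-avoiding 3.8 Å random walk, ≥ 3 Å clearance) segments, attached with
random orientations biased toward the running centroid so chains fold into
compact globules with genuine long-range contacts — without that bias the
neighbour-offset features collapse to a handful of local values and their
16-letter alphabets are untrainable, which is itself a faithful signal that
the features measure tertiary structure. Consecutive spacing is 3.8 ± 0.1 Å
before jitter. `derive_homolog()` applies single-residue indels (insertions
copy a perturbed midpoint, so the ground-truth correspondence stays
well-defined), amino-acid substitutions, and isotropic coordinate jitter,
returning the exact residue correspondence for matrix training.
`make_benchmark_set()` draws independent founders per family and derives
members from them. One seeded stream drives each generator call; none of
them touch the global RNG state.

Default study conditions: chains of ~60 residues, `noise_sigma = 0.5` Å,
`indel_rate = 0.05`, `sub_rate = 0.05`. These produce within-family
structural divergence around 1 Å RMSD with occasional indels — close
homologs by real-world standards — and ~25 distinct offset values per
feature, enough to train every 16-letter alphabet. The substitution rate
exists so the amino-acid feature is informative but not a giveaway; it is
an addition to the generator's parameter set, documented here because a
noiseless copied sequence would let the AA matrix alone solve the
benchmark.

What the simulator does **not** emulate: Ramachandran-consistent dihedrals,
sheet pairing between strands (strands are isolated zig-zags), side chains,
chain breaks, domain flexibility, and the deep-time divergence structure of
real superfamilies. Passing the simulated benchmark therefore demonstrates
that the pipeline's machinery — features, alphabets, matrices, DP, quality,
calibration, counting — is correct and self-consistent, *not* that the
shipped constants reach any particular sensitivity on real domain sets;
sensitivity numbers on the simulated benchmark (typically 1.0 at FPEPQ 1)
are far above what any method achieves on real remote-homology benchmarks,
exactly because the simulated families are easy.

## Numerical choices and degenerate inputs

* Indices are 1-based everywhere, including the alignment TSV interchange
  format and printed output; letters live in `[1, A_f]`.
* Scalar letter assignment uses strict comparison (`x > threshold`), so
  threshold-exact values take the lower bin; vector assignment ties go to
  the smallest centroid index; NEN ties to the smaller residue index.
* The log-odds matrices are symmetrized exactly (`(M + t(M))/2`) to kill
  last-bit asymmetry from floating-point division.
* Kabsch superposition uses the SVD of the cross-covariance with the
  determinant guard, so near-planar point sets still yield a proper
  rotation; fewer than 3 points or a collinear configuration is an error,
  not a silent answer.
* Empty local alignments (no positive-scoring cell) return score 0 and no
  columns; their LDDT-style score is 0 and their AQ is small but positive.
* Problem sizes in tests and the acceptance script — an 8-family training
  set, a 10×4 benchmark, 60 decoy chains — were chosen as the smallest sets
  on which alphabet training is non-degenerate and the E-value measurement
  at E = 0.1 has a few expected counts.

## Known limitations

* The eight structural features and the constants of the quality statistic
  are this package's documented choices; they span the named feature
  families (neighbour distances, offsets, conformation windows) but are not
  a reproduction of any released tool's trained tables, and no claim is
  made about agreement with such tools' scores.
* The linear exceedance tail is conservative at high AQ by design;
  applications needing calibrated E-values below ~1e-3 would need a larger
  decoy set and a heavier-tailed fit.
* The all-vs-all search is O(n·m) per pair with no acceleration; the
  optional k-mer prefilter is plumbing, not a tuned heuristic, and is off
  by default.
* mmCIF reading covers single-model `_atom_site` C-alpha traces; assemblies,
  insertion-code arithmetic and multi-model NMR handling are out of scope.
* Chain breaks are treated as consecutive residues, since the C-alpha trace
  carries no reliable break flag at this level of parsing.

## A complete run

```{r, eval = FALSE}
library(strataln)
set    <- make_benchmark_set(8, 3, sim_params(seed = 101, n_residues = 60))
tables <- train_tables(set$chains, family_alignments(set), seed = 5)
bench  <- make_benchmark_set(10, 4, sim_params(seed = 202, n_residues = 60))
tables <- calibrate_evalues(tables, bench$chains)
curves <- run_benchmark(bench$chains, bench$labels, tables)
curves$sens_at
autoplot(curves$cve)
```

The same pipeline is exposed as subcommands (`simulate`, `train`,
`calibrate`, `align`, `search`, `bench`) by the installed `strataln`
script, and `scripts/acceptance.R` in the repository reruns it end to end
from a single seed.
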