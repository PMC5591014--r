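---
title: "Models and methods behind contactscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind contactscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactscape)
```

# Scope

`contactscape` implements two linked analyses from regulatory genomics:

1. calling chromatin contacts of a chosen viewpoint (typically a promoter or
   a CTCF-bound site) from 4C-seq data, including replicate-consensus
   significance and a two-condition comparison; and
2. quantifying how close expression-defined gene classes (up, down,
   unchanged-expressed, not-expressed) sit to interval features such as CTCF
   ChIP-seq peaks or predicted tissue enhancers, with permutation and rank
   tests and TSS-centered signal meta-profiles.

Everything runs on plain-text standard formats (FASTA, SAM/BED6, BED,
bedGraph, TSV) and on seeded synthetic data with planted ground truth, so
every stage is testable end to end without external downloads.

# Virtual digestion and the fragment map

4C libraries are built with two restriction enzymes; analysis happens on the
map of *first-cutter* fragments (defaults DpnII/`GATC` and Csp6I/`GTAC`).
`digest()` places a fragment boundary at the **first base of each
primary-motif occurrence** (a blunt model). The real enzyme leaves a 5'
overhang, but the analysis only consumes fragment identity, so the
convention merely has to be fixed and stated; this is it. Consequences that
follow from the convention and are covered by tests:

* a motif at position 0 coincides with the chromosome start and does not
  create an empty leading fragment;
* fragments tile `[0, L)` contiguously with strictly increasing indices;
* digesting the reverse complement reflects internal boundaries with a
  motif-length offset (`p -> L - p - 4` for a 4-mer), not a pure mirror —
  the partition is still equivalent fragment-for-fragment.

Overlapping occurrences are scanned at step 1 and duplicate boundaries are
deduplicated; non-palindromic motifs are scanned on both strands; any `N`
defeats a match (conservative boundaries). A fragment is **blind** when no
secondary-site occurrence is *fully contained* in it — an occurrence
spanning a boundary belongs to neither fragment. Blind fragments behave
anomalously during library preparation, so the flag is carried into the
fragment BED for downstream filtering, though the default pipeline does not
exclude them.

# From reads to capture profiles

A fragment end counts as **captured** — evidence that it ligated to the
viewpoint — only if at least one read maps *exactly at the end and points
into the fragment*: a `+` read starting at the fragment start, or a `-`
read ending at the fragment end. Capture is a presence call (duplicates do
not matter), and reads anywhere else on the fragment are ignored; the
simulator deliberately plants such noise reads to exercise this filter.

Captured sites are summarized in windows of `window_size = 30` consecutive
fragments, so a window holds at most 60 captured sites. Two decisions were
open and are fixed here:

* **Sliding windows (step 1)** rather than tumbling windows: they preserve
  fragment-level resolution; `step` is a parameter for users who want
  disjoint windows. Neighboring windows are therefore correlated, which is
  harmless for the consensus rule but means significant windows come in
  runs — a planted contact is "recovered" when any overlapping window is
  called.
* The **frequency** is `f = c / (2 * window_size)`, a proportion in
  `[0, 1]`. Any monotone rescaling would give identical fits (the decay
  model is rank-based), so the normalized choice is purely for
  interpretability.

Windows touching the viewpoint fragment ±`exclusion_radius` fragments
(default 2) are excluded: self-ligation and undigested templates dominate
there. Analysis is *cis*-only — windows are formed on the viewpoint
chromosome, matching the locus-centered design the method is meant for.

# The monotone distance-decay model

Contact frequency decreases monotonically with genomic distance from the
viewpoint; specific contacts are windows sitting *above* that trend. We fit,
separately upstream and downstream of the viewpoint (chromatin context is
rarely symmetric; `score_contacts` consumes both sides on one grid), an
isotonic non-increasing least-squares curve of `f` against **distance
rank**, solved by pool-adjacent-violators (PAVA). Using rank rather than bp
makes the fit invariant to any monotone transform of distance and avoids
committing to a functional form — the model assumption is monotonicity,
nothing more. The test suite verifies PAVA against exhaustive level-set
enumeration and against `stats::isoreg`.

Residuals `r = f - yhat` are standardized by a robust scale
`sigma = 1.4826 * MAD(r)` (floored at `1e-6` so all-tied residuals do not
divide by zero). The MAD is used instead of the standard deviation so that
the true contacts we are trying to detect do not inflate their own
denominator. z-scores get one-sided upper-tail normal p-values — the method
looks for enrichment, not depletion — and Benjamini–Hochberg adjustment is
applied per replicate across all non-excluded windows of the profile (both
sides jointly; the family is "every window tested for this viewpoint and
replicate").

A window is a **consensus significant contact** when `z > 2` in *every*
replicate and `q < 0.05` in *at least one*. Both thresholds are exposed
(`z_threshold`, `q_threshold`). The unit of testing is the window, not the
fragment: window-level counts are what the decay model describes. Residual
normality is an approximation — binomial counts at 60 ends per window are
skewed where capture is rare — which is why the consensus rule, not any
single p-value, carries the inferential weight; the null simulations below
measure the realized false-call rate directly.

# Comparing conditions

For a two-condition comparison each sample is first rescaled so its total
window count over a **normalization region** — viewpoint ±7.5 Mb, i.e. a
15 Mb span, generalized from the anchored region of the original design and
configurable as `normalization_span_bp` — equals the across-sample mean of
raw regional totals. This preserves within-sample proportions exactly and
is idempotent. Per window, `group_stats()` reports condition means, `n - 1`
standard deviations, and the difference of means (antisymmetric under label
swap).

The count test, `nb_test()`, is a self-contained **exact conditional
test**: conditioning on a window's total raw count across both conditions,
the first condition's sum is binomial under the null with success
probability equal to that condition's share of the effective library size;
the two-sided p-value sums all outcome probabilities no larger than the
observed one. It consumes *raw* counts (pre-normalization, with regional
totals as library sizes). A method-of-moments common dispersion across
windows is reported as a diagnostic (`attr(, "dispersion")`), but the test
itself assumes dispersion 0: with strong biological overdispersion it is
anti-conservative, and the diagnostic is the warning light. This is a
deliberate trade — an explicit, enumerable test whose null calibration the
suite verifies by permutation, rather than a port of quantile-adjusted
negative-binomial machinery.

# Gene-set proximity to features

`nearest_distance()` measures from the TSS to the nearest *occupied base*
of a feature: 0 inside a feature, otherwise `min(|TSS - start|,
|TSS - (end - 1)|)` — not the half-open `end`, which is one past the
feature. `window_frequency()` reports, per class, the fraction of genes
with at least one feature in a window of width `w` **centered** on the TSS
(10 kb and 20 kb by default; `w = 0` degenerates to the TSS base itself),
expressed relative to the unchanged-expressed class (`RF`), a ratio of
proportions.

The permutation null draws `n_draws = 5000` same-size gene sets **without
replacement** from the expressed-gene pool and uses add-one empirical
p-values, `p = (1 + #extreme) / (n_draws + 1)`, so the smallest attainable
p is `1/5001` and p-values are exactly uniform under the null. The
statistic is pluggable (mean nearest distance by default in the pipeline;
a window frequency works equally) because the same null applies to several
summaries. `mann_whitney()` is two-sided by default, exact (full
enumeration, verified against a rank-assignment oracle) when
`n + m <= 14` with no ties, and a tie-corrected continuity-corrected normal
approximation otherwise.

`tissue_specific_peaks()` coalesces the other tissues' intervals into a
merged union and removes any focal interval overlapping it by **at least
1 bp** — the simplest reading of subtraction, asserted directly in tests.

`meta_profile()` extracts signal in ±2 kb around each TSS in 10 bp bins
(sampling the bedGraph step function at bin centers; uncovered positions
count as 0 and are tallied), flips minus-strand genes so downstream is
positive, z-scores **per chromosome** (each chromosome's own mean and SD
over all its extracted values — this removes per-chromosome baseline
offsets exactly, which the tests assert), averages within class, and
smooths with a centered moving average (default 5 bins, shrinking at the
edges). A constant track yields an identically zero profile.

# The synthetic-data generators

`make_genome()` builds a random background *free of both motifs* (chance
occurrences are mutated away iteratively) and injects primary and secondary
sites as a joint non-overlapping Poisson process, so realized site counts
are Poisson at exactly the requested rates — the property recovery tests
rely on. Defaults: 500 kb, rates 0.004/bp for both cutters (the 1/256
genomic density of a 4-mer), giving ≈2000 fragments of ≈250 bp.

`simulate_4c()` captures each fragment end with probability
`P(d) = min(0.9, A * (max(d, 1 kb) / 10 kb)^(-alpha))`, defaults
`alpha = 1` and `A = 1`: capture is near-saturated out to ~10 kb of the
viewpoint and decays hyperbolically beyond, the regime real cis profiles
show. Planted enriched fragment ranges multiply `P(d)` (capped at 0.95).
Captured ends emit one exact-position, inward-oriented read plus a
negative-binomial extra count (mean 2, dispersion 0.5); 10% noise reads are
placed strictly off end positions. All randomness fans out from one seed
through named substreams (`genome`, `reads_<condition>_<rep>`, `genes`,
...), so components regenerate independently and byte-identically.

`make_gene_fixture()` plants proximity effects as exponential nearest
distances: unchanged-expressed genes at scale 20 kb, a class with effect
`k` at scale `20/k` kb. Defaults encode the motivating biology — CTCF peaks
3-fold closer for both up- and down-regulated classes, enhancers 4-fold
closer for the down class only — and the signal track adds Gaussian bumps
(SD 150 bp) at CTCF peak centers over distinct per-chromosome baselines, so
the meta-profile's per-chromosome standardization is genuinely exercised.

What the generators do **not** emulate: mappability and alignment error,
PCR duplicates (capture calls are duplicate-insensitive anyway), blind-end
capture artifacts, trans contacts, domain structure beyond a single
power-law decay, and clustered or width-varying feature geometry. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to every artifact of real libraries.

# Numerical choices and degenerate inputs

* `sigma` floored at `1e-6`; upper-tail p floored at the smallest positive
  double before BH (q must stay in `(0, 1]`).
* Fewer than 5 usable windows per side is an error ("insufficient windows
  for decay fit"); an all-zero side warns and returns `z = 0`.
* A chromosome shorter than one window yields a single truncated window,
  flagged and excluded from fitting.
* Equal-probability outcomes in the exact conditional test are included in
  the rejection sum with a `1 + 1e-9` relative tolerance, so exact ties are
  counted once rather than lost to floating-point noise.
* Nearest-feature ties break toward the smaller coordinate (affects the
  reported partner only, never the distance).
* `pipeline_config()` validates eagerly, rejects unknown keys by name, and
  refuses to run without an explicit seed.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run on one ≈2000-fragment genome;
contact recall and null calibration use 50 seeded simulations of two
replicates each in the suite (30 in the acceptance script), decay-exponent
recovery 50 (30) single-replicate simulations, the permutation-uniformity
check 200 repetitions of a 199-draw null, and fixtures 200 genes per class.
These sizes put Monte-Carlo error well inside the asserted margins while
keeping a full run around a minute; all of them scale up by changing the
corresponding arguments.

# Known limitations

* The count test's dispersion-0 null (see above); the dispersion diagnostic
  and permutation calibration are the mitigations.
* Cis-only windows: trans contacts are counted in the capture log but never
  windowed.
* The decay fit assumes one monotone regime per side; a viewpoint at a
  domain boundary with a step-like profile will absorb the step into the
  isotonic fit rather than flag it.
* The exponent estimate is a diagnostic for simulated decays, not a general
  chromatin-physics estimator; it assumes a single power law and unsaturated
  windows.
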