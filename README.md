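# contactscape

Chromatin-contact calling from 4C-seq and gene-set proximity analysis for
regulatory genomics.

## The problem

Circular chromosome conformation capture (4C-seq) reads out, genome-wide,
which loci touch one chosen **viewpoint** (a promoter or a CTCF-bound
site). Contact frequency falls off monotonically with genomic distance, so
"significant contact" only means anything *relative to that decay*. In
parallel, questions about regulators such as CTCF are often phrased as
proximity statements — are down-regulated genes closer to tissue enhancers
than expressed-but-unchanged genes? — which need distance statistics with
honest permutation nulls rather than eyeballing.

`contactscape` provides both arms as composable R functions:

* **Contacts.** Virtual digestion of a reference into the first-cutter
  fragment map (DpnII/Csp6I defaults, "blind" fragments annotated); capture
  calls for reads mapping exactly at fragment ends facing inward; sliding
  30-fragment windows with captured-site count *c* ∈ [0, 60] and frequency
  *f* = *c*/60; an isotonic (monotone non-increasing, pool-adjacent-
  violators) fit of *f* versus distance rank on each side of the viewpoint;
  robust residual z-scores *z* = (*f* − *f̂*)/(1.4826·MAD) with one-sided
  normal p-values and Benjamini–Hochberg adjustment; and the
  replicate-consensus rule — a window is a contact when **z > 2 in every
  replicate and q < 0.05 in at least one**. Conditions are compared after
  total-signal normalization over a 15 Mb region around the viewpoint, with
  an exact conditional binomial count test per window.
* **Proximity.** Nearest TSS-to-feature distances (to the nearest occupied
  base), class frequencies of features within 10/20 kb TSS windows relative
  to unchanged genes, Mann–Whitney tests (exact for small samples),
  5000-draw permutation nulls sampled without replacement from the
  expressed-gene pool, tissue-specific peak derivation by interval
  subtraction, and per-chromosome z-scored signal meta-profiles in ±2 kb
  around the TSS.
* **Synthetic truth.** Seeded generators for genomes with controlled cutter
  density, 4C reads following a planted power-law decay with enriched
  windows and noise reads, and gene/feature fixtures with planted proximity
  effect sizes — every statistical claim in the test suite is checked
  against known ground truth.

## Worked example

```r
library(contactscape)

genome <- make_genome(seed = 42, length = 3e5)   # ~1100 DpnII fragments
map <- fragment_map(genome)
#> FragmentMap: 1 chromosome(s), 1137 fragments (GATC/GTAC)

frs <- map$fragments$chrS
vp <- viewpoint_spec("promoter", "chrS",
                     floor((frs$start[600] + frs$end[600]) / 2), map)

# two replicates with one 30-fragment region enriched 10-fold
enriched <- data.frame(frag_first = 800L, frag_last = 829L, fold = 10)
reads <- simulate_4c(map, vp, seed = 42, replicates = 2, enriched = enriched)

profiles <- lapply(names(reads), function(r)
  capture_profile(reads[[r]], map, vp, replicate = r))
calls <- score_contacts(lapply(profiles, fit_decay))
sig <- calls[calls$consensus_significant, ]
nrow(sig)
#> [1] 36
head(sig[, c("window", "start", "end", "z_rep1", "z_rep2", "q_rep1", "q_rep2")], 3)
#>     window  start    end z_rep1 z_rep2   q_rep1   q_rep2
#> 749    783 211070 216970   3.11   3.58 2.73e-02 5.17e-03
#> 750    784 211272 217011   4.21   4.01 4.19e-04 9.52e-04
#> 751    785 211448 217587   5.31   4.88 1.93e-06 1.78e-05
```

The 36 called windows are the sliding windows overlapping the planted
fragment range 800–829 (bp 214,644–220,577): the z-scores in both
replicates clear the consensus threshold exactly where the enrichment was
planted, and `estimate_decay_exponent(profiles[[1]])` returns `1.049`
against the generating exponent 1.

The proximity arm on a fixture with enhancers planted 4-fold closer to
down-regulated genes:

```r
fx <- make_gene_fixture(seed = 42, n_per_class = 200)
d <- nearest_distance(fx$genes, fx$enhancers)
median(d$distance[d$class == "down"])                  # 2422.5 bp
median(d$distance[d$class == "unchanged_expressed"])   # 5116 bp

mann_whitney(d$distance[d$class == "down"],
             d$distance[d$class == "unchanged_expressed"])$p
#> [1] 5.04e-08

permutation_null(function(g) mean(g$distance),
                 d[d$class == "down", ],
                 d[d$class != "not_expressed", ],
                 n_draws = 5000, seed = 42)
#> PermutationNull: observed = 3952, null = 6452 +/- 416.5 (N = 5000)
#>   p (upper/lower/two-sided) = 1 / 0.0002 / 0.0003999
```

Down-regulated genes sit at a mean enhancer distance of 3,952 bp; no
random same-size draw from the expressed pool got that close (lower-tail
p = 1/5001, the estimator's floor). `run_pipeline()` chains all stages on a
config (YAML or list) and writes every table, plus a manifest with
parameters and checksums, into a run directory.

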