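---
title: "Methods: binning and temporal analysis of rare and abundant gene pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binning and temporal analysis of rare and abundant gene pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raretide)
```

## The problem

Shotgun metagenome assembly requires sequencing coverage that rare
community members rarely reach, so the reads that fail to map back to
contigs — the *unassembled* fraction — are enriched in the rare
biosphere's genetic material, while the *assembled* fraction reflects
the abundant, well-covered taxa. `raretide` analyses these two gene
pools from derived tables rather than reads: feature-by-sample count
tables (16S OTUs; protein or KO clusters) per fraction, sample dates
and environmental covariates. This vignette explains each model in the
pipeline, the parameters that matter, and the choices made where the
design was genuinely open.

## Compositional preprocessing

Sequencing counts are compositional: only relative information is
meaningful, and log-ratio methods need strictly positive parts.

* **Prevalence filter.** Features whose grand total is 1 (global
  singletons) or that are detected (count ≥ 1) in fewer than
  `min_samples = 20` samples are dropped. "Detection" is exposed as
  `detect_min` because a stricter definition is sometimes wanted; count
  ≥ 1 is the default. The filter is intended to run on the table
  concatenating both fractions' samples (80 columns for a 40-month
  series), which is how `scripts/acceptance.R` applies it; per-fraction
  filtering is the same call on a single table.
* **Zero replacement (czm).** Each zero becomes the proportion
  `0.5/N` (half a count of the sample total `N`) and nonzero
  proportions are multiplicatively shrunk to restore the unit sum — the
  count-zero-multiplicative treatment. In degenerate samples (tiny `N`,
  many zeros) that rule would impute more mass than the sample holds,
  so the imputed proportion is capped at 0.65 times the smallest shrunk
  nonzero proportion; the cap solves
  `δ = 0.65 · p_min · (1 − δz)` exactly, which keeps every imputed
  value below every observed one and the sample strictly positive. For
  ordinary microbiome-scale samples the cap never binds.
* **CLR.** `clr(x)_i = ln x_i − mean_j ln x_j` per sample; columns sum
  to zero to well below 1e−9.
* **Rare vs abundant.** Within each sample, relative abundance
  > 0.01 % is abundant, < 0.01 % rare. The definition leaves exact
  equality unassigned; we class it rare (the conservative choice for a
  rare-biosphere analysis) and warn when it occurs.

## Differential abundance between fractions

The test follows the ALDEx2 recipe. For each sample, `n_mc` probability
vectors are drawn from Dirichlet(counts + 0.5) — the same draws serve
all features — and CLR-transformed. Within every Monte-Carlo instance a
Welch t-test and a Wilcoxon rank-sum test compare the fractions per
feature; the *expected* p-value is the mean across instances. A feature
is significant when **both** expected p-values are below α = 0.05: the
"convergence" of the two tests. This intersection is conservative,
which the calibration test confirms (type-I error well under α on null
data). The effect size is the median over instances of (median CLR in
A − median CLR in B), and the enrichment direction is its sign.

Open choices resolved here: the Dirichlet prior is the standard 0.5 per
feature; raw expected p-values drive the default call because the
convergence rule is stated on raw `P < 0.05`, while Benjamini–Hochberg
adjusted expected p-values are always reported and can drive the call
via `use_bh = TRUE`. Welch and Wilcoxon p-values are computed by
vectorised routines (exact rank-sum distribution when untied, tie- and
continuity-corrected normal approximation otherwise) that the test
suite checks against `stats::t.test()` and `stats::wilcox.test()` to
1e−12.

## CAG binning by PLS relevance networks

A Co-Abundance gene Group (CAG) is a set of genes whose abundance
profiles covary across the time series, used as a genome proxy when
assembly is impossible. The binning has three stages.

1. **PLS regression** (NIPALS, regression mode, both blocks centred and
   unit-scaled) predicts the gene CLR table from the OTU CLR table.
   With `keep_x` set, X-weights are soft-thresholded to retain the
   requested number of OTUs per component (sparse PLS). Successive
   X-scores are mutually orthogonal; rank exhaustion returns fewer
   components with a warning.
2. **Relevance weights.** The association between OTU `o` and gene `g`
   is reconstructed from the shared latent space as
   `w(o,g) = Σ_h cor(x_o, t_h) · cor(y_g, t_h)`, the established
   relevance-network convention for PLS; it is isolated behind
   `relevance_weights()` so alternatives can be swapped. Edges with
   weight below 0.8 and orphan vertices are deleted. The threshold is
   applied to the *signed* weight by default — CAGs group positively
   covarying genes — with an absolute-value mode available, since the
   convention is not fixed by the method's description.
3. **Extraction.** Each OTU with surviving gene edges anchors a CAG. By
   default a gene joins only its maximum-weight OTU (`unique` mode), so
   CAGs partition the binned genes — required for unambiguous median
   profiles downstream; `multi` mode lets genes join every linked CAG.
   Ties break lexicographically and are logged.

Defaults: `n_components = 2` (a seasonal community's CLR profiles live
essentially in the plane spanned by the annual sine and cosine, so two
latent components capture the co-variation structure; more components
mostly fit noise) and dense `keep_x` (sparsity unset), both exposed.

The **canopy** alternative clusters per-gene normalised profiles
directly: genes are visited in order of decreasing total abundance,
each unassigned gene seeds a canopy that absorbs genes correlating
≥ 0.9 with the canopy centroid (recomputed to stability), and canopies
whose centroids correlate ≥ 0.97 are merged transitively. On noise-free
data both methods recover a planted partition exactly.

## The CAG–environment network

CAG temporal profiles are the median member-gene abundance per sampling
date (relative abundance by default). Redundant CAGs — full-profile
Spearman ρ > 0.95 *and* identical taxonomy *and* amino-acid identity
> 95 % when an AAI matrix is supplied — are collapsed by transitive
closure, keeping the CAG with the most genes per group; chains of
pairwise redundancy are grouped because the pairwise definition alone
does not say how they should resolve. All three thresholds are strict
inequalities, matching their definitions.

The signed network joins CAG profiles and environmental series
(temperature, oxygen, nitrite), treated identically: Spearman ρ with
average-rank ties, edges kept only when ρ > 0.8 or ρ < −0.8 (strict; a
correlation of exactly 0.8 is dropped). Constant series have undefined
rank correlations and are removed with a warning. Louvain modularity
clustering runs on |ρ| edge weights — modularity is undefined for
negative weights, and the negative-edge handling is not otherwise
specified — while the sign stays on the edges for display and for the
keystone score. ExpectedInfluence is the one-step signed sum
`EI(v) = Σ ρ` over incident edges (negatives subtract), with strength
Σ|ρ| reported alongside; ΣEI over nodes equals twice the total signed
edge weight, which the tests assert to 1e−12.

## Seasonality

Bray–Curtis dissimilarity `BC(a,b) = Σ|x_a − x_b| / Σ(x_a + x_b)` is
computed on count tables (via `vegan`). The lag-similarity curve
averages `1 − BC` over all sample pairs separated by exactly `L`
calendar months (ISO dates are binned to whole months); an annually
recurring community peaks at lag 12 and dips at lag 6. Similarity is
taken as `1 − BC` — the natural complement on the [0, 1] scale. ANOSIM
uses `vegan::anosim()`: `R = (r̄_between − r̄_within)/(M/2)` on ranked
dissimilarities, `p = (1 + #{R* ≥ R})/(1 + n_perm)`, seed-fixed.

## Pathway coverage

A gene set's metabolic capability is summarised per pathway as the
fraction of the pathway's KEGG orthologs present; a pathway is reported
at coverage ≥ 25 %. Unlike the network thresholds this boundary is
inclusive ("at least"), so 1 of 4 KOs reports. Many-to-many KO→pathway
maps are supported; query KOs absent from the map are ignored with a
logged count.

## The synthetic generator

`generate_dataset()` emulates the study design so every stage is
testable without real reads: `n_samples = 40` monthly samples, OTU `i`
has expected abundance `exp(μ_i + A·sin(2π(t − φ_i)/12))`, counts are
multinomial per sample at a fixed library size (the simplest model
producing compositional, zero-inflated tables with exact column sums),
and one master seed drives every stream.

Design choices, made once and documented here:

* **Anchors occupy staggered seasonal niches**: the `n_cags` anchor
  phases are evenly spaced around the year with small jitter, while
  non-anchor OTUs draw uniform phases. Distinct bloom seasons are what
  make co-abundance binning identifiable at all; coincident phases are
  unresolvable in principle by any covariation method.
* **Half the CAGs anchor on rare OTUs** (when the rare pool allows),
  mirroring a rare/abundant CAG split, so the unassembled fraction
  receives whole seasonal CAGs.
* **Gene factors absorb the anchor's mean level**: a gene's expected
  profile is its anchor's profile scaled to unit mean times a fixed
  lognormal factor, then multiplied by lognormal noise (`noise_sd`,
  swept in tests since no quantitative gene–OTU noise model is given).
  The gene table is its own composition, so a rare taxon's gene pool
  still carries observable mass — as in real data, where the
  unassembled fraction holds the majority of reads.
* **Background genes are aseasonal** "housekeeping-like" abundant
  genes, emulating the temporally stable core gene pool; they dilute
  the assembled fraction's seasonal signal, which is why the
  unassembled lag-similarity contrast is reliably the larger one.
* **Rare OTUs** are rescaled to mean relative abundances log-uniform in
  [1e−6, 3e−5], below the 0.01 % cutoff even at seasonal peak.
* **Fraction assignment** uses the anchor OTU's realised relative
  abundance as a coverage proxy (read-level assembly being out of
  scope): a gene's counts go to "unassembled" where the anchor sits
  below `coverage_threshold` (default 1e−3, roughly the abundance at
  which a 100k-read sample stops supporting assembly); background genes
  use their own relative abundance. The two fraction tables sum
  cell-wise to the original.
* **Environment**: temperature is a sinusoid peaking in late summer,
  oxygen anti-phase with it (solubility), nitrite peaking in winter,
  each with small Gaussian noise.
* An expected-abundance oracle (`otu_expected`, `gene_expected`,
  noise-free, arbitrary units) is always returned: each CAG gene's row
  is an *exact* scalar multiple of its anchor's, enabling exact
  recovery tests.

What the generator does **not** emulate: read-level artefacts (PCR and
GC bias, chimeras), strain heterogeneity, taxon–taxon interactions
beyond shared seasonality, overdispersion beyond the lognormal gene
noise, and missing months. Passing tests therefore show the methods are
correct and well-calibrated under the stated statistical structure, not
that they overcome those real-data complications.

## Problem sizes and numerical choices

The test suite and acceptance script run the study-scale configuration
(40 samples, ~60 OTUs, ~400 genes) for end-to-end checks; the
planted-recovery experiment uses 8 CAGs × 30 genes over a compact panel
of 10 OTUs (8 anchors + 2 unanchored distractors) — enough to exercise
gene-stealing by phase-colliding distractors while keeping the adjusted
Rand index interpretable against the planted partition; calibration
simulations use 200 features × 40 samples with 16 Monte-Carlo
instances and 20–50 replicates. NIPALS converges at 1e−9 on the weight
vector; zero-variance features correlate as 0 with a warning rather
than erroring; Welch p-values on degenerate (constant) groups are set
to 1 for that instance with a warning; all ID-based tie-breaks are
lexicographic and logged.

## Limitations

CAG binning presumes gene–taxon covariation is visible in relative
abundances; horizontal transfer, multi-copy 16S variation and shared
housekeeping genes blur anchors in real data. The Louvain |ρ| choice
discards the sign structure during clustering (a signed-modularity
variant would not, at the cost of a nonstandard null model). Redundancy
collapse without an AAI matrix degrades to profile + taxonomy evidence
only, and taxonomy labels are taken as given, not inferred.
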