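---
title: "Methods: promoter interactome calling, differential contacts and regulatory annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter interactome calling, differential contacts and regulatory annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promhic)
library(data.table)
```

promhic analyses promoter capture Hi-C (PCHi-C) data: chromatin contact
libraries enriched for restriction fragments that contain gene promoters
("baits"). The input is a table of ditag counts — read pairs assigned to
pairs of restriction fragments — per condition, plus peak calls for
chromatin marks, TSS annotation and gene-level FPKM values. The package
calls significant promoter interactions, compares two cell types, overlays
chromatin state, and integrates expression. Because the methods are
heuristic in places, the package ships a synthetic-data generator with
planted ground truth, and its entire test suite is built on recovering that
truth.

## Significant-interaction calling

### Background model

A ditag is modelled as two fragment ends drawn nearly independently: with
$c_i$ the *relative coverage* of fragment $i$ (its share of all fragment
ends, $\sum_i c_i = 1$), the probability that a random ligation joins
fragments $i$ and $j$ is

$$p_{ij} = \min(1,\; 2\,c_i c_j),$$

and the observed count $N_{ij}$ out of $N$ total reads is tested against
$\mathrm{Binomial}(N, p_{ij})$, upper tail. This coverage-product
(random-ligation) model is the classical binomial background for Hi-C
enrichment testing. q-values are Benjamini–Hochberg across all tested
pairs, and the *significance* of a pair is $s = -\log_{10} q$.

P-values and q-values are computed in log space (`pbinom(log.p = TRUE)` and
a log-space step-up), because strong contacts in deep libraries reach
$p < 10^{-300}$: without this, q-values underflow to zero and significances
become infinite, which breaks the threshold construction below.

The coverage-product model is deliberately blind to genomic distance. Real
contact frequencies decay roughly as a power law in distance, so proximal
pairs are systematically *under-expected* and their p-values are inflated.
This is a known property of the model; it is absorbed by the per-promoter
threshold, not by the test itself.

### Per-promoter significance thresholds

Promoters differ enormously in their local background, so a single global
q-value cutoff either drowns strong promoters in proximal noise or starves
weak ones. For each promoter we instead:

1. collect the significances $s$ of every interaction touching the bait
   (for promoter–promoter pairs, the interaction belongs to both baits);
2. form the empirical density of $s$ on a uniform grid of `grid_points`
   (default 256) cells over $[0, \max s]$ — this is the first derivative of
   the cumulative significance curve;
3. smooth it with a centred moving average of width `smoothing_window`
   (default 5 grid cells; edge windows are partial rather than
   zero-padded);
4. locate the *antimode*: on a more heavily smoothed copy (window
   `grid_points/16`), the first empty run of cells after the main mode —
   the gap that separates the bulk of weak, background-driven significances
   from the promoter's strong contacts;
5. place the threshold at the *inflection of the derivative*: the grid cell
   where the curvature (second finite difference) of the smoothed density
   turns from negative to positive — i.e. where the decline from the bulk
   has levelled off — choosing, among such cells at or below the antimode,
   the one closest to it.

Interactions with $s$ at or above the threshold are kept ("above the
background significance level" is read as $\geq$). The construction falls
back to a global cutoff of $q \le$ `fallback_q` (default 0.05, i.e.
$s \ge 1.30$) when the promoter has fewer than `min_interactions`
(default 10) interactions, when no empty run exists, when the density at
the candidate antimode exceeds `bimodal_ratio` (default 0.1) times the
modal density (no trustworthy gap), or when no curvature sign change lies
below the antimode. The threshold never drops below the fallback cutoff.

Two readings of "inflection point of the first derivative" are possible:
the curvature sign change of the derivative (implemented as the default,
`method = "inflection"`) or the extremum of the derivative itself
(`method = "derivative_minimum"`, which places the threshold at the
antimode). Both are exposed; they differ by at most the width of the gap.

Replicates are pooled by count summation before testing; the binomial test
on the pooled table equals the test on element-wise summed replicates by
construction (verified as a property test). Sex chromosomes can be excluded
via `exclude_chroms` when the compared lines differ in sex. Read-depth
matching between conditions uses `subsample_to_depth()`, an exact
multivariate hypergeometric subsample of the read multiset.

## Differential interaction calling

Two conditions are compared directly: for each fragment pair in the union
of pairs observed in either table, the *expected* value is the reference
condition's count scaled by the two totals, i.e. the test-condition count
is referred to $\mathrm{Binomial}(N_\text{test},\, n_\text{ref}/N_\text{ref})$,
upper tail. When a pair has reads in only one condition, a count of 1 is
imputed in the condition with the missing value (so log ratios stay
finite); the pseudocount applies only in that case. Each direction
(test-specific, ref-specific) is tested by a separate run with the roles
swapped; the two one-sided runs are reconciled so a pair is significant in
at most one direction.

Multiple testing is controlled at a 5% false discovery rate with a
covariate-weighted Benjamini–Hochberg procedure in the spirit of
independent hypothesis weighting: the covariate (log10 pair distance, the
dominant nuisance for contact counts; trans pairs form their own stratum)
is cut into `n_bins` quantile bins, per-bin weights with unit mean are
learned by cross-fold grid search over a one-parameter family built from
per-bin non-null proportion estimates, and weighted q-values are BH on
$p_i / w_{g(i)}$. With one bin the result reduces *exactly* to plain BH —
that reduction is the correctness anchor of the implementation. Weights are
scored on a fixed ladder of FDR levels (0.02, 0.05, 0.10) so that the
learned weights, and hence the discovery set, are monotone in the level the
caller thresholds at.

### A caveat on error control

The differential test plugs the reference count in as if it were the true
expectation. Under a two-sample null (both conditions sampled from the same
contact distribution), the reference count carries the same sampling noise
as the test count, so the far tail of the p-value distribution is inflated
roughly as $\bar\Phi(z/\sqrt{2})$ instead of $\bar\Phi(z)$ — at any read
depth. The consequence, measured by this package's own calibration tests on
simulated independent null tables, is that the procedure's realized false
discovery proportion at a nominal 5% FDR is far above 5%: discordant pairs
produced purely by double sampling noise reach very small p-values in
numbers that BH (weighted or not) cannot control. The test is nevertheless
implemented exactly as specified, because it is the method under study;
its ranking of pairs is informative (planted differential contacts are
recovered with sensitivity ~1 and label direction correctly), but the
nominal FDR should not be taken at face value. A dispersion-aware
two-sample test (e.g. the conditional binomial on $n_\text{test}$ out of
$n_\text{test}+n_\text{ref}$) would restore calibration at the cost of
departing from the published procedure; it is deliberately out of scope.

## Chromatin annotation

*Homotypic interactions*: a called interaction is homotypic for a mark
(H3K27me3, CTCF, ...) when both fragment intervals overlap at least one
peak of that mark by ≥ 1 bp. Classification operates at fragment
resolution, matching the assay's resolution; a pair may be homotypic for
several marks. Per-mark *cell-specific fractions* are the percentage of a
mark's homotypic interactions that fall in the differential set, with an
all-interactions baseline.

*Enhancer states*: H3K4me1 peaks more than 1 kb from every TSS (end-to-end
gap; overlap counts as distance zero; strand-aware TSS points when strand
is available) are classified as **active** (overlap H3K27ac but not
H3K27me3), **poised** (overlap H3K27me3, which dominates H3K27ac), or
**intermediate** (neither). The *stringent* active-enhancer list is the
base-pair intersection of DNase, H3K4me1 and H3K27ac peaks, merged when
separated by less than 300 bp (transitively, left to right) and filtered to
lengths in [100 bp, 3 kb]. All overlap thresholds default to 1 bp and are
configurable.

*Matched peaks*: covariate-matched peak selection (length and ChIP signal
density, the latter defined as count / (total reads × peak length)) is a
greedy 1:1 nearest-neighbour matching without replacement in z-scored
covariate space, with a caliper (default 0.25 pooled sd) that drops poor
matches. Greedy matching is order-independent here because pairs are taken
globally by ascending distance.

## Expression integration

Genes pass the expression filter when their maximum $\log_2$ FPKM over
samples reaches the threshold (−1 by default; −3 is appropriate for
low-depth knockout series). Profiles for clustering are per-gene z-scores
of $\log_2(\text{FPKM} + 0.01)$ across the ordered samples; k-means
(Lloyd, `k = 7` by default, 25 seeded restarts, best inertia kept) is
deterministic given the seed. Zero-variance genes are dropped with a
message. Cluster enrichment of an annotated gene set is its representation
in a cluster relative to its overall abundance; the cluster-size-weighted
mean of enrichments is identically 1, which the tests assert to 1e-12.
Group comparisons report median/quartiles with 1.5×IQR whiskers and Welch
t-tests, BH-corrected across the declared family; categorical comparisons
use Pearson chi-squared without continuity correction and the
two-proportion z-test; multi-group comparisons use one-way ANOVA with
Tukey HSD.

## The synthetic study generator

`simulate_bundle()` generates every input from a single seed:

* **Fragment map** — geometric fragment lengths (mean 4 kb, the scale of a
  six-cutter digest), two 1 Mb chromosomes, 100 bait fragments with
  synthetic gene names. Desk-scale sizes are chosen so the full pipeline
  runs in seconds; they preserve the quantities that drive the statistics
  (reads per bait, pairs per distance stratum).
* **Contacts** — $10^6$ reads per condition, multinomial over the capture
  pair universe (every pair involves a bait) with weight
  $v_i v_j (d + d_0)^{-\alpha}$, $\alpha = 1$, $d_0 = 10$ kb, log-normal
  fragment visibilities (sdlog 0.2), 5% trans reads. Cis pairs closer than
  20 kb are excluded from the universe: in real libraries that range is
  dominated by proximity-ligation products that upstream QC removes, and
  no enrichment caller is expected to interpret it.
* **Planted interactions** — shared and condition-specific pairs get their
  sampling weight multiplied by the fold (default 8). They are allocated
  by cycling over baits, so every promoter carries true contacts (as real
  promoters do), at partner distances drawn from 20–50 kb — the core
  enhancer–promoter range. Both choices matter: a promoter with no true
  contacts has no significance gap for the threshold to find, and spikes
  planted at megabase distances would be statistically weaker than the
  proximal background under any fold.
* **Peaks** — background peaks per mark at a configurable per-fragment
  density; both ends of planted pairs receive peaks of the configured
  homotypic marks with probability 0.8; enhancer-candidate H3K4me1 peaks
  are placed on reserved fragments (preferring planted partner fragments,
  so enhancer–gene links exist) and dressed with H3K27ac / H3K27me3 /
  DNase to hit configured class proportions. Independently placed peaks on
  the same fragment are confined to disjoint halves so planted classes are
  not corrupted.
* **Expression** — 7 clusters × 100 genes; centroids are drawn directly as
  z-form profiles (mean 0, sd 1 across samples) and redrawn until all
  pairwise distances reach 6 noise-sd, because the clustering operates on
  z-scored profiles where additive expression shifts are invisible —
  separation enforced in any other space would not guarantee
  recoverability. FPKM $= 2^{\,3 + \text{centroid} + \mathcal{N}(0,
  0.25)}$. Genes linked to TF-bound planted enhancers are biased into a
  factor-specific cluster with probability 0.8.

What the generator does *not* emulate: chromatin-loop extrusion structure
(TADs, stripes), copy-number and mappability artefacts, biological
replicate variability beyond binomial sampling, peak-calling noise, and
isoform-level expression. Passing the planted-truth tests therefore
demonstrates that the statistical machinery recovers the structures it was
designed for under its own stated noise model — not that the pipeline is
robust to every pathology of real data.

### Null calibration

The calibration tests for the interaction caller sample from the caller's
own null: a factorizable background (visibility biases, no distance decay,
all fragment pairs) on ~51k pairs at $10^6$ reads. Under the decaying,
capture-restricted generator the coverage-product model is deliberately
mis-specified — that is the realistic regime the per-promoter threshold
exists to handle, and it is exercised by the planted-truth tests instead.

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open; BED I/O is native.
* HindIII cut convention A^AGCTT (`cut_offset = 1`); digestion scans
  motif occurrences left to right.
* Trans distances are `Inf`, never a large number; distance-stratified
  code must branch.
* Ties at the promoter threshold are kept ($\ge$); candidate inflections
  tie-break toward the antimode, then toward larger $s$ (more stringent).
* `subsample_to_depth` with the full total is the identity; a target above
  the total is an error.
* Pairs with zero background probability but positive counts warn and get
  p = 0.
* Empty peak sets annotate nothing; marks with zero homotypic pairs report
  `NA` fractions; empty clusters report `NA` enrichment.
* `ihw_adjust` collapses to one bin (with a warning) when there are fewer
  than 10 tests per bin.

## Problem sizes

The shipped defaults — 2 × 1 Mb chromosomes, ~500 fragments, 100 baits,
$10^6$ reads, ~45k candidate pairs, 700 genes — were chosen so that a full
simulate-call-compare-annotate-cluster cycle completes in a few seconds
and the whole validation suite (including 200-replicate calibration loops)
in a few minutes, while keeping per-bait read depth (~10k) and per-pair
counts (~20) in the regime of a deeply sequenced capture library.

## Known limitations

* The differential test's nominal FDR is not trustworthy under two-sample
  noise (see the caveat above); treat the differential list as a ranking.
* Promoter–promoter pairs are tested with the same binomial background as
  promoter–genome pairs and flagged; the dedicated promoter–promoter
  background (a logit-based model in the literature) is not implemented.
* The per-promoter threshold needs a visible gap in the significance
  distribution; promoters whose true contacts are as weak as their
  proximal background fall back to the global cutoff.
* Replicate-aware dispersion modelling is out of scope by design; the
  model is binomial on pooled counts.
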