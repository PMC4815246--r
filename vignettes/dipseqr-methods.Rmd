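---
title: "Methods: region-level DIP-Seq analysis in dipseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-level DIP-Seq analysis in dipseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dipseqr analyses DNA immunoprecipitation sequencing (DIP-Seq) of the two
cytosine modifications 5-methylcytosine (5mC, MeDIP) and
5-hydroxymethylcytosine (5hmC, hMeDIP). DIP-Seq signal is fragment-level:
an antibody pulls down modified fragments, short single-end reads are
mapped, and the information available per library is a set of
uniquely-mapped tag 5′ positions. There is no single-base methylation call;
everything in this package is therefore region-level by construction. This
vignette describes each model and procedure, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## Coordinates and input contracts

All intervals are 0-based half-open (`[start, end)`, BED convention)
internally; the only conversion happens at I/O boundaries (wiggle export is
1-based per that format's standard; IRanges is used 1-based internally to
the overlap helpers). Chromosome names are opaque strings — no "chr"
normalisation is attempted, so a mismatch between tag files and chromosome
sizes surfaces as an error rather than a silent rename. A tag is the 5′
position of a uniquely-mapped read; reads are not extended or shifted
toward fragment centers. Extension would sharpen domain edges by roughly
half a fragment length, but with 1-kb analysis windows the effect is
negligible and no extension parameter is part of the input contract; tags
enter window counts exactly where they mapped.

## Enrichment segmentation

Tags (typically pooled over the replicate libraries of one
tissue × condition × mark cell) are counted in windows of width
$W$ = 1000 bp. Two notes on that default: 1 kb matches the fragment-scale
resolution of DIP enrichment, and `optimize_window()` reproduces the
window-tuning loop — run the full procedure per candidate width and keep
the width that maximises the number of enriched regions (ties go to the
smaller window, the more conservative choice at equal yield).

The window **step defaults to the width** (tiling). A sliding window with
$s < W$ is available, but tiling makes window counts sum-conserving (every
tag counted once), keeps the Monte-Carlo null cheap, and loses little:
signal split across a window boundary is recovered when significant
windows are merged. Merging bridges gaps up to one window width by
default — the smallest nontrivial slack, so that a single sub-threshold
window inside a true domain does not split the call.

The enrichment threshold is empirical. For a library of $N$ tags, $B$
randomizations (default 20) place $N$ tags uniformly over the genome —
the matching null for the generator's homogeneous background; real-data
users can restrict the randomization with a mappability mask supplied as
excluded intervals. For each integer count $t$:

$$\widehat{\mathrm{FDR}}(t) =
  \frac{\mathbb{E}_{\mathrm{rand}}[\#\{\text{windows} \ge t\}]}
       {\max(\#\{\text{observed windows} \ge t\}, 1)}$$

and the returned threshold is the smallest $t$ with
$\widehat{\mathrm{FDR}}(t) \le \alpha$ (default 0.05). The search grid
runs one count past the randomization maximum, not just to the observed
maximum. This matters on background-like data: there the observed and
expected tail counts track each other, the ratio never dips below
$\alpha$ within the observed range, and only thresholds with zero
observed windows (where the denominator's $\max(\cdot,1)$ takes over)
satisfy the criterion — the correct outcome being an empty call set, not a
failure. "No enrichment detectable" is still an error when the input has
no tags at all. Domain totals are re-counted from tags, so reported counts
are exact even when merging bridged a gap.

Pooling before segmentation (rather than intersecting per-replicate
calls) reflects the design the package targets — two replicates per cell
is too few for per-replicate consensus calling — and per-library
segmentation remains available by passing a single library's tags.

## Differential region calling

Candidate regions are the interval union of the two conditions' enriched
domains, so a region enriched in either condition is tested exactly once,
and coordinates never depend on which condition is "first". Two tests are
provided; chi-square is the default because it needs no dispersion
estimate and its pooled 2×2 framing matches the tag-sampling model, while
the negative-binomial mode uses the replicate structure:

* **Chi-square**: Pearson statistic, one degree of freedom, no continuity
  correction, on `[[count_A, N_A − count_A], [count_B, N_B − count_B]]`
  with counts and library sizes pooled within condition. Regions where any
  expected cell is below one are flagged `low_count` rather than dropped.
* **Negative binomial**: a GLM with log link and offset $\log N_j$ per
  library, condition as the only covariate, and a likelihood-ratio test on
  one degree of freedom. Two replicates per condition cannot support
  per-region dispersion, so one dispersion is shared across regions,
  estimated by method of moments on counts scaled to the median library
  size: $\hat\phi = \sum_i (v_i - m_i) / \sum_i (m_i^2 - v_i/k)$ over
  region × condition cells with $k \ge 2$ replicates. The $v_i/k$
  correction removes the upward bias of $m_i^2$ as an estimate of
  $\mu_i^2$ at small $k$; without it the dispersion is underestimated and
  the test runs visibly liberal. A non-positive estimate falls back to
  Poisson with a warning.

p values are Benjamini–Hochberg adjusted within the set of regions tested
together (one mark × tissue — the narrowest natural family, so a strong
signal in one mark cannot mask discoveries in the other), and q < 0.01
defines the reported DMR/DHMR sets. Fold changes use counts scaled to the
median library size with a pseudocount of 0.5 added to each condition's
scaled sum — enough to stabilise $\log_2$ ratios at empty cells without
visibly shrinking well-covered regions; direction is "up" when the
non-reference (irradiated) condition is higher.

## Directional spatial overlap

Whether 5hmC gains sit near 5mC losses is asked as a pairing question:
region $a$ of set A is *paired* when some region of set B lies on the same
chromosome within a gap of $w$ = 25 kb. The gap is edge-to-edge
(overlapping regions have gap 0) — the least restrictive reading of
"within a window", and the window is a parameter. Pairing is counted from
the A side, each A region once regardless of partner multiplicity, which
gives the clean sampling frame $n_{\mathrm{paired}} \le n_A$.

Significance conditions on the **universe of all tested regions** of mark
A, not the whole genome: enriched regions are clustered wherever the
underlying domains are, and a genome-wide null would rediscover that
clustering rather than the directional association of interest. Each
universe region is labelled paired/unpaired with respect to the
*significant* B set; under the hypergeometric null the significant A
regions are an exchangeable draw from the universe, and the upper-tail
probability of the attained pairing count is reported. A permutation mode
(shuffling which universe regions carry the significant label, $p = (1 +
\#\{k_{perm} \ge k_{obs}\})/(1 + B_{perm})$) checks the same null without
the closed form. `venn_summary()` applies this to all four direction
pairs and flags the best-ranked pair(s). No attempt is made to reproduce
any particular published p value: those depend on the original data and an
unstated null; both nulls here are documented alternatives.

## Annotation and repeat densities

Category assignment resolves multi-feature overlaps with a
closest-midpoint rule: candidates are every overlapping feature (TSS
window = TSS ± 1 kb, exon, intron), the feature whose midpoint is nearest
the interval midpoint wins, and exact ties fall to the fixed priority
TSS > exon > intron. Midpoint distance is the metric because it is
symmetric, cheap, and independent of feature length conventions; the 1-kb
TSS flank is the conventional promoter-proximal scale and is a parameter.
A coarse intragenic/intergenic split (`classify_genic()`) accompanies the
four-way classification.

Repeat densities are counts per million within the repeat-overlapping
fraction of the library: tags overlapping several repeat elements are
assigned exclusively to the closest (same midpoint rule), and
$\mathrm{CPM}_c = 10^6 \cdot n_c / \sum_{c'} n_{c'}$, so per-library CPM
sums to $10^6$ exactly — the normalization identity the tests assert. The
alternative denominator (total library size) is available by flag, since
"per million" is ambiguous between the two; the repeat-fraction reading is
the default because it makes classes comparable across libraries with
different overall repeat recovery. Tissue contrasts use a two-sided Welch
t-test per class on per-library CPM (n = 4 per tissue in the reference
design), with p < 0.05 reported as significant; Welch is the documented
choice where the underlying test was not named, as the per-library CPMs
are approximately normal at these counts and unequal variances between
tissues cost nothing.

Gene mapping ranks differential regions by q (ties by |log2FC|, then
coordinate), keeps the top 2000, drops regions with no TSS within 50 kb,
assigns each survivor to its nearest TSS with a strand-aware signed
distance (negative upstream), and collapses duplicate genes keeping the
best-ranked region. The gene list is exported for external
gene-ontology/pathway tools; no enrichment statistics are computed here.

## Density profiles

Metagene matrices use fixed 500-bp flank bins over ±5 kb and 40
length-normalised gene-body bins; values are per-bp densities (count /
bin width, scaled per million tags), so uniform coverage yields flat
columns even though body bins vary in width. Minus-strand genes are
reversed so the 5′ end is always leftmost; rows are ordered by descending
expression. Flank width and body-bin count are parameters — the defaults
are a conventional rendering scale, not a modelling claim.

Colour normalisation clips the matrix at the 0.8 quantile of its nonzero
values and min-max scales to [0, 1]. The quantile is computed as an order
statistic (type 1), which makes the operation exactly idempotent on
matrices containing zeros (interpolating quantile types are not, because
clipping shifts the interpolated threshold on a second pass). Wiggle
tracks emit per-bin density only where the raw count reaches the
segmentation threshold at α = 0.05, scaled by median library size over
library size, so browser tracks show median-scaled signal above
background.

## The synthetic-data generator

The generator emulates the targeted study design: two tissues × two
conditions (sham/proton) × two replicate libraries for each of 5mC and
5hmC. Background tags are homogeneous Poisson at rate $\lambda_0$
(default 0.01 tags/bp/library, i.e. 10 expected tags per 1-kb window);
enriched domains (default 200 per mark and tissue, 1–3 kb) replace the
background rate with $e \lambda_0$, $e = 8$; differential domains scale
the irradiated condition by $\varphi = 3$ ("up") or $1/\varphi$ ("down").
A differential region is its whole host domain: differential signal must
live inside called domains to be testable, and using the full domain keeps
the planted truth aligned with the candidate regions the pipeline
actually tests. A fraction $\kappa$ of 5hmC differential domains is
rejection-sampled to land within 25 kb of a 5mC differential domain of the
paired direction (default pairing: 5mC down / 5hmC up, the
oxidation-coupled demethylation pattern). Planted domains of one mark keep
a 5-kb minimum separation so that neighbouring truths are not merged into
a single call and recall/precision bookkeeping stays unambiguous.

One seed drives everything: placements are drawn first, then per-library
substreams are derived from the seed, so replicates are independent but
the whole simulation is bit-reproducible. Genome defaults are two 5-Mb
chromosomes — large enough for ~hundreds of well-separated domains and
stable calibration counts, small enough that the full pipeline runs in
about a minute.

What the generator deliberately does **not** emulate: mappability
structure, GC bias, copy-number variation, antibody cross-reactivity or
CpG-density-dependent capture efficiency, fragment-length variation, and
read-level sequence content. Passing tests therefore demonstrate that the
algorithms are correct under their stated noise model — they do not
demonstrate robustness to the capture and mappability artefacts of real
DIP-Seq, for which a mappability mask (segmentation) and the usual
library-QC upstream of this package are the available mitigations.

## Validation conditions and numerical notes

The test suite fixes its problem sizes as package choices: segmentation
recovery uses a 10-Mb genome with 200 planted 1–3-kb domains at 8× over a
background of 10 tags per window, matched at ≥ 50% reciprocal overlap;
null calibration pools 20 pure-background repeats (observed vs expected
windows at the chosen threshold are compared with add-one smoothing, as
both are order-one counts at a threshold selected for FDR ≤ 0.05);
negative-binomial calibration uses 2000 null regions at dispersion 0.2
with 2 vs 2 replicates; differential power uses 10 planted 3× regions
among 40 domains per repeat over 20 repeats; coupling detection uses
$\kappa = 0.8$ with 30 differential regions per mark over 20 simulations.
Degenerate inputs are defined rather than special-cased: both-zero counts
give p = 1, all-zero regions give p = 1, empty call sets propagate as
empty-but-valid tables through overlap, annotation and export, and a
constant matrix quantile-scales to zeros.

## Known limitations

* The homogeneous Monte-Carlo null is anticonservative in regions of
  elevated mappable density unless a mask is supplied.
* Common NB dispersion across regions is a forced compromise at two
  replicates; strongly region-specific overdispersion will be
  miscalibrated.
* The hypergeometric overlap null assumes exchangeability of significant
  labels across the universe; when significance correlates with a spatial
  covariate (e.g. region size), the permutation mode inherits the same
  assumption — only a covariate-matched null (out of scope) would remove
  it.
* Chi-square pooling ignores replicate variability entirely; it is exact
  for the generator's Poisson world but liberal on overdispersed real
  libraries, which is why the NB mode exists.
* No paired designs, covariates, or batch correction.
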