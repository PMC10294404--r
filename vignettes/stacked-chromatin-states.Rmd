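---
title: "Stacked chromatin-state annotation: model, methods, and design"
author: "ChromStack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked chromatin-state annotation: model, methods, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChromStack)
```

## The problem

Epigenomic consortia produce hundreds of genome-wide signal tracks — histone
modification ChIP-seq, DNase-seq, ATAC-seq — across many cell and tissue
types. Per-cell-type chromatin-state models annotate each cell type
separately; a *stacked* (full-stack) model instead trains one hidden Markov
model jointly on **all** datasets from all cell types and assigns every
genomic position a single state shared across cell types. Such an annotation
separates constitutively active regions from cell-type-specific ones and
gives analyses that are not inherently cell-type-specific (variant
interpretation, sequence conservation) one common reference annotation.

ChromStack implements that workflow end to end at a scale a laptop can run:
binarization of per-bin read counts, joint HMM training, genome
segmentation, and the downstream state characterizations (annotation
enrichment, positional profiles, gene expression, conservation scores,
cross-species state correspondence) — together with a synthetic-data
generator that produces every input with known ground truth, which is what
the test suite exercises.

## The model

The genome is tiled into fixed bins (default 200 bp; bin $i$ covers
$[(i-1)\,b,\ i\,b)$, 0-based half-open). The observation at bin $t$ is a
vector $o_t \in \{0, 1, \mathrm{NA}\}^E$ of present/absent calls for $E$
datasets. A $K$-state hidden Markov chain $z_t$ with initial distribution
$\pi$, transition matrix $A$, and *independent Bernoulli emissions* governs
the observations:

$$P(o_t \mid z_t = k) = \prod_{e=1}^{E} p_{ke}^{\,o_{te}} (1 - p_{ke})^{1 - o_{te}},$$

with missing entries marginalized out (they contribute a factor of 1). The
emission matrix $p \in (0,1)^{K \times E}$ is the object biologists read:
row $k$ is state $k$'s probability of a present call in each dataset.

Conditional independence of datasets given the state is the core modeling
assumption. It is wrong in detail (replicate datasets are correlated beyond
what the state explains) but is what makes joint training over hundreds of
tracks tractable, and the states themselves absorb the dominant
correlations.

### Training

`baumWelch()` runs expectation–maximization with:

* **Chunked sequences** — each chromosome is split into fixed-length chunks
  (default 5,000 bins) treated as independent sequences sharing $\pi$. This
  mirrors the row-splitting that production implementations use for memory
  and restart behavior, and it is what makes the initial distribution
  estimable from more than a handful of sequence starts.
* **Pseudocount smoothing** — every multinomial/Bernoulli update adds a
  smoothing mass (default 0.02) to numerator counts, keeping all parameters
  strictly inside their open simplexes. The exact constant is a convention,
  exposed in `trainConfig()`.
* **Random restarts** — emissions are initialized uniformly at random in
  (0.05, 0.95) with self-biased transitions; among `nRandomInits` restarts
  (default 10) the highest final log-likelihood wins. The likelihood surface
  genuinely has poor local optima: on 50,000-bin simulations, single-restart
  runs routinely land hundreds of nats below the best restart, which is why
  the model-selection sweep uses several restarts per state count.
  `burnInIterations` switches on the screening schedule large initialization
  searches use: every restart runs only a short burn-in (15 iterations in
  the package's own heavy tests) and the best burn-in likelihood is
  continued to the full budget. On the synthetic study this selects the same
  optimum as training every restart fully at a fraction of the cost.
* **No early stopping by default** — `convergenceDelta = NA` disables the
  likelihood-delta stop and every restart uses the full iteration budget
  (default 200), matching the convention of training the production models
  with the delta check disabled. A relative-change threshold can be set.

Because the M-step maximizes a pseudocount-penalized objective, the *data*
log-likelihood trace is only guaranteed non-decreasing up to the influence
of the smoothing mass; the package tests monotonicity at a relative
tolerance of $10^{-6}$ per iteration, which the smoothing effect stays well
inside at these data sizes.

The forward/backward recursions use per-bin scaling constants, with the
bins-by-states log emission matrix computed as two BLAS matrix products and
the $O(TK^2)$ recursions in compiled code. The numerical scheme is not part
of the contract: the test suite checks log-likelihood, posteriors, and
Viterbi paths against exhaustive path enumeration on hundreds of small
random instances (max absolute posterior deviation below $10^{-9}$).

### Decoding and ties

`segmentGenome()` offers posterior-maximum and Viterbi decoding; both are
provided because production annotations do not document which was used, and
on high-signal data they agree almost everywhere. Ties — in decoding, in
maximally-enriched-state reports, in reciprocal-best-pair extraction — are
always broken toward the lowest state index, and reciprocal pairing treats a
tie as "no pair". This is documented and tested rather than left to
floating-point accident.

### Binarization

`binarizeCounts()` converts read counts to calls with a Poisson upper-tail
test: a bin is "present" when its count reaches the smallest integer $c$
with $P(X \ge c) \le p$ for $X \sim \mathrm{Poisson}(\lambda)$, at
$p = 10^{-4}$ by default. With a matched control, $\lambda$ is the bin's
control count scaled by the signal/control total-read ratio and floored at
the genome-wide uniform expectation; without a control (DNase/ATAC), the
uniform expectation itself. The tail probability is accumulated by direct
summation of the probability mass function via the multiplicative
recurrence — exact for the small $\lambda$ this workflow sees — and the test
suite cross-checks it against the distribution-function oracle. Local
control smoothing windows are deliberately not implemented; the flag space
is reserved.

### Model selection

`stateSweep()` trains one model per candidate $K$ on the full data and
evaluates negative log-likelihood, AIC, and BIC on a fixed set of randomly
sampled, non-overlapping, bin-aligned regions (`sampleRegions()`); the
model is *evaluated*, not retrained, per region set. The free-parameter
count is $KE + K(K-1) + (K-1)$, and BIC uses the number of observation
*bins* as $n$ — the base-versus-bin choice is not standardized anywhere, so
bins were chosen as the model's actual observation unit. Non-overlapping
sampling avoids double-counting likelihood; a request that cannot be packed
into the genome fails with the maximum feasible count. `compareEmissions()`
summarizes how well each focal state survives in an alternative model as
the maximum Pearson correlation between emission rows; zero-variance rows
are reported missing with a warning rather than silently dropped.

## Downstream statistics

**Fold enrichment** (`foldEnrichment()`) is base-level, not bin-level:
annotations are merged and clipped to assembly bounds, segmentation
intervals are expanded exactly as their BED representation, and
$\mathrm{fold}(s,a) = \frac{|s \cap a|/T}{(|s|/T)(|a|/T)}$ with $T$ the
genome size. Base-level counting was chosen because annotations are not
bin-aligned; merging first makes percent-of-annotation well defined. Every
table satisfies the identity $\sum_s \mathrm{frac}(s)\,\mathrm{fold}(s,a) = 1$,
which the tests assert to $10^{-6}$. Column min–max scaling for heatmap
display lives in the reporting layer only (`normalizeColumns()`); stored
statistics are never normalized. No multiple-testing machinery exists here
by design: these are descriptive enrichments, not hypothesis tests.

**Positional profiles** (`positionalEnrichment()`) count states at bin
offsets around anchor points (TSS, TES), snapping anchors to their
containing bin and flipping offsets on minus-strand anchors so positive
offsets always mean "downstream in the direction of transcription". Anchors
near chromosome edges contribute only their valid offsets. The window
default is ±10 bins at bin resolution.

**Gene expression** (`stateAvgExpression()`) implements the
gene-length-normalized average
$$\mathrm{avg}_s = \frac{\sum_{i \in B_s} \sum_{g \in G_i} E_g / L_g}
                        {\sum_{i \in B_s} \sum_{g \in G_i} 1 / L_g},$$
with $E_g = \log_2(\mathrm{FPKM}+1)$, exactly as the double sum is written:
a gene contributes once per overlapping segment, with no base-proportional
weighting inside a bin. "Overlap" uses the full gene body (TSS→TES including
introns) — the natural reading where the formula's source is ambiguous — and
all genes in the table are used. Replicates of a tissue are averaged
arithmetically after the per-state computation, with a single-replicate
fallback on missing values (warned).

**Cross-species correspondence** maps a foreign segmentation through a
per-segment mapping (`mapForeignAnnotation()`), excluding destination bins
claimed by ≥ 2 distinct source segments — collisions are detected at the
bin level after mapping, matching per-bin independent lifting. The
cross-state fold matrix uses the full focal genome as the enrichment
background, mirroring how annotation enrichment behaves when handed a lifted
file; restricting the background to mapped territory would change folds,
and that choice is surfaced here deliberately. Reciprocal best pairs
require unique maxima in both directions. `conservationReport()` ranks
states (descending, average-rank ties) on score average, best cross-species
fold, and constraint-element fold, with a top-$k$ intersection at $k = 20$
by default.

## The synthetic study

`generateStudy()` produces every pipeline input under one master seed. The
default study conditions are: a 10-Mb toy genome of three chromosomes
(50,000 bins of 200 bp), $E = 20$ datasets from 4 chromatin marks × 5
cell-type groups, and a $K = 8$ ground-truth model whose non-quiescent
states each emit one mark either constitutively or in exactly one cell
group — distinct (mark, scope) blocks per state, so the truth is
identifiable — plus a designated quiescent state with all emissions ≤ 0.05.
Missing calls are masked at 1%. Gene expression is drawn per replicate
around a state-conditional mean on the $\log_2$ scale (SD 0.2); the score
track is Gaussian around per-state means, clipped to [0, 1]; the toy
mapping drops 5% of segments and redirects 5% onto already-claimed
destination bins to exercise the exclusion rule. Annotations are planted by
rejection placement against the true path: each annotation bin comes from
the target state's territory with probability $f \cdot \mathrm{frac}(s)$,
giving an analytic expected fold of $f$ (the requested fold is clamped to
the feasible range $f \cdot \mathrm{frac}(s) \le 1$ and the effective value
recorded).

One master seed fans out to per-component child seeds by a fixed affine
rule, so regenerating one fixture never perturbs another, and all
randomness flows through R's RNG (Mersenne-Twister) for cross-platform
determinism.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: read-level noise and fragment pileups, correlated
(batch) structure between datasets beyond the state, realistic annotation
size distributions, genome assembly coordinates, or mappings with split and
strand-flipping segments. The generator validates the machinery, not the
biology.

### Problem sizes used by the tests

The heavy checks run at the study scale the package treats as its reference
condition: parameter recovery trains $K=5$, $E=10$ models on 50,000 bins
with 10 restarts (burn-in screening, relative $10^{-7}$ convergence stop)
over 5 independent seeds (median max-absolute emission error < 0.05); the
model-selection sweep trains $K = 2..10$ with 6 screened restarts each
(relative $10^{-7}$ stop, 120-iteration cap) and evaluates criteria on 30
sampled 100-kb regions.
Enumeration oracles cover 200 random instances at ≤ 4 states × ≤ 6 bins ×
≤ 3 tracks; enrichment and expression oracles use per-base and triple-loop
counting on ~1,000–2,000-bin fixtures.

## Degenerate inputs and numerical choices

* Emissions are kept strictly inside $(0,1)$ by construction (pseudocounts);
  the model class rejects boundary values.
* Empty annotations, states with no territory, states with no scored bases,
  and states with no overlapping genes are all reported `NA`, never 0.
* All-missing observations have log-likelihood exactly 0 and a posterior
  driven purely by the chain.
* The terminal partial bin of a chromosome is a full observation row during
  modeling and is clipped only at BED export; overlap statistics weight it
  by its true base width. Whether other implementations do exactly this for
  the terminal bin is undocumented; the convention is flagged here for
  anyone comparing outputs bit for bit.
* Readers reject malformed lines outright rather than truncating, and all
  text formats round-trip losslessly (tested on randomized fixtures);
  gzip-compressed variants are accepted transparently.

## Known limitations

The package trains comfortably at tens of thousands of bins and tens of
datasets on one core; it is not engineered for the hundreds of genome-wide
datasets of a production run (no disk-backed buffers, no multithreading).
BAM/CRAM ingestion, bigWig output, the computation of conservation scores
themselves, and the coordinate-lifting algorithm are out of scope — the
package consumes count matrices, score tracks, and mapping tables in plain
text. Manual grouping and naming of states into biological families is a
curation step, supported only via label aliases at BED export.
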