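# ChromStack

Joint ("stacked") chromatin-state annotation of a genome from many
epigenomic datasets at once, with the downstream statistics used to
characterize the resulting states.

Per-cell-type chromatin-state models give every cell type its own
annotation. A stacked model instead trains **one** hidden Markov model on
the binarized signal of *all* datasets — histone marks, DNase, ATAC, across
all cell types — so that every genomic position receives a single state
label shared across cell types. That annotation separates constitutively
active regions from cell-type-specific ones and is the natural reference
for analyses that are not cell-type-specific (variant interpretation,
sequence conservation). ChromStack is aimed at methodologists and students
who want the full workflow — binarization, training, segmentation, state
characterization — in a form that runs on a laptop and is testable end to
end against simulated ground truth.

## The model

The genome is tiled into 200-bp bins. The observation at bin *t* is a
vector of present/absent calls for *E* datasets, produced by a Poisson
upper-tail test of read counts against a control-scaled or uniform
background (present iff the count reaches the smallest *c* with
P(X ≥ c) ≤ 10⁻⁴ for X ~ Poisson(λ)). A K-state hidden Markov chain with
initial distribution π, transitions A, and **independent Bernoulli
emissions**

P(o_t | z_t = k) = ∏_e p_ke^{o_te} (1 − p_ke)^{1 − o_te}

is trained by Baum–Welch with pseudocount smoothing, chunked training
sequences, and random restarts; missing calls are marginalized out. The
genome is segmented by posterior-maximum or Viterbi decoding, and states
are characterized by base-level fold enrichment against interval
annotations, strand-aware positional profiles around TSS/TES, gene-length
normalized average expression

avg_s = [Σ_{i∈B_s} Σ_{g∈G_i} E_g/L_g] / [Σ_{i∈B_s} Σ_{g∈G_i} 1/L_g],

conservation-score averages, and cross-species state correspondence through
per-segment coordinate mappings with a multi-mapping exclusion rule. Model
selection across state counts uses NLL/AIC/BIC evaluated on randomly
sampled fixed-length regions. A synthetic-data module generates every input
with known ground truth (the model, the hidden path, planted annotations at
a configured fold, toy genes, mappings, and score tracks).

See the vignette `vignettes/stacked-chromatin-states.Rmd` for the methods
in full, including every numerical convention and design decision.

## Worked example

```r
library(ChromStack)

## a complete synthetic study with known ground truth:
## 50,000 bins x 20 datasets (4 marks x 5 cell groups), K = 8
study <- generateStudy(studyConfig(seed = 42))
study$tracks
#> BinaryTrackMatrix: 20 dataset(s) x 50,000 bins on 'toy1' (1.00% missing)

## train a stacked model and segment the genome (~3 min, one core)
cfg <- trainConfig(K = 8, maxIterations = 150, nRandomInits = 8, seed = 42)
fit <- baumWelch(study$tracks, cfg)
seg <- segmentGenome(fit$model, study$tracks, mode = "posterior")

## emission recovery after matching states to the ground truth
perm <- matchStates(fit$model, study$model)
max(abs(emissionProbs(fit$model)[perm, ] - emissionProbs(study$model)))
#> [1] 0.008770995

## per-bin agreement of the decoded annotation with the hidden truth
mean(perm[unlist(study$truePath)] == unlist(stateSeqs(seg)))
#> [1] 0.96818

## the study plants an annotation enriched in truth-state 1; the decoded
## state matched to it (E7 here, i.e. perm[1]) carries the enrichment
round(foldEnrichment(seg, study$annotations)$fold, 2)
#>    planted_state1
#> E1           0.65
#> E2           0.35
#> E3           0.29
#> E4           0.32
#> E5           0.60
#> E6           0.69
#> E7           4.67
#> E8           0.44
```

The decoded states recover the generating emission parameters to within
~0.01, assign ~97% of bins to the true state, and the annotation planted at
5-fold for truth-state 1 surfaces at 4.7-fold on its matched decoded state
(decoding noise plus sampling).

A command-line wrapper over the same functions is installed at
`system.file("scripts", "chromstack", package = "ChromStack")` with
subcommands `synth`, `binarize`, `train`, `segment`, `select`, `enrich`,
`neighborhood`, `expression`, `crossmap`, `report`.

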