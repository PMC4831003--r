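---
title: "Inferring H3K27ac sequence signatures around TSSs and predicting expression from DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring H3K27ac sequence signatures around TSSs and predicting expression from DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqsig)
```

## The model

H3K27ac marks active promoters and enhancers, and its arrangement in the
2 kbp around a transcription start site (TSS) is strongly informative about
whether, and how strongly, the gene is transcribed. `seqsig` implements a
pipeline that (i) quantifies H3K27ac around TSSs from ChIP-seq coverage as
locally normalized *peak heights*, (ii) learns which 6-bp DNA words
associate with H3K27ac peaks versus depleted ("dip") regions, (iii) turns
that sequence preference plus the mark's cooperative spreading into a
per-position posterior probability of H3K27ac — the *sequence signature* —
computed from DNA alone, and (iv) predicts expression both from the
measured profiles and from the DNA-inferred signatures.

### Windows and peak heights

Each gene contributes a strand-oriented 2,004-bp window centred on its TSS,
tiled into T = 334 non-overlapping 6-bp segments (the TSS falls on the
boundary between segments 167 and 168). Reads are extended to 150 bp from
their 5' ends (ChIP fragments were size-selected near 150 bp); a base
belongs to an enriched region when at least 5 extended reads cover it; and
the peak height at base *i* is its coverage divided by the maximum coverage
in the 2-kbp neighbourhood around *i*, giving values in (0, 1] that equal 1
at local summits and are insensitive to sequencing depth. "Adjacent 2 kbp"
is implemented as the symmetric window of 1,000 bp on each side of the
locus, clipped at chromosome ends. Per 6-bp segment we take the mean of the
six per-base heights by default; the `max` reduction is available and is
what the cell-type comparison uses, since membership of a segment in a peak
is better captured by its best base than by its average.

### The weighted 6-mer spectrum

The height of a segment is read as the probability that the segment sits in
an H3K27ac peak, so a segment with 6-mer *s* and height *h* contributes *h*
to the peak count of *s*. Dip counts come, by default, only from segments
outside enriched regions (`dip_source = "non_enriched_only"`); the
alternative `"residual_everywhere"` also credits the residual 1 − *h* mass
inside enriched regions. Both counters are exposed because the choice is
genuinely open; the default is the more literal reading of "depletion sites
around TSS". Counts over the 4,096 possible 6-mers are normalized into the
emission distributions of the peak (M) and dip (d) states with a Laplace
pseudocount of 1, which keeps every 6-mer strictly positive — required by
the HMM — and stabilizes empty cells at moderate corpus sizes. Because both
spectra are estimated from the same TSS neighbourhoods, their ratio
automatically adjusts for the high GC content of gene-rich regions. 7-mers
and longer words are deliberately out of scope: the number of cells grows
4-fold per added base while the corpus does not.

### The two-state HMM and the signature

Peaks are cooperative: H3K27ac at one segment raises the odds of H3K27ac
next door. This is encoded by a two-state Markov chain over the segment
grid whose persistence `A[M->M]` is estimated as the fraction of
ChIP-labelled peak segments whose immediately next segment is also a peak
(labels default to height > 0.5; the adjacency distance is configurable).
The initial distribution defaults to the empirical marginal state
frequency, with the stationary distribution of `A` as an alternative. Given
the emission spectra and transitions, the forward-backward algorithm yields
the posterior `gamma_i(M) = P(segment i in a peak | the 334 6-mers)`. The
implementation uses per-step scaling, so T = 334 (or far longer sequences)
cannot underflow; with the consistent scaling, `sum_s alpha_i(s) beta_i(s)`
is the same for every position, which the code asserts. Segments containing
`N` emit uniformly from both states and therefore carry only transition
information, which avoids dropping windows with ambiguous bases.
Transitions are estimated directly from ChIP labels — there is no
Baum-Welch re-estimation, matching the intended estimation scheme.
Signatures are banded at the conventional thresholds: very high (> 0.9), high
(0.5, 0.9], medium (0.1, 0.5], low (<= 0.1); boundary values fall in the
lower band, a tie-break the thresholds leave open.

### Expression models

Two predictors are provided. The *fractional logistic model* regresses the
probability-scale target `p* = log2(FPKM + 1) / max log2(FPKM + 1)` on the
mean peak heights in K non-overlapping 200-bp windows around the TSS
(default K = 10 over 2 kbp; K = 5 over the central kilobase is one
configuration switch away, since both spans are in common use). With
continuous targets in [0, 1] the fit minimizes Bernoulli cross-entropy with
fractional labels — the quasi-likelihood extension that reduces exactly to
logistic regression for 0/1 targets — by Newton iterations with a small L2
penalty on the slopes (1e-4) for numerical stability.

The *signature-based predictor* is a neural network over the 334 posterior
signature values. A bottleneck autoencoder (334 → 2 → 334; sigmoid hidden
units, linear output) is trained first and reports its explained variance;
its encoder initializes the prediction network (334 → 2 → 1, linear
output), whose output layer is initialized by least squares on the encoded
training coordinates. Training uses analytic gradients under L-BFGS with a
500-iteration cap rather than a stochastic (Adam-style) optimizer: it is
deterministic given the seed, has no learning-rate schedule to tune, and is
the standard choice for moderate-size problems in R; the random seed enters
only through the weight initialization and the train/validation split. A
small L2 penalty (1e-3) on the weight matrices guards the roughly
2-per-position encoder parameters against overfitting at moderate gene
counts. Genes are split 10,000 / 3,000 into training and validation sets,
scaled proportionally (with a warning) when fewer genes are supplied.
Validation Pearson and Spearman correlations and the ROC AUC against the
1-FPKM detection flag are reported; FPKM in (0, 1] counts as *not*
significantly detected, so the flag is strictly `FPKM > 1`.

### Association screens and cell-type comparison

`association_screen()` relates per-position factor enrichment (200-bp
sliding windows with 100-bp steps, oriented with the gene) to expression by
both Pearson correlation and the maximal information coefficient. MIC is
computed with a MINE-style grid search: total grid cells are capped at
`n^0.6`, one axis is equipartitioned, the other optimized by dynamic
programming over clumps (at most 15 per column), both orientations are
searched, and the best normalized mutual information is reported. A
21-position grid over 2 kbp is internally inconsistent with 200-bp windows
at 100-bp steps (which give 19); the default grid therefore spans 2,200 bp
to produce 21 positions, with the span configurable.
Permutation nulls (`permutation_null()`) calibrate both statistics.

`classify_peaks()`/`classify_signature()` compare two cell types locus by
locus: probability (or height) above 0.5 in both is *common*; above 0.5 in
one and below 0.1 in the other is *cell-type specific*; everything between
is kept as an explicit *unclassified* class rather than silently dropped.
The same 0.5/0.1 defaults are applied to peak heights for want of a
separate convention; they are exposed as configuration.
`specificity_test()` compares signature levels between classes with the
rank-sum test (W = sum of combined-sample ranks of the first group, normal
approximation with tie correction), and `foldchange_summary()` summarizes
`log2((FPKM_A + 1) / (FPKM_B + 1))` per class, the +1 offsets matching the
expression scale.

## What the generator emulates

`generate_dataset()` plants the full generative structure the analysis
assumes: hidden peak/dip paths from a two-state Markov chain, window DNA
drawn from state-conditional 6-mer distributions, per-base Poisson coverage
conditioned on state for two cell types sharing a subset of peak runs, and
expression coupled to the TSS-proximal peak arrangement. Its defaults are
the package's study conditions and were fixed once:

* **Scale**: 2,600 genes on 10 chromosomes — one tenth of the 26,000 genes
  of a full mouse analysis — with the train/validation split scaled
  accordingly. Windows are separated by ~2 kbp of background so that local
  maxima are well defined.
* **Cooperativity**: `A[M->M] = 0.95`, `A[d->d] = 0.98`, i.e. mean peak
  runs of ~120 bp (nucleosome scale) at a ~29% marginal peak frequency
  within TSS windows, far above the ~3% genome-wide enrichment — TSS
  neighbourhoods are exactly where the mark concentrates.
* **Emissions**: each peak class multiplies the dip distribution by a dense
  log-normal field (sd `tau = 1.2`) plus a `delta = 2` boost on 50 driver
  6-mers per cell-type-specific set and 50 shared ones. The dense field
  spreads signal over all 4,096 words (as GC and general composition
  preferences do); the named driver sets give the enrichment-report and
  cell-type tests sharp targets. These values make DNA strongly but
  imperfectly informative about the mark — the regime the method is
  designed for, where sequence-only inference is good but never
  saturates.
* **Coverage**: Poisson per base at 20 reads/bp in peaks vs 1 in dips —
  segment-constant rates, the simplest model consistent with the >= 5
  reads/bp enrichment rule. The generator emits coverage tracks directly;
  `simulate_reads()` provides the read-level route for exercising
  extension and pileup, because 150-bp extension necessarily smears
  state-conditional coverage across the 6-bp grid — a property of the read
  model, not of the pileup code.
* **Expression link**: `log2(FPKM + 1) = max(0, -1 + 7 * s + N(0, 1))`
  where `s` is the weighted mean peak state in the 400 bp around the TSS,
  the downstream 200 bp weighted double — mirroring the observation that
  the mark just downstream of the TSS is the most informative position.
* **Second cell type**: each cell-A peak run is reused with probability
  0.5, and B-specific runs are added from an independent chain. A- and
  B-specific runs draw from their own driver sets so that cell-type
  specific signatures are encodable in a single genome, which the
  cell-type comparison requires.

What the generator does **not** emulate: nucleosome positioning,
mappability and GC bias in coverage, input/IgG background structure,
replicate variability, positional inhomogeneity of peak frequency along
the window, and the motif syntax of real transcription-factor binding
sites. Passing tests therefore demonstrate that the estimators recover the
structure they assume, at realistic signal levels — not that the pipeline
reproduces any particular real-data value. One visible consequence: real
H3K27ac profiles are strongly TSS-anchored, so two autoencoder coordinates
explain nearly all of their variance, while the generator's peaks sit at
chain-stationary random positions and two coordinates explain only a few
percent; the autoencoder's correctness is instead checked on constructed
rank-2 data where the optimum is known.

## Numerical choices and degenerate inputs

* Forward-backward uses per-step scaling; posterior normalization and the
  position-invariance of the denominator are asserted at 1e-9.
* The sliding local maximum is an O(n) monotonic-deque kernel (C++),
  tested for exact equality against the O(n·w) brute-force oracle.
* Logistic fitting stops at gradient norm < 1e-6 and errors (reporting the
  iteration count) rather than returning a non-converged fit; complete
  separation is only reachable with `lambda = 0`.
* Zero-variance vectors: MIC returns 0 with a warning; correlation-map
  cells are NA with a warning; the AUC errors on single-class truth.
* Expression tables reject negative FPKM and duplicated gene ids;
  windows extending beyond chromosome ends are skipped with a warning,
  unknown chromosomes are errors.
* Banding errors outside [0, 1]; classification thresholds must satisfy
  `hi > lo`.
* Minus-strand windows are reverse-complemented so that positions are
  comparable across strands ("upstream of the gene" means the same thing
  on either strand); the unoriented alternative is a switch
  (`orient_minus = FALSE`) for analyses that want genomic-forward windows.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the generator at its default
2,600 genes for the end-to-end discrimination analogues; parameter-recovery
checks use ~10^5 transitions / >= 10^5 peak-labelled segments / n = 5,000
logistic observations; the forward-backward oracle is checked on 100 random
instances of length <= 12 (exhaustive enumeration) and normalization on
1,000 windows of T = 334; null calibration uses 462 screen cells with
pooled permutation thresholds and 400 rank-sum replicates. These sizes keep
every Monte-Carlo bound a few standard errors wide of its threshold.

## Known limitations

* Enrichment detection is the fixed >= 5 reads/bp rule; no parametric
  background model (e.g. a normal-tail p-value on read counts) is fitted
  behind it.
* Transition estimation quantifies "physically close" as
  next-adjacent-segment; other gap distances are a configuration choice.
* Real-data performance depends on genome-scale ChIP-seq/RNA-seq inputs;
  the package's synthetic results characterize the estimators under the
  generator's assumptions and are not substitutes for an evaluation on
  real data.
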