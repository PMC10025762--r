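---
title: "Genome-wide TSS annotation from sequence and RNA-seq coverage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide TSS annotation from sequence and RNA-seq coverage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transcription start sites (TSSs) are mapped experimentally by CAGE-seq, but
CAGE data exist for few tissues. RNA-seq is ubiquitous, and coverage rises
sharply at an active TSS: upstream of the start there are few reads, downstream
the transcript is covered. tsscan annotates TSSs genome-wide by combining two
per-position inputs: the reference DNA sequence (which carries promoter
elements but cannot tell an *active* promoter from an inactive one) and
strand-specific RNA-seq depth (which carries activity but not base-level
precision). A binary classifier is trained on windows centered at active CAGE
peaks, then slid at stride 1 over all expressed positions of the genome; runs
of high-scoring sites are clustered into TSS calls.

## Model

Each training or scanning unit is a *paired window*: a 1001 x 4 one-hot
sequence matrix (channel order A, T, C, G; `N` is an all-zero row) plus the
matched 1001-vector of raw per-base depth from the strand of transcription.
Minus-strand windows are reverse-complemented and their coverage reversed, so
transcription always reads left to right.

Each input branch applies a valid 1-D convolution with 64 filters of width 10
(992 output positions), ReLU, and max pooling. Pooling is *strided*: the 992
conv outputs are split into 16 bins of 62 and the maximum is taken per bin,
giving 16 x 64 features per branch. The two branches are concatenated
(2048 features), passed through one fully connected ReLU layer of 128 units
with inverted dropout (keep probability 0.5 during training), and a 2-unit
softmax gives the TSS probability. The loss is mean softmax cross-entropy plus
an L2 penalty (`weight_decay * sum(W^2)`, weights only), optimized by
momentum SGD (`v <- m*v - lr*g; w <- w + v`).

**Why strided rather than global pooling.** The pooling geometry of the
original architecture description is open (only "the max pooling layer" is
specified), and the choice matters enormously for scanning. Under a *global*
max pool, the feature vector of a window is nearly invariant to where the
promoter signal sits inside it, because a max over all positions forgets
position. A window centered 300 bp downstream of a TSS then scores as high as
one centered on it: measured on synthetic data, the score track plateaus
above 0.5 across roughly +/-450 bp around every TSS, cluster representatives
fall anywhere in that plateau, and only about half of them land within 50 bp
of the true start. Binned pooling keeps coarse position (which 62-bp bin the
coverage step or motif occupies), restoring base-level placement: the score
peak tightens to tens of bp, and with hard-negative retraining (below) the
median representative error on the standard fixture is a few bp. The bin
width of 62 was chosen commensurate with the +/-50 bp positive-shift
augmentation; `pool_size >= 992` recovers a global pool.

All passes are written as im2col + BLAS matrix products with two small C++
kernels (per-bin max with argmax, sliding maximum). Gradients are analytic
and verified against central finite differences (relative tolerance 1e-4) in
the test suite. Evaluation-mode forwards are deterministic.

## Training data

Positives are active CAGE peaks (expression at or above a threshold, default
1.0), one window per peak per epoch, re-centered each epoch at a uniform
shift in [-50, +50] bp — augmentation is re-drawn at materialization time,
not frozen. Negatives are windows whose center lies 500-1000 bp from the
nearest same-strand peak (checked against the full peak set by brute force),
with the strand drawn uniformly among strands carrying peaks; the initial
training set is balanced. Splits are label-stratified.

## Circular (hard-negative) training

A classifier trained on a balanced set faces a wildly unbalanced genome at
scan time. After each training round, the current model scans +/-5000 bp
around up to 100 true TSSs drawn from the training positives; any site
scoring above 0.5 inside the +/-500 bp positive region counts TP, outside FP.
A uniformly chosen half of the negative set is then replaced by windows at
harvested FP sites and training repeats; the negative-set size is invariant,
and round 0 (before any replacement) is bit-for-bit plain training under the
same seed, the built-in ablation baseline.

One adaptation is needed at fixture scale: with TSSs a few kb apart, many
harvested FP sites fall within the +/-500 bp region of a *neighboring* true
TSS. Sites closer than 50 bp (the shift-augmentation range) to any same-strand
peak are excluded from the harvested pool — they are indistinguishable from
training positives and would poison the labels — while sites beyond that are
kept: windows with an off-center coverage step are exactly the hard negatives
the initial geometry lacks, and they supply the positional supervision in the
50-500 bp band that nothing else provides. FP *counts* in the round history
are never filtered. On the standard fixture this drives the scan-level FDR
from about 0.55 to well under 0.1 in one replacement round.

## Meta-learning and fine-tuning

To share structure across cell types, serial Reptile is used: sample a task
(cell type), train a copy of the meta-parameters for k inner batches on that
task alone, then move the meta-parameters a fraction epsilon toward the
trained copy, `theta <- theta + eps * (W - theta)`. Defaults for desk-scale
work: k = 50, eps = 0.1, 200 meta-iterations; each task contributes only its
designated 20% meta-training share. Fine-tuning is ordinary training
initialized from the meta-parameters on one cell type's fine-tuning split;
the meta-parameters are never modified. With one task, no task-sampling draw
is consumed, and with eps = 1 the update is exact adoption, so single-task
Reptile with eps = 1 is bit-for-bit plain SGD — both facts are asserted in
the tests, along with the closed form on a scalar quadratic loss
(one meta-iteration equals `theta - eps*alpha*(theta - c)`).

## Scanning and clustering

Only expressed positions (strand-matched depth >= `min_cov`, default 1 read)
are scored; each is an evaluation-mode forward on the window centered there,
at stride 1. Because each pooled bin is a maximum over a fixed 62-run of conv
outputs, a whole contig needs only one convolution and one sliding maximum
per branch; per-site work is then a gather plus the FC head. The fast path is
tested for exact agreement with window-by-window forwards on both strands.

Sites scoring above 0.5 within 10 bp of each other merge into clusters
(below-0.5 sites are discarded); the representative is the maximal-score
member (leftmost on ties) and the cluster score is the summed member score —
member count times mean score, a density statistic. The exact cluster-level
statistic used by the original pipeline (an empirical P value) is not public;
the density score stands in for it, and the downstream filter (keep clusters
with score >= 2.0 and >= 3 members by default) is an artifact choice exposed
in configuration. Plus- and minus-strand tracks are clustered independently.

## Evaluation

Binary metrics follow the standard formula block (accuracy, recall, FPR,
FDR = FP/(FP+TP), F1 = 2TP/(2TP+FP+FN)); undefined ratios are reported as
`NA`, never silently as zero. Scanning predictions are matched to truths
greedily in decreasing score order, one-to-one, within a 100-bp tolerance
(score ties broken by distance, then position); whether the original
matching is one-to-one is not documented, and one-to-one is the conservative
choice — each extra cluster near an already-matched TSS counts as a false
positive. A truth with no above-0.5 signal within tolerance is a false
negative. True negatives are not enumerable when scanning, so FPR is replaced
by false positives per kilobase scanned.

## Synthetic fixtures

The generator plants `n_tss` TSSs (pairwise >= 2 kb apart) on a uniform
random contig: a TATA-like 8-mer (`TATAAAAG`, 10% per-base mismatch) ends
30 bp upstream of each start on the coding strand; strand-matched coverage is
Poisson background (rate 0.5/bp) plus Poisson(expression) over a 1500-bp
transcript downstream of the TSS; per-TSS expression is log-normal
(meanlog 2, sdlog 0.6), giving an order-of-magnitude dynamic range with
nearly all TSSs above the activity threshold of 1. Decoy sites receive the
motif but no transcript — sequence signal without activity, the case that
makes coverage informative. Ablation fixtures can omit either the motif or
the coverage step. The standard study fixture is 200 kb with 50 TSSs (decoy
fraction 0.2; 0.5 for the hard-negative study). These sizes keep every
end-to-end check a few minutes on one CPU.

What the fixture does *not* emulate: fragment-length smearing of real
RNA-seq coverage (the step here is sharp), sequencing-depth variation,
multi-modal CAGE peaks, intron structure, and the base composition and
repeat content of real genomes. Passing tests therefore demonstrate that the
algorithms are implemented correctly and behave as designed under their own
assumptions — not that the trained models transfer to real data.

## Numerical and degenerate-input choices

* Ambiguous bases one-hot to all-zero rows, keeping row sums in {0,1}.
* Softmax is computed with max subtraction; cross-entropy clamps
  probabilities at 1e-12.
* Max-pool argmax ties take the first (leftmost) position; cluster
  representative ties take the leftmost maximal site.
* Checkpoint selection maximizes validation F1 (evaluated every
  `eval_every` epochs); ties go to the later, more-trained checkpoint.
* Overlapping bedGraph intervals sum; intervals beyond a contig end are
  clipped with a warning; a missing strand file yields zero coverage with a
  warning.
* Zero harvested FPs leaves the negative set unchanged with a message;
  an empty Reptile task is skipped with a warning.
* Filter-to-PWM conversion (for motif-gain extraction) is a per-position
  softmax over channels by default; a min-shift-renormalize alternative is
  selectable. The conversion used originally is not documented; softmax is
  the standard convention and keeps columns stochastic.

## Problem sizes used by the test suite

Unit tests use 21-41 bp windows with 4-8 filters. End-to-end checks use the
200-kb/50-TSS fixture (training about a minute, full scan of ~400k expressed
sites about half a minute on one CPU); the hard-negative study uses 5 seeds
at 40 epochs per round; ablations use 60-kb/12-TSS fixtures. The published
hyperparameter profile (10,000 epochs, batch 4000) is available as the
`"paper"` preset but is not exercised by the tests.

## Known limitations

* The empirical-P cluster calibration of the original pipeline is replaced
  by a documented density score; absolute FDR values on real data would
  differ.
* Coverage ingestion is bedGraph-based; alignment files should be reduced to
  strand-specific per-base depth externally (e.g. `samtools depth` or
  `bedtools genomecov` per strand). No BAM reader is built in.
* The desk preset's learning rate (2e-3, momentum 0.9) is tuned for the
  small synthetic fixtures; real-scale training should start from the
  `"paper"` preset.
* Window length, filter geometry and pooling are configurable but models are
  not interoperable across architectures (checkpoints record their
  architecture and refuse mismatched inputs).
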