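# tsscan

Genome-wide annotation of transcription start sites (TSSs) from a reference
genome and strand-specific RNA-seq coverage.

CAGE-seq maps TSSs directly but exists for few tissues; RNA-seq is
everywhere, and read depth steps up sharply at an active TSS. tsscan trains
a dual-branch convolutional classifier on paired 1001-bp windows — a one-hot
DNA matrix and the matched raw per-base depth vector, both oriented in the
direction of transcription — and then slides it at stride 1 across every
expressed position of the genome. Each branch is a 64-filter width-10
convolution with ReLU and strided max pooling; the concatenated features
feed one hidden ReLU layer (dropout, keep probability 0.5) and a softmax
that returns a TSS probability per site. Sites scoring > 0.5 within 10 bp of
each other merge into clusters; a cluster's maximal-score site is the
reported TSS.

Around that core the package provides:

* **Dataset construction** — active-peak selection, ±50 bp shift
  augmentation re-drawn every epoch, negatives placed 500–1000 bp from the
  nearest same-strand peak, stratified splits.
* **Circular training** — hard-negative mining: after each round the model
  scans ±5000 bp around sampled true TSSs, sites scoring > 0.5 outside the
  ±500 bp positive region are harvested as false positives, and half of the
  negative set is replaced by them. Round 0 is bit-for-bit plain training,
  the built-in ablation.
* **Reptile meta-learning** across cell types
  (`θ ← θ + ε (W − θ)` after k inner steps on one task) with per-cell-type
  fine-tuning from 20% of each task's data.
* **Evaluation** — accuracy / recall / FPR / FDR / F1 from confusion counts,
  tolerance-based (100 bp) matching of scan predictions to true TSSs, and
  FPs-per-kilobase for the scanning regime where true negatives are
  uncountable.
* **Motif-gain extraction** — each fine-tuned convolution filter is paired
  with its meta-model counterpart, both converted to position weight
  matrices, and the difference (gain of motif information, GMI) exported in
  MEME minimal format for matching against motif databases; an
  expression-concordance filter ranks candidate transcription factors.
* **A synthetic fixture generator** — toy genome with planted promoter
  motifs, step-up strand-specific coverage, Poisson background, and decoy
  motif sites without expression — so the whole pipeline is testable
  without downloads.

## Worked example

```r
library(tsscan)

# a 200-kb toy genome with 50 planted TSSs and decoy promoter sequences
fx <- generate_fixture(synth_config(), seed = 1)
fx
#> <synth_fixture> 200,000 bp, 50 TSSs (25+/25-), 12 decoys

# circular training: 3 rounds of train -> scan -> harvest hard negatives
fit <- circular_train(fx$truth, fx$genome, fx$coverage,
                      cfg = circular_config(n_scan_tss = 30L),
                      train_cfg = train_config("desk", epochs = 60L),
                      seed = 1)
fit$history[, c("round", "fp_median_per_window", "n_replaced")]
#>   round fp_median_per_window n_replaced
#> 1     0                535.5         20
#> 2     1                125.0         20
#> 3     2                117.0          0

# scan every expressed site, cluster the score track, call TSSs
track    <- scan_genome(fit$model, fx$genome, fx$coverage, min_cov = 1)
clusters <- filter_clusters(cluster_scores(track))
cc <- scan_confusion(cluster_representatives(clusters), fx$truth)
metrics(cc)[c("recall", "fdr")]
#>     recall        fdr
#> 1.00000000 0.07407407
median(abs(attr(cc, "matched")$offset))
#> [1] 3
```

The history shows the point of circular training: the median number of
false-positive sites per ±5000 bp scan window drops several-fold once
harvested hard negatives enter the training set, and the final calls sit a
few base pairs from the planted starts. (Numbers above are from this code
under the shown seeds; per-round figures vary slightly across platforms and
seeds.)

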