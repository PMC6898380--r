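# hicreg

Predicting Hi-C contact counts between pairs of genomic bins from
one-dimensional regulatory signals.

High-resolution Hi-C contact maps exist for only a few cell lines, because
sequencing cost grows with the square of the number of genomic bins.
Chromatin marks, CTCF and cohesin occupancy, DNase I accessibility and motif
scores are cheap and widely available. `hicreg` treats the normalized
contact count `c(R1, R2)` of a pair of 5 kb bins as the response of a
random-forest regression on the 1D signals at the two bins and in the window
between them, plus genomic distance:

    c(R1, R2) ~ RF( [ s(R1) ; s(R2) ; mean s(W) ; d(R1, R2) ] )

with `s(.)` the 14-dimensional vector of per-bin aggregated,
depth-normalized signals. Three pair encodings are supported -- PAIR-CONCAT
(28 signal features), WINDOW (42) and MULTI-CELL (210, WINDOW blocks from
five cell lines) -- and models transfer across chromosomes and cell lines by
averaging the five region-held-out fold models (and, across training cell
lines, their ensemble). Because the model predicts counts rather than
labels, its output feeds the same downstream machinery as measured data,
all included here:

* distance-stratified Pearson correlation and its trapezoidal AUC summary
  (`AUC = trapz(f) / (n - 1)`, in [-1, 1]);
* a distance-stratified binomial significant-interaction caller with
  Benjamini-Hochberg correction (q < 0.05), plus CTCF
  convergent-motif-orientation and ChIA-PET-style fold-enrichment
  validation;
* directionality-index TAD detection (3-state Gaussian HMM segmentation)
  and a bidirectional best-match Jaccard TAD-similarity score;
* decision-path feature analysis: out-of-bag permutation importance,
  exact path usage counts, pairwise feature co-occurrence with rank-5 NMF
  bi-clustering and network export;
* minimal-dataset discovery by multi-task group lasso
  (`1/2 sum_c ||X_c W(:,c) - Y_c||^2 + lambda ||W||_{l1/l2}`) with greedy
  random-forest refinement;
* a synthetic-study generator (correlated signal tracks, power-law distance
  decay modulated by signals, planted domains and convergent-motif loops)
  so the whole pipeline is testable without any download.

It is aimed at regulatory-genomics researchers who want contact-map
predictions for contexts without Hi-C, and at methodologists who need a
transparent, fully testable reference implementation of this analysis stack.

## Worked example

Simulate a complete study (a 10 Mb chromosome at 5 kb: 2,000 bins, 14
signal datasets in 5 cell lines, planted domains and loops), cross-validate
a WINDOW-encoded forest, call loops and domains, and check them against the
ground truth:

```r
library(hicreg)
library(dplyr)

study <- simulate_hic_study(sim_config(), seed = 1)
counts <- study$contacts[["cellA"]]
counts
#> # Contact table: 379900 pairs at 5000 bp resolution (322787 measured)

cv <- run_cv(counts, study$signals, mode = "window", cell = "cellA",
             max_train_pairs = 20000, seed = 3)
glance(cv)
#> # A tibble: 1 x 6
#>   mode   n_folds n_pairs n_hard   auc overall_r
#> 1 window       5   64361  64361 0.371     0.845

calls <- call_significant(counts)
sig <- filter(calls, significant)
config_enrichment(classify_orientation(sig, study$motifs, 5000),
                  classify_orientation(calls, study$motifs, 5000))
#> # A tibble: 1 x 7
#>   config     q     k     m     S  fold         p
#> 1 +-        46   105   718  2785  1.70 0.0000331

tads <- segment_domains(directionality_index(counts, window_bp = 5e5),
                        seed = 1)
tad_similarity(study$truth$tads, tads)
#> [1] 0.805
```

Reading the numbers: the forest predicts held-out hard pairs (pairs sharing
no bin with any training pair) with a distance-stratified correlation AUC of
0.37 -- far above the distance-only baseline, which sits at about 0 on the
same data, because within a distance stratum distance carries no
information. Significant interactions are 1.7-fold enriched for the
convergent (+ -) CTCF motif configuration that marks true loops
(hypergeometric p = 3e-5), and domains called from the counts match the
planted domains at a bidirectional Jaccard similarity of 0.81.

`autoplot()` methods cover the correlation curve and DI profile;
`plot_contact_matrix()` and `plot_importance()` cover the rest. A thin
command-line front end is installed at `inst/cli/hicreg`
(`hicreg simulate | encode | cv | evaluate | aggregate | call-loops |
call-tads | tad-similarity`).

The methods vignette (`vignettes/hicreg-methods.Rmd`) documents the models,
the estimation and calling procedures, every tunable parameter with its
default and rationale, and what the synthetic generator does and does not
emulate.

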