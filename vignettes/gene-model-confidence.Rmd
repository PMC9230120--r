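---
title: "Scoring gene-model confidence from sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gene-model confidence from sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plant genome annotation pipelines call tens of thousands of gene models per
assembly, and a substantial fraction of ab initio calls are false positives:
fragments of transposons, spurious ORFs in repetitive sequence, or
mis-assembled loci. Conservation is the usual arbiter — a model whose protein
has homologs in other species is very likely real — but homology search
against a comprehensive database is expensive and, by definition, cannot be
the feature set of a classifier meant to flag genes *without* evidence.

`geneconf` trains a classifier to predict conservation-based confidence from
sequence alone. Genes are labelled once using precomputed homology evidence
(label 1, high confidence, if at least one non-self-taxon hit has e-value
strictly below 0.01; label 0 otherwise), then a gradient-boosted decision-tree
model learns to reproduce that label from 14 nucleotide and 41 protein
features. The fitted model scores new annotations with no database in the
loop, and Shapley attributions explain each call.

## The feature sets

**Nucleotide (14):** length (bp), chain molecular weight (Da), GC content and
GC restricted to codon positions 1–3 (%), the population standard deviation
of windowed GC skew and AT skew (window 100 bp), a GC-based melting
temperature (°C), Shannon entropy over non-overlapping codons (bits), the
DEFLATE compression ratio, the codon adaptation index, and start/stop codon
flags.

**Protein (41):** the 20 residue percentages, 9 pepstats-convention class
percentages (tiny, small, aliphatic, aromatic, nonpolar, polar, charged,
basic, acidic), length, molecular weight, isoelectric point, GRAVY,
aromaticity, the Guruprasad instability index, summed Vihinen window-9
flexibility, reduced and cystine-oxidised molar extinction at 280 nm, Ikai's
aliphatic index, the aliphatic-residue percentage, and a leading-methionine
flag.

Both sets follow a published feature recipe whose full appendix listing is
not reproduced anywhere we could consult; the named features of that work's
correlation and importance tables are all present, and the remainder
(AT-skew heterogeneity and start/stop flags on the nucleotide side;
aromaticity and the instability index on the protein side) complete the
counts with standard members of the same toolkits. The completion is a
package design decision and both extractors are column-order-stable, so a
different completion only changes feature columns, not interfaces.

Three choices deserve justification because printed correlations constrain
them:

* **Entropy is per-codon, non-overlapping (k = 3 by default).** A
  mononucleotide entropy saturates at 2 bits almost immediately and cannot
  correlate 0.83 with length; a token-richness entropy over codons grows
  with log-length and can.
* **Flexibility is the SUM of window scores, not the mean.** The windowed
  mean is essentially length-invariant; only an extensive quantity can
  correlate 0.99 with protein length. Each window of width 9 is a weighted
  mean of the Vihinen normalized-flexibility scale with symmetric weights
  (0.25, 0.4375, 0.625, 0.8125, 1, mirrored)/5.25, so a homopolymer window
  scores exactly its residue's scale value.
* **Melting temperature is the GC+salt estimate**
  `Tm = 81.5 + 0.41·GC% + 16.6·log10(0.05) − 600/N`. Nearest-neighbour
  models need stacked-pair parameters and an initiation convention that the
  recipe does not specify; the GC form is the common toolkit default and
  puts a typical 2-kb, 43 %-GC plant CDS near 80 °C, the anchor reported
  for confident genes.

Unit and degenerate-input conventions: IUPAC ambiguity codes are accepted,
excluded from every compositional numerator *and* denominator, and counted
in length; `X` in proteins likewise contributes to length only; a trailing
`*` is stripped; a CDS length not divisible by 3 keeps the record, drops the
trailing partial codon from codon-based features, and warns; a skew window
with zero denominator scores 0 so vectors stay complete; the final partial
skew window is kept when at least half a window long, else merged into its
neighbour. The CAI reference defaults to codon usage computed from the data
itself (`"auto"`), with a 0.5 pseudo-count on unobserved sense codons so
relative adaptiveness stays positive. The compression ratio uses zlib
DEFLATE at its default level (6), fixed for reproducibility.

## Labeling

`assign_labels()` implements the conservation rule: one qualifying hit
suffices, comparison with the e-value threshold is strict (`<`), and
self-taxon hits are excluded by exact case-insensitive taxon match (falling
back to a case-insensitive match against the subject description when the
hit table has no taxon column). Labels are therefore monotone in the
threshold — lowering it can only demote genes — and insensitive to hit
order. We do not run the homology search; the module parses standard
12-column tabular output so the pipeline stays desk-scale and testable.

## Model and hyperparameter search

The classifier is a binary XGBoost ensemble (`binary:logistic`, histogram
tree construction, single-threaded, explicitly seeded, `base_score` 0.5), so
refits are bit-identical. Positive class is 1 = high confidence. The
held-out split is `round(0.8·n)` training rows, stratified by label via
largest-remainder allocation (per-class proportions within one row); a plain
random split is available by flag.

Hyperparameters are tuned by sequential model-based optimization over the
search space: learning_rate 0.01–1.0 (log), min_child_weight 0–10, max_depth
0–50, max_delta_step 0–20, subsample 0.01–1.0, colsample_bytree and
colsample_bylevel 0.01–1.0, reg_lambda 1e-9–1000 (log), reg_alpha 1e-9–1.0
(log), gamma 1e-9–0.5 (log), n_estimators 50–200, scale_pos_weight
1e-6–500 (log). The objective is mean inner-CV accuracy (5 stratified folds
by default; folds fixed across configurations so comparisons share noise).
The search evaluates a Latin-hypercube initial design, then fits a Gaussian
process (squared-exponential kernel on the unit-scaled space, lengthscale
0.5·√d — pairwise distances in a d-dimensional unit cube concentrate near
√(d/6), so a fixed small lengthscale would decorrelate everything and reduce
the surrogate to random search) and picks each next configuration by
expected improvement over a random candidate pool. The returned
configuration maximizes observed mean inner-CV accuracy; everything is
reproducible from one seed. The decision threshold is fixed at 0.5 and the
0.5 tie goes to class 1.

## Evaluation

`evaluate_classifier()` reports the confusion matrix, accuracy (percent),
precision/recall/F1, MCC, a trapezoid AUROC over a tie-grouped threshold
sweep (verified in the tests against the Mann–Whitney identity and against
pROC), and step-interpolated average precision. Zero-denominator ratios are
reported as 0 with a warning, and MCC's zero-factor convention is 0.
Cross-validation is stratified k-fold with the sample standard deviation
across folds. Pearson correlations use the t-transform p-value.

## Explanation

Split-gain and split-count ("F-score") importances are aggregated directly
from the tree dump so unused features appear with weight 0 and gain is the
raw total loss reduction. Shapley attributions use the exact
tree-traversal algorithm in margin (log-odds) space, where local accuracy
(base + Σφ = margin) is exact; the tests verify it per sample at 1e-4 and
check equivalence with brute-force coalition enumeration on ≤3-feature
ensembles. The beeswarm export ranks features by mean |φ| and carries
feature values and percentiles, so plotting is a thin layer.

A caution the package's own tuning experiments made concrete: with
column-subsampled ensembles, split-gain credit distributes arbitrarily among
strongly correlated features (GC content, codon-position GC, melting
temperature form such a group), so gain rankings should be read per
correlated group; mean-|φ| rankings are reported alongside for that reason.

## The synthetic corpus generator

`generate_corpus()` emulates the class contrasts reported for conserved
versus non-conserved plant gene models: per class, CDS length is log-normal
(defaults: mean 1500 bp vs 600 bp, sdlog 0.45), per-gene GC targets are
Beta-distributed (means 42.12 % vs 43.25 %, concentration 80), the first
codon is ATG with probability 0.95 vs 0.70, and an in-frame tandem repeat
(10 codons × 3 extra copies) is planted with probability 0.05 vs 0.15 —
low-confidence genes are shorter, slightly GC-richer, more often lack a
canonical start, and are repeat-enriched. Codons are sampled at the target
composition with internal stops rejected; because the rejected stop codons
are AT-rich, the sampling probability is first passed through the analytic
inverse of the non-stop conditional GC expectation so realized GC hits the
target. Proteins are the standard-genetic-code translation minus the stop.

Presets: `paper_like` (the defaults above), `separable` (exaggerated
contrasts — GC 36 % vs 50 % with concentration 150, length 1400 vs 800 bp,
start probability 0.98 vs 0.30, repeat rate 0.02 vs 0.30 — designed so the
planted GC effect dominates and end-to-end recovery is expected), and
`null` (identical class distributions; any AUC off 0.5 is overfitting).

What the generator does **not** emulate: intron structure and splice
variants, transposon-derived pseudo-genes with residual coding signal,
codon-usage bias tied to expression, assembly errors, and the long-tailed
length distribution of real fragmentary annotations. Passing the
planted-signal tests therefore shows the pipeline recovers known structure
under controlled conditions; it does not certify accuracy figures on any
real annotation, which depend on the label quality and feature distributions
of that genome.

## Problem sizes and numerical tolerances in the test suite

The suite checks every feature against independently coded brute-force
oracles on 100 random sequences per table (1e-6; isoelectric point 1e-3
against a fine-grid scan, matching the bisection tolerance), exercises
end-to-end recovery on a 4000-gene separable corpus with a 25-iteration
search (5 inner folds), chance behaviour on a 2000-gene null corpus, and the
three correlation twins (length–MW, GC–Tm, length–flexibility) on
1000-sequence corpora — sizes chosen so the whole suite runs in a couple of
minutes on one CPU while keeping Monte-Carlo noise far from the asserted
margins. Bisection for pI runs to |charge| < 1e-4 or 60 iterations; the GP
adds 1e-4 observation noise plus 1e-8 jitter to its kernel diagonal.

## Known limitations

* Labels inherit every bias of the homology evidence: database composition,
  taxon coverage, and e-value calibration. "Low confidence" means "no
  qualifying hit", not "wrong".
* Only ATG counts as a start; genuine non-AUG initiation is scored as
  missing, which the discussion of the underlying recipe itself flags as a
  limitation.
* The 14/41 feature completions are reconstructions (see above) and
  swappable; models are only comparable when built from the same feature
  set version.
* Gain importances are unstable under feature collinearity; prefer the
  Shapley ranking when features are correlated.
* The tuning objective is plain accuracy; with severely imbalanced labels a
  cost-sensitive objective would be more appropriate than relying on
  `scale_pos_weight` alone.
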