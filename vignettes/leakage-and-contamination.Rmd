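---
title: "How host contamination and supervised normalization fabricate microbial signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How host contamination and supervised normalization fabricate microbial signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large tumor-sequencing cohorts are overwhelmingly human: a typical
whole-genome sample contains billions of human reads and, at best, a few
thousand genuinely microbial ones. Claims that every cancer type carries a
distinctive microbiome rest on two fragile steps: (i) classifying the reads
that fail to align to a human reference against a microbial genome
database, and (ii) normalizing the resulting genus-level count matrix
before training per-cancer-type classifiers. This package implements
diagnostics for the two ways those steps can fabricate a signal out of
nothing:

1. **Database contamination.** Draft microbial genome assemblies often
   contain mislabeled human contigs. Residual human reads (first-pass
   alignment never removes them all) then match those contigs exactly, and
   an exact k-mer classifier reports them as bacterial. The read counts
   this produces are determined by the database, not by any microbe in the
   sample.
2. **Normalization leakage.** A supervised normalization that retains the
   class label as a "biological" variable while removing technical
   covariates can imprint class-dependent constants onto features - even
   features whose raw counts are zero in every sample. Downstream
   classifiers then rediscover the label that normalization hid in the
   features, with near-perfect accuracy and no biology whatsoever.

Everything here runs at desk scale on synthetic data. The package's aim is
to make both mechanisms reproducible, measurable, and testable - not to
re-estimate the original cohort quantities, which require terabytes of
controlled-access reads.

## The count simulator

`simulate_counts()` draws a sample x genus matrix of negative-binomial
counts with log-linear class and batch effects:

* Genus baselines are log-normal around `baseline_log_mean` (default
  `log(10)`), with negative-binomial size `dispersion` (default 0.5, i.e.
  strongly overdispersed, as genus-level metagenomic counts are).
* A fraction `zero_genus_fraction` (default 0.4) of genera is all-zero,
  and a fraction `rare_genus_fraction` is present in only a handful of
  samples (expected prevalence `rare_max_prevalence / 2`). Together with
  the NB zeros this puts the default matrix near 55-60% zero entries, the
  sparsity regime of real genus-level matrices.
* Per-sample sequencing depth (`library_size` in the metadata) is
  log-normal with per-class offsets equally spaced over
  `library_size_class_spread` natural-log units (default 2, about a
  7-fold depth range across classes). This is the controllable confound:
  real multi-center cohorts are sequenced at systematically different
  depths per disease type, and it is exactly this association that a
  leak-prone normalization converts into a label imprint.
  `batch_class_confounding` analogously ties batch membership to class;
  at its extreme (1 with `n_batches == n_classes`) class and batch are
  collinear and the normalizer correctly refuses to fit.

The defaults (500 samples in 5 classes, 150 genera, 40% all-zero genera,
`rare_genus_fraction = 0`) are the package's reference conditions for the
leakage audit. Rare genera are excluded from the reference audit
deliberately; see *Limitations* below.

What the simulator does **not** model: realistic taxonomic abundance
profiles, read-level noise, compositionality constraints, or correlated
genera. A passing audit therefore shows that the *mechanism* behaves as
analyzed, not that any particular real dataset is clean or dirty.

## The voom transform and the SNM-style adjustment

`voom_transform()` computes

$$v_{ij} = \log_2\!\frac{(c_{ij} + 0.5)}{(L_i + 1)} \times 10^6,$$

with library size $L_i$ either the row sum or, as in the reference
pipeline, the sample's total sequencing depth. Precision weights come from
a lowess fit of the square-root residual SD against the mean log-count
(span 0.5); they are computed for completeness but deliberately unused
downstream, because the audit's point is what classifiers see in the
*values*.

`snm_normalize()` fits, per genus, a linear model with "biological" terms
(retained) and "adjustment" terms (removed). The two modes differ in one
line of algebra:

* **Supervised** (leak-prone): biological terms - including the class
  label - are fitted *first*; the adjustment model is fitted to the
  residuals, and only the (centred) adjustment fit is subtracted. Any
  variation that class and the adjustment covariates could both explain is
  credited to class and retained. For an all-zero genus,
  $v_{ij} = \text{const} - \log_2(L_i + 1)$ exactly, so per-class depth
  differences come out as class-dependent constants with small
  within-class spread: a fabricated signature.
* **Blind**: the class label is banned from the model; the adjustment fit
  is applied directly. Because the all-zero genus's values lie exactly in
  the span of the `log_lib` covariate, the removal is exact and the
  output column is constant to machine precision.

This implementation is a designed, controllable leak - the original
failure was never published in enough detail to reconstruct forensically,
and the package makes no claim to reproduce its exact numbers. What it
reproduces is the phenomenology: bit-identical duplicated values,
single-threshold rules that separate a class almost perfectly, and
near-perfect one-vs-rest classifiers on raw-zero features.

Degenerate cases are pinned down: a constant genus column skips the fit
and passes through unchanged; a rank-deficient combined design is an error
naming the confounded terms; blind mode with no adjustment variables is
the exact identity.

## The audit

`extract_empty_submatrix()` retains genera present in fewer than 50
samples (strict inequality on `count > 0`), then samples with zero counts
in every retained genus. The footprint is all-zero by construction and
maximal. `populate_from_normalized()` fills it from a normalized matrix,
and `one_vs_all_audit()` trains one-vs-rest gradient-boosted trees (200
rounds, depth 3, learning rate 0.1 - a documented stand-in; a ridge
logistic backend is available and reaches the same conclusion) under
stratified 5-fold cross-validation, reporting out-of-fold AUROC and
sensitivity/specificity/PPV/NPV at probability 0.5.

Numerical choices that matter:

* Feature columns whose SD is below `1e-8 * (1 + |mean|)` are treated as
  constant. Blind-mode columns of all-zero genera are analytically
  constant; what floating-point residue remains is rounding noise, and
  letting a scale-free tree learner split on it would manufacture signal
  out of arithmetic. If no informative column remains the class is
  reported at AUROC 0.5 and flagged `"no signal"`.
* `value_multiplicity()` groups by exact float equality, no tolerance:
  the leak manifests as bit-identical values, and any tolerance would
  blur that diagnostic.
* `leakage_score()` is the best one-vs-rest single-threshold balanced
  accuracy over raw-zero samples, in [0.5, 1].

Under the reference conditions the supervised arm yields a median
out-of-fold AUROC of about 0.94 and the blind arm sits at 0.5 - the
package's reproduction of the "highly accurate classifiers on
information-free data" result and its control.

## The k-mer classifier and the contamination experiment

`build_kmer_db()` maps every canonical 31-mer (lexicographic minimum of
k-mer and reverse complement) to the LCA of the taxa containing it;
windows containing N are skipped; genomes shorter than k are skipped with
a warning. `classify_read()` scores each root-to-leaf path by its summed
hits and assigns the deepest node of the maximal path, breaking ties by
the LCA of the tied paths' deepest nodes (a documented choice - the
original algorithm's tie-break is unspecified; this rule reduces to the
sensible answers: hits on one leaf give that leaf, equal hits on two
siblings give their parent, root-only hits give the root). Distinct-k-mer
tallies are exact hash-set counts - at toy scale nothing justifies a
probabilistic cardinality sketch.

The reference experiment (`contam_demo()`) uses a 100 kb host, five 50 kb
bacteria of which three carry one verbatim 500 bp host contig, and 50,000
error-free 67 bp host reads (67 bp matching the short-read cohort the
demonstration mirrors). Without the host in the database, reads
overlapping a contig by at least 31 bp are falsely assigned to the
contaminated bacterium (roughly 500-800 reads at 33x coverage, exclusively
on contaminated genomes). Adding the host moves every contig k-mer to the
host/bacterium LCA (the root), so the false-positive count drops to
exactly zero and the fold decline is reported as infinite, flagged. That
is a sharper collapse than any real re-analysis would see - real reads
carry errors and individual variation, which is why published declines are
large but finite - and `fold_decline()` on the published before/after
counts reproduces those finite ratios (132.9 and 1136.8).

The contaminated fraction is 3 of 5 rather than 5 of 5 so that the claim
"false positives concentrate exclusively on contaminated genomes" is
testable against clean genomes in the same run.

## Inflation statistics

`compare_counts()` inner-joins two count matrices and, per minimum-count
threshold on the original value, tallies pairs at least 10x too high
(re-analysed zero counts as infinitely inflated) and pairs within 50% of
the re-analysed value (asymmetric by design, relative to the re-analysis;
impossible when the re-analysis found zero). `residual_human_summary()`
and `comparison_fractions()` perform the published-table arithmetic from
raw integers, with percentages rounded half-up to one decimal (two when
below 0.05, as small fractions are printed). One published prose figure
(a 2.7% initially-unmapped rate) conflicts with the corresponding table's
integers, which give 0.5%; the package computes from integers and does not
adjudicate.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds (`withr::local_seed`),
and each generator documents its stream order, so outputs are bit-stable
across runs. The test suite and the analysis scripts use the reference
sizes throughout: the 500 x 150 count matrix, the 100 kb / 5 x 50 kb
genome set with 50,000 reads, and smaller instances for the exhaustive
oracle comparisons (all matrix shapes up to 6 x 6 over counts {0, 1, 2};
k-mer databases under 1,000 entries checked against naive path
enumeration). The full leakage audit runs in a few seconds on one CPU; the
contamination experiment in well under a minute.

## Limitations

* **Rare genera and blind adjustment.** When a genus has a few non-zero
  counts, those samples perturb the blind per-genus fit, leaving residuals
  at the zero-count samples that are a small linear function of the depth
  covariate - and therefore weakly class-correlated whenever depth is
  confounded with class. A scale-free classifier can exploit even that
  remnant. This is a genuine observation about residual-based adjustment,
  not an implementation artifact, and it is why the reference audit
  isolates fully-zero genera (`rare_genus_fraction = 0`): the supervised
  vs blind comparison then measures exactly one mechanism. Rare genera
  remain first-class in the simulator and are exercised elsewhere in the
  test suite.
* The leak is a *designed* mechanism consistent with the observed
  phenomenology, not a forensic reconstruction of any published pipeline.
* The simulators are deliberately minimal: i.i.d. base composition, no
  indels or paired ends, no realistic abundance profiles. Conclusions
  transfer to real data only at the level of mechanism.
* The classifier audit's operating point (probability 0.5) and learner are
  conventions; AUROC is the primary metric precisely because it does not
  depend on them.
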