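---
title: "Signature discovery and Pareto-ensemble classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature discovery and Pareto-ensemble classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`mirpareto` implements a two-filter strategy for deriving compact miRNA
signatures of a binary tumor phenotype (recurrence or metastasis) from
miRNA-Seq counts, and a multi-objective ensemble classifier built on the
resulting signature. The chain is:

1. **Normalization.** Counts are scaled to reads per million (RPM) per
   sample; features below an expression floor (default RPM ≥ 1 in ≥ 10% of
   samples) are removed. The floor is a conventional noise filter; results
   are insensitive to it for well-expressed features.
2. **Differential expression (DE).** Each feature is tested for a location
   shift between conditions on `log2(RPM + 1)` with a two-sided
   Mann–Whitney U test (Welch's t is available as a config option), and
   p-values are Benjamini–Hochberg adjusted. A strict adjusted-p cutoff of
   0.05 is the default.
3. **Differential co-expression (DC).** Within each condition, pairwise
   Spearman correlations between features are computed. Feature *i*'s
   connectivity shift is `sum_j |z(rho_pos(i,j)) - z(rho_neg(i,j))|` with
   `z = atanh` (Fisher transform, clipped at |rho| ≤ 0.999). Significance
   comes from a label-permutation null: condition labels are shuffled
   (group sizes preserved, one shared shuffle per permutation across all
   features so the feature dependence structure is kept), the add-one
   p-value `(1 + #{permuted ≥ observed}) / (n_perm + 1)` is BH-adjusted,
   and features with adjusted p < 0.05 are called *altered*. Thresholded
   co-expression networks (default |rho| ≥ 0.6 with BH-adjusted edge
   p < 0.05) are also built per condition for reporting.
4. **Signature.** The signature is the intersection of the DE-significant
   and DC-altered sets, sorted by feature id for determinism.
5. **mRNA integration.** Putative targets are genes whose Spearman
   correlation with a signature miRNA is below −0.25 across shared
   samples; the top-k most negative genes are reported and two signatures'
   kept gene sets can be intersected into a common-target set. Sequence-
   based target prediction is out of scope; a user-supplied miRNA→gene map
   can restrict the pairs instead.
6. **Classification.** Signature miRNA `log2(RPM + 1)` values (optionally
   with encoded clinical covariates) are z-scored using training-split
   statistics only and fed to an NSGA-II-style genetic search over the
   joint space of feature subsets, classifier family (RBF-kernel SVM or
   random forest) and hyperparameter grid indices, under three objectives:
   maximize stratified 5-fold CV accuracy, minimize the number of selected
   features, minimize model complexity. All non-dominated solutions (the
   Pareto front of an elitist archive of every evaluated candidate) are
   refit on the full training split and combined by unweighted majority
   vote, ties going to the positive class. Performance is reported as
   accuracy / specificity / sensitivity for cross-validation and for an
   external test split never seen during search.

# Design choices where the design was open

**DE test statistic.** The derivation of the DE table is done with a
distribution-free Mann–Whitney test on log2 RPM rather than a
negative-binomial count model. This keeps the stage reproducible with no
model-fitting dependencies and is robust to the heavy tails of miRNA-Seq
data; a count-model GLM would gain power at small n but is not the point
of the pipeline. Welch's t on the same scale is exposed as an alternative.

**The connectivity-shift statistic.** "Altered co-expression" is
quantified by a continuous Fisher-z row-difference score with a
permutation null, rather than by differencing two hard-thresholded edge
sets. A continuous statistic is threshold-free, testable, and strictly
more informative; the thresholded networks are still produced for
inspection, so an edge-set convention can be emulated downstream if
wanted. The Fisher transform variance-stabilizes correlations so
differences are comparable across the correlation range; clipping at
0.999 keeps duplicate features finite.

**Permutation count and adaptive pruning.** The add-one estimator bounds
attainable p-values at `1/(n_perm + 1)`, so with `m` features BH at level
alpha can only flag a group of `k` features sitting at that floor when
`n_perm ≥ m / (k * alpha)`. Requiring that a *minimal two-feature module*
(the smallest set a correlation module can contain) be resolvable gives
the working rule `n_perm ≥ m / (2 * alpha)` — 3000 permutations for 300
features at alpha 0.05, which is what the reference-scale runs use (the
generic default of 1000 suits smaller feature sets). To keep this
affordable, features whose exceedance count already guarantees an
unadjusted p above alpha are adaptively dropped from further scoring;
their reported p-value comes from the permutations they did see (still a
valid permutation p-value, at coarser resolution), and the set of altered
calls is provably identical to an exhaustive run because a pruned
feature's p exceeds alpha either way and cannot alter the BH step-up
decision below the cutoff. Exhaustive scoring (`prune = FALSE`) remains
available when the full null distribution of every feature matters, e.g.
for calibration checks.

**Objective 3 (model complexity).** Complexity is `n_trees / max_trees`
for forests and the mean support-vector fraction over CV folds for SVMs.
Both lie in [0, 1], are monotone in effective model size, and are
comparable across families, which the Pareto comparison requires.

**Search defaults.** Population 60 and 40 generations with uniform
crossover, per-bit mask mutation at rate 1/n, classifier flips at 0.1 and
±1 hyperparameter grid steps at 0.2. The SVM grids (`C = 2^-5..2^15`,
`gamma = 2^-15..2^3`, exponent steps of 2) are the standard coarse grid;
forests use 50–500 trees. Because candidate evaluations are cached and the
archive is elitist, additional generations can only extend the front.

**Tie vote.** Ensemble ties predict the positive class: in a
recurrence/metastasis screening setting a false positive is cheaper than a
missed event, so the tie rule favors sensitivity.

**Accuracy as objective 1.** Plain accuracy (not balanced accuracy) is
optimized, matching how headline performance is usually reported for this
task; specificity and sensitivity are always reported alongside so class
imbalance is visible.

**Fold sharing.** One stratified fold assignment per run seed is shared by
every candidate, so objective values are comparable across the population
rather than re-randomized per candidate.

# The synthetic cohort generator

The generator exists so that every stage has a ground truth to be tested
against; it is first-class, tested code. It emulates:

* **Marginals.** Feature baseline means are log-normal (meanlog 3,
  sdlog 1.5) on the RPM scale — median ≈ 20 RPM with a heavy right tail —
  rescaled to per-sample library sizes drawn uniformly (default 0.5–2
  million reads). Counts are negative-binomial with dispersion 0.15
  (variance `mu + 0.15 mu^2`), i.e. strongly overdispersed, as in real
  miRNA-Seq.
* **Class structure.** The true condition is assigned with *exact* class
  counts (defaults 328 positive / 110 negative plus 14 unknown, mirroring
  a recurrence cohort of 452 tumors); the observed label flips the
  condition with probability `label_noise`. An earlier design sketch drew
  labels from a logistic link of signature expression; that cannot
  guarantee exact per-class counts, so the condition-first formulation was
  adopted and classifier difficulty is tuned through the effect-size range
  and `label_noise` instead.
* **Planted DE.** `n_de` features have their positive-condition mean
  multiplied by `2^lfc`, `|lfc|` uniform in `de_log2fc_range`, random
  sign.
* **Planted DC module.** Module features share a standard-normal
  per-sample latent factor added on the log2 scale in the positive
  condition only, with loading
  `lambda_i = s_i * sqrt(dc_rho / (1 - dc_rho))` where `s_i` is the
  feature's NB log2 noise sd, and a mean-preserving correction
  `-lambda_i^2 ln(2)/2`. This yields within-module correlation ≈ `dc_rho`
  in the positive condition and ≈ 0 in the negative without changing
  marginal means. One consequence worth knowing: preserving the *mean* of
  a skewed distribution lowers its *median*, so a rank-based DE test has
  some power against module features too — recovered signatures tend to
  lean towards the whole module (recall is unaffected; precision can dip
  below 1). This is a property of any mean-preserving variance
  inflation, not a bug, and is visible in the pipeline's recovery report.
* **Signature.** `signature_size` features belong to both planted sets and
  receive both effects; remaining DE and module features are disjoint.
* **mRNA coupling.** Each signature miRNA gets `n_targets_per_sig` genes
  whose latent log2 mean couples to the miRNA's realized standardized
  log2 RPM through a Gaussian copula at correlation `target_rho`
  (default −0.6), with latent sd 1.5 and a mean-preserving correction.
  Planted target genes are drawn moderately expressed (log-normal meanlog
  4, sdlog 0.8) so the coupling is observable at sequencing depth —
  mirroring the fact that detectable targets of abundant miRNAs are
  themselves quantifiable mRNAs.
* **Clinical covariates.** Sample type (metastatic/primary), AJCC T stage
  and AJCC stage are tilted towards the *observed* label by a
  proportional-odds shift at odds ratio `clinical_or` (default 3), with 5%
  missing stage codes. Generating them from the recorded outcome rather
  than the latent condition reflects that clinical staging correlates with
  the outcome itself, and gives the covariates information that the
  expression features do not carry (the label-noise flips).
* **Cohorts.** The external test set is a stratified held-out split of the
  same generative process; `test_mean_shift` (default 0) can add a log2
  cohort effect to test samples.

What it does **not** emulate: realistic miRNA nomenclature, isomiR
structure, batch effects beyond the single mean-shift knob, sample-sample
correlation (e.g. paired biopsies), or compositional coupling between the
planted effects and the rest of the library beyond what RPM normalization
itself induces. Passing tests on these cohorts therefore demonstrate that
the *procedures* behave as specified under their own assumptions, not that
any particular real-data signature is correct.

# Numerical and degeneracy conventions

* RPM requires strictly positive library totals; a zero-total sample is an
  error naming the sample.
* Pseudocount 1 on the RPM scale for both the log transform and the fold
  change keeps zeros finite; equal group means give log2FC = 0 exactly.
* Zero-variance features get correlation 0 with everything (rather than
  NA) inside the connectivity machinery, and a DE p-value of 1.
* Spearman ties are handled by average ranks throughout.
* An all-false feature mask is assigned the worst objectives (accuracy 0,
  all features, complexity 1) so the genetic search remains total; masks
  are additionally repaired to keep at least one feature.
* All randomized steps (generator, permutation null, fold assignment,
  forest fitting, genetic search) take explicit integer seeds; a pipeline
  run derives per-stage seeds from one master seed by a fixed 32-bit hash,
  and rerunning a config reproduces `summary.json` byte-identically.

# Problem sizes used by the test and acceptance suites

The reference study scale used by the acceptance checks is 300 miRNAs and
2,000 genes over 400 samples (train 240 positive / 80 negative, external
test 60 / 20 — the 3:1 imbalance of the motivating cohort), 20 planted DE
miRNAs with |log2FC| in [0.8, 2], a 10-miRNA DC module at rho 0.7, a
7-miRNA planted signature, 5% label noise and clinical odds ratio 3.
Monte-Carlo checks use 10–30 replicates; the permutation null uses 3000
permutations at this scale (the `m / (2 * alpha)` rule above, with
adaptive pruning); genetic searches in the suites
run population 16 for 8 generations, which the elitist archive makes
sufficient on a 7–10 feature space (the 60 × 40 default is intended for
larger candidate spaces). These sizes are the package's own reference
conditions and are stated here so results can be reproduced exactly.

# Known limitations

* The Mann–Whitney DE stage tests stochastic ordering, not the mean; as
  noted above it has power against mean-preserving variance inflation,
  which slightly blurs the DE/DC distinction on skewed data.
* Permutation p-values are discrete; with `n_perm` permutations nothing
  below `1/(n_perm + 1)` is attainable, which bounds how many features can
  survive BH at small `n_perm`.
* Plain k-fold CV inside the search optimistically biases the CV figures
  relative to the external test (this motivates reporting both); nested
  CV would remove the bias at substantial cost and is deliberately not
  implemented.
* The ensemble votes all front members equally, including low-accuracy
  few-feature members; this follows the "combine all non-dominated
  solutions" design and in practice costs little against the best single
  member, but it is not an optimized stacking.
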