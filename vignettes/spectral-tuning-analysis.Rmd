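---
title: "Predicting opsin spectral phenotypes from sequence: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting opsin spectral phenotypes from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specTune)
```

## The scientific problem

Visual opsins are G-protein-coupled receptors whose bound retinal
chromophore absorbs maximally at a wavelength λ_max (nm) that varies from
roughly 350 to 611 nm across animal pigments. A modest number of amino
acid positions — spectral tuning sites — account for much of that
variation, but their effects interact (intragenic epistasis), and the
mapping from sequence to phenotype is not additive in general. Given a
curated table of sequences with measured λ_max (wild types, point mutants
in `D83N`-style notation, and transmembrane-domain chimeras), this package
trains and evaluates regressors that predict λ_max from aligned sequence
alone, reports which positions matter, quantifies non-additivity against
explicit additive expectations, and benchmarks the sequence models against
phylogenetic imputation.

## The regression model

Sequences enter as rows of a fixed multiple alignment (alignment itself is
delegated to external tools such as MAFFT or MUSCLE; the package consumes
aligned FASTA). Each retained column becomes a block of indicator
features, one per residue observed at that column in training
(`"p<column>:<residue>"`). Three contracts shape the feature space:

* **Zero-entropy sites are dropped.** A column with fewer than two
  distinct non-gap residues carries no information for a regressor, so it
  contributes no features. Invariance is judged on non-gap residues: a
  column of {A, gap} is invariant.
* **The unseen-residue rule.** At prediction time, a residue that never
  occurred at that column in training encodes as all-zero across the
  block — every unseen residue, and a gap, looks the same to the model.
  This makes prediction total (no errors on novel sequences) at the cost
  of treating all novelty identically. A flag to encode the gap as a 21st
  state exists for sensitivity checks but is off by default.
* **Coordinates are anchored to a reference row.** Columns map to
  bovine-rhodopsin-style numbering (consecutive positions where the
  reference is ungapped; insertion codes `"12+1"` where it is gapped) and
  carry transmembrane-domain labels from a user-supplied boundary table —
  boundaries are configuration, not hard-coded constants.

The regressor suite is a pluggable registry with fixed, documented
defaults: ridge and lasso (glmnet, penalty chosen by seeded internal
cross-validation), a Bayesian ridge fitted by evidence maximization
(implemented in the package, since no installed R package provides one),
a random forest (ranger, 300 trees), gradient-boosted trees (xgboost,
depth 6, eta 0.1, 300 rounds), and boosted depth-1 stumps (an
AdaBoost-style additive learner). Suites are ranked by mean R² over one
seeded k-fold partition (default k = 10) shared by all estimators; ties
break by lower MAE, then name. Five metrics are reported: R², MAE (nm),
MAPE (%, true value in the denominator — safe because λ_max ≥ 350 nm),
MSE (nm²), RMSE (nm).

Position importance sums per-feature importances within each column block
(absolute standardized coefficients for linear families, impurity
importance for the forest, gain for the boosted trees — the metric used is
recorded in the report), scales each model so its top column is exactly 1,
and averages the top three CV-ranked models into a "mean relative
importance" per position.

## Dataset-level protocols

* **Iterative hold-out.** Target records are shuffled once with the seed
  and partitioned into groups (default 25); each group is predicted by a
  model trained on everything else, so every record receives exactly one
  out-of-training prediction. Withheld records are excluded from training
  entirely. Residuals above 10 nm in magnitude (strict inequality) are
  flagged as outliers; breakdowns are reported per record type (wild
  type, single mutant, multimutant, chimera).
* **Learning curves.** Nested training subsets grow by a step of 15–50
  records per increment, three repetitions by default; performance at
  each size is cross-validated R² (we chose CV rather than a fixed test
  set, and document that choice here). Six nonlinear forms are fitted to
  the (size, R²) points by least squares — reciprocal y = a + b/x,
  exponential rise, logarithmic, power, saturating, quadratic — and
  ranked by AIC = n·ln(RSS/n) + 2k (constants common to all models
  dropped; ties broken by fewer parameters). The candidate set is our
  choice, constrained to include the reciprocal form that describes
  performance plateauing with dataset size.
* **Epistasis.** A multimutant is *decomposable* when its wild type and
  every component single mutant (same parent accession — cross-background
  singles are not accepted) are measured. Its additive expectation is
  EAMV = λ_wt + Σᵢ(λ_single,i − λ_wt); a deviation strictly greater than
  1 nm (raw values, not rounded) marks it epistatic. The
  leave-epistatic-out experiment removes all epistatic multimutants from
  training (singles retained) and compares three predictors of their
  phenotypes — the reduced model, a wild-type-only model, and the EAMV
  baseline — pairing squared errors per multimutant for a Wilcoxon
  signed-rank test. The test drops zero differences (the classic
  treatment), uses midranks for ties, enumerates all 2ⁿ sign patterns
  exactly up to n = 25 (configurable), and a tie-corrected normal
  approximation with continuity correction beyond; Bonferroni adjustment
  is min(1, m·p).
* **Phylogenetic imputation.** Brownian-motion tip imputation in its
  standard conditional-normal form: tip covariance C from shared
  root-to-tip path lengths, GLS root estimate
  μ̂ = (1ᵀC_oo⁻¹y)/(1ᵀC_oo⁻¹1), ML rate σ̂², imputed mean
  μ̂ + C_mo C_oo⁻¹(y − μ̂1), conditional variance
  σ̂²(C_mm − C_mo C_oo⁻¹ C_om). Near-singular observed covariance
  (duplicate zero-length tips) receives a diagonal ridge of 1e-8 of tree
  height, with a warning — short branches are a known practical fragility
  of imputation, and the mitigation is explicit. σ̂² is ML rather than
  REML; conditional means do not depend on that choice, variances do.
  Tree inference is external; the package consumes Newick.

## The synthetic generator

`generateStudy()` produces the statistical structure the analysis assumes,
with full ground truth: a Yule tree rescaled to unit height; sequences
evolved by a uniform 20-state substitution process (no indels, so rows are
exactly aligned); a truth model λ = λ₀ + Σδ(site, residue) + Σγ(pair) +
BM + N(0, σ_e²) clamped to 350–611 nm; and mutants spawned from wild-type
parents with notation written by the package's own diff.

Default scales — 200 tips, 300 residues, 5 tuning sites with |δ| between
5 and 25 nm, 2 interacting pairs with |γ| between 5 and 20 nm, σ_e = 3 nm,
baseline 500 nm — echo the spread and error magnitudes of curated opsin
data. Choices a user should know about:

* **Tuning sites evolve faster** (background rate 0.1 per site per unit
  height; designated tuning-site candidates at 15×). Real spectral tuning
  sites are among the most convergently variable opsin positions; the
  elevated rate reproduces that homoplasy, and it is also what makes
  planted effects statistically identifiable — at a uniform slow rate, a
  causal column and the clade-marker columns that mutated on the same
  branch are perfectly collinear, and no regressor could (or should)
  separate them.
* **Effects sit on learnable residues.** At each tuning site, every
  non-consensus residue carried by at least 10% of tips receives its own
  shift; rarer residues carry none, like the consensus. Planting a
  distinct effect on a singleton residue would create phenotype variance
  no held-out evaluation could ever predict.
* **Interacting pairs need co-occurrence.** Pairs are chosen so both
  residues co-occur in at least 15 wild-type tips (with a fall-back to
  the best-supported pair), so interactions remain visible in wild-type
  data after every epistatic multimutant is removed — the premise of the
  leave-epistatic-out experiment.
* **Mutants inherit the parent's background.** A spawned mutant's
  phenotype is computed noiselessly as the parent's λ plus the
  deterministic truth-model difference: laboratory mutagenesis does not
  re-draw phylogenetic history or measurement noise. Multi-edit mutants
  are emitted together with their component singles (as mutagenesis
  studies characterize them), half of the doubles deliberately targeting
  an interacting pair — mirroring how double mutants are constructed at
  suspected interacting sites.
* **The clamp must not engage.** Under default scales the 350–611 nm
  clamp never triggers; the generator stops if it does, so planted
  algebra stays exact.

What the generator does *not* emulate: indels and alignment uncertainty
(rows are exactly aligned by construction, so passing tests say nothing
about aligner-induced error); realistic amino-acid exchangeabilities
(substitutions are uniform over 19 alternatives); taxonomic sampling bias;
and correlated measurement error between records from one study. Passing
recovery tests therefore demonstrate that the machinery is correct under
its own assumptions, not that real opsin datasets meet them.

One visible consequence: in synthetic studies the entropy-vs-importance
regression returns a moderate positive R², because the generator places
effects on deliberately variable (fast-evolving) sites. In real data,
where most variable sites are neutral, that correlation is expected to be
far weaker; the regression is provided exactly to make such comparisons.

## Numerical choices and degenerate inputs

* All randomness flows from explicit integer seeds; the same call with the
  same seed reproduces folds, hold-out groups, trees, sequences and fits
  exactly (tree learners run single-threaded).
* R² is undefined for fewer than two observations or zero-variance truth:
  the metric is NA with a warning, other metrics still returned.
* Duplicate sequences with λ_max spread ≤ 3 nm (configurable) collapse to
  their mean; a wider spread is a loud curation error, never a silent
  average. Whether curated datasets count uniqueness by sequence alone or
  by (sequence, phenotype) pairs is ambiguous; the tolerance encodes our
  policy.
* Notation positions are 1-based in the ungapped native parent by
  default; a reference-frame flag plus the position map supports
  bovine-numbered notation. Two edits at one position are rejected as
  ambiguous. Applying an edit whose stated wild-type residue mismatches
  the sequence is an error — the guard that catches coordinate-frame
  mistakes.
* Nonlinear curve fits use Levenberg–Marquardt with multiple documented
  starts; linear-in-parameters candidates use ordinary least squares. A
  candidate that fails to converge is flagged and the rest are returned.
* The gap-fraction trimmer is deliberately simple (a threshold on the
  per-column gap fraction) and is documented as not equivalent to
  conservation-aware block filters.
* New-sequence projection uses global pairwise alignment to the reference
  row (BLOSUM62, affine gaps, penalties configurable); residues aligning
  to reference insertions are dropped, since the training alignment has
  no columns for them.

## Known limitations

Random-sample cross-validation over phylogenetically related sequences
flatters R², because relatives of training records are easy to predict;
block (clade-wise) cross-validation is the acknowledged alternative and is
not implemented here. The estimator registry ships one gradient-boosted
implementation (plus a stump variant) rather than several. Chimera
notation in the wild varies by curator; `ChimeraSpec` is a functional
reconstruction (parent, donor, domain set, boundary table), not a format
clone. Importance scores are attribution, not causal effect sizes: under
strong collinearity they spread across correlated columns, which is why
the synthetic benchmark controls collinearity explicitly.
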