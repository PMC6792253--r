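---
title: "Methods: phenotype-driven variant prioritization with imbalance-aware classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-driven variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`varprior` ranks a rare-disease proband's filtered variants by the
probability that a clinical analyst would report them. This vignette is the
package's account of the underlying methods: the models and their
assumptions, the parameters that matter, the numerical conventions, what
the synthetic-cohort generator does and does not emulate, and the design
choices made where the design was genuinely open.

## Phenotype-to-gene scoring

Both phenotype scores operate on a directed acyclic ontology of phenotype
terms linked by `is_a` edges, plus curated gene-to-term annotations.

**Binary-vector cosine.** Patient and gene are both represented as binary
vectors over the P non-root terms, with bits set on the *ancestor closure*
of their term sets: annotating "focal seizure" implies "seizure" implies
"neurological abnormality", so matches at any shared level of generality
count. The score is the cosine of the angle between the two vectors.
Conventions:

- The root is excluded from closures and vectors. Every closed set would
  contain it, so it contributes a constant dimension that inflates all
  similarities and makes orthogonality impossible; it carries no phenotype
  information.
- Gene vectors get the same ancestor closure as patient vectors; the
  similarity is symmetric in its two arguments and there is no reason to
  close one side only.
- A zero vector (patient or gene without usable terms) has cosine 0 with
  everything: no information, no similarity.
- Obsolete ontology terms are dropped at parse time; `replaced_by` chains
  are not followed. Annotation rows citing unknown terms are skipped with a
  warning by default (`strict = TRUE` raises instead), because
  gene-annotation releases routinely lag ontology releases.
- Multiple roots are permitted; all roots are excluded from vectors and P
  counts the remaining terms.

**Random walk with restart.** The cosine score sees only curated
annotations. The walk-based score diffuses over the joint graph — term-term
`is_a` edges plus gene-term annotation edges, all undirected — so a gene
can score well via graph proximity even without a directly shared term.
The walker iterates `p <- (1 - r) W p + r p0` with column-stochastic `W`
until the L1 change falls below tolerance; gene nodes' stationary mass is
the score. Parameters, with defaults:

- `restart_prob` (r) = 0.1. Small r lets mass diffuse several hops —
  appropriate when the ontology is the main conduit between patient terms
  and genes; r is exposed because the literature uses anything from 0.1 to
  0.7, and r = 1 degenerates to the restart vector itself.
- `gene_edge_weight` = 1.0: gene-term edges count the same as ontology
  edges. There is no principled reason to privilege either without
  validation data, so the weight is configuration.
- Restart mass is uniform over the patient's *closed* term set (a flag
  restricts it to the directly given terms), mirroring the cosine
  treatment of ancestral terms.
- Convergence: L1 tolerance 1e-10, `max_iter` 1000. With r = 0.1 the
  iteration contracts at factor 0.9, so ~220 iterations reach 1e-10;
  non-convergence warns and returns the best iterate rather than failing a
  whole cohort for one pathological case.
- Isolated nodes get a self-loop so `W` stays column-stochastic; the
  stationary vector sums to 1, which is asserted in tests as a mass
  -conservation check.

Each variant inherits the **maximum** score over its overlapping genes
(a variant spanning two genes is as interesting as its most interesting
gene); variants with no gene links, or genes absent from the score table,
get the floor score 0.

## Clinical filtering

The six-criterion screen reduces called variants to the reviewable set:
minimum total read depth, minimum alternate-allele depth, maximum
population allele frequency, at least one predicted transcript effect, at
least one gene–disease association, and absence from a blacklist of known
sequencing false positives. Conventions:

- Missing depths fail the depth criteria (conservative: unknown evidence
  is not sufficient evidence). A missing population frequency is the
  opposite case — absence from the population database means the allele is
  rare — and is treated as frequency 0.0, passing the criterion.
- Variants without gene links fail the gene–disease-association criterion.
- Defaults (total depth ≥ 8, alt depth ≥ 4, frequency ≤ 0.01) are
  placeholders for a site's clinically validated thresholds; everything is
  configurable via YAML, and no test depends on the defaults.
- The filter logs a per-criterion rejection tally (first failing criterion
  in a fixed order), is idempotent, and is monotone: relaxing a threshold
  never removes a previously passing variant.

## Feature encoding and selection

Raw annotations come in three shapes and become 95 numeric columns under
the reference spec set:

- *numeric_single*: copied through; missing values take the spec's default.
  Defaults sit **outside** the declared expected range on the
  **less-impactful** side (a missing conservation score defaults below the
  observable range — "not known to be conserved"), validated at spec
  construction. Allele-frequency features are the exception: absence means
  frequency 0.
- *numeric_multi* (one value per transcript, say): reduced to the worst
  value, `min` or `max` per the spec's `worst_direction`.
- *categorical, multi-label*: bin-count encoded — one count column per
  vocabulary label plus an `_other` bucket that absorbs dialect drift.
  Counts matter because e.g. five submitters calling a variant pathogenic
  is stronger evidence than one.

The shipped 95-column reference set names the annotations a clinical
analyst actually works from (phenotype scores, scaled CADD, phyloP /
phastCons / GERP conservation, HGMD assessment and confidence bins, gnomAD
frequencies and counts, ClinVar classification bins, splice predictors,
protein-effect predictor bins, transcript-effect categories) padded with
generic numeric slots, because a real annotation stack's full inventory is
site-specific; the spec file is YAML and fully replaceable.

Univariate screening keeps the top 20 of the 95 columns by the one-way
ANOVA F statistic of each column split by the binary label, computed on
**training rows only** and then applied unchanged to the test set. The F
statistic is the natural default for continuous-ish features screened
against a binary label (for two groups it is the squared t statistic); a
chi-square alternative is provided for non-negative count columns. Ties
break by column order, making selection deterministic.

## Classifiers and tuning

All four families must cope with roughly 1 reported variant per 200+
unreported. Their contracts:

- `weighted_forest`: random forest whose training rows are weighted
  inversely to class frequency (weighted bootstrap per tree).
- `weighted_logistic`: L2-penalized logistic regression with the same
  class weights; `reg_strength` is inverse regularization.
- `balanced_forest`: each tree trains on a class-balanced bootstrap that
  under-samples the majority class.
- `undersampled_boost_ensemble`: an ensemble of discrete AdaBoost learners
  (shallow decision-tree base learners), each trained on an independent
  balanced under-sample; member probabilities are averaged.

Tuning is stratified 10-fold cross-validation over a hyperparameter
lattice, recording balanced accuracy (mean of sensitivity and specificity;
chance level 0.5 regardless of imbalance) and F1 of the reported class at
the 0.5 probability threshold. The winning configuration maximizes **mean
F1** — under heavy imbalance, accuracy-like criteria are dominated by the
majority class, while F1 tracks the minority class the ranking cares
about. Ties go to the earlier lattice point; folds are assigned from a
stated seed, stratified on the label only.

Two depth-related defaults deserve a note. Fully grown class-weighted
forests memorize the duplicated minority rows of their weighted bootstraps:
training sensitivity is perfect while held-out sensitivity at the 0.5
threshold collapses to zero, so the class weighting never reaches
predictions. The weighted forest therefore defaults to `max_depth = 4`
(the balanced forest, whose per-tree samples are small and balanced, keeps
`max_depth = 8`); the tuning lattice still offers 4 / 8 / unlimited. The
same reasoning gives the boosting base learners depth 1 (stumps).

`run_end_to_end()` defaults to a one-point grid per family (each family's
defaults) so a complete run of the default-sized cohort finishes in a few
minutes on one CPU; the full lattice ships as `inst/extdata/grids.yaml`
and drops in via the `grids` argument when a real tuning pass is wanted.

## Train/test splitting

Cases are split as whole probands — variants of one case never straddle
the boundary, because within-case variants share phenotype context. Walking
cases in chronological order of analysis, each is assigned greedily to the
side currently holding fewer reported variants (ties alternate). This
yields near-equal positive totals and near-equal early/late proportions,
so drift in annotation databases and analyst practice is shared by both
sides. The greedy rule is one concrete realization of
"balance positives under a chronological constraint"; it is deterministic
given the case order, which the cohort generator records.

## Evaluation

- **Ranking.** Within a case, variants sort by descending predicted
  probability; ties break by variant key (lexicographic), making every
  ranking a deterministic permutation of 1..n. A pessimistic mode (ties
  share the worst rank of their group) is available for sensitivity
  analysis. Reported-variant ranks pool across cases into median (even
  counts: mean of the two central order statistics), mean, and top-1/10/20
  percentages, overall and per ACMG stratum. Note a floor effect: a case
  with two reported variants cannot put both at rank 1.
- **Curves.** ROC by threshold sweep over distinct score values with
  trapezoidal area; the PR area uses the step-wise average-precision
  estimator, because trapezoidal interpolation in PR space is known to be
  optimistically biased.
- **Controls.** Two single-feature rankers (scaled CADD; phenotype cosine)
  are evaluated with exactly the same machinery — the naive orderings an
  analyst might use, and the bar any trained model must clear.
- **External score files** that rank only a subset of a case can be
  completed conservatively: unscored variants are placed immediately after
  the last scored one, in key order — an optimistic completion *for the
  external method*.

## The synthetic cohort generator

Real referral cohorts are controlled-access, so the generator is
first-class, tested code that emulates the statistical structure the
pipeline assumes:

- a random rooted ontology (each term attaches below 1–2 earlier terms)
  and genes annotated with coherent term neighborhoods (an anchor term
  plus its ancestors/descendants, topped up randomly);
- per case: a causal gene; patient terms drawn from that gene's
  annotations with **50% term dropout** and **2–10 spurious terms** added —
  calibrated so that ranking by phenotype cosine alone has a median
  reported-variant rank in the teens-to-twenties, the scale reported for
  real cohorts, rather than acting as an oracle;
- 200–400 filter-passing variants per case plus a ~15% tranche designed to
  fail exactly one filter criterion each; 1–3 planted positives per case,
  always in the causal gene and always filter-survivors;
- a VUS-heavy class mix (0.59 / 0.22 / 0.19 over VUS / LP / Path);
- planted signal confined to 20 designated encoded columns (75 columns are
  pure noise): 16 numeric features shifted by
  `signal_strength x class_weight` standard deviations (defaults 0.4 and
  0.45 / 1.0 / 1.8 for VUS / LP / Path), and 4 prior-curation categorical
  bins (HGMD DM and High-confidence, ClinVar Pathogenic and Likely
  Pathogenic) drawn with class-scaled probabilities. The categorical
  channel is what separates pathogenicity tiers in practice — pathogenic
  variants tend to have been curated before — and it is what lets the
  class gradient show up in rank medians rather than being drowned by the
  class-independent phenotype channel. Population-frequency features are
  zero-inflated (positives mostly absent from the database, negatives
  often so), and setting `signal_strength = 0` switches off every
  positive-specific mechanism, a null checked by test.
- all randomness flows from one master seed through named substreams
  (ontology / cohort / fold assignment / ...), so components are
  independently reproducible and a fixed seed yields byte-identical
  cohorts and reports.

**What passing tests do and do not show.** The generator draws features
independently within class, uses Gaussian backgrounds, has no linkage or
per-gene burden structure, no correlated annotation families (its
conservation scores are independent; real ones are strongly correlated),
no inheritance information, and phenotype noise that is independent across
cases. Synthetic cohorts are consequently *more* separable than real
patient data — the pipeline's end-to-end recovery numbers (AUROC ≈ 0.98,
median ranks 2–4, top-20 > 90% under defaults) demonstrate that the
machinery is wired correctly and recovers planted structure with the right
qualitative ordering (trained models ahead of both single-feature
baselines; pathogenic easiest, VUS hardest; AUPRC far below AUROC), not
that real-world cohorts would yield numbers of that size.

## Numerical conventions and degenerate inputs

- Cosine of any zero vector is 0; mismatched vector dimensionalities are
  errors, not broadcasts.
- The walk warns (not errors) on non-convergence; r = 1 is legal and
  returns the restart vector.
- Encoding is total by construction: no NaN/NA survives assembly, which is
  asserted rather than assumed.
- Zero-variance columns in screening get F = 0 (or +Inf when the
  between-group variance is positive and within-group is zero), keeping
  the ordering well-defined.
- Stratified CV requires at least k positives for k folds and says so.
- All rankings, reports, and fingerprints are deterministic functions of
  (data, seed); report files round floating point to fixed precision so
  byte-identity across runs is meaningful.

## Test and acceptance problem sizes

The test suite exercises oracle equivalences at enumeration-friendly sizes
(100 random ontologies up to 100 terms for the cosine oracle; 100 graphs up
to 50 nodes against the dense linear solve; AUROC vs pairwise concordance
up to 30 points), the filter on a 20-variant designed fixture plus 1000
random variants, selection recovery on a 40 000 x 95 matrix with 20
planted columns, the imbalance contract at 50 : 10 000, and end-to-end
recovery on the default cohort (237 cases, 200–400 filtered variants each).
These sizes were chosen so the full suite runs in minutes on a laptop-class
single CPU while keeping every statistical check comfortably powered.

## Known limitations

- The phenotype channel uses only `is_a` edges and unweighted annotations:
  no information-content weighting, no term frequencies, no cross-species
  evidence, no text-mined edge weights.
- The AdaBoost implementation is discrete (SAMME-style) with a logistic
  link on the additive margin for probabilities; probabilities from the
  boosted ensemble are useful for ranking but are not calibrated.
- `glmnet` fits the penalized logistic on a short lambda path ending at
  the requested penalty; coefficients at the requested lambda are obtained
  by glmnet's warm-started path, not a cold single-lambda fit.
- The classifiers predict per-variant probabilities independently; they do
  not enforce per-case constraints (e.g. "at most a few reported variants
  per case").
- Classification performance on any real cohort will differ from the
  synthetic numbers, and a model trained on one laboratory's reporting
  practice learns that laboratory's practice; per-variant probabilities
  are a review-ordering aid, not an automated reporting criterion.
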