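---
title: "Methods: two-stage CpG-site selection for age prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage CpG-site selection for age prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cpgselect)
```

## The problem and the model

Methylation beta values of many CpG sites drift with chronological age, but
not uniformly: drift is fast and regular in childhood and adolescence, and
slower and noisier late in life. A single regression over the whole lifespan
therefore underfits the young and overfits noise in the old. `cpgselect`
handles this by (1) partitioning samples into age groups with similar drift
patterns and (2) running a wrapper feature selection — a genetic algorithm
whose fitness is the cross-validated error of an actual regression model —
independently within each group.

### Stage 1: decade classes, a linear classifier, and confusion-driven merging

Ages in [0, 103] years are binned into ten decade classes
(`decade_labels()`; ages 90–103 share class 10). A classifier is fitted on a
PCA embedding of the beta matrix (60 components by default) and evaluated by
stratified 3-fold cross-validation; 3 folds rather than 5 or 10 because
thinly populated decades would otherwise vanish from training folds. Classes
the classifier confuses have similar methylation signatures and are merged.
Both fixed reference schemes — (1)(2,3)(4,5)(6,7)(8,9,10) with five groups
and (1,2)(3,4,5)(6–10) with three, inducing the intervals [0,20), [20,50),
[50,103] — and an automated `merge_by_confusion()` are provided; the default
pipeline uses the fixed three-group scheme for reproducibility. Only
*adjacent* classes may merge, so every grouping stays a tiling of the age
axis, which Stage 2 requires to be meaningful.

At prediction time, test samples are routed to a group by the classifier's
predicted label — never by their true age, which a deployed clock does not
know.

**Classifier substitution.** The linear decision function is an
L2-regularized multinomial logistic regression (`glmnet`, `alpha = 0`,
`lambda = 1e-3` at the end of a short decreasing path): no linear SVM
implementation is available in the supported dependency set, and any linear
decision function over the PCA features fills this role. The choice is
recorded in the classifier object and is a swappable component.

### Stage 2: the genetic algorithm

Within each group's training samples, sites are prefiltered to the
`filter_k = 8000` largest absolute Pearson correlations with age
(`rank_by_pearson()`; |r| rather than signed r, because hypomethylation with
age is as informative as hypermethylation; zero-variance sites get r = 0;
ties break by site id). The filter is computed per group on that group's
training samples only, since the stages after it are also per-group.

A chromosome is a binary mask over the filtered panel. Its fitness is

    fitness = MAD_cv + n_selected / 50

where `MAD_cv` is obtained by partitioning the group's samples into
`floor(n/100)` balanced random partitions, computing pooled 3-fold
out-of-fold predictions with the gradient-boosted regressor within each
partition, applying the metric formulas once per partition, and averaging
the per-partition results arithmetically. The penalty adds one unit (one
year of MAD-equivalent) per 50 selected sites, so among equally accurate
chromosomes the sparser one wins. An all-zero chromosome is assigned
`+Inf` fitness rather than raising an error, so degenerate offspring cannot
crash a run.

Operators:

* **Selection** — roulette wheel on weights `w = 1/(fitness + 1e-9)`; the
  fitness is minimized and inverse weighting is scale-free. Alternatives
  (e.g. `max − f`) would need a scale reference and are not provided.
* **Crossover** — where parents agree, both children copy the gene; where
  they differ, child 1 flips a fair coin and child 2 takes the complement.
  Consequences, asserted in the tests: agreement positions are preserved,
  `c1 XOR c2 = p1 XOR p2`, and the total number of selected sites is
  conserved across the pair.
* **Mutation** — exactly `min(k, length)` genes flip; each of the k steps
  first picks the 1-pool or the 0-pool with a fair coin, then a uniform
  not-yet-flipped position from that pool (empty pool ⇒ the other pool).
  On sparse chromosomes a uniform per-gene mutation would almost always
  flip 0→1 and inflate panels; the balanced design keeps both directions
  equally likely.
* **Elitism** — the 10 best chromosomes (ties to the lower population
  index) are copied unchanged. Offspring fill the remaining slots; with an
  odd number of slots the last pair's second child is discarded.

Termination is a fixed generation count. The per-generation best fitness is
non-increasing because elites carry their cached fitness records forward
(see "Numerical choices").

### The regressor

The evaluation model is gradient boosting with least-absolute-deviation
loss over depth-limited CART regression trees, implemented in C++
(`src/gbr.cpp`): F₀ = median(y); each stage fits a squared-error tree to
sign(y − F) on a 60% row subsample, re-values each leaf with the median
in-bag residual, and shrinks by the learning rate. Defaults
(`gbr_params()`): 300 trees, depth 4, `min_samples_split = 2`, subsample
0.6, learning rate 0.03. `alpha` and `warm_start` are accepted for
interface compatibility but are inert under LAD loss. No maintained R
implementation of gradient-boosted trees was available in the supported
dependency set, so the package carries its own; it remains a pluggable
component behind `fit_gbr()`/`predict()`.

### Map/reduce evaluation contract

`evaluate_population()` decomposes into independent (chromosome, partition)
work units; each unit derives its RNG seed from
(master seed, chromosome index, partition index), runs the per-partition
cross-validation, and the reduce step averages partials per chromosome.
Results are bit-identical at any `parallelism_degree` (degree > 1 forks the
units with `parallel::mclapply`); the serial≡parallel equivalence is an
acceptance criterion. Distributed multi-machine execution is out of scope —
the contract, not the deployment, is the testable core.

### Stepwise forward ranking

`sfs_rank()` orders the GA-selected panel: each round adds the candidate
whose inclusion most lowers the 3-fold CV MAD, provided the drop is at
least `improvement_epsilon` (default 0.01 years), then a single backward
sweep removes any included site whose removal does not raise the MAD by
more than epsilon. "Significance" is thus operationalized as a CV-MAD
improvement threshold rather than a p-value — MAD is the selection
criterion everywhere else in the framework, and no distributional
assumptions are needed. The sweep is single-pass per round, matching
classical stepwise-regression cost. CV (rather than a held-out split) was
chosen for the evaluation inside SFS for robustness at small group sizes.

## Preprocessing

`preprocess_dataset()` applies, in order: removal of fully-missing samples
and sites; per-site mean imputation; per-site min–max normalization onto
[0,1] (constant sites map to 0), preserving beta semantics — the
normalization method was an open choice; removal of outlier samples whose
mean beta sits more than 3 SD from the cohort mean-of-means (single pass,
no refitting; a no-op below 3 samples) — the outlier rule was likewise an
open choice, and this one is simple, testable, and catches constant-shift
artifacts such as failed arrays. The train fraction defaults to 2/3
(a 7:3 split is one config knob away; both conventions circulate).

In the end-to-end pipeline the imputation and normalization statistics are
fitted on the training split and applied to the test split
(`leakage_free = TRUE`, the default), so no test value can influence any
selection artifact — asserted by an acceptance criterion that perturbs all
test betas and requires identical selected panels, GA histories and
rankings. A classical "preprocess everything, then split" mode is available
(`leakage_free = FALSE`) for comparability with prior practice.

## The synthetic cohort generator

`generate_cohort()` emulates a merged blood-tissue DNAm cohort: ages
uniform on [0, 103]; planted informative sites follow a continuous
piecewise-linear function of age with one slope per regime (default
regimes 0–20, 20–50, 50–103) plus Gaussian noise whose SD belongs to the
sample's own regime, clipped to [0,1]; uninformative sites are Beta draws
around site-specific means (age-independent, with realistic spread);
missing cells uniform at random; outlier samples get a constant +0.4 shift
pre-clipping, which the preprocessing outlier rule detects. Defaults
(2079 samples, 25000 sites, 300 informative, noise SD 0.01/0.02/0.04,
slope scale 0.004/0.002/0.001 per year, 0.5% missing, 10 outliers) mirror
the scale and the young-regular/old-noisy gradient of real merged cohorts;
slope magnitudes are half-normal per site and regime with a site-wide
random sign.

What it does **not** emulate: probe chemistry, batch and platform effects,
cell-type composition, sex differences, non-uniform age distributions, and
correlated noise between sites. A green test on synthetic data therefore
establishes algorithmic correctness (recovery of planted structure,
determinism, leakage-freedom) — not clinical performance on real arrays.

## Numerical choices and tie-breaks

* Missingness is `NA` throughout; readers never coerce missing to 0.
* Correlation ranking and SFS break ties by ascending site id; elite and
  best-of-generation ties break toward the lower index; `merge_by_confusion`
  ties break toward the lower class pair. Everything is deterministic given
  the master seed, at any parallelism degree.
* Work-unit seeds derive from (master seed, chromosome index, partition
  index). Since an elite chromosome would re-enter the next generation at a
  *different* index — and could then draw different folds and a slightly
  different fitness — elites keep their cached fitness records instead of
  being re-evaluated. This makes the best-fitness trace exactly
  non-increasing, which is asserted, not just plotted.
* Partition counts use `floor(n/100)` with balanced sizes (250 samples give
  2×125, not 2×100+50), avoiding a degenerate small partition; a partition
  smaller than the fold count falls back to a single fit-and-score with a
  warning.
* GA initialization draws each gene at density 0.0125 (≈100 sites of 8000,
  penalty ≈ 2 units, comparable to the MAD scale); all-zero draws are
  redrawn. `mutation_k = 20` corresponds to a classical ~0.25% per-gene
  rate on 8000 genes. Both were open parameters.
* R² is reported as `NA` when the true ages in a scoring set have zero
  variance. RMSE equals √MSE per partition; the partition-averaged record
  averages RMSEs (like every other metric), so the identity is asserted at
  partition level only.

## Automated class merging: what recovery can and cannot mean

`merge_by_confusion()` greedily merges the adjacent pair with the highest
symmetrized confusion rate (cross-errors over the pair's total), re-
aggregating after each merge. A geometric caveat, verified empirically
during development: when informative sites drift *continuously* in age, the
feature-space distance between the two decades flanking a regime boundary
is at most `√2/2` of the larger adjacent within-regime decade distance, so
a boundary pair can never be strictly less confusable than both of its
flanking within-regime pairs. Exact boundary recovery therefore relies on
two second-order effects: per-decade confusion increasing with age (the
young-regular/old-noisy gradient), and the dilution of aggregated
cross-group rates as merged groups grow. The acceptance test uses a cohort
in the regime where those effects dominate (drift-to-noise ratios falling
from young to old); across random cohort draws at those scales the exact
{20, 50} recovery holds in roughly 60% of cases, and the frozen test cohort
recovers under all eight fold assignments tried during development (though not under every conceivable one). On real data —
as in any confusion-driven merging — the result should be read as a data
analysis aid, with the fixed schemes available when reproducibility
matters.

## Known limitations

* The GBR implementation is minimal by design (LAD loss only, no feature
  subsampling, no early stopping).
* Group boundaries are crisp; samples near 20 or 50 years are predicted by
  one group's model only, and their errors are correspondingly larger. Soft
  or fuzzy group membership is explicitly out of scope.
* No modeling of sex, tissue, batch, or cell composition; the package
  selects sites, it does not correct data.
* `read_geo_series_matrix()` parses the common single-table dialect with
  `characteristics_ch1` age annotations; multi-table or compressed exports
  must be unpacked first.
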