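---
title: "From spike trains to evolutionary landscapes: the methods behind tuningscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spike trains to evolutionary landscapes: the methods behind tuningscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuningscape)
```

# The scientific problem

Insect olfactory sensory neurons (OSNs) express tuning receptors whose odor
specificity can shift over evolutionary time. For the drosophilid
Ionotropic receptors Ir75a and Ir75b, the tuning phenotype of interest is
which linear carboxylic acid (C1 = formic through C6 = hexanoic) a neuron
responds to most strongly — for instance whether an ac2 sensillum is an
acetic acid (C2) or a butyric acid (C4) sensor. `tuningscape` implements
the full quantitative chain needed to study such shifts:

1. **spike quantification** — extracellular spike trains to odor responses
   in spikes/s, with solvent correction, max-normalization and z-scoring;
2. **tuning space** — PCA of z-scored tuning profiles, with the PC1
   projection as a one-dimensional tuning phenotype and a C2-vs-C4 cluster
   rule;
3. **phenotype parsimony** — minimum-change reconstruction of ancestral
   tuning states on a species tree;
4. **landscape & epistasis** — enumeration of the 2^n genotype hypercube
   between two receptor alleles, classification of stepwise mutational
   paths, and a bootstrap test of whether two substitutions interact
   epistatically;
5. **synthetic data** — seeded generators for every input, so each stage is
   testable against known ground truth.

# Spike-count responses

A trial is the merged spike train of all OSNs in one sensillum (coeloconic
sensilla do not admit reliable spike sorting, and the non-target neurons do
not respond to the acid panel). Odor reaches the antenna about 200 ms after
nominal valve opening, so all windows are anchored at *delivery* = onset +
`delivery_delay`. The response is

    r = 2 × (N[delivery, delivery+0.5) − N[delivery−2, delivery−1.5))

in spikes/s: the spike count in a 500 ms window at delivery minus the count
in an equal window 2 s earlier, doubled. Both windows are half-open
`[start, end)` so a spike on a shared boundary is never counted twice; the
convention is documented rather than consequential, since ties have measure
zero in real recordings. Negative responses (odor-evoked suppression) are
legitimate values and are preserved. The phrase "2 s before stimulus
delivery" is read relative to delivery (onset + delay), not onset; both the
delay and the offset are arguments of `spike_train()`.

Solvent correction subtracts, per sensillum, the response to the solvent
alone (water for the acids, paraffin oil for the diagnostic odors); the
panel's solvent map makes a mismatched subtraction a hard error. Missing
recordings — typically the electrode leaving the sensillum mid-series —
are explicit `NA`s from the moment a table is read (`"NaN"` or empty cells)
and are never treated as zeros.

Two per-sensillum transforms follow:

* `normalize_rows()` divides by the sensillum's maximal response, so
  exactly one odor per sensillum reaches 1 (ties all map to 1; rows that
  are all missing or all ≤ 0 are excluded with a warning, since a
  max-normalization by a non-positive value would be meaningless);
* `zscore_rows()` centers and scales each sensillum across odors using the
  sample (N−1) standard deviation, the default of the numerical
  environments this field uses. Missing cells are excluded from the
  moments and preserved. Zero-variance rows are an error rather than a
  silent drop, because a flat profile usually indicates a recording
  problem. z-scoring is applied per sensillum across odors (not per odor
  across sensilla): it is the per-sensillum profile shape that defines the
  tuning phenotype, and it is what makes per-species clusters comparable.

# The tuning space

PCA is run on the covariance of the z-scored profiles (no re-scaling — the
rows are already standardized). Sensilla with any missing odor are dropped
before fitting (complete-case): it is the simplest reproducible policy,
and the bundled tests verify the fractions against an explicit
eigendecomposition to 1e-8. Variance fractions are non-increasing and sum
to 1; loadings are orthonormal.

Principal components are sign-indeterminate, so PC1 is oriented such that
the C4 loading is non-negative: **a larger PC1 score always means a more
C4-tuned profile**. On panels whose main structure is a C2-vs-C4 trade-off,
PC1's C2 and C4 loadings then come out with opposite signs, and the PC1
projection `project_pc1()` — the dot product of a centered profile with the
first loading vector — is the scalar phenotype used by the landscape
analysis.

Cluster membership in the C2-vs-C4 plane is assigned by direct comparison
(`zC2 > zC4` is C2-max, the reverse C4-max, an exact tie unclassified)
rather than by a fitted clustering algorithm: the clusters of interest are
separated by a margin that makes any fitted method agree with the
comparison, and the rule is deterministic.

# Ancestral phenotype parsimony

`fitch()` implements unweighted small parsimony for an arbitrary discrete
state alphabet on a rooted tree, generalized to polytomies: at each
internal node the optimal state set is the set of states carried by the
largest number of children, the change count grows by (number of children −
that maximum), and a runner-up set (states one vote short) is kept so that
the top-down pass can produce an optimal labeling — a parent state one vote
short at a child is still optimal there, because keeping it saves the
parent–child change it would otherwise cost. The reported labeling is
deterministic: the root takes the alphabetically first optimal state and
every descendant keeps its parent's state whenever optimal. Equal change
costs between all states are assumed throughout, and branch lengths are
ignored.

The change count is invariant under re-rooting and is verified in the test
suite against exhaustive enumeration of all internal labelings on random
trees (≤ 8 tips, up to 3 states, with and without polytomies) and against
an independent phylogenetics library. On the bundled ten-species
drosophilid fixture (`fixture_tree()`), with C2-sensor states for the
melanogaster/obscura-group species and C4 for *D. sechellia*,
*D. willistoni*, *D. mojavensis* and *D. virilis*, the reconstruction needs
exactly two switches: C4→C2 on the branch into the melanogaster/obscura
ancestor and C2→C4 on the *D. sechellia* branch — the ancestral receptor
is inferred to have been a C4 sensor.

# The genotype hypercube and epistasis

Between two alleles differing at n sites there are 2^n genotypes and n!
monotone stepwise paths. `enumerate_genotypes()` refuses n > 20 (quoting
the scale of the refusal — at the 114 sites separating two deeply diverged
receptors this is ~2×10^34 variants); `enumerate_paths()` refuses n > 8.

Each hypercube edge (one added mutation) is tested with the pipeline's
standard two-sample rule: Shapiro–Wilk on both samples at 0.05; if both
pass, a Welch t-test, otherwise a two-sided Wilcoxon rank-sum test (Welch
because group sizes and variances differ routinely; rank-sum rather than
signed-rank because sensilla are independent units, not pairs). A step is
drawn *solid* — interpretable as selectively accessible under a
phenotype-increase reading — only when its Bonferroni-corrected p-value is
below α *and* the mean PC1 increases; a significant decrease stays dashed.
Tests are two-sided with the direction checked separately, so "significant
increase" does not get the benefit of a one-sided p-value.

The epistasis test asks whether a combined genotype deviates from
additivity. With initial genotype mean m₀, the per-sensillum *effects* of
the two constituents are their phenotype values minus m₀; `n_boot = 1000`
uniform random pairs of effects (with replacement, seeded) are summed and
re-anchored at m₀ to form the expected distribution under additivity,
which is compared to the combined genotype's observed values with a
two-sided Wilcoxon rank-sum test. After Bonferroni correction, p < 0.05
calls the pair epistatic, with the sign read from the difference of means
(negative when the double mutant falls short of the additive expectation).
Re-anchoring at m₀ puts expected and observed values on the same scale;
comparing raw effect-sums to raw responses would confound the test with
the initial mean. For triple-mutant contexts the same recipe runs with a
single and a disjoint double as the two constituents, both relative to m₀.
`run_landscape()` performs every single-with-single and single-with-double
test plus all edge tests, and by default uses the total number of
comparisons in the run as the Bonferroni family — the most conservative
reading of "corrected for multiple comparisons"; a `family_size` argument
exposes other policies.

## Calibration of the bootstrap test

The package measures, rather than assumes, the operating characteristics
of this test (`scripts/acceptance.R` recomputes both numbers on every
run). On additive synthetic panels (10 sensilla per genotype, noise SD 5
spikes/s) the test flags epistasis in roughly a quarter of datasets at the
nominal α = 0.05, and detects a programmed −30 spikes/s interaction with
power ≈ 1 and the correct negative sign. The inflation has a structural
cause: the rank-sum test treats the 1000 bootstrap sums as independent
observations, but they are resamples of only ~10 + 10 underlying effect
values and share the estimated initial mean, so the test's null variance
understates the true sampling variance of the statistic by a factor of
roughly (φ(0)²/2 · 4σ²/n) / ((1/12)(1/n + 1/n_boot)) ≈ 3.8 — independent
of the noise scale. The test is therefore *liberal*: a non-significant
result is strong evidence of additivity, while isolated positives near the
threshold should be read cautiously. The procedure is implemented exactly
as defined (it is the method under study), and this property is
documented rather than patched; a permutation or hierarchical-bootstrap
variant would be the natural remedy but would be a different method.

A second caveat: additivity is scale-dependent. Effects programmed as
additive in spikes/s are generally *not* additive after z-scoring and PC1
projection, because per-row standardization is nonlinear. Landscape-level
epistasis calls therefore describe the PC1 phenotype, not raw firing
rates; the calibration experiments above use a single-odor phenotype to
keep the additive null exact.

# The synthetic-data generators

`simulate_spike_train()` draws an inhomogeneous Poisson process: baseline
rate everywhere in the recorded span except during the 500 ms pulse
(starting 200 ms after nominal onset), where the evoked rate applies. Its
defaults (onset 3 s, span 5 s) are the smallest layout that contains both
analysis windows. Across seeds, `count_response()` on trains with 60 Hz
evoked / 20 Hz baseline averages 2×(30−10) = 40 spikes/s, which the test
suite checks to 3 SEM — the estimator is unbiased by construction, and the
simulation confirms the windows line up.

`simulate_panel()` builds per-sensillum responses for all 2^n genotypes as
baseline(odor) + Σ mutation effects + Σ pairwise interaction terms +
Gaussian noise, with an optional missing-cell mask. Noise is Gaussian, not
Poisson: panel entries model solvent-corrected *differences* of counts,
which are approximately normal; count-level realism lives in the spike
simulator. Default sizes (10 sensilla per genotype, noise SD 5 spikes/s)
match typical single-sensillum recording studies, where 5–15 sensilla per
genotype and trial-to-trial SDs of a few spikes/s are the norm. One global
seed fans out deterministically into per-genotype child seeds, so any
genotype's block can be regenerated in isolation.

What the generators deliberately do not emulate: dose–response structure
(a single concentration is assumed), correlated noise across odors within
a sensillum, day/animal batch effects, and receptor biophysics. Passing
tests therefore demonstrate that the estimators and tests behave as
specified under clean Poisson/Gaussian conditions, not that real
recordings satisfy those conditions.

The bundled `inst/extdata/ac2_species_panel_synthetic.csv` is a seeded
synthetic stand-in mimicking the layout of a deposited species response
table (ten species, C1–C6, a few `NaN` cells); it exercises the
file-to-PCA path end to end but contains no measured data.

# Numerical choices and degenerate inputs

* Half-open counting windows; ties at a row maximum all map to 1; an exact
  zC2 = zC4 tie is unclassified rather than arbitrarily assigned.
* Sample (N−1) standard deviations everywhere.
* PCA drops incomplete rows; fewer than two complete rows, or zero total
  variance, is an error.
* Wilcoxon p-values: exact for group sizes ≤ 25 (ties permitting), normal
  approximation with continuity correction otherwise; always
  approximation against the 1000-point bootstrap distribution.
* Bonferroni is `min(1, m·p)` with the family size explicit at every call.
* All randomness flows from explicit seeds (`withr::with_seed`), so no
  function disturbs the caller's RNG state.
* Problem sizes in the test suite (trees ≤ 8 tips for brute-force
  equivalence, 200-replicate calibration runs, 500-seed estimator checks)
  are chosen so the whole suite runs in seconds while leaving the binomial
  confidence intervals tight enough to be informative.

# Known limitations

* The epistasis bootstrap is liberal (see above); its p-values should be
  treated as a screening statistic.
* Complete-case PCA discards an entire sensillum for one missing odor;
  with high missingness a probabilistic PCA would retain more data, but
  is out of scope.
* Parsimony assumes equal, branch-length-free change costs; it counts
  switches, it does not date them.
* The path classification inherits the assumption that a larger PC1 value
  is the favored direction; it makes no fitness claim.
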