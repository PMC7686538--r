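---
title: "Detecting population-discriminating mitonuclear genotype combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting population-discriminating mitonuclear genotype combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mitochondrial and nuclear genomes co-operate in core metabolic pathways, and
human populations from different climates are expected to carry co-adapted
combinations of mitochondrial variants and variants in nuclear genes involved
in thermogenesis (brown-adipose-tissue metabolism, uncoupling proteins, and
related regulators). Detecting such mitonuclear combinations is statistically
awkward: even a modest gene panel yields millions of SNV pairs (the
`pair_feature_space()` table for the bundled 13-mitochondrial x 28-nuclear
cold-adaptation panel tops out above 1.1e7 pairs for a single gene pair), so
exhaustive pairwise interaction testing is hopeless at ordinary sample sizes.

This package implements a machine-learning alternative: collapse each gene —
or each gene pair — into a single per-subject *frequency score*, classify
populations with random forests on those scores, and read population
structure out of which features the classifiers need. Conventional
population-genetics baselines (LD pruning, Weir–Cockerham Fst with a
permutation null, DAPC) are included so the ML calls can be cross-checked
against standard methodology.

## The frequency score

Fix a *reference* population R. For a gene with SNVs $i = 1,\dots,M$ and
state alphabet $S_i$ (alleles $\{0,1\}$ for haploid mitochondrial sites;
genotypes $\{\text{hom-ref}, \text{het}, \text{hom-alt}\}$ for diploid
nuclear sites, with the two phased heterozygote codes merged), let
$f^{R}_i(s)$ be the frequency of state $s$ at site $i$ among the reference
subjects. Subject $x$ with states $x_i$ receives the gene score

$$ F(x) = \frac{1}{M} \sum_{i=1}^{M} \bigl(1 - f^{R}_i(x_i)\bigr), $$

the mean *rarity in the reference* of the states the subject carries: 0 when
every state is fixed in the reference, 1 when none was ever observed there.
For a gene pair, the same average runs over all $M \times K$ site pairs and
the six joint states (mt allele crossed with nuclear genotype). One subject
is thereby reduced to 13 mitochondrial scores, 28 nuclear scores, or
13 x 28 = 364 pair scores.

Two readings of the defining equation are possible; we use the state the
subject actually carries (not a fixed allele), which is the only reading
under which the score is a "distance from the reference population".
Reference subjects are scored against their own population's table
(leave-in): their scores are the population's mean state rarity, not zero,
and all subjects enter subsequent classifiers. A leave-one-out variant is
deliberately out of scope.

**Computation.** Materializing joint frequencies for every site pair is
infeasible (1.1e7 pairs for one gene pair alone). The package instead uses
an agreement-matrix identity: with $G[x,r]$ the number of sites at which
subject $x$ and reference subject $r$ carry the same state,
$\sum_i f^R_i(x_i) = \frac{1}{n_R}\sum_r G[x,r]$, and for pairs
$\sum_{ij} f^R_{ij}(x_i, y_j) = \frac{1}{n_R}\sum_r G^{mt}[x,r]\,
G^{nuc}[x,r]$. Pair scoring is therefore linear in sites, not site pairs;
a brute-force double loop is kept in the test suite as the oracle.

## Classification protocol

Binary classifiers are built per ordered population pair: the *reference*
population defines the score tables and the *target* is discriminated from
it. Swapping the roles changes the features themselves, so the accuracy
table over ordered pairs is not symmetric. The classifier is a random forest
with 500 trees and impurity (mean decrease) importances, evaluated by
stratified 10-fold cross-validation (the stratification is our choice: at
~100 subjects per class, unstratified folds can become badly unbalanced).
The R implementation is `ranger`; forests, fold splits and prediction
tie-breaks all derive from one pipeline seed, so every experiment is exactly
reproducible.

Feature selection is serial: features are ranked by full-model importance
(ties broken lexicographically), cross-validated accuracy is recomputed on
the top-$k$ set for $k = 1, \dots, K$, and the *optimal* $k$ is the smallest
one whose accuracy is within a tolerance (default 0.01, an absolute reading
of "no worse than 1%"; the relative reading is available through the
`tolerance` argument) of the curve maximum. The reported experiment accuracy
is the curve value at the optimal $k$. Note a small but systematic
consequence: under the null, "optimal accuracy" is approximately the maximum
of $K$ noisy chance-level estimates, and therefore sits a few points above
0.5 — the null-calibration tests check the per-mode mean across seeds
against the 0.5 ± 0.15 band with this bias in mind.

A feature is *specific* to a population when it appears in the optimal list
of every experiment involving that population (four experiments per
population with three populations). *Combination gains* compare the pair
model with the single-genome models per orientation: pairs recruited while a
constituent gene was not selected, and pairs carrying more (normalized)
importance than either constituent did in its own model. Because importances
are normalized within model, the raw comparison is conservative — the pair
model spreads importance over many more features; we prefer it to rank
percentiles, which mechanically favor the larger feature space (the top pair
of 364 always out-percentiles the top gene of 28), and keep the rank method
as an option.

At SNV resolution the same forest protocol runs on joint-state features
(one integer 0–5 per site pair, in the canonical six-state order) for one
nuclear gene against all mitochondrial genes, without any reference
population; the top-100 importance lists per population pair are
intersected for specificity. The categorical-as-ordinal encoding is
accepted deliberately: forests split on thresholds and recover the
categories; a one-hot encoding would triple the feature count for no
observed benefit at these scales. Running all nuclear genes at SNV level is
a non-goal (the feature space is the full table above).

## Population-genetics baselines

- **LD pruning**: sliding windows of 50 SNVs, step 10; within a window the
  later site of any pair with $r^2 > 0.1$ (squared Pearson correlation of
  dosages) is removed. Our tie-break keeps the earlier site; PLINK's
  MAF-based tie-break differs, so exact PLINK equivalence is not promised.
- **Fst**: Weir–Cockerham variance components, combined across loci as a
  ratio of sums. Diploid sites use the full a/b/c decomposition with the
  heterozygosity term; haploid (mitochondrial) sites use the haploid
  mean-squares form. (For purely homozygous data the diploid components
  reduce algebraically to the haploid form — the two branches agree there
  and diverge as soon as heterozygotes exist.) Significance comes from 200
  label permutations preserving group sizes, with the add-one empirical
  p-value $(b+1)/(n+1)$; we deliberately avoid fitting a parametric density
  to 200 permuted values, which would add a family choice without adding
  information. A gene is called specific to population P when both
  P-involving p-values fall below 0.05 and the third does not, and
  discriminant for all populations when all three do.
- **DAPC**: PCA rotation of the centered dosage matrix, keeping by default
  the smallest number of components explaining 90% of variance (capped at a
  third of the subject count), then linear discriminant analysis on the
  retained components — at most two axes for three populations. Centroid
  Euclidean distances on those axes quantify divergence. When group means
  coincide exactly (identically distributed groups) there is no
  between-group direction and all centroids are placed at the origin.

## The synthetic-data generator

Real 1000 Genomes genotypes cannot ship with the package, so every claim is
exercised on synthetic data with known structure:

- **Divergence**: Balding–Nichols — per site, each population draws its
  allele frequency from $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ around an
  ancestral $p \sim U(0.05, 0.95)$, so the per-gene parameter $F$ *is* the
  expected Fst, giving the estimator a closed-form anchor.
- **Sampling**: haploid Bernoulli alleles for mitochondrial sites; two
  independent Bernoulli alleles per nuclear site (Hardy–Weinberg within
  population), collapsed to dosage.
- **Linkage**: sites are independent by default; a per-gene `ld_copies`
  parameter replicates sites into linked blocks (with optional redraw noise)
  to exercise LD pruning and to build many coupled site pairs.
- **Interactions**: `plant_interaction()` permutes whole nuclear-gene rows
  among the subjects of one population so that the mitochondrial allele at
  one site and the nuclear genotype at another become coupled, up to the
  Fréchet maximum at `delta = 1`, while every per-site marginal count is
  *exactly* preserved (a permutation cannot change counts) and within-gene
  linkage survives. `delta` interpolates by coupling a random `delta`
  fraction of subjects; `delta = 0` is an independent shuffle. This
  construction makes "pairs beat singles" a clean test: single-genome
  features see unchanged marginals, only joint features see the coupling.
  The defaults of `sim_config()` (three populations of 100/100/97 subjects)
  echo the 297-subject three-population design the pipeline targets.

What the generator does *not* emulate: coalescent LD decay, mitochondrial
phylogeny (haplogroups), selection, missing genotypes. Passing tests
therefore demonstrate the statistical machinery under idealized
differentiation, not robustness to real-data artifacts such as batch
effects or admixture.

## Test problem sizes and numerical choices

The simulation-backed checks use: null calibration with 3 x 100 subjects,
10 genes (3 mitochondrial, 7 nuclear — echoing the panel's mt:nuc
imbalance), 20 seeds, plus 500 null repetitions of the permutation Fst
(200 permutations each) for the uniformity check; recovery with one gene at
F = 0.2 among four at F = 0.01 over 10 seeds; interaction detection with
three fully coupled gene pairs of five linked copies each (75 coupled site
pairs, ancestral frequencies 0.4–0.6 so genotype classes are balanced and
the coupling is maximally expressive) over 10 seeds per condition, with the
affected population as reference — with an uncoupled reference and balanced
marginals the per-feature score distributions of the two populations can
coincide exactly, an instructive asymmetry of reference-relative scores.
Estimator anchors run at 1000 sites and 100 subjects per population.

Degenerate inputs are handled explicitly: empty blocks are an error for
scoring, monomorphic site pairs an error for `ld_r2`, an Fst pair with no
polymorphic site is reported missing, heterozygous mitochondrial calls
(heteroplasmy), indels and multiallelic records are excluded at parse time,
and a site with any missing call is dropped (the score has no missing-data
term; the targeted 1000 Genomes phase 3 calls are essentially complete).
Invariant-site filtering pools all subjects (one retained-SNV count per
gene), not per population.

## Limitations

- Gene-level scores discard within-gene haplotype structure by design;
  a strongly interacting single SNV pair inside large genes is diluted by
  the $M \times K$ averaging (which is why the SNV-level mode exists).
- The optimal-accuracy statistic is upward-biased under the null (see
  above); compare accuracies between modes, not against 0.5.
- Importance comparisons across models with different feature counts are
  interpretive however normalized; both available conventions are
  documented.
- With 200 permutations the smallest attainable p-value is 1/201, so
  per-gene significance is bounded; increase `n_perm` for finer resolution.
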