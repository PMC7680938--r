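---
title: "Methods: simulating genotype mislabeling in clonal genomic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating genotype mislabeling in clonal genomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the simulator answers

Genomic selection (GS) replaces phenotypic selection with selection on
marker-based predictions of genetic value.  It involves more handling
steps than phenotypic selection — DNA sampling, genotyping, merging of
genotype and phenotype records — and every step can attach a marker
profile to the wrong plant.  In a clonally propagated crop the damage is
persistent: a clone is genotyped once, and the same (possibly wrong)
genotype is reused through every later trial stage and model update.
`mislabelGS` simulates a recurrent GS breeding programme for a
cassava-like clonal outcrosser and injects genotype–phenotype label
errors at controlled rates, to quantify how much genetic gain,
genetic variance, and prediction accuracy are lost, and through which
mechanism.

Two error mechanisms are modelled (`inject_source_error()`,
`inject_substitution_error()`):

* **Source error** — the DNA analysed under a clone's label came from a
  *backup population* (extra progeny of the same parents), so the linked
  genotype belongs to an individual outside the phenotyped cohort.
* **Substitution error** — genotypes of clones *within* the cohort are
  permuted against their phenotypes.  The permutation of the affected
  subset is a derangement: no mislabeled clone keeps its own genotype.

Both mechanisms alter only the genotype–phenotype linkage.  True
genomes, phenotypes, and crossing behaviour are untouched: when a
mislabeled clone is selected as a parent, the plant that was phenotyped
is crossed, because that is the plant standing in the nursery.

## The breeding programme

One trajectory (`run_scheme()`) covers four cycles of selection:

1. 200 founder clones carry *historical* phenotype records
   (clone-mean error variance 1, so clone-mean heritability
   $h^2 = 1/(1+1) = 0.5$).  A genomic prediction model is trained on
   those records and the top 40 clones by predicted genotypic value are
   selected (`select_top()`, ties broken by stable id order).
2. Random crosses among the 40 selected clones (independently drawn
   unordered pairs, no selfing, Poisson crossovers with uniform
   positions — Haldane's model) produce a cohort of 600 seedlings.
3. Each new cohort is genotyped once; labeling errors are injected at
   that moment at rate $e \in \{0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5\}$
   (exactly `round(e * N)` clones per cohort).  The *seedling scheme*
   phenotypes the cohort at the seedling stage (error variance 36,
   $h^2 = 1/37 < 3\%$) and updates the model before selecting; the
   *no-seedling scheme* never uses seedling records, so its second
   selection reuses the historical-data model.
4. Nonselected clones advance to a clonal evaluation trial (CET, error
   variance 16) one cycle later; the full cohort reaches a preliminary
   yield trial (PYT, error variance 9) the cycle after that
   (`schedule_trials()`).  Selected clones move to the crossing nursery
   and are therefore never CET-phenotyped.  From cycle 3 onward both
   schemes train on all accumulated records.

Gain is the mean true genotypic value of a cohort relative to the
founders (population 0 is centred at 0); genetic variance is the
variance of true genotypic values; prediction accuracy is the Pearson
correlation between true and predicted values **among correctly labeled
candidates**.

### Mislabeling of the historical training population

The historical founder cohort is genotyped once like every other
cohort, and is mislabeled at the same rate.  The design was genuinely
open — one reading treats the 200 historical clones as curated and
error-free — but that reading is inconsistent with the system being
modelled: it would make cycle-1 accuracy independent of the error rate
and would make the cycle-1 selection-bias test degenerate (zero
mislabeled selections at every rate).  With historical errors included,
accuracy declines with the error rate from the first cycle, which is the
behaviour the downstream analyses quantify.  For *source* errors in the
founder cohort the erroneous genotypes come from a *shadow germplasm*
sample: `n_backup` extra clones drawn in the same coalescent simulation
(`founder_config(n_backup = )`), i.e. unrelated accessions of the same
population with the same LD structure.  The shadow sample never enters
any founder statistic (MAF filter, LD validation, trait scaling).

## Founder genotypes

`simulate_founders()` draws founder haplotypes from an equilibrium
coalescent with recombination (msprime backend, one independent tree
sequence per chromosome).  The default genome is 18 chromosomes of
110 cM, each split into 11,000 segments of 100 bp; recombination occurs
between but not within segments, at the fraction given by Haldane's
function for the 0.01 cM inter-segment distance; the effective
population size is 100 and 200 diploid founders are sampled.  SNPs are
filtered to minor allele frequency > 0.01, then 2500 markers and 100 QTL
are drawn uniformly without replacement, mutually disjoint (markers tag
but never equal causal loci).

Two deliberate numerical choices:

* **Mutation rate.**  The default is $2 \times 10^{-7}$ per bp per
  generation.  At the nominal $10^{-8}$ sometimes quoted for this kind
  of genome, Watterson's formula gives only about 520 segregating sites
  for 400 sampled haplotypes over the 19.8 Mb of modelled sequence —
  far too few to support a 2600-locus panel after MAF filtering.  At
  $2\times10^{-7}$ the expectation is about 10,400 sites (about 7,000
  after filtering), which supports the panel with a comfortable margin
  at every seed.  LD structure is unaffected: linkage disequilibrium
  depends on $C = 4N_ec$, not on the mutation rate.
* **Expected LD.**  `hill_weir_expected_r2()` implements
  $E[r^2] = \frac{10+C}{(2+C)(11+C)}\Big[1 +
  \frac{(3+C)(12+12C+C^2)}{m(2+C)(11+C)}\Big]$ with $C = 4N_ec$ and $m =
  2n$ chromosomes sampled from $n$ diploids.  At $N_e = 100$, $n = 200$
  and the 0.79 cM average marker spacing this evaluates to 0.18 — the
  design value for the simulated species.  Validation compares like with
  like: the expectation is a ratio of expectations
  ($\sigma_d^2 = E[D^2]/E[p_1q_1p_2q_2]$), so `adjacent_marker_r2()`
  reports the ratio-of-sums estimator $\sum D^2 / \sum p_1q_1p_2q_2$
  next to the $w$-weighted mean of per-pair expectations at the
  *realized* spacing.  The plain mean of per-pair $r^2$ is also reported
  but is systematically smaller under a 1% MAF filter (rare-allele pairs
  cannot reach high $r^2$); it is not the quantity the formula predicts.

## The prediction model

`gblup()` fits
$$y = X\beta + Zu + \varepsilon,\qquad u \sim N(0, K\sigma_u^2),\qquad
\varepsilon \sim N(0, R\sigma_e^2)$$
with the overall mean as the only fixed effect, $Z$ mapping phenotype
records to genotyped clones (a clone contributes records from several
stages), $K$ a VanRaden-type realized relationship matrix
(`compute_kinship()`, allele frequencies recomputed from all genotyped
clones at every model update), and $R$ the known diagonal of relative
error variances (1/36/16/9 by stage — the values the phenotypes were
simulated with).  Premultiplying by $R^{-1/2}$ makes the residuals
homoscedastic and the transformed model is solved in the ordinary way;
only relative values of $R$ matter (rescaling $R$ by any positive
constant leaves predictions unchanged — this is a tested invariant).

REML is profiled over the variance ratio
$\lambda = \sigma_u^2/\sigma_e^2$ using a spectral decomposition.
Because $Z'R^{-1}Z$ is diagonal, the non-null spectrum of
$R^{-1/2}ZKZ'R^{-1/2}$ equals that of $S^{1/2}K_{tt}S^{1/2}$ with
$S = \mathrm{diag}(Z'R^{-1}Z)$, so each fit costs a single
eigendecomposition of an $n_\mathrm{clones}$-sized matrix rather than an
$n_\mathrm{records}$-sized one, and the one-dimensional REML search (on
$\log\lambda$, tolerance $10^{-8}$) is then almost free.  The solver is
verified against a dense mixed-model-equation oracle on toy instances to
$10^{-6}$ relative error.  Unphenotyped candidates are predicted through
the kinship covariance with the training clones; phenotyped candidates'
own records contribute, giving a weighted average of own phenotype and
information from relatives.  Degenerate kinships are handled by the
eigenvalue floor at zero; an estimate at the search boundary raises a
warning.

## Post-simulation analysis

* `gain_summary()` — mean and CV of gain across replicates.
* `selection_bias_test()` — exact two-sided binomial test of whether
  mislabeled clones are selected at a frequency other than $e$.
  **Calibration:** the cohort contains exactly `round(e N)` mislabeled
  clones, so under unbiased selection the count among the 40 selected is
  Hypergeometric$(N, \mathrm{round}(eN), 40)$, and the binomial test is
  discrete; both facts push its true rejection rate below the nominal
  5%.  `selection_bias_null_rate()` computes the exact null rejection
  probability (binomial or hypergeometric null), and
  `selection_bias_summary()` reports observed significant counts next
  to that exact expectation.  The acceptance check compares observed
  counts to the exact expectation, not to the nominal level a discrete
  test cannot attain.
* `interaction_anova()` — the fixed-effects model
  $y = \mu + m + s + ms + \varepsilon$ per response and cycle, with
  Bonferroni correction across the family (three responses × cycles);
  the family definition is configurable because no canonical family
  exists for this design.
* `pairwise_gain_tests()` — final-population comparisons between all
  scenario pairs within an error type, paired by replicate (scenarios
  within a replicate share founders and random substreams by
  construction), Bonferroni-adjusted.  Unpaired tests are available via
  `paired = FALSE`.
* `response_decomposition()` — the breeder's-equation view
  $R = (1-e)\, i\, r\, \sigma_A$ (`expected_response()`,
  `selection_intensity()` computes $i$ by numerical integration of
  normal order statistics).  Since $i$ is constant over cycles 2–4, the
  observed response is summarised as the mean increment from population
  1 to population 4 and compared, per replicate, with the error-free
  baseline; the per-cycle $r\,\sigma_A$ ratio against baseline isolates
  the accuracy-variance trade-off: at cycle 2 the ratio sits below 1 and
  falls with $e$ (training-set corruption), while at cycles 3–4 it
  typically exceeds 1 because weaker selection under mislabeling
  preserves genetic variance, which raises heritability and with it
  later-cycle accuracy.

## Randomness and pairing

Every draw comes from a named substream,
`substream_seed(master, replicate, cycle, purpose)`.  Within a
replicate, all scenarios share the founder population, trait
architecture, historical phenotypes, and the per-cycle crossing and
phenotyping streams, so scheme and rate contrasts are paired — this is
what makes paired t tests and per-replicate ratios meaningful.  The
same master seed reproduces every table bit for bit.

## Problem sizes

`experiment_spec()` provides three scales.  The `full` preset is the
full design (18-chromosome genome, 2500 markers, cohorts of 600, both
error mechanisms, 100 replicates): a multi-hour batch run intended for a
cluster or an overnight job.  The `reduced` preset is the package's
desk-scale working point, chosen so that the complete paired grid —
source errors at 7 rates × 2 schemes × 20 replicates — runs in roughly
ten minutes on one CPU while preserving every structural feature of the
design (4 cycles, 200 founders, 40 selected, staged heteroscedastic
phenotyping): 6 chromosomes, 500 markers, 50 QTL, cohorts of 300.  The
`toy` preset is a seconds-scale smoke test for examples and CI.  The
acceptance checks and the worked examples use `reduced`; all qualitative
conclusions (gain ordering, variance retention, seedling advantage,
unbiased selection, the $r\sigma_A$ reversal) are stable at this scale,
while exact magnitudes carry the larger Monte-Carlo error of 20
replicates.

## What the generator does and does not emulate

The synthetic data reproduce: equilibrium LD consistent with the
Hill–Weir expectation at the simulated $N_e$; a purely additive
polygenic trait (100 QTL, standard-normal effects rescaled so founder
genetic variance is exactly 1 and founder mean exactly 0); stage-wise
clone-mean phenotypes with known heterogeneous error variances; and
once-only genotyping with persistent label linkage.  They do **not**
emulate: dominance or epistasis; genotype-by-environment structure
beyond what the stage error variances absorb; multi-location or
plot-level field models; partially wrong genotypes (per-marker error,
sample contamination); demographic histories other than a single
equilibrium population; or any mislabel-detection and correction
procedure.  Passing tests therefore support conclusions about the
*mechanism* of mislabeling damage under these idealisations, not about
absolute gains in any particular real programme.

## Known limitations

* The coalescent backend runs through the system `python` (msprime); the
  R functions fail with a clear error when no interpreter is found
  (`MISLABELGS_PYTHON` overrides the lookup).
* REML uses a dense eigendecomposition per model update; fits stay
  comfortable up to a few thousand genotyped clones, which covers the
  full design, but the cost grows cubically beyond that.
* The no-seedling scheme is implemented as "seedling records never enter
  the training data"; the alternative reading (seedling records of past
  cohorts eventually enter) differs only at the margin because those
  cohorts contribute CET/PYT records anyway, but it is not what this
  package runs.
* Backup populations are regenerated per cohort with the same parents
  and an independent seed; backup clones are never phenotyped and never
  recycled into the programme.
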