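---
title: "Simulating closed honeybee breeding programs: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating closed honeybee breeding programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apisim)
```

## The genetic model

A honeybee colony phenotype is determined by two generations at once: the
queen and her worker group. apisim implements the standard two-effect
colony model

$$y = a^Q_q + \bar{a^W_w} + E + \varepsilon,$$

where $a^Q_q$ is the additive *queen effect* of the colony's queen,
$\bar{a^W_w}$ the mean additive *worker effect* of her worker group, $E$
an apiary-by-year environmental effect, and $\varepsilon$ a residual.
Two traits are carried: an early trait, recordable before a queen's
first full season, and a late trait (total honey yield is the canonical
example) that forces a two-year generation interval if it must be
recorded on candidates themselves.

Every genetic entity carries a length-4 breeding-value vector
(worker-T1, queen-T1, worker-T2, queen-T2). The base-population
covariance is the Kronecker product of a 2x2 between-trait correlation
matrix and a 2x2 within-trait worker/queen covariance matrix
(`build_G()`). Defaults fix the scale at $\sigma^2_{A_W} = 1$, with
$\sigma^2_{A_Q} = 0.5$ (half the worker variance, one third of the
residual variance $\sigma^2_\varepsilon = 1.5$) — ratios in the range of
field estimates for honey yield, royal jelly yield, swarming and
hygienic behaviour. The worker–queen correlation $r_{W,Q}$ is 0 by
default (−0.5 is the usual alternative), and the between-trait
correlation $r_{T1,T2}$ spans −0.6 to 0.6 on the scenario grid. Both
traits share all variances, so scenarios differ only in correlations
and breeding-goal weights.

Haplodiploid inheritance is explicit: a gamete carries half the parent's
vector plus a Mendelian deviation with covariance
$0.25\,(1 - F)\,\mathbf G$, shrinking linearly in the parent's
inbreeding coefficient $F$; a drone *is* one maternal gamete and
transmits it clonally, so daughters of one drone are super-sisters with
additive correlation 0.75. A queen mates with 8 drones (polyandry;
values above 5 are known to behave near-identically). The worker group
is treated as infinitely many workers: maternal sampling deviations
average out and the paternal contribution is the equal-share mean of
the 8 father drones.

Apiary-by-year effects are i.i.d. normal per trait with variances set
to 1/3 (early) and 2/3 (late) of the phenotypic variance
$\sigma^2_P = \sigma^2_{A_W} + \sigma^2_{A_Q} + \sigma^2_\varepsilon = 3$.
The phenotypic variance is not defined uniquely in the colony model (it
depends on the relationship structure of the population); fixing the
convention to the sum of base variances keeps all scenarios comparable.

## Pedigree relationships

The relationship machinery represents each pedigree node — queen,
worker group, or open-mating pseudo-sire — as a weighted sum of its
parent nodes plus an independent Mendelian residual. That single
recursion yields the dense relationship matrix `compute_A()`, the
sparse inverse `compute_A_inverse()` (generalized Henderson rules:
each node contributes $(e_i - c_i)(e_i - c_i)'/d_i$), and inbreeding
coefficients, with bee-specific coefficients:

* a queen takes 0.5 from her dam and 0.5 from the drone-producing queen
  (DPQ) whose drones inseminated her dam — a drone being a random
  gamete of its mother, the DPQ enters exactly like a diploid sire; her
  residual variance is $0.25(1-F_{dam}) + 0.25(1-F_{DPQ})$;
* a worker group takes 0.5 from its queen and 0.5 from her mate; its
  residual is the paternal sampling variance of the finite drone set,
  $0.25\,(1-F_{DPQ})/8$ — this is where polyandry enters the matrix;
* open matings are represented by pseudo-sire rows: a pool of 100
  unknown, unrelated dummy DPQs. The row carries the pool average
  (variance $0.25/100$); daughters and worker groups of open-mated
  queens take coefficient 1 on it, with residuals
  $0.5 - 0.25/100$ and
  $\mathrm{Var}(\text{mean of 8 pool drones}) - 0.25/100$
  respectively. Only pseudo-sires, queens and worker groups receive
  rows; single-DPQ matings do not get separate rows.

Two deliberate approximations follow from this row structure. First,
two daughters of the same mating can share the same father drone
(probability 1/8), adding $(1/32)(1-F_{DPQ})$ to their true covariance;
A, like any formulation that treats the mate as a diploid parent,
carries the expected value without this excess. Second, daughters of an
*open-mated* queen share her specific 8-drone sample with her worker
group; the pool-average row carries only the pool-level part of that
covariance. Both simplifications keep A non-singular (an exact
mating-average row would make every worker-group row a linear
combination of its parents) and are inherited by the inverse the
evaluation uses.

`gene_drop_A()` validates all coefficients by an independent route:
discrete allele identities are dropped through the same generative
assumptions and identity-by-descent sharing is scored directly. The
polyandry term in the worker-group diagonal, the pool terms, and the
inbreeding coefficients all emerge from allele counting with no shared
code with the recursion. The true-breeding-value machinery in the
simulator, by contrast, *does* share the 8 stored drones among a dam's
daughters (the biology); the super-sister checks are run on that
machinery directly.

## Genetic evaluation

`build_mme()`/`solve_blup()` assemble and solve the Henderson equations
of the two-trait colony model: fixed apiary-by-year-by-trait effects
(levels built from the data, so none are empty), and genetic effects
for every pedigree node with covariance $\mathbf A \otimes \mathbf G$.
Missing traits are handled by per-trait incidence — no imputation.
Records of a colony link the *worker* effect of its worker-group node
with the *queen* effect of its queen node; worker and queen EBVs of the
same trait are summed before the breeding-goal weights are applied
(`selection_index()`). Dams are ranked on their worker group's index —
a breeding queen is mated before she can be selected, so her offspring
have the expected value of her worker group — and sires on their own.
Ties are broken by node id, which is deterministic and documented.

`reml_estimate()` re-estimates $\mathbf G$ (all 10 components over the
4 effects) and the residual covariance by average-information REML with
expectation-maximization fallback. All traces are exact: the selected
inverse of the coefficient matrix is computed by the Takahashi
recursion on the sparse Cholesky factor, with the (nearly dense)
trailing block of the factor handled by dense inversion — the trailing
block of $C^{-1}$ equals $(L_{TT}L_{TT}')^{-1}$, so it can be computed
with LAPACK and spliced in. Numerical safeguards, in the order they
act: Levenberg–Marquardt damping of the AI step with
likelihood-monitored revert; an eigenvalue pseudo-inverse for AI
matrices that are rank-deficient on small data, with the null space
moved toward the EM fixed point; half-stepping and projection onto the
positive-definite cone when an update crosses the boundary (boundary
estimates such as zero genetic variance are therefore pinned rather
than rejected). Starting values follow the established convention of
0.9 times the genetic and 1.1 times the residual prior values, and the
convergence criterion is the squared relative norm of the parameter
change below $10^{-11}$ — the criterion of the standard AI-REML
programs this mirrors. Non-convergence marks the replicate as failed;
the grid runner records the failure and draws a fresh replicate.

A *known-parameters* mode evaluates at the true $\mathbf G$ and
$\mathbf R$, skipping REML. It is exact for ranking when the truth is
known, much faster, and used for scaled-down runs — but it removes
estimation noise, which the full mode deliberately keeps because
estimation error degrades selection accuracy in practice (see
Limitations). When the goal puts zero weight on a trait and both
covariance matrices are block-diagonal across traits, the evaluation
drops the unweighted trait's equations — an exact optimization in that
case.

## The breeding schemes

`run_initialization()` builds the shared starting population: 24
founder queens in year 1, open-mated to base drones; from year 2, every
selected dam produces 18 candidate breeding queens (BQs) and 18
candidate DPQs; 25% of each cohort is eliminated before phenotyping and
another 25% after, leaving 243 two-year-old candidates per path, of
which the best 24 are kept on a phenotypic index (within-cohort
standardized phenotypes, weighted like the breeding goal). New BQs are
inseminated by a single selected DPQ each, with balanced random
assignment (closing the population from the year-4 cohort on); DPQs are
always open-mated. Mortality is applied as an *exact* fraction, which
is what makes the candidate and record counts exact rather than
expectations (432 born → 324 phenotyped → 243 candidates; 2,616 records
per trait by the end of Initialization).

Cohorts are allocated to 18 apiaries before any mortality: each sister
group of 18 is split 6/6/6 over 3 apiaries and each apiary tests 4
sister groups per path, i.e. 24 BQs + 24 DPQs before mortality and 36
surviving colonies per apiary and test year on average. The allocation
randomizes group and apiary labels over a cyclic base design.

`run_base()` continues with two-year generation intervals and complete
phenotyping on both paths: evaluations and selections in every even
year from 12 to 30 (first REML sees 3,264 records per trait; the final
file holds 9,096). `run_alt()` halves the dam interval: dams are
selected at one year old among 324 candidates (selection rate 7.4%
versus 9.9%, selection intensity 1.89 versus 1.76) on the early trait
only, every year; sires keep the two-year interval with complete
phenotyping. Records of one-year-old DPQs enter the performance file
only the following year, together with their late trait. In the
transition year 11 the new queens are mated by the DPQ pool selected at
the end of Initialization (born in year 8); from year 12 on, queens are
always mated by two-year-old DPQs. By year 30 the accelerated scheme
has produced 20 dam cohorts against 10, with final record counts of
15,252 (early) and 8,772 (late).

Paired replicates (`run_replicate()`) share one Initialization: the
state is deep-copied and each scheme runs under its own named random
substream derived from the replicate seed, so the shared phase is
bit-identical and within-replicate relative differences are meaningful.
Setting both breeding-goal weights to zero replaces every ranking by a
uniform random one — the drift-only control, which must show a flat
genetic trend with still-rising inbreeding.

## Comparison statistics

`scenario_comparison()` aggregates paired replicates: gains and added
inbreeding are expressed against the year-10 cohort, relative
differences are computed *within* replicate and then averaged (the mean
of ratios, not the ratio of means), and the empirical probability that
the accelerated scheme strictly outperforms the reference carries the
binomial standard error $\sqrt{\hat p(1-\hat p)/n}$, reported as
non-estimable at $\hat p \in \{0, 1\}$. `expected_selection_intensity()`
integrates the exact normal order-statistic densities (no
infinite-population approximation): top 24 of 243 gives 1.76 SD units,
top 24 of 324 gives 1.89. `inbreeding_rates()` converts a trajectory
into per-year and per-generation rates; generation counting (10 for the
reference, 20 dam generations for the accelerated scheme, or an
averaged dam/sire count) is an explicit argument because only totals
are well-defined.

## The synthetic dataset generator

`simulate_colony_data()` is the test bed for the evaluation module: a
multi-generation random-mating population (no selection) with the full
colony model — single-DPQ inseminations, polyandry 8, apiary fixed
effects — returning pedigree, records and true values. By default each
daughter receives an *independent* gamete of her dam's mate, so the
data match the expected-relationship matrix exactly; that is the right
setting for estimator validation, and with it a 20-seed study at 5,000
records recovers every variance component to within a few percent.
Setting `share_drones = TRUE` switches to the biological process (the
dam's stored 8 drones), which adds the super-sister covariance the
matrix does not carry; the same recovery study then shows a systematic
worker-up/queen-down redistribution of a few percent — a useful
reminder that the evaluation model is an approximation of the biology,
inside this simulator just as in the field.

What the generator does *not* emulate: selection (so no Bulmer effect),
overlapping generations, unbalanced family sizes from mortality, or
missing records. Passing recovery tests on it therefore validates the
estimator under the model, not the robustness of the estimator to those
real-data features — the scheme engine exercises them.

## Problem sizes and numerical choices in the test suite

The shipped tests run the full population design (24 x 18 cohorts, 18
apiaries, years 1–30) wherever a check depends on the design, and
scale only the replication: the long-horizon stochastic comparison uses
8 paired replicates per scenario in known-parameters mode, with
tolerances that combine the published standard errors with this run's
own Monte-Carlo error. Monte-Carlo validations use 2x10^4 to 10^5
draws with 3-standard-error bands. The REML recovery study uses 20
seeds of 5,000 records (4 generations of 50 dams x 25 daughters, 50
DPQs — a design chosen for identifiability of the queen-effect
variance); REML convergence is additionally checked on
Initialization-scale data (2,616 records per trait, the deep closed
pedigree of years 1–10).

One scenario deserves an explicit note. When the breeding goal weights
only the late trait and the between-trait correlation is zero,
candidate dams in the accelerated scheme carry no phenotypic
information of their own: their index is driven by the parent average
and by their mate's merit, so selection concentrates on few families
and inbreeding accumulates fastest of all scenarios. In this
implementation the 20-year added inbreeding for that scenario comes
out around 35% (the long-horizon test reports the exact run), and the
figure is stable across evaluation modes — a full in-loop-REML
replicate (roughly 45 minutes of single-core time) lands within a
standard error of the known-parameters mean, so estimation noise does
not materially temper the family co-selection here. All other
gain and inbreeding outcomes of the two schemes, including the
accelerated scheme's inbreeding under the early-trait goal, agree
closely with published expectations for this design; this one quantity
is sensitive to exactly how much within-family information the dam
index carries, and should be read with that sensitivity in mind.

## Limitations

No explicit genomes or loci: the infinitesimal model has no
Mendelian-sampling depletion beyond the $1-F$ factor, no sex-locus
(csd) brood loss, and no inbreeding-depression discounting of
phenotypes or survival. Mortality is random, so longevity is not
heritable. Non-additive effects are absent. The pseudo-sire device
assumes open-mating drone pools are unrelated to the breeding
population and constant over years — appropriate for a large
surrounding base population, optimistic for an isolated mating area.
Worker groups are infinite averages; finite worker-group noise would
add a small colony-level variance component that the residual absorbs
here.
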