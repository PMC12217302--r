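# apisim

Stochastic simulation of closed honeybee breeding programs, for
quantitative geneticists and breeding-program designers who want to
compare selection schemes before running them on real bees.

Honeybee colony phenotypes are shaped by two generations at once: the
queen and her worker group. apisim implements the two-effect colony
model

    y = a_Q(queen) + mean a_W(worker group) + apiary-by-year + residual

with explicit haplodiploid inheritance (drones are clonal maternal
gametes; a queen mates with 8 drones), two traits — an early trait
recordable in a queen's first year and a late trait that otherwise
forces a two-year generation interval — and breeding goals
`H = w1*(T1 worker+queen) + w2*(T2 worker+queen)`.

On top of that model the package provides:

* **Bee pedigree relationships**: a relationship matrix over queens,
  worker groups and open-mating pseudo-sires (pools of 100 unknown
  dummy drone-producing queens), its sparse inverse via generalized
  Henderson rules, inbreeding coefficients, and a gene-dropping
  validator (`compute_A()`, `compute_A_inverse()`, `gene_drop_A()`).
* **Genetic evaluation**: the two-trait colony-model BLUP with fixed
  apiary-by-year effects and missing-trait handling, and
  average-information REML with exact traces from a sparse selected
  inverse (`solve_blup()`, `reml_estimate()`).
* **Scheme engines**: a shared Initialization phase (years 1–10), a
  reference scheme with two-year generation intervals and complete
  phenotyping (`run_base()`), and an accelerated scheme with a one-year
  dam interval and early-trait-only dam phenotyping (`run_alt()`),
  with exact-fraction mortality, apiary allocation and balanced
  matings. Paired replicates share the Initialization state.
* **Comparison statistics**: within-replicate relative differences,
  empirical superiority probabilities with binomial SEs, exact
  truncation-selection intensities, inbreeding rates per year and per
  generation (`scenario_comparison()`,
  `expected_selection_intensity()`, ...).

## A worked example

One paired replicate at full population size (24 selected queens per
path, 432 candidates born per cohort, 18 apiaries, years 1–30),
breeding goal entirely on the early trait, evaluation at the true
variance components:

```r
library(apisim)
cfg <- scheme_config(weights = c(1, 0), params = genetic_params(),
                     evaluation = "known")
rep1 <- run_replicate(cfg, seed = 1)
tb <- rep1$summary_base$trajectory
ta <- rep1$summary_alt$trajectory
round(c(base_gain = tb$gain_H[tb$year == 30],
        alt_gain  = ta$gain_H[ta$year == 30],
        base_addF = 100 * tb$gain_F[tb$year == 30],
        alt_addF  = 100 * ta$gain_F[ta$year == 30]), 2)
#> base_gain  alt_gain base_addF  alt_addF
#>      8.07     12.29     27.78     28.48
```

Read: after 20 years of selection the reference scheme gained 8.07
genetic-SD-scaled units on the breeding goal while the accelerated
scheme gained 12.29 (+52% in this replicate — shortening the dam
generation interval pays off when the goal is the early trait), at the
cost of mean inbreeding rising by 27.8 vs 28.5 percentage points over
the same period in this draw. Replicated comparisons with standard
errors come from `run_grid()`:

```r
man <- run_manifest(weights = list(c(1, 0)), r_T1T2 = 0,
                    n_replicates = 8, seed = 7, evaluation = "known",
                    out_dir = "out")
res <- run_grid(man)
res[[1]]
#> scenario_comparison over 8 paired replicates
#>   gain H   base   8.04 +/- 0.13 | alt  11.94 +/- 0.22 | rel diff +48.5% +/- 2.8% | p^ 1.00 (NE)
#>   ...
#>   added F  base 21.50% +/- 0.93 | alt 27.72% +/- 1.72 | rel diff +29.6% +/- 7.5%
```

In-loop REML re-estimation before every selection
(`evaluation = "reml"`, the full protocol) costs on the order of tens
of minutes per paired replicate on one core; grids of such replicates
are overnight runs.

There is also a command-line entry point:

```sh
Rscript inst/cli/apisim.R run --config scenario.yaml --replicates 50 \
    --seed 1 --mode known --out results/
Rscript inst/cli/apisim.R tables --in results/
Rscript inst/cli/apisim.R validate-pedigree --pedigree ped.csv
```

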