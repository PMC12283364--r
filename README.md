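# cloneclock

Colony-level whole-genome analysis of somatic mutations in normal blood:
phylogenies, molecular-clock timing, mutational signatures, burden
models and clonal architecture — with a synthetic-cohort generator so
the whole chain is testable without controlled-access sequencing data.

## The problem

A single hematopoietic stem/progenitor cell (HSPC) expanded into a
colony yields, after whole-genome sequencing, the somatic mutations of
its founder cell. Across many colonies from one person this supports
three measurements:

* **Burden.** Somatic single-base substitutions (SBS) accumulate nearly
  linearly with age, `E[SBS] = β₀ + β₁·age` (reference coefficients
  β₀ = 54.57 mutations at birth, β₁ = 16.832 per year). Deviations —
  for example after mutagenic chemotherapy — are modelled with a
  Poisson *identity-link* mixed model,
  `y_ij ~ Poisson(β₀ + β₁ age_i + β₂ exposed_i + u_i)`,
  `u_i ~ N(0, σ²)` a per-individual random intercept.
* **Phylogeny and timing.** Shared mutations place colonies on a rooted
  maximum-parsimony tree (the zygote is the ancestral all-absent
  state). After correcting terminal branches for detection sensitivity
  and normalising the tree to be ultrametric, the constant mutation
  rate acts as a molecular clock: branch lengths become years, and
  mutational events can be timed against known exposure windows.
* **Signatures and architecture.** Each branch's mutations form a
  96-channel spectrum decomposed into signature exposures by
  non-negative least squares (signatures contributing ≤ 5% of a
  sample's burden are not reported); clades with clonal fraction > 1%
  count as expanded, and driver-gene mutations are overlaid on the
  tree.

All of this is exercised end to end by a generator
(`sim_config()` / `simulate_cohort()`) that emulates the assay:
coalescent genealogies, clock-like mutation accrual, chemotherapy
"pulses" hitting every lineage alive at the exposure age, driver-clone
expansions, germline variants, culture artifacts and binomial read
sampling — with a full truth channel for validation.

## Worked example

Simulate a 48-year-old with a chemotherapy pulse at age 10 (+400 SBS
per lineage, alkylating-agent-like T>A signature), then run the chain:

```r
library(cloneclock)

cfg <- sim_config(
  ages_years = 48, colonies_per_individual = 8,
  chemo_pulses = list(list(age_years = 10, expected_extra_sbs = 400,
                           signature_id = "sig_alkyl")),
  seed = 42
)
sim  <- simulate_individual(cfg, 1)
gm   <- filter_variants(sim$counts, filter_config(), mode = "simple")
gm
#> genotype_matrix: 3704 variants x 8 colonies; 3304 kept

tree <- reconstruct_tree(gm)
sens <- estimate_sensitivity(
  mean_depth = setNames(colMeans(sim$counts$depth), sim$counts$colonies),
  method = "depth_model"
)
tree <- scale_to_age(make_ultrametric(correct_terminal_branches(tree, sens)), 48)

pulse <- intersect(
  sim$truth$catalog$variant_id[sim$truth$catalog$true_signature == "sig_alkyl"],
  unlist(tree$mutations)
)
exposure_window_overlap(tree, pulse, c(10, 10))
#> 0.999

fits <- assign_branch_signatures(tree, gm$variants,
                                 example_signatures()[c("sig_clock", "sig_alkyl")])
fits[["12"]]   # the branch carrying the largest alkylating exposure
#> exposure_fit over 1058 mutations
#>          sig_clock sig_alkyl
#> count      635.131   415.673
#> fraction     0.600     0.393
#> unassigned: 7.2
```

Reading: of 3,704 simulated variants, 3,304 survive filtering as
somatic (400 germline removed by the majority rule); 99.9% of the
chemotherapy-pulse mutations land on branches whose time interval
covers the exposure age; and the most exposed branch decomposes into
~635 clock-like and ~416 alkylating-signature mutations — the pulse
dose the simulation planted.

The clock arithmetic itself:

```r
predict_burden(age_years = 13)
#> 273.386
poisson_prediction_interval(273.386)
#> lower upper
#>   241   306
fold_rate_increase(1000, 1, 18)
#> 55.6
```

An expected burden of 273 SBS at age 13, a 95% Poisson prediction
interval of 241–306, and +1,000 SBS in one year being a ~56-fold rate
increase over the 18/yr baseline.

## Package layout

| Area | Functions |
|---|---|
| Simulation | `sim_config`, `simulate_individual`, `simulate_cohort`, `simulate_duplex_spectrum`, `true_colony_burdens` |
| Filtering | `filter_config`, `genotype_calls`, `filter_germline_majority`, `filter_depth_sites`, `filter_binomial_cohort`, `colony_qc`, `filter_variants` |
| Phylogeny | `fitch_score`, `parsimony_score`, `reconstruct_tree`, `assign_mutations`, `missingness_report` |
| Timing | `estimate_sensitivity`, `correct_terminal_branches`, `make_ultrametric`, `scale_to_age`, `exposure_window_overlap` |
| Signatures | `build_spectrum`, `abundance_correct`, `cosine_similarity`, `fit_exposures`, `extract_denovo`, `assign_branch_signatures`, `compare_exposures` |
| Burden | `count_burdens`, `fit_burden_model`, `predict_burden`, `poisson_prediction_interval`, `fold_rate_increase` |
| Architecture | `clade_fractions`, `expanded_clades`, `annotate_drivers`, `clone_growth`, `architecture_summary`, `driver_catalog` |
| Orchestration | `pipeline_config`, `run_pipeline` (writes all outputs plus an MD5 manifest) |

The methods vignette (`vignettes/colony-genomics-methods.Rmd`) documents
the models, the generator's assumptions, numerical choices and known
limitations.
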