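---
title: "Methods: colony phylogenies, mutational signatures and burden models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony phylogenies, mutational signatures and burden models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneclock)
```

## The measurement problem

Hematopoietic stem and progenitor cells (HSPCs) acquire somatic
single-base substitutions (SBS) at a near-constant rate across life —
roughly 54.6 mutations present at birth plus about 16.8 per year. Because
a colony grown from one HSPC is genetically a copy of its founder cell,
whole-genome sequencing of many colonies from one person yields (i) the
per-cell mutation burden, (ii) the shared-mutation structure of the HSPC
population, from which a phylogeny of the sampled cells can be built, and
(iii) the 96-channel spectrum of the mutational processes that acted on
each lineage. Mutagenic chemotherapy perturbs all three: it can add a
large "pulse" of mutations with an agent-specific spectrum to every
lineage alive at treatment, and it can reshape the clonal architecture of
blood toward the oligoclonal profile of old age.

`cloneclock` implements the full desk-side analysis chain for such data:
variant filtering from per-colony read counts, maximum-parsimony tree
reconstruction with per-branch mutation assignment, molecular-clock
timing, signature quantification, burden modelling and architecture
metrics — together with a synthetic-cohort generator that emulates the
statistical structure of the real assay so that every stage can be
validated against a known truth.

## The synthetic-cohort generator

`sim_config()` / `simulate_cohort()` draw, per individual:

* **Genealogy.** A neutral Kingman coalescent over the sampled colonies,
  squashed so that all lineages coalesce exactly at birth (age 0, the
  zygote) and tips sit at the sampling age. This reproduces both the flat
  tree shape of young adults and, with driver clades enabled, the
  expanded-clade trees of older or chemotherapy-exposed individuals.
* **Clock mutations.** Each branch receives a Poisson number of SBS with
  mean `burden_slope` × branch time-span (default 16.832/yr); each child
  branch of the root additionally receives Poisson(`burden_intercept`)
  mutations (default 54.57), treating the birth burden as attached to the
  earliest branches — its finer placement is unobservable. A colony's
  root-to-tip burden is therefore marginally Poisson with mean
  intercept + slope × age.
* **Chemotherapy pulses.** For each configured pulse, every branch whose
  time span contains the exposure age receives Poisson(`expected_extra_sbs`)
  mutations with channels drawn from the pulse signature. A per-lineage
  gamma multiplier (`pulse_overdispersion`) is available because the
  true cell-to-cell variability of dose is unknown; the default is 0.
* **Driver clades.** Driver events arise at rate `driver_rate` per
  lineage-year; each realized clade competes for colonies with sampling
  weight `driver_advantage` × (clade age fraction) against a background
  pool of weight equal to the colony count, so advantage 1 leaves clades
  rare and advantage ≫ 1 produces multiple expanded clades.
* **Observation layer.** Germline heterozygous variants (VAF 0.5 in all
  colonies), private in-vitro artifacts with VAF ~ Beta(2, 6) (mode
  ≈ 0.17, mostly below the 0.2 genotyping threshold), and reads: depth
  ~ Poisson(`mean_depth`, default 25× as in colony WGS), alt reads
  ~ Binomial(depth, true VAF).

Contexts are simulated as channel labels only — no reference genome is
involved, because every downstream computation (spectra, signature fits,
corrections) consumes channels, not sequence. The built-in signatures in
`example_signatures()` are analytic constructions (clock-like CpG C>T
enrichment, flat, T>A-dominated alkylating-like, platinum-like,
thymine-focused) — deliberately synthetic, so recovery tests cannot
silently compare a fit against its own reference.

What the generator does **not** emulate: mapping and calling artifacts
with locus structure, copy-number changes, indels, depth correlation
along the genome, or contamination between colonies. Passing tests
therefore demonstrate correctness of the statistical machinery under the
generative assumptions, not robustness to every real-data pathology.

Default study conditions used in the recovery experiments: 20
individuals with ages uniform on 0–80 years, 8 colonies each — the
high-depth per-individual colony counts typical of this assay — and 10
replicate cohorts; these sizes make the clock coefficients estimable to
a few percent while keeping a full run in minutes on one core.

## Filtering

Two strategies mirror the two data regimes:

* **Simple (high-depth) mode** — `genotype_calls()` calls a variant
  present on ≥ 2 supporting reads at VAF ≥ 0.2 (autosomes) / ≥ 0.4 (sex
  chromosomes); sites with mean depth < 8 or > 50 across the individual
  are removed; variants present in strictly more than half the colonies
  are removed as germline (a variant in exactly half is retained — the
  boundary case is deliberately kept, matching the strict reading of the
  rule). Genotypes at sites with depth < 6 and no alt support are
  *unknown*, not absent, so missing data propagate to the phylogeny
  rather than being imputed away.
* **Cohort (binomial) mode** — for large phylogenies, aggregated counts
  across colonies are tested against VAF 0.5 with an exact binomial test
  (germline if not rejected at α = 10⁻⁵ and the aggregate VAF is within
  0.4–0.6), and non-germline variants with beta-binomial overdispersion
  ρ < 0.1 across colonies (a similar low VAF everywhere) are flagged as
  systematic artifacts. True somatic variants — VAF ≈ 0.5 in carriers,
  0 elsewhere — are strongly overdispersed and survive. The
  overdispersion fit fixes the mean at the aggregate VAF and maximises
  the beta-binomial likelihood in ρ alone; this one-parameter profile is
  stable even for variants carried by a single colony.

A caveat worth stating: with 4–10 colonies the strict-majority rule
necessarily removes genuinely somatic mutations from the earliest
branches (those shared by most colonies). This is intrinsic to the rule,
not a defect of the implementation; burden analyses that need the birth
burden should use the cohort mode or more colonies.

Colony-level QC classifies duplicates (Jaccard overlap of somatic
variant sets > 0.8; the lower-coverage member is flagged), nonclonal or
contaminated colonies (mode of the somatic VAF histogram below 0.4,
using fixed 0.05 bins as a deterministic surrogate for visual
inspection of VAF distributions), and low-coverage colonies (mean depth
< 8×, a configurable default since no exact threshold is canonical).
Colonies with fewer than 20 somatic variants are reported as
indeterminate rather than silently classified.

## Phylogeny reconstruction

Somatic presence/absence data are inherently polarized — the zygote
carried none of them — so trees are rooted at an all-absent ancestral
state and no outgroup is needed. The small-parsimony scorer is a rooted
Fitch algorithm over state sets, with unknown genotypes contributing no
constraint, vectorised across characters and run on the set of *unique*
genotype patterns weighted by multiplicity.

Search strategy:

* ≤ 8 tips: exhaustive enumeration of all rooted binary topologies
  ((2n−3)!! trees), guaranteeing the global optimum; ties resolve to the
  lexicographically smallest canonical (sorted-Newick) form.
* > 8 tips: stepwise addition (colonies in descending somatic-burden
  order), nearest-neighbour-interchange descent, subtree-prune-regraft
  descent, and finally a seeded parsimony ratchet: 10 rounds in which
  ~30% of the character mass is temporarily upweighted, the tree is
  re-optimised under the perturbed weights, and the result is
  re-descended under the true weights, keeping improvements. The ratchet
  was adopted because plain NNI (and even NNI + SPR) demonstrably stalls
  in local optima on homoplasy-dense matrices, failing agreement with
  exhaustive search; with the ratchet the heuristic reproduced the
  exhaustive optimum on every random 6-tip instance tested. The ratchet
  RNG is private and seeded (`search_seed`), so reconstruction is
  deterministic and does not disturb the caller's random state.

Every retained mutation is then assigned to the branch whose subtended
colony set minimises the symmetric difference with the variant's
present-set (unknowns excluded); ties break toward the root, then the
smallest branch id. The per-variant mismatch count is kept as a
homoplasy/genotyping-error diagnostic, and the branch `raw_length` is
the count of assigned mutations, so lengths and assignments are
conserved by construction.

## Timing: sensitivity, ultrametric normalisation, age scaling

Terminal branches under-count mutations where coverage is thin. Two
sensitivity estimators are provided: the fraction of known germline
heterozygous variants recalled in the colony (germline hets are a
natural VAF-0.5 truth set), and a closed-form model
Σ_d P(D = d; Poisson(λ)) · P(Alt ≥ max(2, ⌈0.2 d⌉); Binomial(d, ½)),
truncated where the Poisson tail is below 10⁻¹². Terminal branch lengths
are divided by the colony's sensitivity; internal branches, supported by
several colonies, are left unchanged.

Because all colonies come from one draw, corrected root-to-tip distances
should differ only by Poisson noise, and the tree is normalised to be
ultrametric with an iteratively reweighted means scheme: bottom-up, each
internal node's height above the tips is the weighted mean of child
height + child branch length — weights are subtree tip counts in the
first iteration and subtree mutation totals thereafter (the
"reweighting"; both weightings are exposed because either choice is
defensible and the difference is small on clock-like trees) — then a
top-down pass rebuilds branch lengths as height differences, clamping
negatives at zero, which implicitly redistributes the deficit along the
descendant path. Iteration ends when no height moves by more than `tol`
(10⁻⁶), and the tree is scaled so its height equals the mean corrected
root-to-tip distance; total length changes by under 5% on simulated
clock-like trees.

The constant mutation rate then acts as a molecular clock:
`scale_to_age()` scales the ultrametric tree linearly so every
root-to-tip path equals the age at sampling (plus an optional gestation
offset, default 0 — prenatal time is ignored unless requested, as for
cord blood). Each branch acquires a time interval, and
`exposure_window_overlap()` reports what fraction of a mutation set lies
on branches whose interval intersects a given exposure window — the
quantitative version of "the mutations are timed to the treatment".

## Mutational signatures

Spectra live on the fixed 96-channel layout (six pyrimidine-strand
substitution classes × 16 flanking-base contexts). Duplex-sequencing
spectra are first rescaled channel-wise by target/observed trinucleotide
abundance and renormalised to the original total; the correction is the
identity when abundances agree and inverts exactly when the arguments
are swapped.

`fit_exposures()` solves a non-negative least-squares problem of the
spectrum on signature profiles (Lawson–Hanson NNLS), scales coefficients
to mutation counts, and applies the reporting rule that only signatures
contributing more than 5% of the sample's burden are kept: the smallest
sub-threshold signature is dropped and the fit repeated until all
survivors exceed the threshold. The non-negative residual is reported as
*unassigned* mutations, so attributions plus unassigned always equal the
spectrum total. Per-branch attribution applies the same fit to each
branch's spectrum; branches with fewer than 20 mutations — where NNLS on
a count spectrum is unstable — inherit the exposure fractions of their
parent clade's pooled fit, scaled to the branch's own size.

De novo extraction is a generalized Kullback–Leibler NMF with
multiplicative updates, 20 random restarts per candidate rank, and rank
selection requiring both a stable factorisation (mean cosine silhouette
of the clustered restart signatures ≥ 0.85) and a material drop in
reconstruction error over the previous rank (≥ 5% relative — the elbow).
This is the package's own extraction method; it plays the role that
hierarchical-Dirichlet-process extraction plays in larger toolchains,
and it is validated by recovery of planted signatures on synthetic
mixtures (cosine ≥ 0.95), not by comparison to any published catalog.
The per-mutation notion of "could not confidently be assigned" is
operationalised as the fit residual, since no mutation-level assignment
rule is canonical.

Exposure differences between groups use the two-sided pooled-variance
(equal-variance) t test per signature with Benjamini–Hochberg and
Bonferroni adjustments across signatures. Zero pooled variance is
handled explicitly: equal means give p = 1, unequal means give p = 0
with a degeneracy flag.

## The burden model

Per-colony burdens are modelled as
y_ij ~ Poisson(β₀ + β₁·age_i + β₂·exposed_i + u_i), u_i ~ N(0, σ²) —
an *identity* link, because mutations accumulate additively in time and
exposure adds a fixed increment, with a per-individual random intercept
absorbing shared-lineage correlation. The marginal likelihood integrates
u_i by adaptive Gauss–Hermite quadrature (21 nodes; per-individual
Newton search for the mode and curvature-based rescaling), with the mean
clamped at 10⁻⁶ inside the likelihood because an identity link can go
non-positive during optimisation. Optimisation starts at deterministic
method-of-moments values (OLS coefficients; spread of per-individual
mean residuals), and the exposure effect gets a likelihood-ratio
p-value. In the zero-variance limit the fit coincides with an ordinary
identity-link Poisson GLM to four significant figures, which the test
suite checks against `stats::glm` as an independent route.

`predict_burden()` is the linear clock (intercept + slope × age; with
the reference coefficients, 273.4 SBS at age 13), and
`poisson_prediction_interval()` returns central Poisson quantiles — the
smallest counts whose CDF reaches (1−level)/2 and 1−(1−level)/2; at mean
273.386 and level 0.95 this is (241, 306). `fold_rate_increase()`
expresses an extra mutation load as a multiple of the baseline accrual
rate (default 18 SBS/yr).

## Clonal architecture

Each branch defines a clade whose clonal fraction is its colony share —
colonies are treated as a random sample of the HSPC population, so
colony fractions estimate population clonal fractions. A clade is
*expanded* when its fraction strictly exceeds 1% **and** it holds at
least 2 colonies; the second guard exists because at 40–260 colonies a
single colony can exceed 1% by itself, which no one would call an
expansion. Maximal (non-nested) expanded clades are reported separately.
Driver overlays label each clade with every catalog gene mutated on its
stem or ancestral branches (nested drivers accumulate on the inner
clade); the driver-class rule is configurable — truncating variants in
catalog genes always count, missense only via an explicit whitelist —
replacing manual oncogenicity curation with a reproducible rule. The
shipped 18-gene catalog is a synthetic default of canonical clonal
hematopoiesis genes and should be replaced for real analyses.
`clone_growth()` compares a clone's colony fraction between two
samplings with exact Clopper–Pearson intervals and flags clones absent
at baseline.

## Numerical and design notes

* Poisson interval convention: central quantiles defined through the
  CDF (smallest count reaching each tail bound) are used throughout;
  this reproduces (241, 306) at the age-13 mean and gives (1, 8) at
  mean 4.
* NNLS coefficients can overshoot the simplex by rounding; exposure
  vectors are rescaled to the spectrum total in that case so
  conservation holds exactly.
* The ultrametric clamp guarantees non-negative branch lengths at the
  cost of locally compressing descendants of an over-tall sibling; on
  clock-like data the clamp almost never binds.
* All stochastic components (simulator, ratchet, NMF restarts) run on
  explicit or derived seeds; identical configurations give bit-identical
  outputs, which the pipeline verifies with MD5 manifests.
* Exhaustive tree search is the default up to 8 tips (135,135
  topologies, seconds once genotype patterns are collapsed); beyond
  that the ratcheted heuristic is used.

## Known limitations

Indels, structural variants and copy-number changes are out of scope, as
are read-level simulation and upstream variant discovery. The de novo
extractor assumes well-separated processes and moderate sample counts;
heavily collinear signatures will merge. The burden model treats
exposure as a binary covariate; per-agent dose effects would need a
design extension. Clonal fractions are colony fractions — no correction
is attempted for the (unknown) sampling bias of colony culture.
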