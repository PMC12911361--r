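---
title: "Methods: linking plankton community structure to biogeochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking plankton community structure to biogeochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(planktonet)
```

planktonet connects two views of a plankton survey: the *community* view
(amplicon sequence variants — ASVs — counted across samples) and the
*biogeochemical* view (net community production, NCP, in mmol O~2~ m^-2^
d^-1^; particulate organic carbon, POC, and nitrogen, PON, in µmol L^-1^).
The pipeline asks which parts of the community covary with those bulk
measurements, and which taxa co-occur tightly enough to be treated as one
ecological unit — a "microbial neighborhood". This vignette explains each
stage, the model assumptions, the tunable parameters, and the design
decisions taken where the methods literature leaves choices open.

## Data model and preprocessing

An `asv_table` is a samples-by-ASVs matrix of non-negative integer read
counts for one marker gene (16S for prokaryotes, 18S for eukaryotes).
Counts are rarefied to a common depth (`rarefy()`, a multivariate
hypergeometric draw without replacement; the depth defaults to the minimum
sample total so no sample is dropped, and the seed is mandatory and
recorded) before relative abundances are computed. Rarefaction before
relative abundance keeps detection probability comparable across samples;
whether persistence should be called on raw or rarefied counts is not
settled, so `classify_persistence()` accepts either — the choice simply
changes which low-count ASVs count as "detected".

ASVs are mapped to six phytoplankton-containing groups: the cyanobacterial
genera *Prochlorococcus* and *Synechococcus*; the eukaryotic divisions
Archaeplastida, Dinoflagellata and Haptophyta; and photosynthesising
Stramenopiles, retained only for the classes Coscinodiscophyceae,
Bacillariophyceae, Mediophyceae, Chrysophyceae, Bolidophyceae,
Dictyochophyceae, Pelagophyceae and Pinguiophyceae. Everything else —
including heterotrophic stramenopiles and all Opisthokonta — is `Other`.

Samples are placed in three biogeographic regions by two fronts: the
subtropical-gyre boundary at 34.82 ppt salinity (NPSG south of it) and the
0.15 mg m^-3^ chlorophyll-a front separating the southern (STZ) from the
northern (NTZ) transition-zone subregion. Both cuts are configurable
defaults, not constants; when per-sample hydrography is missing the
assignment falls back to per-cruise interpolated front latitudes.

**Persistence.** An ASV detected (count > 0 in any sample) in all three
survey years is *persistent*; in one or two years, *ephemeral*. Persistence
is the package's main filter before modelling: the persistent fraction of
the community dominates total relative abundance even though ephemeral ASVs
dominate richness. A useful identity here: because Bray–Curtis between two
probability vectors is half their L1 distance, the dissimilarity between a
renormalised persistence class and the whole community equals exactly one
minus that class's abundance share — so the persistent and ephemeral
distances in `subset_vs_whole_dissimilarity()` always sum to one where both
classes are present. The distance distributions are therefore a direct
re-expression of abundance shares, which is what makes them a good summary
of how well a class "stands in" for the whole community.

## Ordination and permutation statistics

Bray–Curtis dissimilarities (`vegan::vegdist`), non-metric multidimensional
scaling (`vegan::monoMDS`, global model), ANOSIM and EnvFit
(`vegan::anosim`, `vegan::envfit`) stand behind thin wrappers that add
validation, seeding and a uniform return shape. NMDS runs `n_restarts`
times; the first start is classical scaling of the dissimilarities, so the
returned stress can never exceed the metric solution's, and the remaining
starts are random. Convergence is monotone-regression majorisation with a
stress-change tolerance of 1e-6 and at most 500 iterations per restart.
ANOSIM uses midranks for ties and the permutation p-value
(1 + #{permuted R ≥ observed}) / (n_perm + 1); its type-I error is checked
against the binomial band in the test suite.

## Variance partitioning by multi-kernel REML

The central model is a linear mixed model per trait:

y = Xβ + Σ~g~ u~g~ + ε,  u~g~ ~ N(0, σ²~g~ K~g~),  ε ~ N(0, σ²~e~ I)

where each K~g~ is a *group kernel*: Bray–Curtis dissimilarities on the
group's ASV-level relative abundances, converted to a similarity by Gower
centering of the squared dissimilarities (S = -½ C (D∘D) C), eigenvalue
clipping at zero, and trace normalisation to n. This is the standard
kernel-from-distance construction that guarantees a positive semi-definite
random-effect covariance while preserving ASV-level resolution; the
clipping discards the non-Euclidean part of Bray–Curtis, which is small for
these data. Fixed effects are the survey design: year-by-month interaction,
size fraction, and depth bin (aliased columns dropped automatically;
single-level factors skipped).

Variance components are estimated by REML: the restricted log-likelihood
ℓ~R~ = -½[log|V| + log|XᵀV⁻¹X| + yᵀPy] + const, V = Σ σ²~g~K~g~ + σ²~e~I,
is maximised directly by bound-constrained quasi-Newton (L-BFGS-B) from
four starting points, with non-negativity enforced by the box constraint.
We chose direct maximisation over EM/average-information iterations because
it is simpler to verify: the test suite compares the optimum against a 20³
exhaustive grid over the variance components (the optimiser must not lose
more than 1e-4 of log-likelihood) and against the closed-form one-way
ANOVA REML estimates on balanced data. The reported quantity per group is
its variance *fraction* σ²~g~ / (Σσ² + σ²~e~) — the "donut" share — with
AIC = -2ℓ~R~ + 2k and BIC = -2ℓ~R~ + k·log(n), k = components + rank(X),
on the restricted-likelihood basis. Because published scores are sometimes
deltas against a null model, `information_criteria()` reports both absolute
values and deltas against the kernel-free fit.

A group's *direction* of covariation is the sign of the correlation between
its BLUPs û~g~ = σ²~g~K~g~V⁻¹(y - Xβ̂) and its total relative abundance per
sample; groups with a fraction below `min_fraction` (default 1%) or a
non-significant correlation are reported directionless. Traits enter the
mixed model untransformed (the Box–Cox step belongs to the module-detection
stage); missing traits are handled by listwise deletion per response. One
kernel is fitted over all modelled samples, both size fractions included,
with size fraction as a fixed effect — fraction-specific kernels would halve
the sample support of each kernel for little gain at these sizes.

## Co-abundance modules

Weighted co-abundance analysis runs on the standardised relative abundances
of persistent phytoplankton ASVs, restricted to samples that carry
NCP/POC/PON. The adjacency is unsigned, |cor|^β (signed available); β is
chosen by scale-free fit (`pick_soft_threshold()`: binned log₁₀ p(k) vs
log₁₀ k regression, smallest β with R² ≥ 0.8, else the argmax; fits with a
positive slope score 0). The topological overlap matrix

TOM~ij~ = (Σ~u≠i,j~ a~iu~a~uj~ + a~ij~) / (min(k~i~,k~j~) + 1 - a~ij~)

is clustered by average linkage on 1 - TOM. Instead of the full dynamic
hybrid tree cut we use a three-stage approximation whose pieces are each
easy to test:

1. **Adaptive static cut.** A fixed absolute height is not comparable
   across soft powers (at β = 1 all heights compress toward the top of the
   tree), so by default the cut height is chosen by scanning the tree's
   merge-height quantiles for the cut producing the most branches of at
   least `min_module_size`, breaking ties by weighted-graph modularity of
   the branch partition. Over-splitting at this stage is deliberate.
2. **Membership refinement.** Every ASV is (re)assigned to the module whose
   eigengene (first principal component of the standardised member
   profiles, sign-oriented toward positive mean member correlation) it
   correlates with best, provided that correlation reaches `kme_rescue`
   (default 0.5); otherwise it is unassigned. Two rounds. Final membership
   thus rests on eigengene correlation, which does not depend on the power
   — this is what makes module membership reproducible across powers 1–8,
   the robustness check the pipeline reports.
3. **Eigengene merging and a cohesion screen.** Modules whose eigengenes
   correlate above 1 - `merge_threshold` (default 0.75) merge iteratively;
   surviving modules must show mean within-module correlation above
   2/√n_samples, which removes the self-justifying clusters that pure noise
   can produce (a five-member noise module's eigengene trivially correlates
   with its own members).

Modules are named from a fixed colour palette in size order, "grey" meaning
unassigned. Module–trait association is the Pearson correlation of each
eigengene with each Box–Cox-transformed trait (λ maximising the profile
log-likelihood on a grid over [-5, 5] in steps of 0.01, with a documented
shift when values are non-positive), with the exact t-based p-value on
n - 2 df and pairwise deletion of missing traits.

## Sparse co-occurrence networks

Conditional (direct) associations are estimated on centered log-ratio
transformed counts, clr(x) = log(x + 1) - mean(log(x + 1)), by
Meinshausen–Bühlmann neighbourhood selection: an L1-penalised regression of
each standardised CLR column on all others over a shared path of 20
geometric λ values from λ_max (the largest absolute pairwise correlation)
down to 0.01·λ_max. Neighbourhood selection was preferred to the graphical
lasso because its directed selections map directly onto the out-degree
view used when ranking hub taxa. Sparsity is chosen by StARS: 50 random
subsamples of size ⌊10√n⌋ (⌊0.8n⌋ when n < 144, capped at n - 1), edge
selection frequencies θ~e~ per λ, instability D(λ) = mean 2θ~e~(1-θ~e~),
monotonised from the sparse end; the selected λ* is the smallest λ (densest
graph) whose monotonised instability stays within β = 0.05 — the least
regularised graph that subsampling still reproduces. The final network
combines directed selections at λ* with the "or" rule ("and" available) and
symmetrises weights by the mean of the available directed coefficients.
16S and 18S tables are concatenated over shared samples into one network;
samples missing either marker are dropped with a message.

## Microbial neighborhoods

The integration stage selects *candidate* ASVs from modules positively and
significantly correlated with at least one trait (α = 0.05 on raw
p-values, mirroring how such tables are usually reported; a
Benjamini–Hochberg option exists), extracts each candidate's first-degree
network neighbours sorted by symmetrised weight (ties broken by ASV id),
cross-tabulates neighbour module membership by edge sign, and scores
same-module enrichment of positive versus negative edges as an odds ratio
(Haldane–Anscombe-corrected when a cell is empty) with a label-permutation
p-value. `check_known_association()` resolves two taxon labels
case-insensitively against the taxonomy and reports any linking edge — the
positive-control pattern for a known host–symbiont pair.

## The synthetic survey generator

All validation rests on `generate_community()`, which emulates the study
design the package targets: three yearly surveys along a 24–42°N latitude
gradient, two filter size fractions, six phytoplankton-containing groups
with latitude-structured abundance (gyre-adapted groups peaking in the
south, transition-zone groups in the north), salinity and chlorophyll
fields that induce the NPSG/STZ/NTZ partition, persistent and ephemeral
ASVs, planted co-abundance modules, and a planted sparse
conditional-dependence graph. Latent log-abundances are Gaussian niche
curves plus module factors plus multivariate Gaussian noise with the
planted precision matrix; counts are softmax-to-multinomial draws with
lognormal sequencing depth (median 20,000 reads). The logistic-normal-
multinomial construction was chosen over Dirichlet-multinomial precisely so
that the planted precision matrix *is* the conditional-dependence truth the
network stage must recover.

Choices that define the planted truth:

- **Precision matrices** plant partial correlations directly: Ω = I - P
  with P holding the signed target partial correlations (default magnitude
  0.3–0.35), shrunk only as far as positive definiteness requires. A
  positive ecological association therefore corresponds to a negative
  precision entry and a positive regression weight. Modular graphs make
  within-block edges predominantly positive and between-block edges
  predominantly negative, matching networks in which negative partners
  occupy opposing community regimes.
- **Module factors** are latitude bumps with survey-to-survey amplitude
  variation plus sample noise; members load on the shared factor and have
  their individual niche contribution damped to 25%. That is what a
  co-abundance module *is* — taxa with one coinciding spatial profile — and
  the year modulation keeps module factors distinct from the static group
  niche trends, which both the module-recovery and the cross-power
  stability benchmarks require ("strongly separated" planted modules).
- **Ephemeral ASVs** (default 30%) are zeroed outside their one or two
  assigned years, so persistence classification round-trips exactly at
  realistic depths.

What the generator does **not** emulate: real surveys have thousands of
ASVs (the fixtures have 150), uneven station spacing, depth structure
beyond one bin, taxon-specific rRNA copy-number bias, and gradients that
confound conditional-dependence estimation far more aggressively. Passing
the planted-truth benchmarks therefore shows the estimators are correct and
well calibrated under the generative model they assume, not that every
inference on field data is reliable.

## Benchmark problem sizes and expectations

The packaged benchmarks (also recomputed by `scripts/acceptance.R`) use:

- **Variance partitioning:** planted fractions (0.45, 0.20, 0 + 0.35
  residual), 204 samples, 20 replicates with a fresh community each; mean
  absolute fraction error stays below 0.08 and the null group stays below
  a 5% fraction in at least 16/20 replicates.
- **REML oracle:** 30 samples, two kernels; optimiser log-likelihood within
  1e-4 of a 20³ grid maximum.
- **Modules:** 150 ASVs (105 persistent), 60 samples, four planted modules
  of 12; adjusted Rand index ≥ 0.8 over planted members, trait-linked
  module found with r > 0.6 and p < 0.001, its membership Jaccard ≥ 0.8
  across powers 1–8. The trait built from a module factor with noise
  σ = 0.5 has expected eigengene correlation ≈ 1/√1.25 ≈ 0.89.
- **Networks:** 40 ASVs, 300 gradient-free single-fraction samples, modular
  precision (four blocks, within-block edge probability 0.35); median edge
  precision ≥ 0.7 and recall ≥ 0.6 over 10 seeds, beating an
  edge-count-matched marginal-correlation baseline in ≥ 8/10. The gradient
  is switched off here because the property under test is graph recovery,
  not gradient removal; with full gradient structure both conditional and
  marginal estimators degrade, the conditional one less.
- **Known pair:** one planted partial correlation of 0.6 between a
  cyanobacterial and a haptophyte ASV; detected in ≥ 9/10 seeds, an
  arbitrary planted-independent pair in ≤ 1/10.
- **Calibration:** ANOSIM on random groupings and module–trait tests on
  permuted traits, 200 replicates each; p-values uniform (KS test at
  α = 0.01) and type-I error inside the binomial band.
- **Integration:** communities with both planted modules and a planted
  modular graph (204 samples); candidates from the trait-linked module
  recover, at the median, ≥ 60% of their planted positive partners among
  their top-10 positive neighbours, with same-module enrichment of positive
  edges.

These sizes keep the full suite and the acceptance script to a few minutes
on one CPU while leaving each estimator enough data to meet its published
operating characteristics.

## Numerical details and edge cases

- Rarefaction at exactly the sample total returns the sample unchanged;
  samples below depth are dropped and logged.
- Kernel construction reports rank 0 (instead of failing) when all samples
  are identical; samples with zero group abundance are dropped or imputed
  uniformly, per configuration.
- V or XᵀV⁻¹X near singularity gets a 1e-8 ridge; a kernel numerically
  equal to the identity is flagged as aliased with the residual rather than
  silently split.
- glmnet paths that stop early on degenerate data reuse the nearest fitted
  λ; constant CLR columns are skipped.
- StARS returns the sparsest λ with a flag when no λ meets the instability
  bound; the odds ratio is NA when one sign margin has no edges.
- Box–Cox shifts non-positive responses by min + 0.1% of the range and
  records the shift.

## Known limitations

- The static-cut-plus-refinement module detector is an approximation of
  the dynamic hybrid tree cut; very unbalanced or nested module structures
  may still split or merge differently than WGCNA's reference
  implementation.
- Fraction estimates from highly collinear group kernels (groups whose
  compositions turn over along the same gradient) trade variance between
  components; the benchmarks quantify this at n ≈ 200.
- Neighbourhood selection estimates the precision support, not the
  covariance; symmetrised lasso coefficients are useful edge weights but
  are not partial correlations on a calibrated scale.
- No multiple-testing correction is applied to module–trait p-values by
  default, by design parity with how such tables are reported; use the BH
  option for screening many modules.
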