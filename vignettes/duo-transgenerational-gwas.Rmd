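---
title: "Maternal-effect and mother-child interaction GWAS in case-control duos"
author: "duogwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal-effect and mother-child interaction GWAS in case-control duos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duogwas)
```

## The problem and the design

A case-control sample of mother-child pairs ("duos") supports three
distinct questions at every biallelic marker: does the **child's**
genotype shift disease risk (an ordinary case-control GWAS), does the
**mother's** genotype shift the risk of having an affected child
independently of inheritance (a maternal main effect, e.g. via the
prenatal environment), and does a **combination** of maternal and
offspring genotypes carry risk beyond both main effects
(transgenerational epistasis, e.g. maternal-fetal genotype
incompatibility)? Because mothers transmit half their alleles, the
three signals masquerade as one another; this package implements the
scan-then-dissect design: stratified Cochran-Mantel-Haenszel (CMH)
screens for each hypothesis, followed by likelihood-ratio tests in a
multinomial model that can separate them.

## Genotype representation

Genotypes are a1-allele dosages in {0, 1, 2, NA}. The a1 allele is
fixed per marker by an explicit allele-reference table rather than by
observed frequency: frequency-based coding can flip between the
maternal and child sample sets, which would silently corrupt every
pair-level classifier. Positions are 1-based (MAP convention); no
strand flipping is attempted; there is no imputation anywhere in the
discovery pipeline.

## Quality control

`apply_qc()` applies, in order: a per-sample call-rate filter
(strictly > 0.97), a per-marker call-rate filter (fail iff < 0.97) run
separately in the maternal and child sets with the combined panel being
the **intersection** of the two passing sets, a duo Mendelian-error
filter (a marker fails with more than 10 opposite-homozygote duos — the
only duo-detectable Mendelian inconsistency at a biallelic locus), and
a Hardy-Weinberg exact-test filter in **control mothers**
(fail iff P < 1e-10). The HWE test uses the standard (not mid-p)
two-sided tail — the sum of probabilities of all heterozygote counts no
more probable than the observed one — enumerated in log space, exact up
to totals around 1e5.

Two diagnostics are reported but never auto-exclude: the inbreeding
coefficient `F = (O_hom − E_hom)/(L − E_hom)` computed against
frequencies estimated in control mothers (flag at F < −0.15, a value
judgment standing in for an outlier call on contamination), and the
duo IBS0 rate / moment-estimator pi-hat (a true parent-offspring pair
has IBS0 = 0 and pi-hat ≈ 0.5; the misidentification flag defaults to
IBS0 > 0.01).

## Stratification and the choice of K

Population structure is handled empirically: complete-linkage
agglomerative clustering on the 1 − IBS distance, with the cluster
count K the only tuning parameter. Mothers and children are clustered
separately; the maternal solution stratifies the maternal and
pair-classifier tests and the proband solution the proband test. For
each K in 1..k_max the package computes the genomic inflation
λ = median(X²)/qchisq(0.5, 1) of the proband and maternal genome-wide
scans and selects the K minimizing `max(|λ_p − 1|, |λ_m − 1|)`, ties
toward the smaller K. The max-deviation form is a deliberate choice
where "overall inflation" is otherwise ambiguous: it penalizes
deflation (over-stratification) symmetrically with inflation, and a
joint criterion prevents one scan being calibrated at the other's
expense. The λ-vs-K scans may be thinned (`thin` in
`pipeline_config()`) to bound cost on very dense panels.

## The five scans

All five discovery models reduce to stratified 2×2 tables tested by the
1-df CMH statistic without continuity correction (the conventional
form; the correction would shift borderline P-values). Strata
contribute nothing when they hold fewer than two observations or have a
zero margin; a marker whose strata all drop is reported untestable
(P = NA) rather than erroring out of a genome-wide loop.

The three pair classifiers partition every (mother, child) dosage
combination: opposite homozygotes are excluded as Mendelian errors
(they are genotyping artifacts by the QC logic, not "unexposed"
biology), missing pairs are excluded, and the remainder is exposed or
unexposed. Two classifier modes are provided because the discovery-side
treatment of uninformative pairs is genuinely ambiguous:

* **literal** (default): every Mendelian-consistent complete pair is
  classified — e.g. the offspring-heterozygous model calls (child het,
  mother hom) exposed and everything else unexposed;
* **conditioned**: mirrors the trio replication analogues by
  additionally excluding homozygous-child pairs (offspring-het model)
  or homozygous-mother pairs (maternal-het model) as uninformative.

Both modes satisfy the same invariants (partition, allele-label
invariance, exposure implies the defining heterozygosity).

## The multinomial likelihood and its LRTs

Under HWE and random mating at allele frequency *q*, the population duo
distribution is `μ(m, c) = HWE(m; q) · P(c | m, q)` with the mother
transmitting a1 with probability m/2 and a random-mate father with
probability q. Risk is multiplicative:
`ρ(m, c) = R₁^c-copies · S₁^m-copies · J^[exposed cell]`, with
`R₂ = R₁²` and `S₂ = S₁²` enforced. Case duos follow μρ renormalized;
control duos follow μ itself.

Two modeling decisions matter. First, the baseline risk α is absorbed
by the multinomial normalization: with ascertained case/control counts
only *relative* risks are identifiable, so α is not a free parameter.
Second, controls are modeled as population duos — a rare-disease
approximation appropriate when prevalence is ≪ 1 (the synthetic
generator defaults to α = 0.01 precisely so this approximation holds
in-simulation). The interaction indicator in the likelihood matches the
literal classifier mode and switches with it for internal consistency.

Optimization is on log risk parameters (|ln θ| ≤ ln 50) and
logit-frequency, by L-BFGS-B from three starts (free risk parameters at
0.5, 1, 2), with a 1e-8 log-likelihood tolerance; when *q* is held
fixed it is pinned at its moment estimate from the control duos.
Non-convergence across all starts is flagged, not thrown. The two
standard tests are maternal ({q,R₁,S₁} vs {q,R₁}) and transgenerational
({q,R₁,S₁,J} vs {q,R₁,S₁}), each 1 df.

## Replication in trios

Family data replace the missing control duos: the transmission
disequilibrium test replicates proband effects; the mother-vs-father
allele-frequency test replicates maternal effects (assuming maternal
effects are maternal-specific — a general parental effect acting in
both parents is invisible to this contrast); and three trio analogues
replicate the classifiers. "Opposite genotype" in the difference
analogue is read as *genotype not identical to the proband's*,
consistent with the discovery model's identical/non-identical
dichotomy. Per-dataset log odds ratios (Woolf standard errors, with a
Haldane-Anscombe 0.5 only when a cell is zero and the merged path is
not taken) are pooled by DerSimonian-Laird random effects; when any
dataset has an empty cell the per-dataset tables are summed and a
single merged chi-square reported instead. The Bonferroni gate divides
0.05 by the number of marker-model results carried into replication and
additionally requires the replication effect to point the same way as
the discovery effect.

## The synthetic generator

`sim_duos()` draws each duo's stratum, maternal genotype (HWE at the
stratum frequency), and child genotype (Mendelian transmission plus a
random-mate paternal allele); `sim_trios()` retains the father.
Structure uses the Balding-Nichols model — per-stratum frequencies
Beta-distributed around the ancestral frequency with divergence Fst —
the standard minimal model with a single controllable difficulty dial.
Ancestral frequencies are uniform on (0.05, 0.5); markers are unlinked
(LD is out of scope); the default sample sizes are 366 case and 369
control duos, the discovery study's composition. Status at the causal
marker is drawn from the *exact* conditional distributions
`μ·π/Σ` (cases) and `μ·(1−π)/Σ` (controls) with
`π = min(1, α·bias·ρ)` — equivalent in distribution to rejection
sampling against status quotas, but deterministic in runtime and free
of any rare-disease approximation on the generating side. An optional
per-stratum bias multiplier on α confounds status with stratum to
exercise the stratification machinery.

What the generator does **not** emulate — linkage disequilibrium,
genotyping-error structure beyond uniform missingness, assortative
mating, X-linked inheritance, and the real study's self-reported
ancestry mixture — bounds what passing tests demonstrate: calibration
and recovery under the model's own assumptions, not robustness to every
feature of real array data.

## Numerical choices and degenerate inputs

* CMH/Pearson statistics are computed in double precision from integer
  counts (coerced up front; products of 2×2 margins overflow 32-bit
  integers at realistic sample sizes).
* HWE enumeration compares tail probabilities with a 1e-12 relative
  slack so ties at the observed probability are included.
* The IBS distance is a rescaled Manhattan distance, which handles
  missing calls by averaging over the jointly observed markers; a pair
  with zero overlap is an error.
* Zero or undefined odds ratios are reported as NA and written as the
  literal token `NA`.
* Cluster assignments are deterministic given input order; with
  continuous IBS distances ties have measure zero.

## Problem sizes used by the test suite

The suite exercises the pipeline at desk scale, chosen to keep each
property statistically decisive: type-I calibration over 1e4 null
markers at 366/369 duos; structure correction at Fst 0.2 over 5e3
markers; MMLM recovery over 200 replicates of 2,000 duos and null-LRT
calibration over 1,000 replicates; trio-test calibration over 1e4
markers at 500 trios; end-to-end determinism on a 5,000-marker,
735-pair run; and the power computation at 385/379 with 2,000 replicate
markers.

## Known limitations

* The trio analogues treat the mother and father of the same trio as
  independent observations, as the replication design specifies. For
  the offspring-heterozygous analogue this is consequential:
  conditioning on a heterozygous child makes the parents' homozygosity
  *negatively* correlated (at q = 0.3, P(both parents homozygous | het
  child) = 0.21 against 0.25 under independence), so the unmatched
  chi-square rejects a true null at roughly 0.075 instead of 0.05. A
  matched McNemar-type test on discordant parent pairs would restore
  calibration; it is noted here rather than silently substituted
  because the replication analyses are defined as unmatched tests.
* The maternal-vs-paternal contrast cannot detect parental effects
  shared by both parents.
* The exact HWE test is conservative at small counts (discreteness),
  so its null rejection rate sits below nominal.
* Only biallelic, autosomal, unlinked markers are supported; BED/BIM
  binary formats and VCF ingestion are out of scope.
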