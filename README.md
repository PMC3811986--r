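# duogwas

Genome-wide tests of **maternal genetic main effects** and
**mother-child genotype interaction** (transgenerational epistasis) in
case-control mother-child pair ("duo") data, with family-based trio
replication.

Most association studies ask only whether the affected individual's own
genotype shifts disease risk. Two further mechanisms are biologically
plausible, especially for neurodevelopmental phenotypes: the *maternal
genotype* may shape the prenatal environment independently of what the
child inherits, and particular *combinations* of maternal and offspring
genotypes (for example allele configurations resembling maternal-fetal
incompatibility) may carry risk that neither main effect explains.
`duogwas` implements a complete, testable pipeline for screening both on
a genome-wide scale from case-control duos, for statistical geneticists
working with PLINK-era PED/MAP genotype data.

## The tests

For each biallelic marker with a1-dosage coding (genotypes 0/1/2):

* **Proband and maternal main effects** — a 1-df Cochran-Mantel-Haenszel
  (CMH) allele-frequency test between cases and controls, run in the
  children and (with "affected" meaning *mother of a case child*) in the
  mothers. With per-stratum 2×2 tables [[a,b],[c,d]] the statistic is

  `X² = (Σₖ aₖ − Σₖ Eₖ)² / Σₖ Vₖ`,  `E = (a+b)(a+c)/n`,
  `V = (a+b)(c+d)(a+c)(b+d) / (n²(n−1))`,

  with the Mantel-Haenszel common odds ratio
  `OR = Σ(aₖdₖ/nₖ) / Σ(bₖcₖ/nₖ)` and no continuity correction.

* **Three binary mother-child classifiers**, each tested by the same
  stratified CMH on exposed/unexposed pair counts:
  *offspring-heterozygous* (the child carries an allele the mother
  lacks: child het, mother homozygous), *maternal-heterozygous* (the
  mother carries an allele the child lacks), and *difference* (mother
  and child genotypes not identical). Opposite-homozygote pairs are
  Mendelian-impossible and excluded.

* **Stratification** — samples are clustered by complete linkage on
  1 − IBS (identity-by-state) distance; the cluster count K is chosen to
  minimize the genomic inflation factor
  `λ = median(X²) / qchisq(0.5, 1)` of the proband and maternal scans.

* **Multinomial maximum-likelihood model (MMLM)** — duo genotype counts
  follow a multinomial over mother×child cells with population
  distribution given by HWE and random mating at frequency *q*, and
  multiplicative risks `R₁` per child allele copy (`R₂ = R₁²`), `S₁` per
  maternal copy (`S₂ = S₁²`), and an interaction multiplier `J` on the
  active model's exposed cells. Nested likelihood-ratio tests show
  whether a maternal hit survives removal of `S₁` given `R₁`, and
  whether an interaction hit survives removal of `J` given both main
  effects: `2Δln L ~ χ²₁`.

* **Trio replication** — transmission disequilibrium test,
  mother-versus-father allele-frequency test, and trio analogues of the
  three classifiers (e.g. among heterozygous-offspring trios, homozygous
  mothers versus homozygous fathers), combined across datasets by
  DerSimonian-Laird random-effects meta-analysis (with a merged-counts
  fallback when a dataset has an empty cell) and gated by Bonferroni
  correction plus effect-direction agreement.

A seeded synthetic-data generator (`sim_duos()`, `sim_trios()`,
`sim_null_genome()`) produces duo and trio datasets under the same risk
model, with optional Balding-Nichols population structure, so every
stage is testable without external data.

## Worked example

Simulate 735 duos (366 case / 369 control) with a planted maternal
effect (`S₁ = 2` at a MAF-0.30 marker) and run the discovery pipeline:

```r
library(duogwas)
sim <- sim_duos(sim_config(n_markers = 2000, seed = 7,
                           risk = list(model = "maternal", s1 = 2,
                                       maf = 0.3), causal = 1))
res <- run_discovery(sim$gm_m, sim$gm_c, sim$duos,
                     pipeline_config(k_max = 2, seed = 7))
res$lambda_table
#>   K lambda_proband lambda_maternal  criterion
#> 1 1       1.012055       0.9636194 0.03638065
#> 2 2       1.017466       0.9693731 0.03062692
res$report[res$report$marker == "snp00001",
           c("marker", "model", "stat", "p", "or_mh", "lrt_p")]
#>     marker    model stat        p or_mh    lrt_p
#> 1 snp00001 maternal 46.4 9.86e-12  2.11 1.07e-12
#> 3 snp00001  proband 27.0 2.00e-07  1.78       NA
```

The genome is structure-free, so both candidate stratifications leave
λ ≈ 1. The causal marker tops the maternal scan (CMH OR 2.11, close to
the planted per-copy risk of 2); the proband scan also lights up because
the child inherits half the maternal risk alleles — exactly the
confounding the likelihood-ratio test resolves: LRT P ≈ 1e-12 means the
maternal effect is *not* explained by the child's own genotype. Rows
from the three interaction scans would appear here with their own LRT
columns; under a pure maternal main effect none reaches the suggestive
tier.

Power of the allelic test at the discovery sample size:

```r
allelic_power(n_case = 385, n_control = 379, maf = 0.30, grr = 2.0,
              alpha = 5e-8, n_rep = 2000, seed = 1)$power
#> [1] 0.8595
```

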