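# mtgblup

Single-trait versus multi-trait GBLUP genomic prediction, evaluated on
simulated breeding populations.

In genomic selection a model trained on a phenotyped, genotyped reference
population predicts breeding values for genotyped but unphenotyped
selection candidates.  Most programmes still model one trait at a time,
although economically important traits are often genetically correlated;
a multi-trait model can exploit that correlation, at the cost of a harder
variance-component estimation problem.  `mtgblup` is for quantitative
geneticists and breeding researchers who want to quantify that trade-off
under controlled genetic backgrounds: it simulates the whole experiment —
genomes, matings, traits — and fits both models to the same data.

## What it computes

Single-trait GBLUP mixed model:

    y = 1μ + Zg + e,   g ~ N(0, G σ²ₐ),   e ~ N(0, I σ²ₑ)

with the VanRaden genomic relationship matrix
`G = MM' / Σⱼ 2pⱼ(1−pⱼ)` (dosages centred by 2pⱼ).  The bivariate model
stacks two traits with additive covariance `G ⊗ M` and residual
covariance `I ⊗ R`, where `M` and `R` are free 2×2 matrices.  Variance
components are estimated by average-information REML (with covariance
bending and an ascent-guaranteed line search); candidate breeding values
come from the mixed-model equations; model performance is the squared
correlation between predicted and true breeding values over the
candidates.

The surrounding simulation machinery provides:

* founder genomes with geometrically decaying LD (`simulate_founders`),
  PLINK bed/bim/fam and ped/map I/O (`read_plink`, `write_plink`), and
  chip-style QC with an exact Hardy–Weinberg test (`qc_filter`,
  `hwe_pvalue`);
* F1 construction under a 1:24 sire:dam design with 12 offspring per dam
  and 4–6 crossovers per chromosome per gamete (`mating_design`,
  `build_f1`, `sample_candidates`);
* genetically correlated trait pairs built from LD-matched QTL pairs
  carrying identical signed Gamma(0.4, 2/3) effects
  (`simulate_trait_pair`), with residual variance set from
  `h² = V_g/(V_g+V_e)`;
* scenario drivers sweeping heritability × genetic correlation ×
  reference size with replicate-level seeding (`run_scenario1`,
  `run_scenario2`, `summarize_scenario`), and a small CLI
  (`exec/mtgblup`).

## Worked example

Simulate 500 phenotyped founders, an F1 candidate set, a trait pair with
heritability 0.3 and genetic correlation 0.8, then fit both models:

```r
library(mtgblup)

pan  <- simulate_founders(500, n_chrom = 2, snps_per_chrom = 1000,
                          n_males = 20, seed = 1)
des  <- mating_design(pan, dams_per_sire = 24, offspring_per_dam = 12, seed = 2)
f1   <- build_f1(pan, des, seed = 3)
cand <- sample_candidates(f1$panel, 400, seed = 4)
all  <- combine_panels(pan, subset_panel(f1$panel, cand))

sim <- simulate_trait_pair(all, trait_spec(0.3), trait_spec(0.3),
                           target_r = 0.8, founder_ids = pan$ids, seed = 5)
cor(sim$trait_a$tbv, sim$trait_b$tbv)
#> [1] 0.8038974

G  <- compute_grm(dosages(all))
ya <- sim$trait_a$phenotype[pan$ids]
yb <- sim$trait_b$phenotype[pan$ids]

gblup(ya, G)
#> Single-trait GBLUP fit (AI-REML), 500 phenotyped of 900 individuals
#> Variance components:
#> sigma_a2 sigma_e2
#>  64.2940 192.4691
#> Heritability: 0.250
#> Restricted log-likelihood: -1623.9645 (converged, 8 iterations)

fitm <- gblup(cbind(A = ya, B = yb), G)
fitm
#> Bivariate GBLUP fit (AI-REML), 500 phenotyped of 900 individuals
#> Variance components:
#>  sigma_g1 sigma_g12  sigma_g2  sigma_e1 sigma_e12  sigma_e2
#>   64.5147   65.7771   79.3095  191.3955    6.1751  201.5206
#> Heritabilities: 0.252 / 0.282; genetic correlation: 0.920
#> Restricted log-likelihood: -3245.6784 (converged, 9 iterations)

fit1 <- gblup(ya, G)
accuracy(predict(fit1, cand)[, 1], sim$trait_a$tbv[cand])
#> [1] 0.3076028
accuracy(predict(fitm, cand)[, "A"], sim$trait_a$tbv[cand])
#> [1] 0.4814004
```

The single-trait model recovers the simulated heritability (0.25 vs 0.3,
within sampling error at n = 500) and the bivariate model roughly doubles
the information available for trait A through its 0.8-correlated partner,
lifting candidate accuracy from 0.31 to 0.48 in this configuration.  Note
the genetic-correlation estimate (0.92) exceeds the simulated 0.8 — a
known property of this trait architecture at desk scale, discussed in the
methods vignette (`vignettes/multitrait-gblup.Rmd`).

Scenario sweeps follow the same pattern at larger scale:

```r
cfg <- scenario_config(ref_sizes = 800, n_replicates = 20,
                       n_candidates = 500, seed = 11)
res <- run_scenario1(cfg)
summarize_scenario(res)   # mean/sd accuracy per cell + improvement column
```

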