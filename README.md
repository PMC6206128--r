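# pondmix

Inference tools for secondary contact zones ("hybrid zones") studied
with multi-allelic co-dominant markers (microsatellites) and a
maternally inherited sequence marker (mtDNA), the classic design for
fine-scale gene-flow studies in amphibians and reptiles such as pond
turtle contact zones.  The package covers the full chain such a study
runs:

* **Admixture clustering** — an EM fit of the admixture model
  (P(allele) = Σₖ q·f per copy), giving per-individual ancestry
  proportions *Q* and cluster allele frequencies, with Evanno ΔK
  selection of the cluster number over replicate runs.
* **Hybrid classes and ancestry thresholds** — simulation of F1, F2
  and backcross genotypes from two parental pools (Mendelian gametes
  from realised F1s) and calibration of the mixed-ancestry threshold
  (the conventional *Q* < 0.85 rule ships as default).
* **Geographic clines** — the equilibrium cline model
  f(x) = (1 + tanh(2(x−c)/w))/2 with exponential introgression tails
  and three frequency scalings (the classical 15-model family), fitted
  by Metropolis–Hastings MCMC to per-site mean *Q* or mtDNA lineage
  frequencies against great-circle transect distances, with AIC model
  selection.
* **Demographic ABC** — a structured coalescent under explicit
  admixture-pulse scenarios (stepwise-mutation microsatellites,
  Jukes–Cantor mtDNA at Ne/4), the classical ten-summary-statistic
  design, and closest-1% rejection with optional local-linear
  regression adjustment; times convert to years at 15 y/generation.
* **Diversity & divergence** — Nei-unbiased heterozygosities, rarefied
  allelic richness, private alleles, Weir–Cockerham F_ST with
  permutation tests, one-level AMOVA, dosage PCA, and a null-allele
  screen (Brookfield estimator + homozygote-excess test).
* **Haplotype networks** — minimum-spanning networks on Hamming
  distances with tie-equivalent edges and within/between-lineage
  mutational step summaries.
* **Synthetic data with ground truth** — drifted parental taxa
  (Balding–Nichols model, F_ST dialled directly), transects crossing a
  known cline, star-phylogeny mtDNA lineages and a cytonuclear
  discordance knob, so every stage is testable end to end.

## Worked example

Simulate a two-taxon hybrid zone with a cline of known centre
(500 km) and width (40 km), select the cluster number, and fit the
cline to per-site mean ancestry:

```r
library(pondmix)

taxa <- make_taxa(2, n_loci = 15,
                  F_vector = rep(drift_for_fst(0.3), 2), seed = 11)
sim <- simulate_transect(taxa[[1]], taxa[[2]],
                         true_center_km = 500, true_width_km = 40,
                         site_positions_km = seq(0, 1000, length.out = 11),
                         n_per_site = 12, seed = 11)

ks <- run_replicates(sim$genotypes, 1:3, n_reps = 4, seed = 1,
                     max_iter = 300)
ks
#> Evanno delta-K selection
#>    K  mean_lnL       sd_lnL    deltaK
#> K1 1 -6623.948 0.000000e+00        NA
#> K2 2 -5314.126 4.627925e-06 256349927
#> K3 3 -5190.672 1.861859e+01        NA
#> selected K = 2

fit <- ks$best_fit[[paste0("K", ks$selected_K)]]
mq <- mean_q_per_site(fit, sim$sites, cluster = 2)
tro <- transect_data(sim$sites, "t1",
                     data.frame(site = mq$site, freq = mq$mean_Q,
                                n = 2 * mq$n))
fit_cline_mcmc(tro, "fixed", "none", iterations = 18000,
               burnin = 2000, seed = 1)
#> cline_fit [fixed scaling, none tails]: centre 498.67 km
#> (95% CI 480.03-506.55), width 15.87 km (6.36-120.35), AIC 7.62
```

The ΔK curvature ratio picks K = 2 (the huge value reflects replicate
runs converging to one optimum on cleanly separated taxa), and the
fitted cline centre lands within a few kilometres of the generating
truth, with the 95% credible interval covering it.  Width is
underestimated here because per-site mean *Q* is smoother than a raw
binomial frequency — the effective steepness of ancestry means exceeds
that of allele counts, a known feature of mean-Q clines.

The same stages run as a pipeline over a YAML config:

```sh
Rscript inst/scripts/pondmix all --seed 1 --out pondmix_out
```

which writes genotypes, alignments, diversity tables, Q matrices,
cline fits, a haplotype network, an ABC posterior and a manifest
tracing every artifact to the config and seed.

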