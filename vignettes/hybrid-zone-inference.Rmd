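---
title: "Hybrid-zone inference with pondmix: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-zone inference with pondmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondmix)
```

## The problem

When two or more divergent lineages meet after range shifts — the
motivating system is a three-taxon contact zone of European pond turtle
subspecies along a mountain barrier — four questions recur: how many
genetic clusters are present and who belongs to which; which
individuals are recent hybrids rather than pure representatives; how
sharply does ancestry turn over in space; and when and how strongly did
the lineages mix.  `pondmix` implements that full chain for the two
marker systems classically used at this scale: co-dominant,
multi-allelic microsatellites and a maternally inherited mtDNA
sequence fragment (1031 bp is the package's alignment-length
convention).  Every stage can be exercised on synthetic data with
known truth, which is how the package validates itself.

## The admixture model

Ancestry is estimated under the standard admixture likelihood: allele
copy $a$ at locus $l$ in individual $i$ has probability
$\sum_k q_{ik} f_{kla}$, where $q_{ik}$ is the fraction of $i$'s genome
from cluster $k$ and $f_{kla}$ the allele frequency in that cluster.
Copies are treated as independent (unlinked loci, unphased genotypes);
missing copies contribute nothing.  We maximise this likelihood by EM
rather than sampling it by MCMC: the E-step distributes each allele
copy over clusters, the M-step re-estimates $Q$ and $F$, and the
log-likelihood is provably non-decreasing — the package asserts this on
every iteration in its tests.  Frequencies are modelled independently
per cluster (no correlated-frequency prior); for the well-separated
clusters this pipeline targets, the $Q$ semantics are the same and the
result is deterministic given a seed.  Initialisation takes $Q$ from a
flat Dirichlet and $F$ from jittered empirical frequencies;
convergence defaults are a `1e-6` log-likelihood tolerance and 2000
iterations.  The burn-in/chain-length settings familiar from Bayesian
clustering tools (250,000 + 750,000) are carried in the pipeline config
as descriptive metadata only; they do not govern EM.

The number of clusters is chosen by the Evanno curvature ratio:
$\Delta K = |\bar L(K-1) - 2\bar L(K) + \bar L(K+1)| \,/\, \mathrm{sd}(L(K))$
over replicate runs (default 10 per $K$), applied to the EM maximum
log-likelihoods in place of a marginal-likelihood estimate — the two
track each other for the model-selection purpose served here, and the
equivalence is flagged rather than assumed silently.  One genuine edge
case: on cleanly separable data every replicate converges to the same
optimum, the replicate SD collapses to zero, and the ratio is formally
undefined.  Zero spread with non-zero curvature is overwhelming
support, not missing evidence, so the package substitutes a small SD
floor (`1e-6`) and flags the substitution instead of failing over to a
different criterion (maximum mean likelihood would systematically pick
the largest $K$).

Uneven sampling biases clustering, so sites contributing 25 or more
individuals are reduced to a random 20 before fitting; both numbers
are arguments.

## Hybrid classes and the mixed-ancestry threshold

Hybrid categories are simulated from two parental pools the way
dedicated hybrid-simulation software defines them: F1 draws one allele
per locus from each pool's empirical allele pool; F2 and backcross
gametes segregate from *realised* F1 genotypes, one allele of the two
per locus at random, rather than from pooled F1 frequencies.  This
makes the Mendelian invariants exact: F1 heterozygosity is 1 wherever
the pools share no alleles, and the F2 heterozygote fraction at such
loci is 1/2 in expectation.

The conventional cut-off — individuals with maximum cluster membership
below 85% have mixed ancestry — ships as the default.  Because the
source convention states the outcome but not the rule behind it, the
calibration routine makes a rule explicit: fit $K=2$ to parents plus
simulated hybrids, take the 1st percentile of pure max-$Q$ and the
99th percentile of backcross max-$Q$, and propose their midpoint
(clamped to $(0.5, 1)$; if the percentiles cross, fall back to 0.85
with a flag).  Confusion tables at both the proposed and the 0.85
threshold are always reported.  The boundary convention is documented
and tested: a membership exactly at the threshold counts as pure.

## Geographic clines

Per-site ancestry (mean $Q$) or mtDNA lineage frequency is fitted
against cumulative transect distance (haversine on WGS84 coordinates,
Earth radius 6371 km).  The central cline is
$f(x) = (1 + \tanh(2(x - c)/w))/2$ with centre $c$ and width $w$ (the
inverse of the maximum slope).  Tails attach beyond junctions at
$c - \delta_L$ and $c + \delta_R$ as exponentials that match the
sigmoid's value there, with slope $\tau$ times the sigmoid's junction
slope: $\tau = 1$ is C1-continuous, $\tau < 1$ flattens the tail into a
longer shoulder of introgression.  Value-matching makes continuity and
monotonicity hold by construction — both are asserted on random
parameter draws — which is why this parametrisation was chosen over
fitting unconstrained tail curves.  Scaling is `fixed` (0 to 1),
`observed` (data min/max) or `free` ($p_{\min}, p_{\max}$ estimated);
crossed with five tail options this gives the classical 15-model
family, compared by $AIC = 2k - 2\ln L_{max}$ with ties broken toward
fewer parameters.

The likelihood is binomial per site with effective counts: two nuclear
lineages per diploid individual for mean-$Q$ data, haploid counts for
mtDNA.  Sampling is Metropolis–Hastings with joint Gaussian proposals
whose scales adapt only during burn-in (preserving detailed balance
afterwards); the study-scale budget is 10,000 burn-in + 90,000
iterations, and the package's own experiments use 2,000 + 18,000,
which the recovery tests show is ample for 15-site transects.  Priors
are uniform: centre over the transect span expanded by half a span each
side, width log-uniform on [0.1 km, twice the span], tail distances
uniform on [0, span], $\tau$ and scaling bounds uniform on (0, 1].
After sampling, the best state is polished by Nelder–Mead so the AIC
rests on a stable likelihood maximum rather than on MCMC noise; for
the two-parameter models (no tails, fixed or observed scaling) the
marginal 95% credible intervals are additionally computed by exact
quadrature on a (centre, log width) grid, because MCMC quantile
endpoints carry Monte-Carlo error of a few tenths of a kilometre that
matters exactly when an interval boundary sits near a value of
interest.  Degenerate transects (all frequencies equal) are flagged:
the width is then unidentifiable and the fit should not be
interpreted.

## Demographic inference by ABC

Two admixture demographies mirror the study design.  The Atlantic-range
scenario has two parentals and one admixed population formed by a
single pulse $t$ generations ago with rate $r$; the
Mediterranean-range scenario has three parentals, an unsampled
intermediate admixed pool, and two dated pulses ($t_1 < t_2$) with
rates $r_1, r_2$.  Events are declared backward in time (admixture
pulses redirect each lineage to one source with probability $r$;
merges pool populations), so arbitrary scenario variants can be
declared with the same constructor.  Priors follow the study: sizes
and admixture times uniform on 10–10,000, divergence times uniform on
10–100,000 generations, rates uniform on (0.001, 0.999), with event
times kept ordered by rejection.

The simulator is a structured coalescent per locus.  Microsatellites
are diploid (two lineages per individual) with strict stepwise
mutation — one repeat up or down, reflecting at a lower bound — and
per-locus rates drawn log-uniformly in $[10^{-4}, 10^{-3}]$ per
generation; a generalised (multi-step) model was considered and left
out because the downstream statistics at these depths are insensitive
to it.  mtDNA is one haploid, maternally inherited locus at effective
size $N_e/4$ with Jukes–Cantor finite-sites substitution at a per-site
rate in $[10^{-9}, 10^{-7}]$ per generation; at cytochrome-b depths
this is far from saturation, so a richer substitution model would add
parameters without information.  Whether the source's mtDNA bounds are
per year or per generation is ambiguous; per generation is adopted and
stated here.

Ten summary statistics form the rejection space: per population, mtDNA
haplotype count, segregating sites, mean pairwise differences and
private segregating sites; per population pair, mean pairwise
differences within (W) and between (B) and haplotype-frequency
$F_{ST}$; for microsatellites, mean allele count, mean unbiased gene
diversity, and pairwise Weir–Cockerham $F_{ST}$.  They are computed by
the same code paths as the package's diversity module, and a test
asserts exact equality.  Rejection standardises statistics by the
reference table's median absolute deviation (robust to the long-tailed
distributions these statistics have under wide priors; an SD option
exists), drops zero-MAD statistics with a warning, and keeps the
closest `ceil(tolerance * N)` rows — 1% of $10^5$ at study scale,
with a desk-scale default of $10^4$.  A local-linear regression
adjustment is available and is what the package's own recovery
experiments use: the conditional-mean regression is trained on the
closest 10% of the table (Epanechnikov-weighted, logit transform for
rate parameters) — the retained 1% alone is too sparse in statistic
space to estimate the local slope stably — and each retained draw is
shifted by the fitted mean difference, the classical regression-ABC
correction.  Plain rejection summaries are available alongside.  Scenario choice pools tables and takes each
scenario's share among the globally closest rows.  Times convert to
years at 15 years per generation, the life-history value for
long-lived freshwater turtles.

## Synthetic data: what it emulates and what it does not

The generator produces exactly the structure the pipeline expects to
meet: parental taxa drifted apart under a Balding–Nichols Dirichlet
model (each taxon's frequencies drawn around shared ancestral
frequencies with concentration $(1-F)/F$), with 12–29 alleles per
locus by default.  Under this model the expected pairwise
Weir–Cockerham $\theta$ between two taxa equals $F$ itself, so
`drift_for_fst()` is an identity with the derivation documented —
differentiation from weak (0.08) to strong (0.36) is dialled directly.
Transects place sites along a line; each allele copy at position $x$
originates from the far taxon with probability
$(1 + \tanh(2(x-c)/w))/2$, and each individual's mtDNA lineage follows
its majority nuclear origin except for a `discordance` fraction
(default 0.2, an arbitrary but stated value — no quantitative
discordance rate is available to copy) whose lineage is re-drawn
independently, emulating cytonuclear discordance.  mtDNA lineages are
star phylogenies around founder haplotypes a fixed number of
substitutions apart (16 by default), matching the
shallow-within/deep-between pattern of real haplotype networks at
trivial cost.

What this does *not* emulate: linkage, null alleles (added separately
in tests when needed), spatially explicit dispersal, selection against
hybrids, and genealogical noise in the nuclear markers (the ABC module
has its own coalescent for that).  Passing recovery tests on these
data therefore shows the estimators are correct and well calibrated
under the stated models, not that real data meet those models.

## Numerical choices and degenerate inputs

* Missing genotypes: `-9` (two-row dialect) and `000`/`0000`
  (GenePop) both map to one internal missing state; a half-missing
  genotype is rejected rather than guessed.
* Estimators: $H_E$ is Nei's unbiased form $2n/(2n-1)(1-\sum p^2)$
  (the plain form is not offered, to keep Table-style outputs
  unambiguous); allelic richness uses exact hypergeometric
  rarefaction at twice the smallest per-group complete-genotype count
  unless a size is given; monomorphic loci yield $\hat r = 0$ in the
  null-allele screen and are never flagged.
* AMOVA is one level (among/within groups) on squared distances;
  percentages always sum to 100 even when the among-group component is
  negative, which is reported rather than clamped.
* PCA imputes missing dosages with column means — deterministic and
  standard for dosage matrices.
* EM guards: probabilities floored at `1e-12` before renormalising;
  an individual with no scored loci is an error, not a silent NaN.
* Cline fits clamp predicted frequencies to `[1e-9, 1 - 1e-9]` before
  the binomial likelihood; observed scaling widens a zero-width
  frequency range by `1e-6` to stay proper.
* The haplotype network masks every column containing a gap or `N`
  before collapsing (strict policy, default) so step counts are
  comparable across all pairs; pairwise deletion is available and
  changes step counts, which is why strict is the default.
* Tie-equivalent edges: an edge enters the minimum-spanning network
  when its weight equals the bottleneck weight of the MST path between
  its endpoints; a configurable `max_steps` replaces a statistical
  parsimony connection limit, whose probability calculus is out of
  scope.

## Problem sizes used by the package's own experiments

The validation suite runs at deliberately desk-scale sizes chosen to
keep the full chain exercised end to end: two-taxon ancestry recovery
at 15 loci and 20+20 individuals over 20 seeds; cline recovery on
15-site transects with 40 diploids per site at the reduced MCMC budget;
ABC recovery from a $10^4$-row reference table at 12 diploids per
population and 8 loci plus a 600 bp mtDNA fragment.  The study-scale
settings ($10^5$ simulations, 10,000 + 90,000 MCMC iterations, 15
loci, 1031 bp) are the defaults or documented config values
throughout.

## Known limitations

The EM admixture model has no correlated-frequency prior, so very
recently diverged clusters need more loci to separate than a
correlated-frequency sampler would; $\Delta K$ inherits its usual
inability to evaluate $K = 1$; rejection ABC with ten summary
statistics cannot identify all six demographic parameters jointly at
desk scale (the recovery tests target the admixture rate, the
best-identified parameter); and the cline machinery assumes a single
transition per transect — multimodal ancestry profiles need transect
redesign, not a richer model.
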