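# pedpop

Pedigree-based estimation of breeding, adult, and minimum population sizes
from noninvasive multilocus genotypes.

## The problem

For elusive, long-lived carnivores such as brown bears, classical
capture–recapture treats a genotype as a tag and says nothing about age
structure or reproduction. But multilocus genotypes identify
parent–offspring relationships: reconstructing the pedigree of the animals
found during a short intensive survey — backed by decades of opportunistic
hair, scat and dead-recovery sampling — lets us count **breeders**,
including breeders that were never sampled because their offspring were.
`pedpop` is for wildlife geneticists and managers who have such data (or
want to study the estimator's behaviour on simulated data) and need
population bounds that are traceable animal by animal.

## The estimator

Parentage is assigned by likelihood: per locus, the candidate hypothesis
is scored against the unrelated baseline,
`LOD = Σ_ℓ ln(P(g_o | parents, e) / P_HWE(g_o))`, with genotyping error
`e` modelled as per-call replacement by a random Hardy–Weinberg genotype.
Confidence rests on **Δ**, the LOD gap between the best and second-best
candidate, calibrated by Monte-Carlo simulation (10,000 cycles, 150
candidates per offspring, 40% of true parents sampled, 1% mistyping): a
parent pair is accepted with zero mismatches at the 80% threshold, or with
one mismatch at the 95% threshold when both parents independently top the
single-parent rankings; remaining slots go to an 80% single-parent step
with zero mismatches, then to sibship clustering that explains groups of
unassigned offspring with shared **hypothetical parents**. Mitochondrial
haplotypes filter mothers, Y haplotypes filter fathers of sons, and the
reconstructed pedigree is forced to be acyclic.

The demographic step then computes, per sex,

```
N_min = confirmed breeders + parents demonstrably alive in the census year
N_max = N_min + round( Σ s^k  +  alive hypothetical parents )
```

where unresampled parents are discounted by sex-specific annual survival
`s` (0.94 F / 0.89 M) per year since last identification, and parents
estimated past reproductive senescence (30 F / 28 M, via a 7.3-year
generation interval) or exceeding the observed limits on coexisting
generations (4 matrilineal / 3 patrilineal) are ruled dead. Adding bears
with evidence of age ≥ 4 gives adult bounds; a deduplicated census of
bears demonstrably present in the reference year gives the minimum
population size and density.

## Worked example

Simulate a small population with known truth, run the whole pipeline, and
compare:

```r
library(pedpop)
params <- sim_params(years = 2008:2020, n0 = 50, seed = 42)
truth  <- simulate_population(params)
stream <- simulate_sampling(truth)
catalogue <- build_catalogue(stream$samples, stream$genotypes, truth$panel,
                             window = c(2019, 2020))
pedigree <- reconstruct_pedigree(catalogue$individuals, catalogue$genotypes,
                                 truth$panel,
                                 config = assignment_config(n_simulation_cycles = 2000),
                                 seed = 42, window = c(2019, 2020))
estimate <- estimate_population(catalogue$individuals, pedigree,
                                demography_config(reference_year = 2019))
summary(estimate)
```

```
Pedigree-based population estimate (reference year 2019)
  Breeding population size: 18-28 (F), 11-17 (M)
  Adult (>=4 years) population size: 22-32 (F), 19-25 (M)
  Minimum population size: 62 (30 F / 32 M)
  Density: 3.5 / 4.5 bears per 100 km2 (study / forest area)

Minimum population by age class:
         F  M
>=4     19 14
2-3      1  1
1        2  1
0        0  2
unknown  8 14

Parent liveness ledger:
               alive counted-minimum dead-observed
  existing         4               1             6
  hypothetical    13               2             0
```

Reading this: 256 samples resolved to 119 individuals; 18 females and 11
males are confirmed or demonstrably-alive breeders (the interval's floor),
while the ceiling adds survival-discounted unresampled parents and the 13
alive hypothetical parents postulated by sibship clustering. The truth
object records 34 living breeders and 83 bears alive in 2019, so the
breeding interval (29–45 in total) brackets the truth and the minimum
census (62) undercounts it, as designed. `estimate$liveness` is the
per-parent audit ledger behind every counted unit, and `run_pipeline()`
writes all stage artifacts (TSV/CSV/JSON plus a manifest) for a
configuration in one call.

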