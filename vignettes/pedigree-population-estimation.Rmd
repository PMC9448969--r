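---
title: "Estimating breeding and minimum population sizes by pedigree reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating breeding and minimum population sizes by pedigree reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Census methods for elusive, long-lived carnivores usually treat a genotype
as a mere tag for capture--recapture arithmetic. A multilocus genotype
carries much more: with enough loci it identifies parent--offspring
relationships, and a reconstructed pedigree lets us count *breeders* --
including breeders that were never sampled themselves, because their
offspring were. `pedpop` implements this estimator for populations like a
high-density brown bear population sampled over two decades by hair traps,
scat collection and recovery of dead animals, with a final two-year
intensive survey. The package covers the full chain: individual
identification from replicated genotypes, likelihood-based parentage with
calibrated confidence, sibship clustering that postulates unsampled
("hypothetical") parents, and the demographic bookkeeping that turns the
pedigree into population bounds.

## Individual identification

Samples are genotyped at a panel of microsatellite loci (default 21, with
a 6-locus screening subset). A sample that fails to amplify at any
screening locus is discarded. A unique exact match on the screening subset
resolves the sample; otherwise the full panel decides, and a novel
complete profile founds a new individual. The screening subset is
justified by the probability of identity,

$$\mathrm{PI} = \prod_{\ell} \Big( \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2 \Big),$$

which for six loci of ordinary diversity is already far below one in ten
thousand, so collisions are negligible and two identical full-panel
profiles are treated as one animal.

Routine confirmatory re-typing is part of the protocol the data model
assumes: every released genotype reflects at least two independent PCRs,
so the *consensus* per-locus error rate is roughly the square of the
per-PCR rate. The simulator exposes this as `replicates`; the likelihood
model still budgets 1% mistyping per locus, which is deliberately
conservative.

## Parentage likelihoods and the error model

For offspring genotype $g_o$ and candidate parents, each locus contributes
Mendelian transition probabilities: $T_2(g_o \mid g_m, g_f)$ for a trio,
$T_1(g_o \mid g_p)$ with the unknown parent integrated over Hardy--Weinberg
proportions, and the unrelated baseline $T_0(g_o)$ (the Hardy--Weinberg
genotype probability). Genotyping error is modelled as independent
per-locus mistyping of each compared call at rate $e$, a mistyped call
being replaced by a random Hardy--Weinberg genotype. Expanding over which
calls are wrong:

$$P_{\mathrm{trio}} = (1-e)^3 T_2 + e(1-e)^2 (T_{1,m} + T_{1,f}) + \big(e^2(1-e) + e\big) T_0,$$
$$P_{\mathrm{dyad}} = (1-e)^2 T_1 + \big(1 - (1-e)^2\big) T_0.$$

At $e = 0$ this is pure Mendelian segregation and an incompatible genotype
yields a log-likelihood of $-\infty$ (an exclusion); at $e > 0$ exclusions
soften into penalties, which is what lets one mismatching locus be
tolerated where the rules allow it. The LOD score of a candidate (or pair)
is $\sum_\ell \ln (P / T_0)$ over loci called in the offspring and at least
one candidate.

## Delta calibration

Assignment confidence rests on $\Delta$, the LOD gap between the best and
second-best candidate. Thresholds are calibrated by Monte-Carlo
simulation, by default 10,000 cycles with 150 candidate parents per
offspring, each true parent present with probability 0.40, and 1% of loci
mistyped. Per cycle the true parents and the offspring are simulated from
the estimated allele frequencies, candidate sets assembled (candidate
*pairs* for the trio analysis, formed column-wise so that
partially-sampled pairs occur), and $\Delta$ recorded together with
whether the top candidate was the true parent. The threshold for a
confidence level $c$ is the smallest $\Delta$ such that, among cycles at
or above it, a fraction $c$ of the best-candidate assignments is correct.
Cycles in which every candidate is excluded carry no assignment and sort
below every threshold. If the requested confidence is unreachable the
calibrator warns and returns $+\infty$, i.e. never accept.

## The assignment cascade

For every candidate offspring, candidate mothers are females sharing the
offspring's mitochondrial haplotype (unknown haplotypes pass), candidate
fathers are males, additionally Y-filtered for sons; candidates must not
be known dead before the offspring's birth (mothers) or conception year
(fathers), and must be at least four years older when both birth years are
known. Males whose mitochondrial haplotype was never seen in any sampled
female are flagged immigrants: excluded as candidate offspring, retained
as candidate fathers.

The cascade accepts, in order:

1. the best parent pair with zero trio mismatches at the 80% trio
   threshold;
2. the best parent pair with at most one trio mismatch at the 95%
   threshold, provided the same mother and father independently top the
   maternity-only and paternity-only rankings with at most one dyad
   mismatch each;
3. single parents with zero dyad mismatches at the 80% dyad threshold.

A candidate must also beat the unrelated hypothesis outright
($\mathrm{LOD} > 0$); with a single candidate, $\Delta$ is taken against
that baseline. LOD ties break deterministically by candidate id.

After the cascade, pedigree acyclicity is enforced. With unknown ages, a
bear's own offspring is a perfect one-allele match at every locus, so when
the bear's real parents were never sampled (typical of animals already
adult when sampling began) the child can win the ranking. True pedigrees
are acyclic, and these inversions close directed cycles because the same
link is also assigned, correctly, in the other direction. While a cycle
exists, the edge whose assigned parent entered the record latest is
dropped -- in a long-term data set real parents are identified before
their offspring far more often than not. This pass substitutes for the
exhaustive age records a long-running field study would consult.

## Sibship clustering and hypothetical parents

Offspring of the intensive-survey cohort with an empty parent slot are
clustered by pairwise kinship likelihood ratios using the standard IBD
mixtures (unrelated $k = (1,0,0)$, half-sib $(\tfrac12,\tfrac12,0)$,
full-sib $(\tfrac14,\tfrac12,\tfrac14)$). An edge joins two offspring when
the half-sib vs unrelated log-LR is positive (full-sib vs unrelated when
they already share the other parent), and the relevant haplotypes agree.
Groups grow by union-find over edges in decreasing LR order, refusing any
merge that would mix distinct known haplotypes -- plain transitive closure
would happily chain two males with different Y haplotypes through a
shared half-sister, which no single father can explain. Each group becomes
one hypothetical parent, so an unsampled female with several sampled cubs
costs the estimate one bear, not several; this deliberately biases the
maximum bound downward rather than upward. The group's age anchor is the
earliest known offspring birth year (falling back to the earliest first
identification, which can only make the parent look younger, i.e. keeps
it alive -- again conservative only for the minimum side).

## From pedigree to population sizes

All estimates refer to a reference year, the first intensive-survey year.

**Breeders.** Bears identified in the survey window with at least one
pedigree offspring are confirmed breeders. Parents of window-identified
offspring that were not themselves identified in the window are classified
by liveness rules:

* *counted-minimum* -- demonstrably alive at the reference year: mother of
  a cub born in the reference year or the year after, or of a previous
  year's cub that survived to age one (alive until mother--offspring
  separation); father of a cub born the year after (he mated in the
  reference year);
* *dead-observed* -- known dead before the reference year;
* *dead-senescence* -- estimated age at or above 30 (F) / 28 (M), using
  the best lower bound: known birth year, first identification, or the
  oldest offspring's birth year plus the 7.3-year generation interval
  (applied on the real-valued estimate, so 30.3 counts as senescent);
* *dead-generation-limit* -- a hypothetical parent whose chain of living
  same-line descendants would make it a fifth coexisting matrilineal or a
  fourth coexisting patrilineal generation, which long-term monitoring has
  never observed;
* *dead-monitoring* -- an explicit override list for animals known
  missing from an intensively watched area;
* *alive* -- otherwise; a real parent last seen $k$ years before the
  census is discounted to $s^k$ of an individual with sex-specific annual
  survival $s$ (0.94 female, 0.89 male), a hypothetical parent counts 1.

Then per sex
$$N_{\min} = N_{\mathrm{confirmed}} + N_{\mathrm{counted\mbox{-}minimum}}, \qquad
  N_{\max} = N_{\min} + \mathrm{round}\Big(\sum s^{k_i} + N_{\mathrm{hyp,alive}}\Big),$$
with the fractional survival weights summed *before* rounding. Adult
bounds add the bears with evidence of age $\ge 4$ but no breeding record
(known birth year, first identification at least four years back, or a
parent-death bound: a father dead in year $d$ forces birth by $d{+}1$, a
mother by $d$).

**Minimum census.** The deduplicated union of (1) bears identified in the
reference year, including those that died in it; (2) bears whose presence
is inferred from the pedigree (the counted-minimum parents); (3) bears
identified only in the following year with evidence of being at least one
year old then -- anything that could be a cub of that following year is
excluded. Age classes (4+, 2--3, 1, 0, unknown) use exact ages where
known; a lower bound of four or more places a bear in the adult class,
weaker bounds leave it unknown. Density is the census divided by the area
basis, per 100 km².

## The simulator

`simulate_population()` generates the study system: overlapping
generations from an initial population (default 220) across 1998--2020;
survival 0.70 (cubs), 0.85 (yearlings), 0.90 (ages 2--3), then 0.94/0.89
by sex; litters of 1--3 every third year from age five; polygamous mating
with male success low before age nine; 21 loci averaging about 5.8
alleles; seven mitochondrial and seven Y haplotypes; occasional immigrant
males carrying a foreign mitochondrial haplotype; cubs orphaned in their
birth year die with their mother. `simulate_sampling()` layers
heterogeneous detection (low monitoring-period rates, high rates in the
final two intensive years), dead recovery with cementum ages, per-locus
amplification failure and replicated-typing error. Everything is
deterministic given the seed, and the truth object retains the full
pedigree and alive sets.

What the simulator does *not* emulate: space (no home ranges or trap
geometry -- the estimator is aspatial), behavioural heterogeneity in
detection, uncertain cementum ages, heteroplasmy or Y
pseudoheterozygosity (haplotypes are opaque labels), and the full
likelihood machinery of dedicated sibship software. Passing recovery
tests therefore show that the estimator's logic is sound under honest
sampling noise, not that field data meet these idealisations.

## Numerical and design choices

* Allele labels are opaque integers; fragment sizes are never used.
* A locus is fully called or missing; single-allele calls are not
  represented. Samples that resolve to nobody and are incomplete on the
  full panel are discarded rather than founding an individual with an
  incomplete consensus.
* Consensus genotypes: first complete profile wins; later higher-quality
  samples overwrite only behind an explicit flag.
* If both a maternity and a paternity dyad would be accepted for one
  offspring, only the higher-$\Delta$ one is kept, so a dyad route always
  sets exactly one parent; the other slot goes to the sibship stage.
* `round()` (nearest integer) is applied once, after summing fractional
  weights.
* Sub-stream seeds are derived arithmetically from the master seed per
  stage, so stages can be re-run independently and every run is
  reproducible end to end.

Validation in the test suite runs at desk scale, chosen to exercise every
stage while keeping a full check fast: recovery studies use 100 simulated
populations of 50 founders over 13 years with 800 calibration cycles;
precision checks use 60 founders over 15 years with 2000 cycles; the
brute-force exclusion oracle uses panels of two to four loci and up to
three candidates per sex. Defaults in the package itself are the
full-scale study conditions (10,000 cycles, 150 candidates, 220 founders,
23 years).

## Known limitations

* The maximum bound inherits the method's structural caveats: it assumes
  breeders do not outnumber the parents of survey-identified offspring,
  so it underestimates under weak sampling; conversely unresolvable
  liveness keeps some dead parents in it.
* Confidence intervals are not available for bounds of this kind; the
  interval is a bracket, not a credible interval.
* The sibship surrogate reproduces the counts the estimator consumes, not
  the joint-likelihood structure of a full MCMC reconstruction; with few
  shared loci or rich polygamy it will split or lump groups differently.
* With error rates well above the calibrated 1%, exact-match
  identification fragments individuals; the data model assumes replicated
  typing keeps consensus error negligible.
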