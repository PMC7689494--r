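---
title: "Modelling split-drive killer-rescue gene drives with sdkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling split-drive killer-rescue gene drives with sdkr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdkr)
```

## The system being modelled

Split-drive killer-rescue (SDKR) is a threshold-dependent gene drive built
from two transgenic constructs at unlinked, autosomal, freely recombining
loci:

* **Construct A** carries a dominant toxin ("killer") and one or more
  sgRNAs targeting the wild-type sequence at its own locus.
* **Construct B** carries a Cas9 endonuclease and the antidote ("rescue")
  for the toxin on A.

In individuals heterozygous at locus A (`A/wt`) that carry at least one B,
the sgRNA directs Cas9 to cut the wild-type allele; homology-directed
repair copies construct A onto the homologous chromosome ("homing"), so
such individuals transmit A with probability $(1+\Phi)/2$ instead of the
Mendelian $1/2$. As A spreads, the toxin creates selection for carrying
the rescue, pulling B up behind it. Killer-rescue ($\Phi = 0$, $L = 1$)
and split drive ($\Phi > 0$, $L = 0$) fall out as special cases.

Three model variants extend the base system:

* **NHEJ** — a cut wild-type allele may instead be repaired by end
  joining, producing a resistance allele R whose target site can never be
  cut again. Locus A then has three alleles (`wt`, `A`, `R`).
* **Suppression** — construct A additionally carries either a
  female-to-male sex-conversion element (rate $\delta$) or a
  female-specific lethal element (rate $\gamma$), dominant or recessive in
  A; a two-deme configuration couples a target population to a non-target
  neighbour by unidirectional migration.
* **DDKR** — a third construct C carries a sgRNA that lets Cas9 home
  construct B, daisy-chain style, so B itself is driven in `B/wt`
  individuals carrying at least one C.

## The recursion

The model is a deterministic, discrete-generation, two-sex
genotype-frequency recursion over an infinite, panmictic population. The
state is the joint frequency distribution over (sex, genotype); with two
diallelic loci there are 9 genotypes per sex (18 equations), 18 with the
triallelic NHEJ locus (36 equations), and 27 for the three-locus DDKR
system (54 equations). Each generation:

1. **Mating.** Adults mate at random with contributions proportional to
   their frequencies. Because gamete production is unweighted (all
   selection acts on zygote-to-adult survival), the zygote distribution
   equals the cross of the pooled maternal and paternal gamete
   distributions, which is what `generation_step()` computes; the test
   suite verifies, to $10^{-12}$, that this equals explicit enumeration of
   all mating pairs.
2. **Gametes.** Germline distortion applies identically in both sexes.
   At a distorted locus the cut/repair partition is
   $(1 + c\,\Phi)/2$ for the drive allele, $c\,(1-\Phi)/2$ for R and
   $(1-c)/2$ for wild type, with the cleavage probability $c$ fixed at 1
   outside the NHEJ variant. Undistorted loci segregate Mendelianly, and
   unlinked loci recombine freely, so each parent's haplotype distribution
   is the product of per-locus allele distributions.
3. **Sex assignment.** Zygotes are assigned 1:1 to female and male.
4. **Survival.** Each genotype survives with probability
   `viability x fitness`: genotypes with at least one A and no B die with
   probability $L$ (genotype-level penetrance, independent of A copy
   number, since one rescue copy fully protects); fitness costs are
   multiplicative (next section).
5. **Sex effects.** In the suppression variants, a fraction $\delta$ of
   each affected female class moves to the same genotype's male class
   (conversion, mass-conserving, the converted individuals being fertile
   males) or a fraction $\gamma$ is removed (lethality, mass-reducing).
   Affected classes carry at least one A (dominant) or are `A/A`
   (recessive).
6. **Renormalization.** Frequencies are rescaled to sum to one; the
   pre-normalization surviving masses are retained because the genetic
   load is defined from them.

All quantities are exact floating-point recursions: repeated runs are
bit-identical, and there is no sampling noise anywhere in the package.

## Parameters

| symbol      | meaning                                   | range  | default |
|-------------|-------------------------------------------|--------|---------|
| $\Phi$      | homing (HDR) rate per cut allele          | [0, 1] | —       |
| $c$         | cleavage probability (NHEJ variant)       | [0, 1] | 1       |
| $\varepsilon$ | relative fitness per construct copy     | (0, 1] | —       |
| $\varepsilon_R$ | relative fitness per R copy           | (0, 1] | 1       |
| $L$         | lethal penetrance of the unrescued toxin  | [0, 1] | —       |
| $\delta$, $\gamma$ | sex-conversion / female-lethality rate | [0, 1] | 0 |
| $m$         | migration rate per generation (two-deme)  | [0, 1] | 0.02    |
| $r$         | release ratio (released : wild, 1:1 sexes)| ≥ 0    | 2       |

### Fitness-cost basis

Fitness costs are multiplicative. The open design question is whether
$\varepsilon$ applies once per construct *type* carried (dominant costs)
or once per allele *copy*. The package defaults to the per-copy basis —
a double homozygote for a two-construct system has fitness
$\varepsilon^4$ — because that convention reproduces the published
behaviour of this family of systems: with 30% per-construct costs
($\varepsilon = 0.70$), full penetrance and a 2:1 release, the minimal
homing rate at which the drive spreads is ≈ 70% under per-copy costs
(the acceptance script computes 70.9%) but ≈ 22% under dominant costs,
which would make the system implausibly tolerant of costs relative to
the engineered-underdominance systems it is compared against. The
dominant convention remains available as
`drive_params(cost_basis = "per_construct")` and the R-allele cost
follows the same basis.

## Experiment drivers

### Spread criterion and thresholds

"The drive spreads" is operationalized as: the A-allele frequency is
above 0.95 at the **end** of a 1000-generation horizon (retention).
Requiring retention rather than a transient excursion matters in two
places: a very large release (say at frequency 0.99) starts above any
level but can still collapse, and must count as failure for the
"unable to increase in frequency" sentinel to be reachable; and in the
NHEJ variant the drive can exceed the level transiently before
resistance erodes it. Wherever crossing the level leads to fixation —
all SDKR/DDKR threshold analyses — retention and excursion give the same
answer, and `spread_criterion(when = "any")` restores the transient
reading. Level, horizon and mode are configurable policy; thresholds are
only meaningful together with them, and have roughly ±0.01 sensitivity
to the level.

`find_threshold()` first probes 11 equally spaced release frequencies in
[0, 0.99] and verifies the spread outcome is monotone (a non-monotone
profile raises a diagnostic rather than returning a misleading number),
then bisects the failing/spreading bracket to a default tolerance of
0.002. If nothing up to 0.99 spreads it returns a sentinel result with
`no_spread = TRUE`. The bracketing is testable: simulation at the lower
bracket end fails the criterion and at the upper end passes it.

Note that the A > 0.95 criterion is unreachable by construction in
conversion-type suppression models (all `A/A` females leave the female
pool, capping the A frequency), which is why the suppression analyses are
phrased as equilibrium-load maps rather than introduction thresholds.

### Genetic load

The genetic load is the proportional reduction in reproductive output
relative to an all-wild-type population, with females limiting
reproduction: per wild-type-zygote equivalent, a wild-type generation
retains surviving fertile-female mass 0.5, so

$$G \;=\; 1 - \frac{\text{surviving fertile-female mass}}{0.5},$$

clipped to [0, 1]. This definition makes the load exactly 0 for
wild-type, exactly 1 under total fertile-female loss, and strictly
positive whenever fitness costs alone remove reproductive output (a
fixed two-construct system at $\varepsilon = 0.95$ carries a load of
about 18% from costs alone). An alternative sex-ratio-based definition
($1 - 2\times$ female adult share) was considered and rejected because
it assigns zero load to fitness costs.

One structural consequence is worth stating because it shapes the
dominant-lethality load map: near A-fixation under a *dominant* female
effect every female genotype is affected equally, so the mortality
renormalizes away and exerts no counter-selection, while homing still
converts residual wild-type alleles. A-fixation is therefore locally
stable for any $\gamma < 1$, and the maximum of the equilibrium load map
is set by the establishment boundary (which cells the release can still
invade), not by an interior optimum. With the release used here the
dominant-lethality map maximum computed by the acceptance script is
consequently close to the conversion maximum (~96%), substantially
higher than the ~65% sometimes quoted for such systems; the establishment
boundary, and hence that maximum, is sensitive to the assumed release
size and to the operational load definition, neither of which is uniquely
determined for this design.

### Suppression equilibria and migration

Two-deme runs release construct homozygotes into the target deme only.
Each deme advances one generation independently; the non-target adult
pool is then replaced by a mixture of resident non-target adults, weight
$(1 - G_{nt})$, and target-deme migrants, weight $m\,(1 - G_t)$ — deme
sizes proxied by one minus their genetic loads, so that migrants from a
suppressed source count for less. At zero suppression the migrant share
is $m/(1+m) \approx 2\%$ at the default $m = 0.02$, matching the nominal
migration rate. Migration is strictly one-way: the target deme's
composition is unaffected (asserted to $10^{-12}$ in the tests).

Suppression equilibria are assessed 1000 generations after the release,
from an introduction frequency of 0.75, safely above threshold across
most of the map; within a cell's basin of attraction the equilibrium
load is insensitive to the release size, and cells the release cannot
invade report the small load of the wild-type-dominated equilibrium.
`equilibrium_summary()` attaches a convergence flag (every tracked
quantity moved < $10^{-8}$ over the last 100 generations) so
non-equilibrated cells are identifiable.

### Persistence

`persistence_time()` counts the generations in which the A-allele
frequency exceeds 0.8 — the level at which, under Hardy–Weinberg
proportions, over 95% of individuals carry at least one copy. The count
is the **total** number of generations above the level (release
generation included), not the contiguous run from the peak; the two
differ only for trajectories that dip and recover, which does not occur
in these monotone-erosion systems, and the total count is the more
conservative choice. Without an erosion mechanism the count is simply
the horizon minus the ramp-up; with NHEJ it is finite and measures the
window in which the drive could act.

### Grid scans

`scan_grid()` maps any subset of {threshold, target load, non-target
load, persistence, equilibrium R frequency} over a named parameter grid,
one deterministic cell at a time. The suppression maps use a step of
0.05 over $(\Phi, \delta)$ or $(\Phi, \gamma)$ — 441 cells of 1000
generations each, about a minute per map on one CPU — and the NHEJ maps
use a 2000-generation horizon, matching the slow approach of the
resistance equilibria. These problem sizes are the package's defaults
and are chosen so every map in the test suite and acceptance script is
exactly reproducible at desk scale; finer grids change the maxima by
less than the grid step.

## Numerical choices and degenerate inputs

* States are validated to be non-negative and to sum to 1 within
  $10^{-9}$ on construction; every returned state is renormalized and the
  suite asserts normalization to $10^{-12}$.
* If a generation has no fertile females, no males, or no surviving
  zygotes, the step signals a condition of class `sdkr_annihilation`
  rather than returning NaNs; scan cells that annihilate report a load
  of 1. In the two-deme system an error is raised only when both demes
  are annihilated.
* Fixation of A is treated as absorbing for early exit in threshold
  searches (wild-type and R alleles at locus A are then extinct in every
  variant), triggered at frequency $> 1 - 10^{-9}$.
* Bisection tolerances: 0.002 on introduction frequency, 0.005 when
  bisecting over a model parameter such as $\Phi$.
* Genotype order is lexicographic — first declared locus slowest, allele
  pairs sorted by declared allele order — and is the stable column order
  of all serialized outputs.

## What the deterministic model does and does not capture

The recursion is the infinite-population limit: it captures the
threshold (bistable) structure, equilibrium loads and the deterministic
time scales of invasion and erosion. It does **not** capture genetic
drift or stochastic loss of rare alleles (relevant exactly at the
threshold and at the establishment of rare R alleles), ecological
density dependence (loads are reproductive-output reductions, not
population-size predictions), age structure or overlapping generations,
maternal deposition of Cas9/sgRNA, partial homing products, standing
target-site variation, or linked loci. Passing tests therefore certify
the recursion and its analyses, not field outcomes; real populations at
these parameter values would differ most where frequencies are small.

## Known limitations

* Suppression effectors are modelled on construct A of the two-locus
  system only; the NHEJ and DDKR variants do not combine with
  suppression.
* Migration is unidirectional between exactly two demes.
* The release composition is 1:1 male:female homozygotes; male-only
  releases (natural for female-lethal strains) are expressible only by
  constructing a `population_state` directly.
* `find_threshold()`'s monotone pre-scan is a heuristic guard: a
  bistability structure finer than its 11-point grid would go
  undetected.
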