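---
title: "Modelling the invasion of achiasmatic meiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the invasion of achiasmatic meiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(achiasma)
library(ggplot2)
```

## The question

In many lineages with chromosomal sex determination, the heterogametic
sex has lost crossing over entirely — achiasmatic meiosis. `achiasma`
implements a deterministic, infinite-population model that asks when a
dominant, male-limited mutation abolishing crossing over can invade, and
how the answer depends on where the mutation sits (autosome, X, or Y)
and on which selective force is acting: sexually antagonistic selection,
or selection to avoid the sex-chromosome aneuploidy that heteromorphic
bivalents suffer during chiasmatic meiosis.

## The model

The genome carries three biallelic loci on a line:

* **SDL** — the sex-determining locus, alleles `X`/`Y`; `XX` female,
  `XY` male;
* **SAL** — a sexually antagonistic locus at recombination fraction `R1`
  from the SDL; allele `m` benefits males, `f` benefits females, with
  dominance `h` applying to `m`;
* **ML** — the meiosis locus at recombination fraction `R2` from the
  SAL; allele `c` is chiasmatic, `a` achiasmatic. `R2 = 0.1` puts the ML
  on the sex chromosome; `R2 = 0.5` represents an autosomal ML.

The state of the population is the frequency vector of gamete
haplotypes: 4 egg classes (all `X`-bearing) and 8 sperm classes. One
generation is: random union of gametes; sex determination by the sperm's
SDL allele; viability selection on adults; sex-specific meiosis;
renormalisation of the egg and sperm pools. Every male transmits half
`X`- and half `Y`-bearing sperm — aneuploidy enters as a fitness cost,
never as gamete loss — so `Y` sperm always total exactly 0.5.

Fitness is multiplicative across two factors. At the SAL the scheme is
symmetric: genotypes `mm`, `mf`, `ff` have male fitness `(1+s)`,
`(1+hs)`, `1` and female fitness `1/(1+s)`, `1/(1+hs)`, `1`. At the ML,
chiasmatic males pay the aneuploidy cost `(1-k)`; males carrying at
least one `a` (the allele is dominant and sex-limited) instead pay the
Muller's-ratchet mutational load

$$\mathrm{load}(t) = (1-\delta)^{\mu L t},$$

where `mu` is the per-site deleterious mutation rate, `L` the number of
coding sites that become permanently non-recombining on the Y once
achiasmy arises, `delta` the per-mutation effect, and `t` the
generations since the `a` allele appeared. The two study regimes are
mutually exclusive by construction — sexual-antagonism conditions set
`k = 0`, aneuploidy conditions set `s = 0` — but `male_fitness()`
composes both factors generically. Fitnesses are relative (values above
1 are fine); the recursion divides by the mean.

The load is applied to every `a`-carrying male at generation `t`
regardless of where the ML itself sits: the degenerating object is the
male's Y chromosome, which stops recombining as soon as its carrier is
achiasmatic, not the ML's own chromosome. Using a single global
generation counter (rather than per-lineage mutation histories) is the
natural reading in a deterministic infinite-population model, where all
`a`-carrying Y lineages are exchangeable.

### Meiosis

Females always recombine, with the two intervals recombining
independently (no crossover interference — the standard Haldane-style
assumption): the four meiotic classes have probabilities
`(1-R1)(1-R2)`, `R1(1-R2)`, `(1-R1)R2`, `R1 R2`, each split equally
between reciprocal products. Achiasmatic males undergo no crossing over.
When the ML is sex-linked this means parental haplotypes are transmitted
intact. When the ML is autosomal we keep `R2 = 0.5` in achiasmatic
males: achiasmy abolishes chiasmata, not the independent assortment of
separate chromosomes. This distinction matters — if independent
assortment were suppressed too, an autosomal achiasmy allele would ride
whichever sex chromosome it first found itself with in males, become
effectively Y-linked, and stall at a population frequency near 0.25
(we verified this numerically: under `s = 0, k = 0.05, L = 0` the
suppressed-assortment variant plateaus at 0.252), which contradicts the
behaviour the model is meant to capture.

### Initialisation

The SAL starts with `m` and `f` at 0.5 on every chromosome class, in
linkage equilibrium with the other loci. The achiasmy allele starts at a
conditional frequency of `p0 = 1e-4` within its chromosome class,
divided by the class's relative effective population size (autosome 1,
X 0.75, Y 0.25, from the standard breeding-sex accounting implemented in
`relative_ne()`) when `ne_adjust = TRUE`: a new mutation is one copy in
a smaller pool of chromosomes, so its starting frequency within that
class is correspondingly higher. The adjustment is applied to the
within-class frequency (a Y-located mutation starts at `4e-4` among Y
haplotypes) because that is the scale on which the allele's dynamics and
the fixation threshold are defined; the flag is exposed so either
convention can be run.

No burn-in is applied by default — the starting SAL frequencies are part
of the study conditions — but `burn_in = N` first iterates the
`a`-free model for `N` generations so the SAL can settle (with `s > 0`
the male-beneficial allele accumulates on the Y and is depleted on the
X) before the mutation is introduced.

### Tracking and stopping

`iterate_model()` records, per generation, the population-wide `a`
frequency (eggs and sperm weighted equally), the frequency *within the
mutation's chromosome class*, and the population `m` frequency. The
fixation threshold (0.99) applies to the within-class frequency: a
Y-located allele can never exceed 0.25 population-wide, yet "fixed on
the Y" is exactly what invasion means there. Runs stop at fixation, at
`max_generations = 1000`, or when the allele falls below `1e-15` and is
numerically lost. Equilibrium is flagged at the first generation whose
absolute frequency change drops below `equilibrium_tol = 1e-9`; it never
stops a run, it is bookkeeping for comparing invasion speeds.

Setting `s = 0, k = 0, L = 0` reduces the step to the neutral model
exactly, and `R1 = 0` or `R2 = 0` (complete linkage) are legal and
involve no division by zero. The load exponent is computed in log space,
so extreme (non-default) parameter combinations underflow gracefully;
a fitness-weighted pool that underflows to zero raises an error rather
than propagating `NaN`.

## The factorial experiment

`build_design()` crosses three mutation locations with 200 values of
`L` (0 to 5 Mb in 25 kb steps — roughly the protein-coding content of
the ancestral mammalian X, so the grid spans homomorphic to fully
diverged sex chromosomes), and per (location, `L`): 200 selection
coefficients spanning (0, 0.5] at each dominance `h` in {0, 0.5, 1}
(with `k = 0`), plus 200 aneuploidy rates spanning (0, 0.05] (with
`s = 0`). That is `3 * 200 * (200*3 + 200) = 480000` conditions, with
the location-by-divergence layer contributing 600 combinations.

Two grid conventions are worth stating because "from 0 to X in 200
steps" is ambiguous at the endpoints: the `L` grid includes 0 and
excludes 5 Mb (`0, 25e3, ..., 4.975e6`); the `s` and `k` grids exclude 0
(the zero case is the *other* regime's baseline, present in the design
by construction) and include the upper endpoint. Both are overridable
arguments to `default_grids()`. `R1` defaults to 0.1 (tight linkage);
0.3 is a variant, not part of the 480,000 count — the arithmetic only
works without `R1` variation.

The default suite and the acceptance script run each heatmap at
`stride = 10` — every tenth grid value per axis, a 20×20 panel of 400
conditions per location and regime — which preserves the frontier
geometry of the full 200×200 panels at about 1% of the compute. A full
panel is a `cli_sweep(..., stride = 1)` call away.

### Reading the heatmaps

`heatmap_matrix()` arranges final within-class frequencies with `s` (or
`k`) on the rows and `L` on the columns. Two qualitative properties are
what the desk-scale panels are tested for:

* **Monotone invasion frontier.** For fixed `L`, if the mutation
  invades at some `s` it invades at every larger `s` (same for `k`).
* **Location ordering.** Under sexual antagonism the permissive area
  orders Y ≥ X ≥ autosome (linkage with the male-beneficial allele plus
  male-limited transmission favour the Y); under aneuploidy it orders
  Y ≥ autosome ≥ X (no linkage is needed; what matters is residence
  time in males — 1 for Y, 1/2 for autosomes, 1/3 for X).

"Permissive area" is measured as the fraction of grid cells whose final
within-class frequency reaches 0.5. We use an invasion criterion rather
than the 0.99 fixation threshold for the *area* statistic because a
dominant beneficial allele's sweep has a long tail — once `a` is common,
the chiasmatic homozygotes still paying the cost are rare — so
autosomal conditions that have decisively invaded (frequency > 0.9 and
rising) can still sit just below 0.99 at the 1,000-generation cap.
Fixation fractions are computed and reported alongside.

## What the tests do and do not show

The engine is verified three independent ways: against a per-locus
transmission re-derivation of meiosis; against a brute-force
one-generation enumeration over all ordered genotype pairs; and against
closed-form scalar recursions for Y-located dynamics
(`p' = p λ / (p λ + (1-p)(1-k))` with `λ` the load), which the
12-dimensional engine must reproduce to 1e-10 per generation. Exact
invariants (pool normalisation, Y-sperm total 0.5, strict confinement of
a sex-linked `a` to its chromosome class) are asserted over full runs.

These are checks of the model's internal consistency, not of nature:
the model is deterministic (no drift — a rare mutation's survival is
taken for granted), mutation effects are a constant `delta` with
multiplicative interaction, there are no reversions at the ML, and
`L` enters only through the load exponent. A ZW system is the same
model with labels swapped (Z for X, W for Y, "male" for "female"); the
dynamics are identical, so no separate implementation is provided.

## A worked trajectory

```{r trajectory, fig.width = 6, fig.height = 3.5}
sim <- iterate_model(model_params(location = "Y", s = 0, k = 0.05, L = 0))
glance(sim)
autoplot(sim)
```

The within-class frequency climbs logistically (the Y-located allele is
effectively under haploid selection with advantage `1/(1-k)`), hitting
the 0.99 threshold at generation `r sim$generations_to_fixation`, while
the population-wide frequency saturates near 0.25 — one quarter of all
gene copies at the ML reside on Y chromosomes.

```{r heatmap, fig.width = 6, fig.height = 4}
g <- default_grids()
every10 <- function(x) x[seq(1, length(x), by = 10)]
d <- build_design(
  locations = "Y",
  L_grid = every10(g$L_grid), s_grid = every10(g$s_grid),
  k_grid = every10(g$k_grid), h_values = 0.5, models = "aneuploidy"
)
autoplot(heatmap_matrix(run_sweep(d), "Y", "aneuploidy"))
```

The frontier slopes up-right: larger exposed coding lengths need larger
aneuploidy savings to offset the accumulating load.
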