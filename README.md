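# achiasma

Deterministic population genetics of the evolution of **achiasmatic
meiosis** — the complete loss of crossing over in the heterogametic sex.

Across animals and plants, XY males (or ZW females) often recombine less
than the homogametic sex, and in many lineages (Drosophila and other
brachyceran flies, Lepidoptera females, some voles and gerbils) they do
not recombine at all. This package implements a three-locus model for
two competing explanations and asks where in the genome a mutation
causing achiasmy can invade:

* **Sexual antagonism.** A locus at recombination fraction `R1` from the
  sex-determining locus carries a male-beneficial allele *m* and a
  female-beneficial allele *f* (selection coefficient *s*, dominance *h*
  on *m*, symmetric fitnesses: male `(1+s)`, `(1+hs)`, `1` vs female
  `1/(1+s)`, `1/(1+hs)`, `1` for *mm*, *mf*, *ff*). Suppressing male
  recombination keeps *m* with the Y, removing recombination load.
* **Heteromorphy-dependent aneuploidy.** Chiasmatic males mis-segregate
  heteromorphic sex chromosomes at rate *k*, applied as a viability cost
  `(1 − k)`. Achiasmatic pairing avoids it.

Both benefits trade off against the cost of achiasmy: a Y that stops
recombining exposes *L* coding sites to Muller's ratchet, an
exponentially compounding mutational load

```
load(t) = (1 − δ)^(μ L t),   U = μ L
```

with per-site mutation rate μ = 10⁻⁹, per-mutation effect δ = 0.03, and
*t* generations since the achiasmy allele *a* arose. The allele is
dominant and male-limited; females always recombine.

The population state is a pair of gamete pools — 4 egg and 8 sperm
haplotype frequencies over the loci (SDL `X/Y`, SAL `m/f`, ML `c/a`) —
iterated through random mating, sex-specific selection, and sex-specific
meiosis. Everything is deterministic: no drift, no seeds.

## A worked example

A Y-located achiasmy mutation under the aneuploidy regime
(*k* = 0.05, no antagonism, nothing exposed to the ratchet):

```r
library(achiasma)
sim <- iterate_model(model_params(location = "Y", s = 0, k = 0.05, L = 0))
sim
#> <achiasma_sim>
#>   location=Y  outcome=fixed  final within-class a-frequency=0.990441
#>   generations run=243  to fixation=243  to equilibrium=-
head(tidy(sim), 3)
#> # A tibble: 3 x 4
#>   generation a_frequency a_frequency_within_class sal_m_frequency
#>        <int>       <dbl>                    <dbl>           <dbl>
#> 1          0    0.0001                   0.0004               0.5
#> 2          1    0.000105                 0.000421             0.5
#> 3          2    0.000111                 0.000443             0.5
```

The mutation starts at frequency 10⁻⁴, Ne-adjusted to 4 × 10⁻⁴ within
the Y class (Y chromosomes have one quarter the autosomal effective
population size), grows each generation by the factor
`1 / (p + (1 − p)(1 − k))` — the chiasmatic Y's haploid disadvantage —
and crosses the 0.99 fixation threshold at generation 243.
`autoplot(sim)` draws the trajectory.

The factorial machinery reproduces the invasion heatmaps at any
resolution. A 20×20 desk-scale Y panel:

```r
g <- default_grids()                        # 200-point L, s, k grids
every10 <- function(x) x[seq(1, length(x), by = 10)]
d <- build_design(locations = "Y",
                  L_grid = every10(g$L_grid), s_grid = every10(g$s_grid),
                  k_grid = every10(g$k_grid), h_values = 0.5,
                  models = "aneuploidy")
res <- run_sweep(d)                         # 400 deterministic conditions
autoplot(heatmap_matrix(res, "Y", "aneuploidy"))
```

The full published design is `build_design()` with the default grids —
exactly 480,000 conditions (`3 locations × 200 L × (200 s × 3 h + 200
k)`) — runnable location by location via the CLI:

```sh
Rscript inst/exec/achiasmy run --out out location=Y k=0.05
Rscript inst/exec/achiasmy sweep --model aneuploidy --location Y --stride 10 --out out
Rscript inst/exec/achiasmy sweep --design-count-only   # prints 480000
```

Outputs are a trajectory CSV, a sweep CSV, heatmap TSVs with axis values
in the first row/column, and a JSON provenance sidecar.

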