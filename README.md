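# islandassembly

Likelihood inference and forward simulation for the macroevolutionary
assembly of insular communities from dated phylogenies.

## The scientific problem

How does the biota of a remote island or archipelago accumulate — and does
it tend towards a dynamic equilibrium between species gain and loss?
Classical island biogeography poses the question; dated phylogenies of an
entire insular community (one colonisation time per independent colonist,
plus the branching times of any in-situ radiation) contain the information
needed to answer it quantitatively.  `islandassembly` is for
phylogeneticists and island biogeographers who have such community-wide
data and want rate estimates and model comparisons rather than verbal
arguments.

## The model

Each of the `M` species in a mainland pool independently:

* immigrates at per-species rate γ (a later immigrant replaces a
  still-conspecific island population, resetting its divergence time);
* becomes endemic by anagenesis at rate λᵃ;
* splits in situ (cladogenesis) at per-species rate λᶜ;
* goes extinct on the island at per-species rate μ.

Cladogenesis and immigration may decline linearly with the diversity `N`
of the colonising lineage: λᶜ_N = max(0, λᶜ(1 − N/K′)), and likewise γ_N,
where K′ is a carrying capacity ("number of species niches").  Lineage
classes (e.g. a radiation-prone fraction of the pool vs the background)
may have their own rates.  The likelihood of the observed colonisation and
branching times integrates hidden-state master equations over everything
that is not observed (species that died out, missing taxa, unknown
colonisation times); an exact Gillespie simulator of the same process
provides forward simulation, goodness-of-fit summaries, parametric
bootstrap and an independent Monte-Carlo check of the likelihood itself.
Details and conventions: `vignettes/island-assembly-methods.Rmd`.

## Worked example

The package ships a small synthetic dataset mirroring the design of a
young volcanic archipelago community (8 colonisations, 25 extant species,
a 15-species radiation; all numbers invented):

```r
library(islandassembly)
d <- read_island_dataset(system.file("extdata", "synthetic_archipelago.json",
                                     package = "islandassembly"))
d
#> island dataset: age 4 My, mainland pool M = 1000
#>  classes: DF-type (0.163), non-DF-type (0.837)
#>   8 colonisation(s), 25 extant island species
#>   - radiation-large    status 4  t_c 2.1  clade 15  [DF-type]
#>   - radiation-small    status 4  t_c 3.2  clade 4  [non-DF-type]
#>   ...

fit  <- fit_model(d, island_model("M8"),  n_starts = 20, seed = 1)
fit
#> model M8  logLik -73.591759  AIC 161.18352  BIC 195.5378
#>   gamma =  0.003382
#>   lambda_c[DF-type] =  3.047000
#>   lambda_c[non-DF-type] =  0.339600
#>   lambda_a =  0.582800
#>   mu[DF-type] =  0.618900
#>   mu[non-DF-type] =  0.438700
#>   K_prime[DF-type] = 22.650000
```

The differential-rates model `M8` estimates a fast-turnover, diversity
limited radiation-prone class (λᶜ ≈ 3.0/My towards K′ ≈ 23 niches) against
a slow background (λᶜ ≈ 0.34/My), with rare immigration (γ ≈ 0.0034/My per
mainland species).  Comparing against the 4-parameter equal-rates model by
BIC weights (sample size `n = M`, each mainland species being one
observation unit):

```r
fit2 <- fit_model(d, island_model("M1p"), n_starts = 20, seed = 1)
round(information_weights(list(fit, fit2), "bic"), 4)
#>     M8    M1p
#> 0.0073 0.9927
```

For this gentle synthetic dataset BIC retains the equal-rates model: three
extra parameters are not worth ~5.5 log-likelihood units at this penalty —
the example shows the machinery, not a discovery.  Forward simulation
under the fitted parameters gives diversity-through-time bands:

```r
ens <- simulate_ensemble(fit$params_by_class, M = d$M,
                         class_fractions = d$class_fractions,
                         island_age = 4, n_replicates = 200, seed = 2,
                         dtt_points = 5)
ens$dtt_bands
#>   time median  p2.5   p75
#> 1    0    0.0 0.000  0.00
#> 2    1    3.5 0.000  6.00
#> 3    2    9.0 1.975 15.25
#> 4    3   18.5 4.000 28.00
#> 5    4   29.0 6.000 40.25
```

(the rising, non-asymptotic median is how a community still far from
equilibrium looks in this summary).

## Command line

```sh
island-assembly validate  data.json
island-assembly fit       data.json --model M8 --starts 100 --M 1000 --seed 1 --out fit.json
island-assembly simulate  --params params.json --M 1000 --age 4 --reps 5000 --seed 1 --out sims/
island-assembly bootstrap --params params.json --model M5 --reps 50 --seed 1 --out boot/
island-assembly sweep     data.json --model M1 --axis island_age --values 4,6,8,10,15 --out sweep/
```

Every run writes a `manifest.json` (full configuration echo + package
version) next to its outputs.  The script is installed in the package
`exec` directory; dataset schema: `inst/extdata/dataset-schema.json`.

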