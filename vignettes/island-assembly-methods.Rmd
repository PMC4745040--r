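---
title: "Methods: a likelihood framework for island community assembly"
author: "islandassembly developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a likelihood framework for island community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`islandassembly` fits a stochastic model of how an insular community is
assembled from a mainland species pool, and simulates the same process
forwards in time.  The island is a single arena of age $t_p$ (in million
years, My).  Each of the $M$ mainland species behaves independently:

* it **immigrates** at per-species rate $\gamma$, founding a non-endemic
  island population whose divergence time from the mainland is the
  colonisation time; a re-immigration onto a population that has not yet
  diverged *replaces* it, resetting the observed colonisation time;
* an island population becomes an endemic species by **anagenesis** at rate
  $\lambda^a$ (divergence time unchanged), or splits into two endemic
  species by in-situ **cladogenesis** at per-species rate $\lambda^c$;
* every island species goes **extinct** at per-species rate $\mu$.

Cladogenesis and immigration may be **diversity-dependent**: with $N$
species of the colonising lineage already on the island, the effective
rates are $\lambda^c_N = \max(0, \lambda^c (1 - N/K'))$ and
$\gamma_N = \max(0, \gamma (1 - N/K'))$.  $K'$ is the carrying capacity —
the number of available niches in the absence of extinction; $K' = \infty$
removes the feedback.  Diversity-dependence is clade-local: $N$ counts only
the island descendants (and conspecific population) of the focal mainland
species.  Anagenesis and extinction are never diversity-dependent.

Lineage classes (for example a radiation-prone "DF-type" fraction
$P_{\text{DF}}$ of the pool versus the background) may carry their own
parameter set; the class fractions are fixed inputs, never estimated.

## The likelihood

The data are one record per independent colonisation: an endemicity
status (five types), a colonisation time (possibly only an upper bound),
the branching times of any in-situ clade, and a count of extant species
missing from the phylogeny.  Mainland species are independent, so the
community log-likelihood is a sum of per-colonist terms plus, per class,
(pool size − observed colonists) copies of the probability that a mainland
species leaves no extant descendants.

Per colonist, the machinery integrates a hidden-state master equation in
the number $n$ of island species *not* in the phylogeny, with channels for
"mainland species absent" ($Q_n^k$), "mainland species present"
($Q_n^{M,k}$) and, between colonisation and first branching, the
not-yet-diverged surviving population ($Q_{M,n}$).  $k$ counts phylogeny
lineages and increments at observed nodes.  Between observed events the
generator is constant, so segments are propagated **exactly** with a matrix
exponential; observed colonisations and branchings are rate-weighted
transfer operations, making the result a density in the observed times.
Read-off at the present selects the channel matching the record's status
and the hidden-state cell $n = n_\text{missing}$.

Two conventions deserve attention because the written record of this model
family is ambiguous about them; both were fixed by requiring exact
agreement with an independent Gillespie simulation of the process (the
package's Monte-Carlo oracle, `mc_likelihood_oracle()`):

* **Colonisation initial condition.**  The observed colonisation can land
  on an empty niche *or replace a still-conspecific resident*, so
  $Q_{M,n}(t_c) = \gamma_n Q_n^0(t_c) + \gamma_{n+1} Q_n^{M,0}(t_c)$.
  Dropping the second term is inconsistent with the replacement rule: in
  the immigration-only limit the status-3 density must be the
  most-recent-arrival density $\gamma e^{-\gamma a}$, which only the full
  transfer reproduces.
* **First observed branching.**  The branching is an observed event with
  instantaneous rate $\lambda^c_{n+1}$ whichever channel it comes from:
  $Q_n^2 = \lambda^c_{n+1}\,(Q_n^1 + Q_{M,n})$ and
  $Q_n^{M,2} = \lambda^c_{n+2} Q_n^{M,1}$.  An unweighted transfer of
  $Q_{M,n}$ fails the simulation oracle by orders of magnitude at small
  $\lambda^c$.

Further conventions, each validated against the oracle or documented as a
deliberate choice:

* **Status 2 (colonisation time only bounded above):** the $k=0$ system is
  integrated from the bound to the present from a fresh empty state and
  the mainland-present channel is read off; nothing is assumed about the
  species before the bound.
* **Status read-offs:** status 3 reads the not-yet-diverged channel
  $Q_{M,n}$ at the present (no re-immigration may intervene, as it would
  reset the divergence time); status 4 reads $Q_n^k$; statuses 2 and 5
  read $Q_n^{M,k}$.
* **Missing species** enter through the hidden dimension: the read-off at
  exactly $n = n_\text{missing}$.  The master equations count each
  assignment of "which extant survivors are hidden" as a separate history
  class, so a record with $n_\text{missing} > 0$ carries a
  configuration-dependent multiplicity; this is the convention defined by
  the equations themselves and is shared by maximum-likelihood comparisons
  on a fixed dataset.  For $n_\text{missing} = 0$ no multiplicity arises.
* **Clades founded by re-immigration** after the focal clade's origin are
  tracked only through the hidden dimension — their branching structure is
  not computed (such configurations are rare and absent from typical
  data).
* **No survival conditioning** by default: the likelihood is not divided
  by the probability of a non-empty island.  `loglik_dataset(condition =
  TRUE)` enables it; with the small per-species colonisation probabilities
  typical of remote islands the correction is negligible.

## Numerics

* **Hidden-state truncation.**  The state is truncated at $n_{\max}$,
  initially $\max(10,\, \lceil K'\rceil + 5,\, 2\times$ clade size$)$, and
  doubled until the log-likelihood moves by less than $10^{-6}$ (hard cap
  1024).  With finite $K'$ the hidden dimension is effectively bounded and
  escalation terminates immediately.
* **Propagation.**  Two independent engines implement the same equations:
  a dense matrix exponential (`engine = "r"`, via the exported `q_state`
  operations) and a sparse chunked uniformisation series with a dense
  fallback for extremely stiff segments (`engine = "cpp"`, the default).
  They agree to $10^{-8}$ across mild, diversity-limited and fast-turnover
  regimes, including $\lambda^c = 20$, $\mu = 15$/My.  Because the
  generator is piecewise-constant, integration is checkpoint-invariant by
  construction.
* **Underflow.**  State vectors are renormalised between segments with an
  accumulated log scale, so products over a mainland pool of 1000 species
  and densities of order $10^{-15}$ are representable.
* **Optimisation.**  Nelder-Mead simplex on log-transformed rates (a
  finite $K'$ on $\log(K' - K_{\text{lower}})$ with $K_{\text{lower}}$ the
  largest observed clade), repeated from `n_starts` random starting points
  drawn log-uniformly on $[10^{-3}, 10]$/My (K': up to $100\times$ the
  largest clade).  A soft box keeps the simplex inside $[10^{-8}, 10^3]$/My,
  beyond which parameters have no biological meaning for My-dated data.
  During the search each record uses a leaner fixed truncation; the
  optimum is then verified at doubled truncation and the search resumed if
  the log-likelihood shifted by more than $10^{-6}$.  Boundary estimates
  (rates $\to 0$, $K' \to$ clade size) are flagged, not fatal.
* **Model comparison.**  AIC $= -2\ell + 2p$ and BIC $= -2\ell + p\ln M$:
  the BIC sample size is the mainland pool size $M$, since each pool
  species contributes one observation unit (most of them the "no extant
  descendants" outcome).  This is unusual and deliberate.

## The simulator and what a green test establishes

`simulate_island()` is an exact Gillespie simulation of the same process,
per mainland species, with full genealogy tracking; survivors are reduced
to the reconstructed dataset with the most-recent-immigration convention
for colonisation times, the oldest surviving colonisation as the recorded
clade, and any other endemic survivors counted as missing species.
Anagenesis of an already endemic species is a no-op; cladogenesis of the
non-endemic population converts it into two endemic daughters.
Diversity-through-time is recorded on a 1000-point grid and ensemble
percentile bands are pointwise (the 2.5th/75th band of the headline figure
is the default but both tails are configurable).

The simulator doubles as the fixture generator and as the likelihood's
independent oracle; since both directions are checked against each other
(frequencies vs probabilities, binned densities vs density read-offs), a
green oracle suite establishes that likelihood and simulator describe the
same process — it does not establish that either matches any particular
empirical system.  Synthetic data are ideal in ways real data are not:
node ages are exact (no dating uncertainty), taxon sampling is complete,
the mainland pool is homogeneous within classes, and rates are constant
through time and across the archipelago's geography.

## Stated worlds used by the acceptance checks

The package's acceptance suite simulates data under frozen,
domain-motivated configurations ("Galápagos scale": $M = 1000$, island age
4 My, radiation-prone fraction 0.163, immigration $\gamma = 0.002$/My
giving of order eight surviving colonisations, anagenesis 1/My, a
fast-turnover radiation-prone class $\lambda^c = 1.5$, $\mu = 0.8$ and a
slow background $\lambda^c = 0.3$, $\mu = 0.1$).  Recovery runs condition
on at least one surviving radiation-prone colonisation, mirroring the
situation in which such data are analysed (the refit likelihood is not
conditioned, exactly as for real data; at the ~50% acceptance rate of this
world the induced bias is well inside the recovery tolerance).  The
model-selection check uses an equal-rates world ($\gamma = 0.004$,
$\lambda^c = 0.3$, $\lambda^a = 1$, $\mu = 0.1$, $M = 500$) and asks how
often BIC correctly prefers the equal-rates model.  These values were
fixed before the checks were run and are not tuned.

## Known limitations

* One island, constant area, constant rates; no multi-island structure or
  island ontogeny.
* Diversity-dependence is clade-local; community-wide niche filling is out
  of scope.
* The $P$-class fractions are inputs; mis-specifying them propagates into
  class-specific rate estimates (the sensitivity sweep exists for exactly
  this).
* Re-immigrant-founded secondary clades contribute only through the hidden
  dimension, so their branching times, if ever observed, would be ignored.
* The optimiser is derivative-free; with very flat ridges (e.g. a class
  with no informative records) boundary estimates are returned and
  flagged rather than resolved.
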