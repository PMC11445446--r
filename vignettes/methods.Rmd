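---
title: "Methods: assembly, invasion fitness, and the fate of first-step mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly, invasion fitness, and the fate of first-step mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crevo)
```

## The model

`crevo` simulates large microbial communities competing for $R$
substitutable resources supplied at rates $K_i$.  Each strain $\mu$ is a
resource-uptake vector $r_{\mu i} = e^{X_\mu}\,\alpha_{\mu i}$, split into a
log uptake *budget* $X_\mu$ and a consumption *strategy* $\alpha_\mu$ on the
resource simplex.  After coarse-graining the underlying chemostat over time,
the relative abundances $f_\mu$ follow

$$\frac{\partial f_\mu}{\partial t}
  = f_\mu\Big[\sum_i r_{\mu i}\,h_i(f) - 1\Big],
  \qquad
  h_i(f) = \frac{K_i/\sum_j K_j}{\sum_\nu r_{\nu i} f_\nu},$$

with time in generations and $h_i$ the local availability of resource $i$.
Communities are assembled by sampling a pool of $S$ strains (binary usage:
each resource used independently with probability $R_0/R$, equal strategy
shares on the support, $X \sim \mathcal N(0,\sigma_X^2)$) and relaxing to
the unique uninvadable equilibrium.  Mutations perturb a resident's
phenotype, $X \to X + \Delta X$ and $\alpha \to \alpha + \Delta\alpha$; the
package implements single-resource knock-outs and knock-ins (with the
renormalization conventions below), general multi-resource changes, and
pure budget shifts.

Two community-level coordinates organize everything: the *niche saturation*
$S^*/R$ (fraction of resources "used up" by the $S^*$ survivors) and the
*sampling permissivity* $S^*/S$ (fraction of the pool that survives
assembly).

## Computing equilibria

The equilibrium is computed as the maximizer of the strictly concave
potential

$$\Phi(f) = \sum_i \kappa_i \log\Big(\sum_\mu r_{\mu i} f_\mu\Big)
            - \sum_\mu f_\mu, \qquad \kappa_i = K_i/\textstyle\sum_j K_j,$$

whose gradient is exactly the vector of per-capita growth rates, so the
first-order conditions are the survivor/exclusion conditions of the
dynamics: survivors grow at rate zero, excluded strains at rate $\le 0$
(non-invasibility), and $\sum_\mu f_\mu = 1$ at the optimum.  $\Phi$ is a
Lyapunov function of the dynamics, which makes the maximizer the state the
dynamics actually reach and lets us certify it *a posteriori*.

`compute_equilibrium()` uses a multiplicative (replicator/EM-type) ascent
with trust-region over-relaxation to prune the bulk of the excluded
strains, then an active-set Newton solve (Armijo line search on $\Phi$;
boundary-pinned strains are removed one event at a time) that drives the
KKT residuals to near machine precision.  Any excluded strain whose growth
rate still exceeds the tolerance is re-admitted and the monotone ascent is
re-entered, so the certificate holds over the *entire* pool.  Defaults that
matter:

* KKT tolerance `tol = 1e-10`; states report their residuals.
* Survivors are read off the Newton active set; abundances of excluded
  strains are exact zeros (no thresholding dust).
* A marginal excluded strain (growth within tolerance of zero) flags the
  state `degenerate`, and downstream fate classification keeps the flag
  rather than guessing.
* Resources consumed by no strain have undefined availability; they are
  dropped from the bookkeeping (with a warning) and the supply shares are
  renormalized, equivalent to removing them from the environment.
* In the exactly degenerate corner (e.g. $\sigma_X = 0$ with uniform
  supply, where *every* strain grows at exactly rate zero at the shared
  optimum) the reported abundances are reduced to a basic optimal solution
  with at most $R$ survivors, preserving competitive exclusion, and the
  state is flagged.

`integrate_dynamics()` wraps a stiff `deSolve` integration of the
replicator form and serves as an independent oracle: the test suite checks
survivor sets and abundances against it on randomized instances, and the
acceptance checks do so at scale (sup-norm agreement $10^{-6}$).

Warm starts matter for throughput: sequential invasions re-solve from the
pre-invasion equilibrium plus a rare mutant and typically converge in
tens of milliseconds at $S^* \approx 200$.

## Mutations and invasion fitness

A knock-out zeroes one used resource and renormalizes the remaining
shares.  A knock-in grants the new resource the *mean share of the
currently used resources* and renormalizes, so an equal-share parent on
$k$ resources becomes equal-share on $k+1$; this convention reproduces the
phenotypic magnitude $\lVert\Delta\alpha\rVert \approx 1/R_0$ for both
kinds (the model itself does not dictate the rule; any rule with the same
$\lVert\Delta\alpha\rVert$ gives statistically identical results, which
the test suite verifies directly by comparing against norm-matched random
multi-resource mutations).

The exact invasion fitness of a rare mutant at the unperturbed resident
equilibrium is

$$s_{\mathrm{inv}} = e^{X+\Delta X}\sum_i (\alpha + \Delta\alpha)_i\,h_i - 1,$$

and the mean-field approximation $s_{\mathrm{inv}} \approx \Delta X +
\sum_i \Delta\alpha_i\, g_i$ (with $g_i = h_i/\bar h - 1$ the excess
availability) is computed alongside.  *All simulated fates are driven by
the exact value*; the approximation is only reported for theory
validation.  Knock-ins targeting a resource with no current consumer are
disallowed (their availability is undefined in the coarse-grained model);
this is logged when it binds, and never binds at the study conditions,
where every resource has many consumers.

For equal-share parents the enumerated knock-out DFE has an exact
sum rule (the fitness effects of one parent's knock-outs sum to $k$ times
its growth rate, i.e. to zero at equilibrium), so the enumeration is
mean-centered by construction; its *width* is the non-trivial prediction.

## Calibration and the order-one factor C

Study conditions are stated as $(S^*/R,\ S^*/S)$ targets.  `calibrate_pool()`
sets $S = \mathrm{round}(S^*_{\rm target}/(S^*/S))$ and finds $\sigma_X$ by a
bracketed secant search on pilot assemblies (20 replicates per probe),
using the monotone decrease of the surviving fraction with budget spread.
Saturation targets of 1 are genuinely unattainable at finite $S$
(assembly always excludes some strains); the search then returns the
smallest probed spread, flags the result infeasible, and reports the
achieved saturation — this is what "as close to full saturation as the
pool permits" means operationally (about $S^*/R \approx 0.97$ at
$R = 200$, $S = 2000$).  A Monte-Carlo surrogate (`predict_survivors()`)
stands in for the closed-form self-consistency solution of the assembled
state; its output records the surrogate path.

The mean-field statistics of the excess availabilities,

$$g_i \sim \Big(1-\tfrac{S^*}{R}\Big)\Big[\tfrac{K_i}{\bar K} - 1 +
  Z_i\, C\, (S^*/R)^{-1/2}\sqrt{\tfrac{1-R_0/R}{R_0}}\Big],$$

carry an order-one factor $C$ that depends on the sampling depth $S/S^*$.
`calibrate_C()` measures it once, from the simulated $\mathrm{Std}(g)$ at a
single reference condition ($S^*/R = 0.5$, $S^*/S = 0.1$), and the value is
then held fixed across saturations; with permissivity fixed at 0.1
throughout, a single constant is consistent with the theory's claim.  At
$R = 200$, $R_0 = 40$ this gives $C \approx 1.3$, and the predicted DFE
width $\sigma_{\mathrm{inv}} = \lVert\Delta\alpha\rVert\,(1-S^*/R)\,
(S^*/R)^{-1/2}\sqrt{(1-R_0/R)/R_0}\; C$ matches the simulated knock-out DFE
standard deviation within 10% across $S^*/R \in \{0.3, 0.6, 0.9\}$ (the
acceptance suite enforces 15%).

## Fates, coexistence, and extinction statistics

`resolve_invasion()` classifies an established mutant by re-equilibrating:
`COEXISTS` (parent and mutant both survive), `REPLACES_PARENT`, or the
rare `MUTANT_DIES` (a beneficial invader excluded at the new optimum;
tracked separately and excluded from coexistence numerators and
denominators).  The default *sequential* policy re-equilibrates the
pre-invasion survivors plus the mutant; *reinvasion* adds back the full
original pool (allowing "rescued" species), and *simultaneous* assembles
pool plus mutant from scratch.  Because the equilibrium is the optimum of
a concave program, reinvasion and simultaneous assembly coincide here;
both switches are kept to mirror the distinct experimental protocols they
name.

`sample_successful_mutation()` draws parents, targets, and establishment:
targets uniformly among a parent's eligible resources, establishment with
probability proportional to $\max(s_{\mathrm{inv}}, 0)$ (only relative
weights matter), and parents either proportionally to abundance or
uniformly among survivors.  The choice of parent weighting is a genuine
protocol fork with visible consequences:

* *Uniform* parent sampling matches the typical-background averaging of
  the coexistence theory, and reproduces the predicted decrease of
  $P_{\mathrm{coex}}$ with niche saturation followed by a plateau near
  saturation.  The theory-facing ensembles in the acceptance suite use it.
* *Abundance-weighted* sampling (mutational supply proportional to
  population size) couples the sampling weight to the $f_P$-dependent
  coexistence threshold and lifts $P_{\mathrm{coex}}$ at high saturation
  enough to flatten the trend.  It is the default for the multi-step
  protocol and the extinction ensembles, where mutational supply is the
  physically meaningful weight.

`extinction_statistics()` summarizes collateral damage with parents
excluded from all tallies: the extinction-count histogram with its
zero-matched Poisson reference ($\lambda = -\log \hat P(0)$), the
mutant-displaced shared-resource distribution against the community
background, the fold change in target-resource use among displaced
species, and the extinction probability binned by pre-invasion abundance.
Abundances are scaled by $1/S^*$ and binned on log-like breaks
(`0, 0.01, 0.02, 0.05, 0.1, 0.15, 0.25, 0.5, 1, 2, Inf`): extinction risk
concentrates entirely below a quarter of the mean abundance, so linear
bins of the full range cannot resolve the rare-species limit the
statistic is about; the lowest bin (species below 1% of mean abundance)
measures that limit directly.

## The multi-step protocol

`run_evolution()` iterates the mutation-limited loop — enumerate knock-outs
of all survivors, sample one successful mutation, resolve sequentially,
re-equilibrate — until one surviving strain has accumulated 10 mutations
(mutation counts are inherited, child = parent + 1).  "Time" is the
counter of successful mutations; there is no real-time mutation clock.
Lineage bookkeeping records birth and death steps and founder lineages;
`lineage_statistics()` derives survivor and related-strain trajectories
(a strain is *related* if its founder lineage has at least two living
members, which is equivalent to sharing a surviving relative through an
in-situ diversification), per-divergence coexistence durations
(community-wide mutational steps until one branch loses all members,
right-censored at the end of the run, with a Kaplan-Meier maintenance
curve via the `survival` package), and per-decile coexistence fractions.

One observation from these runs is worth flagging.  The first-step
coexistence probability at the multi-step conditions ($R = 100$,
$R_0 = 20$, $S^*/R = 0.9$) is $\approx 0.20$, but under the sequential
policy the community "hardens" within the first ~15 successful mutations
as its most vulnerable (lowest-abundance) members are culled, and the
per-event coexistence fraction settles near 0.3-0.35 over the first decile
of a run before climbing to ~0.8 late, as accumulated knock-outs shrink
supports and roughly quadruple $\lVert\Delta\alpha\rVert^2$.  Allowing
extinct species to re-invade keeps the early fraction at the first-step
value but suppresses the late rise; the sequential protocol is the one
reported.

## Problem sizes and numerical choices

The validation suite uses the study conditions ($R = 200$, $R_0 = 40$,
$S^*/S = 0.1$; $R = 100$, $R_0 = 20$ for multi-step runs) with 50
communities per DFE point, 400-800 sampled invasions per coexistence
point, 9 evolution runs, and 100 randomized instances for the
program-versus-integrator cross-check; these sizes put Monte-Carlo
standard errors comfortably inside the tolerances being tested while
keeping a full run in the minutes range on one core.  Random number use is
localized: every sampled object takes an explicit seed (or a child seed
derived via a fixed 32-bit congruential split of a master seed), and seeded
operations restore the ambient RNG state.

What the generator does *not* emulate is worth stating: no cross-feeding
(supply rates are external constants), no phylogenetic correlation in the
pool, no spatial structure, no demographic noise, and no clonal
interference (strictly one mutation at a time).  Passing tests therefore
validate the mean-field predictions within this model class, not claims
about any particular real community.

## Known limitations

* Exactly degenerate optima admit non-unique abundances; the basic-solution
  reduction makes a deterministic choice and flags it, but quantities that
  depend on the abundances of marginal strains are not meaningful there.
* Near-saturation conditions are represented by the achievable
  $S^*/R \approx 0.97$, not the idealized limit 1; statistics quoted "at
  full saturation" inherit this.
* The coarse-grained model has no absolute biomass scale, so a knock-in
  onto a completely unconsumed resource (undefined availability) is
  rejected rather than priced against the external supply.
* `predict_survivors()` is a simulation surrogate, not a closed form; it
  inherits Monte-Carlo error (reported) and is the one theory-module
  operation that is not analytic.
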