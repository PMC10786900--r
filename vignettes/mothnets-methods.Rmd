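---
title: "Methods: combined diurnal-nocturnal pollination networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined diurnal-nocturnal pollination networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mothnets)
```

## The problem

Plant–pollinator networks are usually built from diurnal transect
observations, while nocturnal flower visitors — above all moths — are
sampled, if at all, by different means (light traps and pollen-load
analysis). `mothnets` implements a complete analysis chain for asking
whether adding the nocturnal component merely *densifies* a diurnal network
(as more sampling would) or genuinely *restructures* it.

The chain: assemble qualitative bipartite networks from long-format records;
measure fifteen structural descriptors; test nestedness and modularity
against a degree-preserving null; simulate extinction robustness; estimate
sampling completeness; test preferential attachment of moths to well-linked
plants; and run an undersampling "break" experiment that compares adding
nocturnal interactions with adding more diurnal ones.

## Network assembly and the pollen-grain threshold

Records are rows of `plant_id, animal_id, period, session_id,
individual_id, pollen_grains`. Diurnal networks score any recorded floral
contact. Nocturnal networks score a plant x moth-species link only when at
least one *individual* moth carried **three or more** pollen grains of that
plant (inclusive bound, evaluated per individual, then collapsed to species
level). The threshold guards against scoring heterospecific pollen
carry-over as an interaction. All assembly is qualitative: every network is
a 0/1 plant x animal incidence matrix, and species exist in a network only
through links. Raising the threshold can only remove links (monotone
filtering), which the tests assert.

## Structural descriptors

With $A$ animals, $P$ plants and $i$ links: matrix size $A P$, web
asymmetry $(A-P)/(A+P)$, connectivities $i/A$, $i/P$, $i/(A+P)$, and
connectance $i/(AP)$. The observed change when nocturnal pollinators are
added is expressed relative to the *combined* value, $100\,(C-D)/C$ — the
convention verified against every consistent printed pair of the source
material's comparison table.

**NODF** (nestedness by overlap and decreasing fill): for an unordered pair
of species in one guild with marginal totals $f_i \ne f_j$ (both $> 0$), the
paired score is $100 \cdot |\text{shared partners}| / \min(f_i, f_j)$;
equal totals or an empty species score 0. Guild scores average over the
guild's pairs; the total divides the summed scores by
$\binom{P}{2} + \binom{A}{2}$. The pairwise rule is order-free, so no
pre-sorting is applied. A single-species guild contributes no pairs and is
defined to score 0 (with a warning) because subsampling can shrink guilds.

**Barber bipartite modularity**
$Q = \frac{1}{i}\sum_{p,a\,:\,g_p = g_a} \left(B_{pa} - \frac{k_p k_a}{i}\right)$
is maximized by a multi-start label-propagation search: asynchronous
label updates in random node order until no improving move exists, a greedy
module-merge pass, iterated to convergence, with 20 independent restarts
plus perturbation restarts around the incumbent (25% of labels jittered).
This follows the search strategy of the DIRTLPAwb+ family rather than
replicating its exact schedule; on every random network with at most nine
species the search provably attains the exhaustive-search maximum
(100/100 in the acceptance suite). The one-module partition has $Q = 0$,
so the returned $Q$ is never negative; when no partition beats 0 the
canonical one-module partition is returned.

## Null models

Significance of NODF and $Q$ uses a **fixed–fixed** null: random matrices
with exactly the observed row and column sums, sampled by the curveball
trade procedure (default $5(A+P)$ trades per replicate, each replicate an
independent chain from the observed matrix on a replicate-indexed seed
substream). Defaults are 500 replicates for NODF and 100 for $Q$; each $Q$
replicate re-runs the module search. The test statistic is
$z = (\mathrm{obs} - \bar{x}_{null})/s_{null}$ with a two-sided normal
$p$. A degenerate null ($s = 0$, e.g. a marginal-rigid matrix — note that
any fully left-packed staircase is the *unique* matrix with its marginals)
yields a warning and $p \in \{0, 1\}$ by exact comparison.

The **preferential-attachment test** ranks plants of the combined species
pool by diurnal degree, descending (rank 1 = most linked; plants seen only
at night enter with degree 0), averages tied ranks, and applies a
pooled-variance two-sample Student $t$ (the published degrees of freedom
match $n_1 + n_2 - 2$, not Welch). If every rank is tied the statistic is
defined as 0 with $p = 1$.

## Robustness

Random primary-extinction curves: species of one guild are removed in
uniformly random order; partner-guild species left without links count as
secondary extinctions (one-way cascades only). Curves are averaged over 100
replicates by default and **R50** is the smallest fraction of removals at
which the *mean* curve reaches half the partner guild's initial richness
(exact step comparison, no interpolation; the per-replicate-then-average
variant is available via `per_replicate = TRUE` as a sensitivity check —
which of the two the original analysis used is not documented). Exhaustive
enumeration of all removal orders on guilds of up to five species is the
test oracle.

## Sampling completeness

Incidence tables (entity x session, entities being species or
plant–animal pairs; nocturnal entities respect the grain threshold
per-session) feed the Chao 2 estimator with the small-sample factor:
$S_{est} = S_{obs} + \frac{m-1}{m}\frac{q_1^2}{2 q_2}$ for $q_2 > 0$ and
the bias-corrected $S_{obs} + \frac{m-1}{m}\frac{q_1(q_1-1)}{2}$ when
$q_2 = 0$. Completeness is $100\,S_{obs}/S_{est}$. Calibration: with
homogeneous detection (60 species, 12 sessions, detection 0.25) the mean
estimate over 200 simulated surveys carries an intrinsic positive bias of
about half a species, so the calibration test asserts agreement with the
true richness within a documented 2% band rather than within one standard
error of the mean (which is ~0.13 species, tighter than the estimator's
own bias).

## The resampling "break" experiment

With $d$ diurnal and $n < d$ nocturnal links, the diurnal network is
subsampled at 10%, 20%, ... of $d$ (floored), capped at exactly $d-n$, and
the full network appended as a point value; each level gets 100 replicates
and percentile 95% CIs (2.5th–97.5th; no CI method is prescribed by the
source, a normal-approximation CI is available). Matrices are always
rebuilt from the retained link set, so species drop out and re-enter
automatically. The **mixed** endpoint unions a fresh $(d-n)$-subsample with
all $n$ nocturnal links. A metric *breaks* when the full-diurnal point
value falls outside the mixed CI; the direction is the sign of the mixed
mean minus that value. Monitored metrics follow the seven rows of the
source's comparison table (connectance, web asymmetry, total connectivity,
NODF, $Q$, R50 A, R50 P); the accompanying text mentions "eight network
properties" but prints seven rows — the seven are implemented. Inside
replicated loops the modularity search uses 5 restarts and R50 25 inner
replicates (configurable) to stay desk-scale; endpoint values use full
effort.

The CI-overlap rule is not an exact $\alpha = 0.05$ test: under a strict
exchangeability null (see below) per-metric false-positive rates of 5–10%
were measured, which is why the null acceptance band is "at least 90%
non-significant".

## The synthetic world

`generate_community()` emits record sets with the statistical structure the
analysis assumes, at the scale of the study system: ~40 plants x ~100
diurnal animals with 300 diurnal links (lognormal attractiveness on both
guilds gives plant-degree CV > 0.5 and skewed, connected networks —
connectivity enforced by rejection), 15 moth species with 25 nocturnal
links (the field networks held 13–16 moths and 20–34 links), 20 diurnal and
3 nocturnal sessions, and negative-binomial per-individual grain counts
(mean 8, size 0.8 — overdispersed, most moths carrying few grains), with at
least one qualifying individual per intended link and additional
individuals free to fall below the threshold.

Three moth-placement scenarios:

* **random** — moth links uniform over plants; used for type-I calibration.
  The attachment test rejects at ~6% instead of 5% over many seeds: plants
  visited *only* nocturnally enter the rank pool with diurnal degree 0,
  while comparable unvisited plants are unobservable. This detection
  asymmetry is a property of the sampling design itself, not a bug, and is
  mild at the default sizes.
* **preferential** — link probability proportional to current diurnal
  degree; at the documented power configuration (50 plants, 30 links) the
  attachment test rejects in >80% of seeds with moth plants ranking better.
* **syndrome** — a *planted* night module, constructed the way
  planted-partition generators are: a single dominant night-flowering hub
  (think of a dominant *Silene*-like species) receives every moth's primary
  pollen load; satellite syndrome plants receive the moths' secondary loads
  (each satellite at least twice, from hub-sharing moths, so the block is
  connected); each link is redirected to a uniformly random plant with
  probability $1 - \mathrm{assortativity}$ (default 0.95). Syndrome plants
  are the plants least attractive to diurnal visitors, further discounted
  x0.05 — but each keeps at least one diurnal link, mirroring the field
  observation that the large majority of moth-visited plants also receive
  diurnal visits. Designs without that anchoring flip the web-asymmetry
  break direction (new plants offset new moths); designs without the
  hub-and-satellite structure leave the moth block disconnected and the
  planted module unrecoverable. Residual recovery failures (~12% of seeds)
  are almost all cases where two stray-redirected moths sit outside the
  main module.

What a green test does *not* establish: the generator has no phenology, no
abundance-mediated detection beyond session incidence, no shared species
between the diurnal and nocturnal animal pools, and pollen identification
is taken as error-free; real data violate all four.

## Numerical and design choices

* Determinism: every stochastic stage draws a named substream from the
  master seed (`substream_seed`), so changing one stage's replicate count
  never perturbs another; C++ kernels use their own `mt19937` streams.
* Label-propagation ties break toward the first-encountered label in the
  (seeded) random sweep order; improvement requires a gain above 1e-12.
* Fractional subsampling levels floor to integers; the $d-n$ endpoint is
  exact; percentile CIs use `quantile(type = 7)`.
* Module ids are contiguous from 0 and comparable only up to permutation
  (tests compare co-membership).
* Species identity is the exact label string; merging morphospecies with
  indistinguishable pollen is the user's pre-cleaning job.

## Known limitations

Qualitative networks only (no weighted variants, by design); no
degree-ordered attack sequences or area-under-curve robustness; no
Chao1/ACE/jackknife estimators; published site-level NODF/Q/R50 values
require the original field data and are covered here only by property and
oracle tests, not numeric reproduction.
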