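---
title: "Calibrating a rule-matrix immune ABM to clinical ranges: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating a rule-matrix immune ABM to clinical ranges: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmcal)
```

## The problem

Clinical cytokine time series from heterogeneous cohorts are not curves but
*corridors*: at each sampling time the cohort spans a `[min, max]` interval,
and the width of that corridor changes over time.  Calibrating a mechanistic
simulation to the mean of such data discards exactly the biology that makes
the cohort heterogeneous, and tends to produce brittle, over-fitted models.
`mrmcal` takes the opposite approach: a candidate parameterization is scored
by how well the *range* of its stochastic replicate simulations matches the
clinical range, every candidate that cannot be invalidated by the ranges is
retained, and the product of calibration is an *ensemble* of bioplausible
parameterizations rather than a single best fit.

Three ingredients implement this:

1. a reduced stochastic agent-based model (ABM) of the endothelial--blood
   interface after injury, whose cytokine rules are driven by an evolvable
   **Model Rule Matrix** (MRM);
2. a **range-envelope fitness**: replicate trajectories are normalized,
   collapsed into per-cytokine/per-time min--max envelopes, and compared to
   the clinical ranges through their maxima, plus a mortality-rate term;
3. a real-valued **genetic algorithm** (GA) with tournament selection,
   elitism, uniform arithmetic crossover, a rising mutation schedule, a
   non-viability filter and an ensemble-retainment rule.

## The Model Rule Matrix

Rules are rows; the entities that can contribute to a rule are columns
(mediators plus the lattice signals `damage` and `infection`); each element
is a dimensionless coefficient in `[-2, 2]`.  A zero element means "no
connection", so the GA can both re-weight existing rules and switch
connections on or off -- rule existence *is* nonzeroness.  The matrix
flattens row-major into the GA genome and `unflatten()` inverts it exactly
(fixed by round-trip property tests).

Two shape defaults coexist deliberately.  `default_mrm_shape()` is the
reference shape, 18 rules by 24 entities = 432 free continuous parameters.
The reduced simulator shipped here has 8 mediators and therefore 10 entity
columns; its default rule table (6 producing cell types x 8 output mediators
= 48 rules) gives a 480-gene genome.  432 is not divisible by 10, so no
rule-table choice could make the two coincide without changing the mediator
count; both are configuration-driven and nothing downstream depends on the
specific factorization.

## The reduced simulator

The interaction space is a toroidal lattice of endothelial sites (default
40x40; the desk-scale configuration uses 20x20).  Each site carries a damage
level in `[0, 1]` and a non-negative infection level; each mediator has a
concentration field over the lattice.  Mobile agents -- macrophages,
neutrophils, TH0/TH1/TH2 cells -- move over the torus.  A step advances a
fixed substep order:

1. **Diffusion and decay** of every mediator field (4-neighbour averaging at
   rate `diffusion`, then exponential decay at rate `decay`).
2. **Agent movement**: chemotaxis to the strictly-largest neighbouring
   concentration of the cell type's attractant if a gradient exists,
   otherwise a uniform random step; ties break by a seeded draw.
3. **Rule firing**: each agent fires the rules its cell type owns at its
   site; endothelial rules fire at every damaged site.  A rule adds
   `max(0, sum_j M[r, j] * input_j) * production_scale` of its output
   mediator.  Inputs are read from the *start-of-step snapshot* of the
   fields and lattice signals, i.e. the update is synchronous in the rule
   layer.  This choice is what lets the package reproduce hand-iterated rule
   systems exactly: with `decay = 1` (full per-step turnover) the rule output
   *is* the next state, so the two-rule illustration
   `M1' = M1 + M2; M2' = -M1 + M3` (clamped at zero) is recovered
   step-for-step by a 1x1-lattice configuration.  Concentrations then
   saturate at `field_cap`; biologically a secretion/receptor ceiling,
   numerically the guard that keeps runaway positive-feedback genomes (which
   random GA initialization produces routinely) finite.
4. **Infection spread and harm**: infection grows by
   `microbial_invasiveness` times the neighbour mean, damages tissue at
   `microbial_toxigenesis` per unit infection, and is cleared by
   phagocytosing agents.  **Cytokine toxicity** acts here too: circulating
   (lattice-mean) levels of designated toxic mediators (TNFa by default)
   damage all tissue uniformly.  This systemic channel is what makes a
   *sterile* burn lethal: with the microbial parameters at zero there is
   otherwise no mechanism by which damage can grow, and it mirrors the
   systemic inflammatory pathophysiology the full-scale model family
   represents through bystander neutrophil/cytokine damage.  Making the
   channel systemic rather than local is a deliberate dynamical choice: it
   creates a global bistability (runaway inflammation vs. resolution) whose
   outcome genuinely diverges across stochastic replicates, rather than a
   local front whose speed is essentially deterministic.
5. **Repair**: damaged-but-not-dead sites recover `host_resilience` per
   step; dead sites (`damage = 1`) regenerate only from the frontier, at
   `host_resilience` scaled by the fraction of non-dead 4-neighbours.
   Without frontier regeneration an initially fully-damaged burn patch could
   never heal and the died/healed outcome dichotomy would collapse.
6. **Environmental re-exposure** seeds one random site with infection with
   probability `environmental_toxicity`.

The patient **dies** when the total damage fraction exceeds 0.80 (strictly),
**heals** when damage and infection are both exactly zero, and is
**censored** at the horizon (22 days by default) otherwise.  Termination is
applied by `run_simulation()`; `step_simulation()` is a pure state advance.

Per-step lattice totals of every mediator are recorded; clinical sampling
times map to the nearest recorded step.

### Stochasticity and reproducibility

Randomness enters through initial agent placement, un-directed movement,
chemotaxis tie-breaks and re-exposure.  Each simulation owns a private
splitmix64 PRNG seeded from its `seed` argument, so a `(params, genome,
seed)` triple is bit-reproducible across platforms and independent of R's
RNG state.  Replicate and candidate seeds derive from a root seed by a
stateless integer hash (`derive_seeds()`), so evaluations are reproducible
regardless of scheduling order.

### What the reduced model is not

Cell-level fidelity of the full-scale simulator is out of scope: precursor
population dynamics, oxygen/ischemia, and detailed receptor logic are not
represented; agent populations are fixed.  The three generic intermediate
mediators exist to give the genome room for discovered connections, not to
model named biology.  Passing tests on this model demonstrate that the
*calibration machinery* behaves as specified on a system with the right
structure (stochastic divergence, range heterogeneity, a mortality
dichotomy); they say nothing about quantitative agreement with any real
cohort, whose values are not encoded anywhere in this package.

## Injury scenarios

Five dimensionless parameters position a simulation in injury space: injury
size, microbial invasiveness, microbial toxigenesis, environmental toxicity
and host resilience.  A burn is caustic and sterile: both microbial
parameters are zero.  The packaged reference burn
(`reference_burn_injury()`) damages 40% of the lattice and sets
environmental toxicity to zero; host resilience is 0.1 per hour of simulated
time (0.10 per 60-minute desk step, 0.10/6 per 10-minute reference step).

## Fitness, viability, bioplausibility

For cytokine $i$ and sampling time $t$, let $C^e_{i,t}$ be the clinical
range and $C^m_{i,t}$ the replicate envelope of normalized model totals.
The fitness of a candidate is

$$F \;=\; \sum_{i,t} w_i \left| \max(C^e_{i,t}) - \max(C^m_{i,t}) \right|
\;+\; k \left| R_e - R_m \right|,$$

summing over the evaluated (non-held-out) sampling times, with $R_e$ the
cohort mortality rate, $R_m$ the replicate mortality, $w_i$ a per-cytokine
weight, and $k$ the mortality coefficient.  Lower is better; $F = 0$ iff
every evaluated envelope maximum equals its clinical maximum and
$R_m = R_e$.  `range_mode = "minmax"` adds the symmetric range-minimum terms
for users who prefer the both-ends reading of "range difference".

Choices embedded here:

* **Normalization.** Model totals and clinical ranges are each divided by
  the per-cytokine clinical maximum over all sampling times
  (`normalize_trajectory()`, `normalize_targets()`), mapping every cytokine
  into `[0, ~1]` so that the weights $w_i$ are comparable across cytokines
  of very different absolute magnitude.  `compute_fitness()` itself is the
  bare printed equation and requires its two arguments on a common scale;
  `evaluate_candidate()` wires the normalization correctly.
* **Weights.** Default 1, except IL-10 at 2.  A cytokine that spikes late
  and is near zero elsewhere contributes little to an equally-weighted
  fitness, so candidates that simply never produce it are barely penalized;
  doubling its weight suffices to recover the late peak.
* **Mortality coefficient.** No principled value presents itself *a priori*;
  the package default is $k = 10$, which puts a full-scale mortality
  mismatch (one) on the same footing as roughly ten fully-missed envelope
  maxima, and is overridable everywhere.
* **Held-out times.** 48 h and 8 d (192 h) are excluded from $F$ by default
  as an overfitting guard; they remain in the targets object and can be
  compared after calibration.
* **Dead replicates.** A replicate that dies (or heals) before a sampling
  time contributes its last recorded value, carried forward, so the
  envelope stays rectangular.  This is isolated in `sample_at_targets()`.

A candidate is **non-viable** if a replicate dies before the first clinical
sampling time (3 h); under the strict default (`nonviable_mode = "any"`) one
early death suffices.  Non-viable candidates are replaced by a uniformly
chosen viable candidate of the same generation.  An optional fitness ceiling
`F_c` can additionally be enabled but is off by default.

A candidate is **bioplausible** if its whole envelope lies inside the
clinical ranges (boundaries inclusive, held-out times not examined): the
data then cannot invalidate it.  Every bioplausible candidate encountered in
any generation enters the append-only ensemble archive (duplicates stored
once).  Note that containment is a statement about the replicate sample, not
the generating process: re-evaluating a bioplausible candidate with fresh
seeds can place an envelope edge slightly outside narrow target ranges.
Range envelopes from small replicate counts are noticeably unstable; the
package's own tests use 30-replicate targets and width-proportionally
inflated corridors (`inflate_targets()`) when asserting containment under
re-sampling.

## The genetic algorithm

Generational, minimizing, population even-sized (default 1024 full scale;
64 desk scale):

* **Tournament selection**, size 2: random pairs, lower fitness wins, ties
  break by a seeded coin flip; the pool has population size.
* **Elitism**: the `floor(0.10 n)` worst pool members are replaced by the
  `floor(0.10 n)` fittest candidates of the previous generation.  Elites
  are *also* copied verbatim into the next generation, carrying their cached
  evaluation.  Both halves matter: because fitness is re-estimated from
  stochastic replicates, a re-evaluated elite could score worse by sampling
  luck alone, and the best-fitness trace would no longer be monotone.
  Carrying the cached evaluation makes the monotone-trace guarantee exact.
* **Crossover**: uniform arithmetic, `c1 = b*p1 + (1-b)*p2`,
  `c2 = b*p2 + (1-b)*p1`, with an independent `b ~ U(0,1)` *per gene* --
  the per-gene draw is what makes the operator uniform; a single-`b`
  variant is available (`crossover_mode = "single_beta"`).  The identity
  `c1 + c2 = p1 + p2` holds gene-wise to machine precision.
* **Mutation**: one draw per child; with probability
  `r_m = 0.01 + 0.002 g_n` (capped at 1; the cap binds only beyond
  generation 495) exactly one uniformly chosen gene is replaced by a fresh
  `U(-2, 2)` value.  The rising schedule re-injects diversity as the
  population converges.
* **Pairing** is a random permutation of the pool (without replacement) by
  default; with-replacement pairing is available.
* **Stopping**: fitness exactly 0 (a single parameterization explains the
  data perfectly -- not observed on heterogeneous targets) or the
  generation cap.

The whole loop is a deterministic function of `root_seed`: R-level draws
come from one seeded stream and candidate evaluations use hash-derived
seeds keyed by `(root, generation, slot)`.

**Diversity** is tracked per generation as the sum over genome positions of
the across-population range of that position (at most 4 per gene).  On the
packaged desk run the trace starts near-maximal, collapses during
convergence and recovers slightly as the mutation rate rises.

## Fixtures: targets with and without a known answer

No machine-readable clinical dataset exists for this problem -- the
published cohort's values were only ever available by inspecting figures --
so the package generates everything it needs and makes no attempt to encode
the real values:

* `make_clinical_like_targets()` emulates the documented *shape* of such a
  dataset: 5 cytokines (GCSF, TNFa, IL-4, IL-10, IFN-gamma), 15 sampling
  times over 22 days starting at 3 h, 50% cohort mortality, held-out points
  at 48 h and 8 d, and a log-normal-like pulse per cytokine with the IL-10
  pulse centred at day 5 and narrow.  Amplitudes are arbitrary units; range
  widths default to 60% of the maximum, mild seeded jitter keeps the curves
  from being suspiciously smooth.
* `make_surrogate_targets()` runs a *known* genome and converts its
  replicate envelope into targets, making calibration a recovery problem
  with a known answer: the generating genome scores exactly `F = 0` when
  re-evaluated with the same replicate seeds, and the desk GA's best
  fitness must fall below its random-initialization best.
* `make_reference_calibrated_genome()` is the packaged, deterministic,
  hand-designed parameterization: damaged endothelium secretes TNFa and
  GCSF; macrophages and neutrophils amplify TNFa and are suppressed by
  IL-10; macrophages produce IL-10 downstream of TNFa; TH1/TH2 produce
  IFN-gamma/IL-4.  One scalar -- the pro-inflammatory amplification gain --
  was calibrated once, by scanning it and estimating replicate mortality at
  n = 450, so that the reference burn sits on the stochastic separatrix
  between runaway inflammation and resolution with death probability close
  to 0.5.  The calibrated values (gain 1.53 full scale, 1.70 desk scale)
  are frozen in code; 50 replicates then die at a rate statistically
  consistent with a 50% cohort rate, with both died and healed outcomes
  present and no death before the 3 h viability cutoff.

## Problem sizes and numerical choices

The packaged desk scale -- 20x20 lattice, 60-minute steps, population 64,
10 replicates per candidate, 30 generations -- was chosen so that a full
surrogate-recovery calibration (about 19,000 simulations) completes in well
under a minute per generation on one core while still exercising every
mechanism; the reference scale (40x40, 10-minute steps, 50 replicates) is
used for single-parameterization work such as the mortality check.  Rates
are per step, so the desk configuration's per-step constants are the
reference constants scaled by the step-length ratio.

Other numerics: gene bounds are enforced by clamping after mutation;
boundary comparisons in bioplausibility use a 1e-12 absolute tolerance so
that exact-equality containment counts as inside; envelope construction
requires at least one replicate and errors on empty input; genome
serializations write 17 significant digits so JSON round trips are exact;
all file formats are plain text (CSV, JSON, JSON Lines, YAML).

## Known limitations

* The reduced simulator's mortality dichotomy rests on the systemic
  toxicity channel; parameterizations with near-zero TNFa production are
  effectively immortal and are filtered only by fitness, not viability.
* Ensemble containment is sample-based (see above); archive members are
  bioplausible with respect to their recorded seeds.
* The GA evaluates candidates serially; the evaluation contract
  (stateless, seed-keyed) admits process-level parallelism, but none is
  implemented here.
* Desk-scale GA runs recover fitness reliably but rarely reach the
  bioplausible corridor of *un*-inflated surrogate targets within 30
  generations; the ensemble archive is expected to be sparse at desk scale.
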