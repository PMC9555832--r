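---
title: "Drift on a lattice: the driftgrid model and its design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift on a lattice: the driftgrid model and its design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftgrid)
```

## The model

driftgrid simulates neutral genetic drift in a haploid, single-locus
population arranged on a bounded `rows x cols` lattice (default 32 x 32,
hence 1,024 individuals). Dynamics follow a spatial Moran model in its
death-birth (voter-model) form. One elementary event:

1. a **target** cell is drawn uniformly among all non-barrier cells;
2. if occupied, its occupant dies, leaving the cell momentarily empty —
   in particular the dying individual can never be its own parent;
3. a **parent** is drawn uniformly among the target's *occupied* Moore
   neighbours (the up-to-8 adjacent and diagonal cells); barrier cells
   and empty cells never parent offspring;
4. the offspring occupies the target, copying the parent's allele with
   probability `1 - mu`, or carrying a brand-new allele with probability
   `mu` (the infinite-alleles model: every mutation is novel, allele ids
   are globally unique and never reused);
5. if the target has *no* occupied neighbour, the event is a **no-op**:
   an occupied target's individual survives and an empty target stays
   empty. No-ops are counted (`noop_count`) for transparency.

Edges are hard — there is no wraparound. Corner cells have 3 neighbours,
edge cells 5, interior cells 8, which produces a small, real edge effect.
A **generation** is a batch of `steps_per_generation` events (default
2,000), and is the granularity at which trajectories are recorded and
fixation is evaluated.

**Initialization (Hoppe's urn).** The founding population is built
sequentially: the first individual always carries a new allele, and
individual $i+1$ carries a new allele with probability
$\theta/(\theta+i)$, otherwise copying a uniformly chosen earlier
individual, with $\theta = 2N\mu_{\text{init}}$ and $N$ the number of
non-barrier cells. The allele partition is then Ewens-distributed, with
$\mathrm{E}[K] = \sum_{i=0}^{N-1} \theta/(\theta+i)$ distinct founder
alleles expected. Urn outputs are placed on the open cells in row-major
order; since the urn sequence is exchangeable, this choice costs no
generality while keeping runs deterministic given the seed.

**Theory anchor.** For `mu = 0` on a fully occupied grid, let
$W(a) = \sum_{v:\,x_v = a} d_v$ with $d_v$ the Moore degree. One event
changes $\mathrm{E}[W]$ by
$\frac1N \sum_v d_v \left( \tfrac1{d_v}\sum_{u\sim v} x_u - x_v \right) = 0$,
so the degree-weighted frequency $W(a)/\sum_v d_v$ is a martingale and an
allele's fixation probability equals its initial value. The test suite
checks this two ways: exactly, against a brute-force absorbing-chain
solve on 2 x 2 and 1 x 3 grids (state spaces enumerated independently of
the engine), and by Monte Carlo on 8 x 8, where a corner allele must fix
with probability $3/420$.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `rows`, `cols` | 32, 32 | cells | the standard classroom grid; 1,024 individuals keep fixation times in the hundreds-to-thousands of generations |
| `init_mu` | 0.001 | probability/birth | sets founder diversity via theta = 2N mu = 2.048 (about 13 expected founder alleles) |
| `run_mu` | 0 | probability/birth | pure drift by default; raise it to study mutation-drift balance |
| `steps_per_generation` | 2000 | events | snapshot cadence; about two birth opportunities per cell per generation on the full grid |
| `seed` | none | — | seeds R's RNG at initialization; every subsequent draw comes from that stream |
| `max_generations` | 100000 | generations | guards non-terminating loops; hitting it sets `cap_hit`, never an error |

## Design decisions

Several points were genuinely open; the choices made, and why:

* **One adjacency for everything.** Moore (8-cell) adjacency is used both
  for parent selection and for connected-component labelling. A
  diagonal-only gap in a barrier is therefore passable — alleles leak
  through it — and the component report agrees with what the kernel can
  actually do. Labels are ordered by each component's smallest row-major
  cell so reports are stable.
* **Empty cells are ordinary targets.** Removing a barrier leaves the
  cell *empty*, not occupied; because targets are drawn uniformly over
  all non-barrier cells, empty cells are recolonized by the same kernel
  that drives drift — no second "fill" process exists. Filling an empty
  cell is the only step-driven population change; on a barrier-free full
  grid population size is exactly conserved.
* **No-parent events are survivals.** A target whose neighbourhood is all
  barrier/empty could alternatively kill the occupant; that would
  silently shrink walled-in pockets, contradicting the accounting that
  population declines only through barrier creation. We chose survival
  and count the no-ops.
* **Mutation fires on births only**, never on no-ops, and the mutation
  uniform is drawn on every birth regardless of `mu`, so the RNG stream
  layout does not depend on the value of `mu`. The fixed per-event draw
  order is: target, parent index (only if a parent exists), mutation
  uniform (only on a birth).
* **theta uses the non-barrier count.** When a mask is passed to
  `hoppe_urn_init()`, N counts the open cells. The scripted experiments,
  mirroring an interactive session, initialize the *full* grid first and
  then draw barriers as generation-0 events, so their theta is 2.048.
* **Fixation on snapshots.** Fixation is detected at generation
  snapshots, not per event; a mid-generation fixation is reported at the
  next snapshot. With `mu > 0` the stop rule is the first monomorphic
  snapshot, an approximation (new mutants may appear immediately after).
  A component's fixation is judged on its occupied cells; a fully empty
  component never fixes and is reported via the generation cap.
* **Initial/mutant colors.** The palette rule (18 basic colors for
  founder alleles, 6 neon for mutants, cycling) needs only the value of
  `next_allele_id` at the end of initialization: ids below it are
  founders. No per-allele provenance is stored.
* **Barrier geometry of the experiments.** The quadrant experiments use a
  horizontal line at row 15 and a vertical line at column 15 (quadrants
  of 225, 240, 240 and 256 cells — "roughly equal"), with a 3-cell
  corridor at the midpoint of the vertical line's upper segment (rows
  6-8), which merges the two top quadrants only. All of this is
  configurable; the defaults are declared conventions, not measurements.

## The quadrant-independence comparison

`activity2_quadrant_study()` checks that a quadrant behind absolute
barriers fixes on the same time distribution as an independent,
free-standing population. Two calibrations are required for the
comparison to be an apples-to-apples one:

* **Initial diversity.** The quadrant's founders are a size-n subsample
  of the full grid's urn; by the subsampling consistency of the Ewens
  distribution such a subsample is Ewens with the *same* theta. The
  independent arm therefore uses `init_mu = theta_full / (2 n_quad)`
  rather than the default.
* **Event clock.** Inside the barred grid a quadrant of n cells receives
  on average `2000 n / 961` events per generation (961 = open cells after
  the 63 barrier cells), while a free-standing grid of n cells would
  receive 2000. The independent arm uses
  `steps_per_generation = round(2000 n / 961)` so "a generation" means
  the same amount of per-cell turnover in both arms (the rounding error
  is below 0.1%).

With both matched, the two arms are compared by a Kolmogorov-Smirnov test
at alpha = 0.01 over 500 replicates per arm in the acceptance suite.

## What the generator emulates — and what it does not

The simulator reproduces the mechanics of neutral drift on a lattice:
finite-N sampling noise, spatially local inheritance, isolation by
barriers, gene flow through corridors, and infinite-alleles mutation. It
deliberately omits selection, diploidy and recombination, multiple loci,
back-mutation, long-range dispersal, demographic growth, and
continuous-time dynamics. Passing tests therefore validate the *neutral
spatial null model*, not any claim about populations with selection or
non-local dispersal; real data will additionally contain features (e.g.
overlapping generations with variable fecundity) the Moran kernel only
caricatures.

## Numerical and testing choices

Reproducibility is seed-based: a config's seed is applied at
initialization and every later draw (urn, targets, parents, mutation)
comes from R's Mersenne-Twister stream, consumed identically by the
R-level and the batched C++ paths — so recording a trajectory on or off,
or replaying from an event log, yields bit-identical populations. The
problem sizes used by the test and acceptance suites are chosen to give
tight checks at desk scale: 2,000 urn initializations at N = 1024 for the
Ewens mean (3-standard-error band), 100,000 Monte-Carlo runs per tiny
grid against the exact chains (99% binomial CIs), 5,000 replicates for
the 8 x 8 martingale check, and 500 replicates per arm for the
Kolmogorov-Smirnov comparison. Trajectory CSV serializes frequencies to
10 significant digits; round-trips are exact at that precision.

## Known limitations

* Fixation times are reported in whole generations; sub-generation
  resolution requires `steps_per_generation = 1`, which is supported but
  verbose for large grids.
* The component labelling is recomputed from the barrier set; there is no
  incremental update, which is fine at classroom scales (a 32 x 32
  labelling costs about a millisecond) but would not scale to very large
  lattices.
* With `mu > 0` "fixation" is a stopping heuristic, not an absorbing
  state; interpret `generations_to_fixation` accordingly.
* Barrier edits are instantaneous and exogenous; there is no scheduling
  of edits at sub-generation resolution.
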