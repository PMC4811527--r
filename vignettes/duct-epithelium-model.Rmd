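---
title: "An agent-based model of the mammary ductal epithelium: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of the mammary ductal epithelium: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ductsim)
```

## The model

`ductsim` simulates a segment of mammary duct as a discrete-time agent-based
model. The tissue is a two-dimensional lattice of columns with three canonical
layers — fibroblasts, myoepithelial cells (the basement membrane), and luminal
epithelial cells — plus an overflow band above the luminal layer that holds
hyperplastic expansion, and a sub-membrane compartment reachable only by
invasion. One step is one day; a simulation covers forty 365-day years of
menstrual cycling, the span between menarche and menopause. The
post-menopausal state is deliberately out of scope.

Each luminal cell carries: its ER expression state, a telomere counter
(remaining divisions), an unrepaired-DNA-damage level, an abstract
intracellular proliferation signal (called AKT), and a twelve-gene functional
genome under a two-hit copy-number model. The genes and their functions:

```{r}
gene_table()
```

### Hormones and paracrine signalling

Estrogen and progesterone follow a deterministic, strictly periodic 28-day
waveform (`hormone_cycle()`): a follicular estrogen baseline rising to a
single periovulatory peak at day 12 with a smaller luteal plateau, and a broad
luteal progesterone peak centred on day 21. The waveform is idealized and
normalized — only its shape matters, because every downstream threshold is
calibrated in the same units. Progesterone is carried in the state (PR
expression follows ER expression) but has no behavioural hook by default.

ER+ luminal cells respond to estrogen by producing amphiregulin. Fibroblasts
convert local amphiregulin into HGF with a saturating (Michaelis) response.
HGF drives proliferation of ER− luminal and myoepithelial cells through
c-Met; ER+ cells normally suppress c-Met and instead respond to amphiregulin
through EGFR, with an early-saturating receptor response. A small constitutive
mitogenic tone keeps regions transiently distant from ER+ cells from
freezing; it is deliberately not attributed to HGF, whose production is zero
at zero amphiregulin. Growth inhibition is a crowding tone proportional to
the local (column-smoothed) luminal density; most of it is TGF-β signalling
that cells escape by losing the TGF-β receptor, and the remainder is physical
crowding that cannot be escaped. Signals are recomputed each day from
occupancy within a finite column radius — there is no carry-over and no
long-range field.

### AKT dynamics and mitosis

Each cell integrates its mitogen inputs minus the crowding tone into AKT,
with a small daily decay, clamped at zero and capped at the mitosis
threshold. A cell at threshold attempts mitosis: the damage checkpoint runs
first (senescence above the lower threshold, apoptosis above the higher one,
both bypassed by P53 loss), then the telomere check (an exhausted telomere
without telomerase means replicative senescence). Daughters are placed in a
free adhered slot in the same or an adjacent column; when no adhered space
exists, only anoikis-resistant (E-cadherin-null) lineages may place daughters
in the overflow band, up to a configured per-column depth. Cells of the
invaded compartment divide without lattice constraint but under a (weaker)
crowding tone of their own compartment. Both division products have their
telomere decremented (unless telomerase is active), AKT reset, and receive
mutation hits independently; the unrepaired lesion burden is diluted two-fold
by replication. Daughters inherit the parent's genome snapshot and its ER
state; with a small probability, daughters placed in the organized adhered
layer differentiate (redraw their ER state at the baseline ER+ proportion).
Disorganized overflow or invaded growth breeds true — a design decision that
makes a tumor's receptor status a property of its founding lineage and its
drivers rather than of clone age.

### Damage, repair and mutation

Every day each luminal cell acquires a uniform random damage increment on
`[0, d_max]` (bounded, "random but limited"), capped at a physical ceiling,
and repairs a fixed daily capacity. Losing a repair gene multiplies the
capacity: strongly for BRCA1, mildly for P53; a single remaining BRCA1 copy
is haploinsufficient (a mild multiplier), which is what distinguishes the
germline-carrier arm beyond needing only one further hit. Cells dividing
with unrepaired damage acquire mutations: each division product receives
`Bernoulli(min(1, beta * damage)) + Bernoulli(epsilon)` allele hits — a
damage-dependent term linear in the carried damage, plus an independent
replication-error term. Each hit targets one of the twelve genes uniformly;
a hit to a gene already at zero copies is absorbed (it has no functional
meaning and is not recorded). The second ESR1 hit draws one of three variant
behaviours uniformly: V1 produces amphiregulin autonomously regardless of
estrogen, V2 adds a direct estrogen-to-AKT input (non-genomic signalling),
V3 combines both at half strength.

Mutation targeting is uniform by design: no gene-specific rates exist
anywhere in the model, so every differential mutation pattern reported by the
cohort statistics — early BRCA1 in ER− tumors, early telomerase/TGF-β-receptor
in ER+ tumors and hyperplasias — is produced by selection, not by input bias.

### Outcomes

A run stops the day the malignancy definition is first met: luminal
population above ten-fold baseline together with basement-membrane breach
(at least one living MMP3-null cell having claimed a sub-membrane position;
the breach flag is sticky). Hyperplasia — a final census above twice baseline
without malignancy — is assessed only at the end of the simulated period, so
transient expansions that regress count as normal. Receptor calls use strict
thresholds on the final luminal population: ER+ above 9% of cells expressing
ER (the physiologic baseline rate of ER expression in the model's normal
tissue), HER-2+ above 5%.

A population's "total mutations" is the length of the mutation history of its
dominant final lineage — the modal identical-history group among living
luminal cells, ties broken to the earliest-created genotype. This matches the
event-count notion used by the cohort statistics (allele-loss events acquired
by a cell lineage); a population-weighted alternative was considered and
rejected because lineage histories are what the early-mutation analysis
consumes.

## How tumors arise in the model

Three emergent routes matter, and the calibration shapes their balance:

1. **The hyperplasia ladder.** A lineage that loses E-cadherin can expand
   into the overflow band; further losses (TGF-β receptor to escape the
   crowding brake, telomerase to sustain replicative depth, RUNX3 or ESR1
   variants to amplify the estrogen-driven path) raise its carrying capacity
   step by step. These clones are predominantly ER+ — the potent amplifier
   rungs act through the estrogen/amphiregulin axis — and mostly stall as
   persistent hyperplasias; a minority that also loses MMP3 breaches and
   progresses.
2. **The repair-window cascade.** Losing the second BRCA1 copy collapses
   repair capacity below the mean daily insult: damage then drifts upward
   until the checkpoint senesces the lineage. Within that window the lineage
   is hypermutable at division; if it also loses P53 (bypassing the
   checkpoint) the state becomes permanent and the lineage accumulates
   functional losses quickly. In the carrier arm a single somatic hit opens
   this window in any lineage, which is why carrier incidence is more than an
   order of magnitude higher and why carrier tumors are enriched for early
   BRCA1 loss and for ER− status (window entry is proportional to division
   activity, not to the ER+ amplifier set).
3. **Fertile ground.** Hyperplastic clones divide far more than resting
   tissue, so cascades preferentially ignite inside them — the route by which
   ER+ hyperplasias transform.

## Parameters

All parameters live in a single nested configuration (`ds_config()`), every
one with a default; the defaults are the package's calibrated operating
point. The primary calibration knobs, in model units:

* `damage$d_max` (0.12/day) and `damage$repair_capacity` (0.10/day) set the
  wild-type damage steady state safely below the senescence threshold (1.0;
  apoptosis at 1.5, ceiling at the configured maximum a cell can carry).
* `damage$epsilon` and `damage$beta` set the background and damage-dependent
  mutation intensities. They control, jointly with turnover, the mean
  mutation count of normal populations and (quadratically, through two-hit
  co-occurrence) every downstream event rate — the model is deliberately
  sensitive to them.
* `damage$deficit_brca1`, `damage$het_deficit_brca1`, `damage$deficit_p53`:
  repair-capacity multipliers. The BRCA1-null multiplier is chosen so that
  repair capacity falls just below the mean daily insult — a slow upward
  drift that gives the mutable window its duration.
* `cells$baseline_apoptosis` (per day) sets epithelial turnover, hence
  replicative depth over forty years; `cells$telomere_initial` leaves enough
  margin that normal tissue never senesces en masse while expansions still
  require telomerase. `cells$overflow_apoptosis_factor` (<1) encodes the
  reduced apoptotic turnover of disorganized masses.
* `cells$overflow_capacity` bounds in-duct expansion below the ten-fold
  malignancy census, so malignancy mechanically requires invasion;
  `cells$invaded_brake` is the residual crowding of the invaded compartment.
* Growth-effect sizes (`runx3_multiplier`, `v1_amphi`, `v2_estrogen_gain`,
  `cmyc_inflow`, `her2_multiplier`, `egfr_multiplier`) shape which driver
  combinations expand; ER+-specific rungs act on the amphiregulin axis,
  hormone-independent growth on a constant inflow.

The calibration harness (`calibrate()`) is a deterministic random search over
the stochastic-mutation knobs against the two cohort incidence targets at
reduced cohort size; `write_calibration()` / `read_calibration()` persist its
output. The packaged defaults were fixed with this harness plus wider
parameter sweeps at cohort sizes of a few hundred replicates per arm;
receptor-subtype proportions and mutation-count means were never calibrated
directly — they are emergent and are only checked afterwards.

## What the simulations do and do not emulate

A cohort (`run_cohort()`) is a set of independent virtual patients — one
40-year tissue each, seeds drawn consecutively from a base seed. The
generator emulates: cyclic hormone forcing, stochastic bounded DNA damage
with capacity-limited repair, replication errors at mitosis, heritable
two-hit genetics with lineage tracking, spatially gated homeostatic turnover,
and outcome classification at the tissue level. It does not emulate:
three-dimensional duct architecture or mechanics, pathologic subtypes of
hyperplasia (usual/atypical/DCIS), PR or HER-2 pathway internals beyond
expression flags, adipocyte or immune compartments, post-menopausal
physiology, or person-level risk factors (parity, obesity, breastfeeding).
Passing tests therefore support internal consistency and the stated
population-level behaviours of this abstraction; they are not evidence about
any individual patient-level prediction.

## Numerical choices

* Every stochastic draw of a run goes through one per-simulation PCG32
  stream seeded from the run seed; identical (config, group, seed) gives
  bitwise-identical trajectories, event logs and results, independent of
  platform.
* Within a day, phases run in a fixed order (hormones, signals,
  damage/repair, AKT, mitosis, death checks, invasion, census); cells iterate
  in an order reshuffled daily from the run's RNG, so no lattice position is
  systematically favoured.
* Dominant-lineage ties break to the earliest-created genotype; with no
  mutations the dominant lineage is the wild-type root.
* Column smoothing uses a triangular kernel with clamped edges (the duct
  segment has closed ends); the locality radius is configurable and small.
* Degenerate inputs are rejected early: lattice width below 10 columns,
  senescence threshold at or above the apoptosis threshold, negative rates.

## Problem sizes used by the packaged checks

The test suite exercises reduced tissues (width 30–100 columns, 2–10
simulated years) for property checks, a reduced two-arm cohort (400
replicates per arm) for the directional and quantitative cohort checks, and
the acceptance script runs 2,500 replicates per arm of the full 40-year
protocol. These sizes were chosen so that Monte-Carlo error is small relative
to the tolerances being checked while a complete reproduction stays
convenient on a single CPU; the full-scale experiment (3,000 per arm) is a
single argument change (`--n 3000`).

## Calibration fidelity

The two cohort incidences are the calibrated quantities; every other cohort
statistic is emergent. At the packaged operating point the carrier-to-wild-type
incidence ratio is structurally limited to roughly eight- to ten-fold: the
background mutation intensity is pinned by the normal-population mutation
burden, and the same background that gives the carrier arm its second-hit
windows also seeds wild-type repair cascades through somatic BRCA1
heterozygotes. Pushing the wild-type rate down therefore pulls the carrier
rate down nearly proportionally. The configuration ships at the compromise
the calibration harness selected; the acceptance script reports whatever the
cohorts actually produce, and the per-target agreement is assessed there, not
assumed here. The ER+ share of wild-type tumors is likewise somewhat below
the level that a strictly estrogen-dominated tumor route would give, because
repair cascades ignite in proportion to division activity rather than to ER
status.

## Known limitations

* The 9% ER-positivity threshold sits near the normal baseline ER fraction
  by construction, so receptor calls on borderline mixed populations (a
  modest invaded clone over a living duct) can be sensitive to the residual
  duct census at the stopping day.
* Incidence levels are controlled by rare-event rates that scale steeply
  (quadratically to quartically) with the background mutation intensity;
  re-calibration is required after any change to `epsilon`, `beta`, or
  turnover.
* The model tracks malignant transformation only in the luminal compartment;
  structural layers are homeostatic boundary conditions.
* Forty years is simulated as 14,600 days with the 28-day cycle free-running
  against the 365-day year; an alternative cycle-locked year is a config
  change (`days_per_year`).
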