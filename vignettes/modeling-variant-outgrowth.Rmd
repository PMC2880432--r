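---
title: "Modeling variant HMEC outgrowth on a lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling variant HMEC outgrowth on a lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological system and the model

Primary human mammary epithelial cells (HMEC) grown in serum-free culture
proliferate for a limited number of divisions and then enter *stasis*, a
p16-dependent senescence-like arrest. Rare variant cells (vHMEC), in which
the p16 gene is epigenetically silenced, escape stasis and eventually
overgrow the culture. On a population-doubling (PD) curve this appears as a
*growth plateau*: near-exponential growth, a stall while the normal majority
senesces, and resumed exponential growth once the variants take over the
dish. Ionizing radiation accelerates variant outgrowth not by creating new
variants but by prematurely senescing the normal competition.

`hmecsim` models this as an agent-based simulation on a pixel lattice with
exclusive occupancy. Four rules drive everything:

1. an agent divides when its cycle completes and open space surrounds it;
2. when space is short it may still divide, with the participants
   *compressed* down to a minimum footprint;
3. an agent that has reached its division limit stops dividing and converts
   permanently to a senescent type;
4. senescent agents do not reattach at subculture and are discarded when the
   culture is replated.

Everything else in the package — serial passaging, the radiation module, and
the analysis layer — is built around these rules.

## Parameters, units and defaults

| Parameter | Default | Meaning |
|---|---|---|
| grid | 400 x 400 px | culture surface |
| `pixel_area` | 175/21 um^2 | microscopy calibration: a full cell is 21 px = 175 um^2 |
| `max_area` | 21 px | uncrowded cell footprint (175 um^2) |
| `min_area` | 6 px | fully compressed footprint (50 um^2) |
| `cycle_hours` | 26 h | cell-cycle duration, both classes |
| `division_limit_normal` | 7 | serial-passage scenario (3 in the co-culture validation) |
| `division_limit_variant` | 40 | effectively removes the limit on the simulated horizon |
| `seed_count` | 1,200 | agents replated per passage (about 20% confluence) |
| `trigger_saturation` | 0.80 | replate when this fraction of the grid is covered |
| `replicates` | 5 | independent simulations per condition |
| `dt` | 1 h | integration step |
| `search_radius` | 5 px | how far an agent looks for free space |

The only published spatial calibration is 21 px = 175 um^2 (and 6 px =
50 um^2); the grid itself then corresponds to about 1.33 mm^2 of dish. Cycle
phases are initialized uniformly on `[0, 26)` h at plating and replating to
desynchronize the population; division timers are otherwise deterministic.

## Spatial mechanics

Footprints are 8-connected quasi-circular pixel blobs grown by
nearest-pixel accretion around an anchor. An "open" division places a
daughter at full size in adjacent free space. When reachable free space
(within `search_radius` BFS layers through free pixels) is insufficient, the
divider performs a compressed division: mother and daughter split the
locally available area, down to two minimal footprints.

Compression is shared with the neighborhood: a dividing agent may squeeze
the cells in contact with it toward `min_area`, and under-sized
proliferative agents re-spread into adjacent free pixels at every step, up
to their preferred size. Senescent agents never regrow, but they do yield
under pressure. Both choices were forced by the dynamics rather than taken
from the written rules, which do not specify whose footprint shrinks. If
only the divider itself may compress, colonies grow strictly at their rim:
the frontier lineage then gains one division per 26 h cycle and exhausts
even a 40-division budget while crawling around the senescent debris, and —
worse — free space trapped in pockets behind rigid senescent footprints
(about a quarter of the grid in the serial scenario) becomes permanently
uncolonizable, so the culture can never reach the 80% replating trigger.
Shared compression restores the observed phenomenology: replating happens,
variants overgrow the senescent regions, and exponential growth resumes.

Blocked dividers hold their completed timer and retry every step, so space
released later is used immediately. Update order is reshuffled every step.
Division counting is symmetric: both daughters carry the mother's count
plus one.

## Serial passaging and bookkeeping

A culture is seeded with 1,200 agents (a fraction `f` of them variant;
`round(n * f)` exactly by default, per-agent Bernoulli optionally) and
stepped until confluence reaches 80%, when it is harvested: senescent agents
are discarded, up to 1,200 proliferative agents are sampled uniformly
without replacement and re-dispersed at full size on a fresh grid with their
division counts preserved.

Population doublings follow the standard subculture bookkeeping
`PD = log(A/B)/log 2`, with `A` the harvested and `B` the plated count,
accumulated over passages. As in the laboratory bookkeeping, cells that
senesce before harvest still appear in `A` although they are not replated,
so late in stasis the cumulative PD can drift above the per-lineage
division budget; the bookkeeping is kept as the laboratory defines it
rather than corrected.

Two guards bound a run without participating in normal dynamics: a passage
that makes no progress at all (every proliferative agent space-blocked,
nothing regrowing) is harvested early, and a simulation stops once it
reaches `max_total_pd` (default 24) cumulative doublings, `max_passages`,
or `max_sim_days`. The doubling cap only trims the resumed exponential tail
after the plateau of interest: the plateau begins near 7 PD and the widest
plateaus end well before 20 PD, leaving several doublings of post-plateau
baseline for the detector.

## Radiation module

Radiation-induced senescence is exponential in dose: the fraction of cells
remaining non-senescent after dose `D` is `exp(-alpha * D)`, with `alpha`
fitted per cell class by nonlinear least squares on the natural scale
(log-linearization would overweight near-zero fractions; R^2 is reported on
the natural scale). `irradiate()` converts each proliferative agent with
probability `1 - exp(-alpha_class * D)`, independently, leaving footprints
and already-senescent agents untouched.

The bundled `irradiated` preset uses `alpha_normal = 0.39` and
`alpha_variant = 0.022` per Gy. These are the package's calibration to the
reported assay bounds for the two classes: 2 Gy must senesce more than 40%
of normal but less than 5% of variant cells, 6 Gy more than 90% of normal
cells, and 10 Gy less than 20% of variant cells; the chosen pair satisfies
all four with margin. The exposure is applied at plating of the first
passage (`time_hours = 0`); the event time is configurable, so the
alternative ordering — growth first, exposure just before the first
subculture — is a one-line change.

The induction index `(Ps(D) - Ps(0)) / (1 - Ps(0))` corrects an observed
senescent fraction for cells already senescent before exposure; it is
reported unclipped and can be negative.

## Growth analysis

`detect_plateau()` operationalizes "the PD rate deviates from exponential":
the baseline rate is measured on the record's own first passage (compression
makes the realized rate slightly lower than the theoretical 26 h doubling,
so a theoretical baseline would be biased), the smoothed rate is a centered
difference over a 2-day window, and the plateau is the longest contiguous
interval below 25% of baseline. Threshold and window are exposed because no
formal test is prescribed. The reported width corrects the smoothing
window's edge bias (`+ window * (1 - 2 * threshold)`, exact for
piecewise-linear curves), so a planted flat segment is recovered at its
nominal width; an interval running into the end of the record is extended
by the half-window instead.

The plateau width `W` shrinks as the initial variant fraction `f` grows;
`fit_plateau_power_law()` fits `W = a * f^(-b)` by ordinary least squares in
log-log space and `infer_initial_fraction()` inverts it,
`f = (a / W)^(1/b)`, warning when the inversion extrapolates beyond the
fitted range (as it routinely must for real specimens). In the simulated
sweeps the exponent lands near `b = 0.5`, consistent with the surface-
limited regrowth geometry (the area each variant clone must recolonize
scales as `1/f`, its radius as `f^(-1/2)`).

Replicate dispersion is summarized as the per-timepoint relative standard
error (SE/mean) of cumulative PD on a shared hourly grid. Timepoints before
the first mean doubling are excluded from the reported maximum because
SE/mean diverges trivially as the mean approaches zero.

## Stochasticity, determinism and degenerate inputs

All randomness — placement, class assignment, initial phases, update order,
subculture sampling, radiation conversion — flows through R's RNG, so a
seeded trajectory is exactly reproducible. At very small fractions
(`f <= 0.1%`, one seeded variant cell) the variant lineage can be lost
outright to subculture sampling; such runs terminate early when the normal
divisions are exhausted and are censored from sweep width averages with a
warning. Fractions at which every replicate went extinct are dropped from
the power-law fit.

Degenerate inputs are rejected with informative errors: non-positive grid
dimensions or counts, insufficient space at seeding (reported with the
achievable count), all-zero dose tables, single-fraction power-law fits,
records too short to span two passages. A negative best-fit `alpha` is
clipped to zero with a warning.

## What the synthetic generators emulate — and what they do not

`generate_fixture()` plants known truths: exponential dose-response tables
with multiplicative lognormal noise, piecewise-linear PD curves with a
plateau of known width, and lattice states of known occupancy. They make
every analysis routine testable against an arithmetic oracle, but they do
not emulate biological heterogeneity (per-cell cycle-time variation,
partial reattachment of senescent cells, migration, paracrine signaling) —
none of which the agent rules contain either. Passing tests therefore
demonstrate internal consistency of rules, bookkeeping and inference, not
fidelity to any particular tissue specimen.

## Problem sizes used by the test-suite and acceptance script

The bundled checks run the full 400 x 400 serial scenario at 5 replicates,
the irradiated variant at 5, and a six-point fraction sweep (0.06%-3.5%) at
2-6 replicates per fraction, with the extra runs at the extinction-prone
lowest fractions; unit and property tests use grids between 3 x 4 and
200 x 200. These sizes were chosen so the whole suite completes in minutes
on a single core while keeping every scenario at the full grid resolution
of the modeled experiments.

## Known limitations

- Compression redistributes area only through one contact layer per
  division; pressure propagates over subsequent steps via re-spreading
  rather than instantaneously.
- Plateau width at very small `f` is partly set by stall-and-replate rescue
  events, flattening the power law below ~0.1%.
- The division-limit bookkeeping interacts with spatial growth: lineages at
  an expanding front divide more often than interior ones, so a 40-division
  variant limit can bind during very long recolonizations. This is visible
  as occasional variant senescence late in wide plateaus.
- No cell death, migration, or soluble-factor coupling; radiation quality
  (LET) and dose rate are out of scope.
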