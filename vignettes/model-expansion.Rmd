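---
title: "Growing mechanistic models from learned gene associations"
author: "GRNexpand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing mechanistic models from learned gene associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GRNexpand)
```

## The problem

Penalized-regression analyses of paired multi-omics measurements (protein
versus mRNA, chromatin accessibility versus mRNA) yield *signed gene–gene
association networks*: undirected edges with a coefficient whose sign says
whether two genes' readouts co-vary or anti-vary under a stimulus. Mechanistic
ODE models, in contrast, encode curated biochemistry but omit genes nobody has
wired in yet. GRNexpand converts the former into extensions of the latter, so
that statistically nominated genes can be interrogated dynamically — simulated,
calibrated and knocked out — inside a mechanistic model.

The motivating use case is interferon-γ signaling and immune-checkpoint
regulation: a candidate network around STAT1, IRF1 and PD-L1 (gene CD274) is
grafted onto a model whose only overlapping gene is STAT1, and the new genes
are then ranked by their simulated influence on IRF1/PD-L1 dynamics.

## The model

### Gene expression module

Every gene `g` in a model carries a deterministic expression module:

* **Gene switching.** `GCN` gene copies switch between inactive and active
  states with rates `kG_ac` and `kG_in` (1/s):
  `dg/dt = kG_ac (GCN − g) − kG_in g`, so the equilibrium active-copy count is
  `g* = GCN · kG_ac / (kG_ac + kG_in)`. Switching is treated as its expected
  value, not stochastically: the package's outputs are single deterministic
  trajectories, and all calibration targets are population-average time
  courses. Active/inactive copies are dynamical state, not species: only
  mRNA, protein, and (if measured) phosphoprotein of a gene appear in the
  species table.
* **Transcription.** Active copies produce mRNA at
  `v_TC = g · kTC_basal · M(regulators)` molecules/s, converted to nM/s
  through the mRNA compartment volume (`mpcToNM`).
* **Degradation, translation.** First-order mRNA decay `kTCd·[mRNA]`;
  translation `kTL·[mRNA]`; protein decay `kTLd·[protein]`. Translation and
  protein degradation live in the rate-law table (two reactions per gene);
  transcription and mRNA decay live in the gene module.

### Regulation: transcriptional activators and repressors (TARs)

Each directed regulatory interaction is a Hill term
`h(x; K_A, n_A) = (x/K_A)^n / (1 + (x/K_A)^n)` evaluated at the regulator
species concentration. A gene's regulatory multiplier is

```
M = (1 + Σ_activators h) · Π_repressors (1 − h)
```

Additive activation with a preserved basal leak and multiplicative repression
is **our** combination choice: it guarantees that a gene with no active
regulators transcribes at its basal rate, that activators can at most add
their saturating contribution, and that any saturated repressor silences the
gene. Other conventions (pure multiplicative activation, competitive forms)
exist; the chosen form is implemented in one place (`transcriptionFlux` and
the RHS assembly) and is embedded identically into SBML kinetic laws.

The *regulator species* of a gene defaults to its protein, but a base model
may designate an activated form — in the bundled toy system, STAT1's
regulator species is the ligand-activated transcription factor `aSTAT1`, so
interferon dosing *induces* STAT1 targets rather than depleting them. This
mirrors the biology in which the activated nuclear transcription-factor pool,
not total protein, drives transcription.

### From association edges to TARs

Each undirected signed edge produces **two** directed TARs (protein of gene1
acts on gene2, protein of gene2 acts on gene1), with:

* sign: positive coefficient → activator, negative → repressor (strict sign,
  no magnitude threshold; zero coefficients are rejected at load time);
* `n_A = 4` for all new interactions;
* `K_A` initialized to half the regulator's initial concentration; a
  regulator starting at zero falls back to half the model-wide median nonzero
  protein concentration (logged), keeping `K_A` positive.

Candidates that duplicate an existing `(regulator, target, sign)` triple are
collapsed. A self-association edge (gene paired with itself) emits two
*identical* candidates, so exactly one survives as an autoregulatory TAR:
a 14-edge list with one self-association yields 27 interactions from 28
candidates. Setting `selfRegulation = "drop"` in `expandModel()` removes
autoregulation entirely instead; the default keeps it because autoregulation
(e.g. of interferon-pathway transcription factors) is biologically real and
is the only reading consistent with pairing 14 undirected edges with 27
directed regulatory mechanisms.

### Parameterization from omics

Rate constants for a new gene derive from absolute measurements (molecules
per cell for mRNA, nM for protein, hours for half-lives, copies for GCN):

| constant | formula | guarantees |
|---|---|---|
| `kTCd` | `ln 2 / t½(mRNA)` | measured mRNA half-life |
| `kTLd` | `ln 2 / t½(protein)` | measured protein half-life |
| `kTC_basal` | `kTCd·m*·(kG_in+kG_ac)/(kG_ac·GCN)` | mRNA fixed point = `m*` |
| `kTL` | `p*·kTLd / m*_nM` | protein fixed point = `p*` |

Missing omics fields fall back to the mean of the corresponding values over
existing model genes (nonzero entries only) and are reported in the expansion
report's `defaultsUsed`; gene on/off rates for new genes default to the base
model's means. With complete omics no defaults are used.

**Basal-rate rebalancing.** The two fixed-point guarantees hold under a
neutral regulatory multiplier (`M = 1`). Once TARs are attached, resting
regulators make `M ≠ 1` and the measured state would drift. `expandModel()`
therefore rescales each target gene's `kTC_basal` by `1/M(initial state)` by
default (`rebalanceBasal = TRUE`), making the omics-derived state an exact
fixed point of the *expanded* model. This is the closed-form counterpart of
grid-fitting basal rates until mRNAs stop drifting, and it is why a freshly
expanded model passes a 48-hour no-ligand steady-state check to well below
1%. Disable it to reproduce the raw-formula behavior and fit basal rates
numerically instead (`fitBasalRates`).

## Simulation

`simulateModel()` integrates the full system (species in nM plus per-gene
active copies) with `deSolve::lsoda`, rtol `1e-8`, atol `1e-10` nM. Doses are
step changes of ligand concentrations: onset-zero doses modify the initial
state, later onsets are solver events. An optional pre-equilibration phase
settles the undosed system first, standing in for pre-stimulation culture in
basal growth medium. Negative solver excursions are clipped to zero in
*reported* output only, never during integration; inside the right-hand side,
concentrations are floored at zero before evaluating Hill terms and rate
laws, which keeps the derivative field well defined arbitrarily close to
zero.

## Calibration

The calibration stage mirrors a semi-automated sequential grid search:

1. **Grids.** `logGrid(default, decades = 3, points = 15)` spans three
   orders of magnitude of the default value. We read "within three orders of
   log10-magnitude" as a *centered* ±1.5-decade span: it is the only reading
   that can both raise and lower a parameter; one-sided spans remain
   available via `span =`. With 15 points the incumbent default is itself a
   grid value (the middle one), which makes the coordinate descent
   non-increasing in its objective by construction.
2. **Basal rates** (`fitBasalRates`): genes are examined one at a time in the
   order they were added; a gene whose mRNA drifts ≤ 1% (inclusive) over the
   no-ligand window is skipped, otherwise `kTC_basal` is grid-searched to
   minimize that drift and frozen before the next gene. The 1% tolerance is
   the package's choice of "constant level".
3. **Half-maximal constants** (`fitKA`): one `K_A` at a time in the order
   the interactions were added; for each grid value the model is
   pre-equilibrated without ligand (default 100 h) and simulated under every
   stimulation condition (default: growth factor alone at 1.5625 nM, and
   growth factor plus interferon at 1.1834 nM, 48 h); the summed
   fold-change SSE (`timeCourseSSE`) selects the value, which is frozen
   before the next parameter. Simulation failures score `+Inf` and are
   logged.

Fold change means `value(t)/value(0)` on the stimulation window, matching
how such time-course data are normalized; data tables carry their own
condition and species columns (an observable→species mapping is supported).

**Tie-breaking and flat profiles.** Grid values whose SSE lies within a tiny
band of the minimum (`1e-9` absolute or `1e-6` relative) are treated as
tied, and ties resolve to the value log-closest to the incumbent, then the
smaller. Without this, solver-level noise on a flat SSE profile would walk
insensitive parameters randomly across three decades; with it, an
insensitive parameter provably stays at its default. An optional
golden-section refinement between the best value's neighbors
(`refine = TRUE`) stands in for manual adjustment between sampled values and
is off by default so results are pure grid outputs. `sweeps > 1` repeats the
sequential pass, re-centering each grid on the incumbent.

The free parameters of a calibrated expansion are enumerated by
`calibrationInventory()`: one `K_A` per added interaction plus the mRNA and
protein degradation constants of every added gene — for the nine-gene,
14-edge case-study shape, 27 + 16 = 43.

## Knockout screening

`knockoutGene()` zeroes a gene's copy number, mRNA count, basal transcription
and the initial concentrations of its mRNA, protein and phosphoprotein; with
zero initial pools and zero production, the knocked species remain
identically zero, without touching any other gene's parameters or the
species list. The gene's TAR edges are retained — with its protein pinned at
zero they are functionally inert, which is equivalent to removing them.
`screenKnockouts()` simulates wild type once, then each knockout under the
identical scenario, and reports per readout the maximum and terminal relative
deviation `|ko − wt| / max(|wt|, 1e-9)`; a gene is "observable" when its
maximum deviation exceeds a configurable threshold (default 5% — the
magnitude of effect a time-course figure would visibly resolve; the
observable/negligible partition is parameter-dependent and should be read
qualitatively). `knockoutReachable()` provides the graph-theoretic
soundness check: a readout not reachable from the knocked-out gene in the
directed influence graph cannot deviate beyond solver noise, and the tests
hold screens to that standard (≤ `1e-7`, ten times the solver's relative
tolerance scale).

## What the synthetic generators emulate

`makeToyBaseModel()` stands in for a large curated signaling model with: one
1 pL compartment; EGF and IFNG ligand species; the overlap gene STAT1 whose
protein converts to an active transcription factor at
`(k_actIFNG·[IFNG] + k_actEGF·[EGF])·[p_STAT1]` (defaults `1e-4` and `1e-6`
per nM per s), decays back at `5e-5`/s, with ligands cleared at `1e-5`/s —
rates chosen so interferon produces an hours-scale transient activation that
peaks and declines within a 48-h window, qualitatively like transient
STAT1 activation; further base genes parameterized from synthetic omics; and
one base TAR so expanded models coexist with pre-existing regulation.
`makeSyntheticOmics()` draws log-uniform values in ranges typical of absolute
mammalian measurements (mRNA 1–1000 mpc, protein 0.01–1000 nM, mRNA
half-life 1–24 h, protein half-life 10–100 h, GCN 2).
`makeGroundTruthTimeCourses()` samples fold changes on a dense-early /
sparse-late grid (0, 1, 4, 8, 24, 48 h) with optional multiplicative
lognormal noise (CV configurable; 5% is a realistic default for such
assays).

What they do **not** emulate: receptor-level detail (ligand→TF activation is
first order, with no receptor species, internalization or feedback);
chromatin-level inputs; measurement-specific normalization quirks of real
RNA-seq/RPPA pipelines; and stochastic transcriptional bursting. Passing
tests on these fixtures therefore demonstrates the correctness of the
expansion algebra, the fixed-point construction, the calibration machinery
and the screen — not that any particular biological parameter set is right.

## Numerical choices and degenerate inputs

* Internal units: seconds, nM, liters; half-lives enter in hours and are
  converted once at the boundary.
* `translationRate` refuses a zero mRNA concentration when protein is
  nonzero (it would imply an infinite rate); zero protein simply gives zero
  translation.
* `initialKA` never returns zero (fallback path above).
* Duplicate unordered association pairs collapse keeping the first, with a
  warning; conflicting-sign directed duplicates keep the first and warn.
* Knockout sets copy number to exactly zero; validity allows this only as a
  knockout state.
* SBML identifiers are sanitized to the SId grammar with a logged mapping;
  exports embed gene-state equilibria as constant parameters (the SBML view
  is the deterministic expectation of the gene module).

## Problem sizes

The shipped tests and the acceptance script run, by choice, on: the
nine-gene/14-edge case-study-shaped expansion of a 3-gene base model
(counts, steady state, inventory, round trips), and a 3-new-gene/4-edge
expansion (8 interactions) for calibration recovery — ground truth placed on
grid points, displaced by −3 and +2 steps on the two earliest-added
interactions — and knockout soundness. These sizes keep the whole suite in
tens of seconds while exercising every code path; nothing in the machinery
is specific to them.

## Known limitations

* One-pass coordinate descent can leave strongly coupled parameter pairs at
  compensating values when many parameters start far from truth;
  identifiability is not guaranteed, and the SSE profiles stored in
  `FitResults` are the first diagnostic to inspect.
* The TAR combination form is a convention, not an inference; switching to a
  different form changes fitted `K_A` values.
* SBML export covers the deterministic core (no events, no gene-switching
  species); the exported document re-imports with identical counts and
  values but is not guaranteed to interoperate with tooling that expects
  gene states as explicit species.
* Phosphoprotein species are carried as measured pools without their own
  kinetics until a rate law references them.
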