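---
title: "From expression timelines to cell-type-selective kinetic models"
author: "eicotwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expression timelines to cell-type-selective kinetic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`eicotwin` builds deterministic compartmental ODE models. Every state
variable is the concentration (uM) of one species in one compartment,
addressed as `id@compartment`. Compartments carry relative volumes
(cytoplasm = 1); a flux computed in the concentration units of its
reference compartment (the first substrate's, or the product's for
translation) is converted to an amount flux by multiplying with the
reference volume and redistributed to each participating state as
`stoichiometry * V_ref / V_state`. This makes every cross-compartment
process — transport, secretion, translocation — conserve amount exactly,
which the tests verify to solver precision.

Rate laws:

* **Michaelis–Menten** for enzymatic steps, `v = kcat * E * S / (Km + S)`,
  with `v = 0` at `S = 0` (including the degenerate `Km = S = 0` limit).
  Each enzymatic reaction names exactly one enzyme species and one
  substrate; multi-substrate enzymology is out of scope.
* **First order** for non-enzymatic conversion (e.g. thromboxane A2
  hydrolysis to its stable product TXB2), transport and secretion.
* **Translation / degradation** coupling enzyme levels to mRNA:
  `dP/dt = ks * m(t) - kd * P` per proteoform per compartment. The mRNA is
  a *forcing function*, not a state variable: the measured transcriptome is
  the model input, so no mRNA synthesis/decay kinetics are invented for it.

All reactions are irreversible; a reversible step is written as two
reactions. This keeps every rate law in the single stated forward form.

## From omics tables to forcing profiles

Expression tables are replicated `(gene, time, value, replicate)`
measurements. Replicates are averaged per time point first (the model
consumes one interpolant per gene), then a **natural cubic spline** is
fitted through the means. Outside the measured window the profile is
extrapolated as a constant — a cubic tail would let synthesis run away
beyond the last sample — and negative interpolated values are clipped to
zero on evaluation. The spline coefficients are computed in the package
(tridiagonal solve) and stored explicitly, because generated programs embed
them verbatim; the test suite checks them against `stats::splinefun(method
= "natural")` as an independent oracle, to 1e-9 on dense grids.

The translation rate is anchored at baseline:
`ks = P0 * kd / m(t0)`, so that the proteomics-measured baseline `P0` is an
exact steady state of the coupling ODE. A protein with `P0 = 0` gets
`ks = 0`; a positive `P0` with zero baseline mRNA is refused with an error
naming the gene (it needs manual parameterization). With the default
turnover `kd = 2/h` (protein half-life about 21 minutes) enzyme levels
follow their mRNA with a delay of roughly `1/kd`; the quasi-steady-state
limit `P -> (ks/kd) m(t)` is verified numerically at `kd` of 1, 10 and
100 per hour. `scaleToRange()` is provided to place mRNA profiles on a
protein concentration scale for plotting/comparison; the pipeline itself
uses baseline anchoring, which is the same affine freedom fixed per gene by
data rather than by a global target range.

## Pruning semantics

Individualization removes, in order:

1. every Michaelis–Menten reaction whose enzyme gene is not expressed
   (baseline replicate mean at the earliest time `<=` threshold; default
   threshold 0), together with the unexpressed protein species and their
   transport reactions;
2. every reaction with a metabolite substrate outside the least fixpoint of
   substrate-flow reachability from the seed metabolites, iterated to
   convergence;
3. species left with no reaction participation, except seeds.

Two deliberate choices here: the reachability fixpoint is computed **over
metabolites only** — proteins and mRNAs count as available whenever the
species is present, because their production (translation) lies outside the
metabolic closure; and step 3 never drops a protein whose gene is
expressed, even if it is momentarily orphaned, because translation
reactions and translocation events attach to proteins only after pruning
(the cytosolic PLA2G4A reservoir participates in no metabolic reaction at
all, yet is the substrate of the calcium-burst translocation).
Non-enzymatic reactions are never removed for expression reasons. The
result is order-independent (a least fixpoint); reports are nevertheless
emitted in sorted order for reproducible diffs.

## Events and the calcium burst

The stimulation schedule is discrete. Lipid A at 0 h is a marker — its
transcriptomic consequences enter through the measured mRNA profiles. ATP
at 4 h triggers a cytoplasmic calcium burst which the model abstracts as an
instantaneous translocation: a fraction of the cytosolic enzyme *amount*
moves to a membrane compartment, and a first-order return flux is armed
from then on. Calcium itself is not a state variable; the burst-to-membrane
recruitment biology is captured by the event, not mechanistically modeled. Multiple translocation rows in one event apply
sequentially, so two moves with fractions f1, f2 from the same source
relocate `1 - (1-f1)(1-f2)` of the original amount — the composition rule
the tests assert. The default schedule moves 60% of cytosolic PLA2G4A to
the ER membrane and 50% of the remainder to the Golgi membrane, with return
rate 0.5/h; ATP time, fractions and rates are configuration.

Integration restarts at every event time (no event-crossing interpolation):
`lsoda` with `rtol = 1e-8`, `atol = 1e-10` by default. At an interior event
time the pre-event state is reported. Solver undershoot above `-1e-6` uM is
clipped to zero; anything lower aborts with diagnostics.

## The bundled eicosanoid network

The flagship asset covers the major arachidonic-acid derivatives:
membrane-esterified AA pools on the ER and Golgi membranes (the seeds),
PLA2G4A release of free AA with first-order reacylation back into the pool
("recycling"), cyclooxygenases PTGS1/PTGS2 to PGH2, terminal synthases to
PGD2 (PTGDS), PGE2 (PTGES), PGF2a (AKR1C3), prostacyclin (PTGIS) and
thromboxane (TBXAS1; the legacy label "TBXA1" is kept as an annotation
alias), non-enzymatic TXA2 -> TXB2 hydrolysis, the 5-lipoxygenase
leukotriene branch, 12-/15-HETE branches, and first-order secretion of
PGD2/PGE2/TXB2/LTB4 into the extracellular medium. Compartment volume
ratios (Cyt 1, ERMem 0.15, GolgiMem 0.05, Ecs 10) are configuration, as are
the enzyme localizations (prostanoid synthases on the ER membrane by
default).

**Every kinetic constant is a placeholder**, tagged as such in the shipped
parameter table: Km in the 1–50 uM range, kcat in the hundreds to thousands
per hour, first-order rates of order 1–100/h, chosen once so that the
default stimulation plays out on the hours scale of the experiment
(esterified-AA release over ~1–2 h after the burst, TXA2 hydrolysis within
minutes). No quantitative agreement with any published curve is claimed —
the asset demonstrates the pipeline's structure, and its tests assert
structural and qualitative properties only (branch routes, reachability,
zero secretion before the ATP event, a post-event surge, branch-selective
knockouts).

## The synthetic-data generator

The generator emulates the statistical shape of the macrophage-activation
datasets the pipeline is designed to consume: per-gene logistic induction
`m(t) = b (1 + (F-1) / (1 + exp(-(t - t_on - 2 tau)/tau)))` on the hours
scale (PTGS2 strongly induced, fold 12; PLA2G4A modestly; housekeeping-like
genes near flat), sampled at 0–24 h with 3 replicates and mean-one
lognormal noise (mRNA CV 0.2 by default); a proteomic baseline snapshot;
and extracellular lipidomics obtained by forward simulation plus lognormal
measurement noise. Randomness is confined to this module and fully
seed-deterministic (identical seeds give byte-identical tables).

What it does **not** emulate: single-cell count noise (dropout, negative
binomial dispersion), batch effects, normalization artifacts, or real
kinetic constants. Passing tests therefore demonstrate that the pipeline's
*mechanics* are correct — pruning, coupling, integration, code generation,
and that parameters are identifiable from data of the assumed quality —
not that the placeholder model reproduces any real measurement.

The parameter-recovery harness fits log-parameters to log-observations
(additive floor 1e-6 uM inside the logs, since pre-stimulation observations
are zero) with bounded derivative-free optimization: Brent for one free
parameter, Nelder–Mead from a small deterministic set of starts spread over
the log-bound range otherwise. At most 5 free parameters — the desk-scale
identifiability limit for two observables. In the standard study (two free
terminal-synthase kcats, 5% measurement CV, n = 3, 20 seeds) the median
relative error is a few percent.

## Problem sizes and numerical choices

The shipped checks use: 200 random networks (4–14 metabolites) for the
pruning oracle, 100 for reachability, 1000 random translocation events for
conservation, 10 random toy models plus the bundled model for the
generated-code round trip (tolerance 1e-6, normalized per variable by its
trajectory maximum), and 20 seeds for the noisy recovery study. These sizes
make the full suite run in a few minutes on one CPU while keeping the
property tests informative.

Serialization is JSON (numbers at full double precision) so that
`parseNetwork(writeNetwork(net))` is the identity on random networks;
YAML input is also accepted for hand-written documents. All emitted
documents and programs order elements lexicographically by id, and code
emission is a pure function of (model, dialect): byte-identical sources and
checksums on repeated calls.

SBML export targets Level 3 Version 2: kinetic laws in extent units
(concentration rate times reference volume), enzymes as modifiers, mRNA
forcing as assignment rules over piecewise cubic MathML, translocations as
events whose assignments move the conserved amount and switch indicator
parameters gating the return reactions. The package validates exported
documents structurally; the test suite additionally re-integrates a
pure-decay export through a minimal MathML interpreter that reads only the
document.

## Known limitations

* Kinetic parameters of the bundled network are placeholders; quantitative
  predictions require curated constants.
* Michaelis–Menten steps are single-substrate; cofactor dependence and
  multi-substrate mechanisms are not representable.
* Proteoforms are distinguishable states `(gene, tag, compartment)`, but no
  interconversion kinetics between post-translational states are modeled.
* No stochastic (SSA) semantics, spatial PDEs, flux-balance reduction, or
  mechanistic calcium signaling.
* Expression thresholding uses whichever baseline table is supplied
  (protein if available, else mRNA); mixed evidence per gene is not
  reconciled.
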