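---
title: "Metabolic hydrogen accounting: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic hydrogen accounting: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenh2)
```

## The problem

Rumen fermentation continuously generates reducing equivalents —
metabolic hydrogen, written [2H], one pair of electrons and protons
equivalent to one H2 — which must be re-oxidised for fermentation to
continue. Methanogenesis is the dominant sink (4 [2H] per CH4). When it
is chemically inhibited, the spared [2H] redistributes among reduced
volatile fatty acids (VFA), gaseous and dissolved H2, and other
acceptors. Quantifying that redistribution requires converting
heterogeneous bench measurements (outflow concentrations, gas volumes and
compositions) into a common currency of mmol [2H]/d and balancing sources
against sinks. That conversion-and-balance pipeline is what this package
implements, for semi-continuous fermenter (RUSITEC) experiments with a
treatment x vessel x day structure.

## The stoichiometric model

Every end product formed from glucose carries a fixed integer [2H]
coefficient (see `h2_stoichiometry()`): acetate and butyrate release
2 [2H]/mol; formate, propionate and valerate take up 1; heptanoate takes
up 2; CH4 takes up 4; gaseous H2 is itself one [2H] pair and is scored at
1. The model's assumptions, inherited from the fermentation-biochemistry
literature it encodes:

* straight-chain VFA arise from glucose fermentation only;
* branched-chain VFA (isobutyrate and the co-eluted
  isovalerate/2-methylbutyrate pool) arise from branched-chain amino
  acids, whose [2H] bookkeeping is ambiguous — they are carried in flux
  tables with `in_ledger = FALSE` and never scored;
* heptanoate forms by condensation of one propionyl-CoA with two
  acetyl-CoA, a net uptake of 2 [2H]/mol.

**Caproate scenarios.** Caproate can form by elongation of propionyl-CoA
(net −4 [2H]/mol) or by condensation of acetyl-CoA units (net
+2 [2H]/mol), and outflow measurements cannot distinguish the routes. The
ledger therefore evaluates both extremes: SC1 places all caproate on the
consumed side at 4 [2H]/mol, SC2 on the produced side at 2 [2H]/mol. For
any flux table, `balance(SC2) − balance(SC1) = 6 x caproate flux` — a
useful invariant that the test suite checks on randomised inputs.

**Double-counting switch.** The heptanoate reaction co-produces one
propionate per heptanoate, yet propionate is also scored from its own
measured concentration. The default follows the convention of scoring
every product from its measurement (faithful to how such ledgers are
reported); `deduct_heptanoate_propionate = TRUE` removes the coupled
propionate before scoring for users who prefer the stricter accounting.

**Balance and recovery.** `balance = produced − consumed` (mmol/d) and
`recovery = 100 x consumed/produced` (%). Recovery far below 100% — the
typical outcome — means most released [2H] ends in sinks the measured
products do not capture. Recovery is flagged `NA` (with a warning) when
nothing is produced, never silently infinite.

## Units and conversions

| parameter | default | unit | rationale |
|---|---|---|---|
| temperature | 312.15 | K | 39 °C incubation |
| pressure | 1.013e5 | Pa | ambient |
| saliva outflow | 0.626 | L/d | infusion rate of the emulated system |
| vessel volume | 900 | mL | working volume (gives 2.9 %/h dilution) |
| molar volume | RT/P = 25.619 | L/mol | `"paper"` switch forces 25.6 |

Concentration (mM) x outflow (L/d) gives mmol/d; gas volume (mL/d)
divided by molar volume (L/mol) gives mmol/d directly. The exact RT/P
value is used by default; the `"paper"` switch reproduces tables printed
with the rounded 25.6 L/mol bit-for-bit. Internally everything is double
precision; `ledger_report()` rounds only for display (2 decimals
per-product, 1 decimal for totals, matching how such tables are printed).

**The gas-percentage basis.** Gas composition is routinely reported as
percentages of the sum of the four quantified gases (CH4, H2, CO2, N2O),
not of the total collection-bag volume. The two need not reconcile: in
the fixture tables, total volume x percentage overstates the CH4 molar
flux about four-fold relative to the flux implied by the printed [2H]
ledger, and the printed CO2-equivalent totals are only consistent with a
four-gas sum near 0.18 L/d against a 0.74 L/d bag total. For this reason
`build_flux_table()` accepts per-gas daily moles (`gas_mmol`) as
first-class inputs and prefers them over the volume x percentage route;
`fixture_gas_mmol()` backs consistent molar fluxes out of the printed
ledger itself. The volume x percentage fallback remains available and is
what the synthetic generator exercises (self-consistently on both the
truth and estimate sides).

## The nitrate treatment

A nitrate-supplemented treatment adds an electron sink (dissimilatory
nitrate reduction to ammonium, 4 [2H]/mol nitrate; denitrification to
N2O) that outflow VFA and gas measurements do not capture. Computing its
consumption total without that term would be materially wrong, so
`run_pipeline()` masks consumption, balance and recovery to `NA` for any
treatment whose records show nonzero nitrate outflow, unless a
`nitrate_sink` value is supplied. `nitrate_h2_sink()` provides one: the
default rule scores disappeared nitrate (intake − outflow) at 4 [2H]/mol;
documented variants credit back 3 [2H] for nitrate that left as nitrite
and score the (tiny) denitrification branch at a lower coefficient. The
nitrate intake is derived from the mass dose via a molar mass of
62.004 g/mol.

## Auxiliary sinks and their reconstruction limits

Several side calculations are faithful implementations whose inputs, as
printed, do not reproduce the originally reported numbers. The package
computes them honestly and documents the gaps rather than forcing
agreement:

* **Nitrate sink**: from the printed dose (803 mg/d) and outflows, the
  default rule gives 51.1 mmol [2H]/d where 51.6 was reported; the exact
  outflow correction used originally is not recoverable.
* **Reduction extent**: printed outflows give 98.5% of nitrate
  unaccounted in outflow, where "maximum 94% fully reduced" was reported.
* **Microbial biomass sink**: two presets ship. The calibrated per-mg-N
  preset (0.0271 mmol [2H]/mg microbial N) reproduces the reported
  1.62/1.89/1.48/1.41 mmol/d quadruple to within 0.01. The literature
  chain (0.41 mol [2H]/g dry cells, 54.5% crude protein per cell, 16% N
  in protein) yields values ~170x larger; the unit of the 0.41
  coefficient is evidently not what a face-value reading suggests. Both
  presets are computed as documented; treatment *ratios* are
  coefficient-free either way.
* **Supersaturation factor** `Sf = dH2 / (Henry constant x pH2)`: no
  Henry constant default is shipped, because no tested constant
  reconstructs the originally reported Sf values from printed inputs; the
  user must supply one with provenance.

## The synthetic-data generator

`simulate_experiment()` emulates the measurement structure of the
emulated design: 4 treatments x 4 vessels x a 6-day window (days 8–13) by
default, with every analyte drawn as

    value = treatment mean + vessel effect + day effect + residual

truncated at zero. Treatment means default to the fixture tables. The
variance model is anchored to the printed pooled SEMs: with n = 4
vessels, the implied between-vessel-mean SD is 2 x SEM, and its variance
is split 50/25/25 between vessel, day and residual components — the
source tables report SEMs but no variance partition, so the split is a
declared, configurable convention. Day effects are shared across vessels
of a treatment on a given day. Conventions chosen for realism and
validity:

* truncated normal rather than lognormal: at the small CVs involved the
  truncation is almost never active, the mean is essentially unbiased,
  and parameters stay interpretable;
* structural zeros: analytes with a zero treatment mean (nitrate without
  a nitrate dose) stay exactly zero instead of acquiring half-normal
  noise;
* compositional closure: the eight-acid VFA shares and four gas
  percentages are renormalised to their treatment-mean closure sums, so
  simulated records always pass validation and zero noise reproduces the
  means exactly;
* dissolved H2 is simulated as one daily value; intra-day kinetics
  (the dense within-day sampling such experiments use) are out of scope.

What passing tests on simulated data do **not** show: the generator has
no mechanistic fermentation dynamics, no adaptation or recovery-period
trends, no correlation between analytes beyond compositional closure, and
no vessel-by-treatment interaction — real data violate all of these to
some degree, so parameter-recovery results certify the pipeline's
arithmetic, not the biology.

**Validation scale.** The parameter-recovery check runs 1000 replicates
of the 4 x 4 x 6 design, computes each replicate's treatment-mean ledger
(days averaged within vessel, then vessels averaged), and compares to the
ground-truth ledger of the generating means. "Within Monte-Carlo error"
is operationalised as |estimate − truth| ≤ 3 x the across-replicate SD of
the estimator, per treatment x scenario x quantity cell; ≥ 99% of cells
must pass. The across-replicate SD is used rather than the per-replicate
estimated SEM (whose ±3 coverage under t with 3 degrees of freedom would
be ~94% even for a perfect pipeline) or the analytical SEM (which
compositional renormalisation perturbs slightly).

## Reproduction quality of the printed tables

Running the ledger on the printed treatment means reproduces the printed
[2H] table to different degrees depending on how each cell was
originally computed:

* cells that are pure arithmetic on printed means (control and
  nitrooxypropanol acetate, propionate, valerate, heptanoate) reproduce
  exactly at display precision;
* the control column's remaining cells and totals reproduce within
  0.1 mmol/d;
* other treatments' cells sit within 1.5 mmol/d. The residual gap is not
  an implementation artifact: the printed values are repeated-measures
  least-squares means, which do not commute with products and sums of
  means — indeed some printed balances disagree with the printed totals
  they summarise (e.g. one treatment's totals give 46.5 − 24.0 = 22.5
  where the balance row prints 21.4). The test suite encodes these three
  tiers explicitly, including the unmet 0.1-tier checks for those
  balances, so the discrepancy stays visible rather than papered over.

## Degenerate inputs and numerical conventions

Validation errors name the offending row and field. Missing measurements
are `NA`, never zero (a measured 0.00 mM is a measurement). Zero
propionate flags VFA ratios `NA`; zero [2H] production flags recovery
`NA`; zero intake flags reduction extent `NA`; a residue exceeding the
substrate input reports negative disappearance with a warning instead of
clipping. All-zero flux tables yield all-zero ledgers without error.
Aggregation treats the vessel as the experimental unit: repeated days are
averaged within vessel before means and SEMs are taken across vessels,
and single-vessel groups report `NA` SEM rather than a silent `NaN`.

## Known limitations

* The ledger is a hydrogen balance only; no carbon, oxygen or
  thermodynamic-feasibility checks.
* Ethanol and n-propanol fluxes are computed and reported but carry no
  [2H] coefficients, mirroring the accounting it implements; users can
  extend the registry.
* No inferential statistics (mixed models, multiple comparisons,
  ordination): the package stops at means and SEMs by design.
* The gas-percentage basis ambiguity means volume-derived gas fluxes
  should be treated as internally consistent rather than absolutely
  calibrated; supply measured per-gas moles where available.
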