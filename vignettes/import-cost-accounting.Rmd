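---
title: "Import cost accounting for medical supply shipments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Import cost accounting for medical supply shipments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(importcost)
```

## The problem

Health programs that procure medical supplies abroad pay import costs —
international transport, customs clearance, and national transport — on top
of the purchase price. These costs are rarely itemised per product: air
freight is billed per cargo, a truck is rented at a lump sum, and a customs
agent charges by declaration line. `importcost` applies activity-based cost
allocation to such shipments so that every cost ends up attributed to the
cargo, the item, and ultimately the single unit (one tablet, one vial, one
test) that caused it.

The motivating case is a major 2016 shipment of tuberculosis-program
supplies from Amsterdam to Nukus, Karakalpakstan (Uzbekistan): three cargo
types (standard, cool, frozen), 85 items, 1.8 million units. The package
ships that case as a golden fixture (`uzbek_tb_shipment()`) built from its
published cargo-level aggregates.

## The allocation model

Let a shipment contain cargos $c$ with billed air freight $A_c$, gross
weight $G_c$ (including cargo packaging), and items $i$ with unit weight
$w_i$ (grams), ordered quantity $q_i$, and customs item line $\ell(i)$.
Let $L$ be the land-freight lump sum and $f$ the customs fee per item line.

1. **Shipment parts.** If one cargo is split between final destinations,
   only the part forwarded to the program causes import costs; its share of
   $A_c$ is proportional to the gross-weight split between the parts.
2. **Cargo shares.** $L$ is allocated across cargos proportionally to their
   (program-part) gross weights: $L_c = L \, G_c / \sum_{c'} G_{c'}$.
3. **Units.** Transport costs are allocated to units through the order net
   weight $W_c = \sum_{i \in c} w_i q_i / 1000$ (kg, excluding cargo
   packaging). The per-kg rates are $r^{air}_c = A_c / W_c$ and
   $r^{land}_c = L_c / W_c$, and a unit of item $i$ costs
   $$u_i = \frac{w_i}{1000}\left(r^{air}_c + r^{land}_c\right)
          + \frac{f}{N_{\ell(i)}},$$
   where $N_\ell = \sum_{i:\ell(i)=\ell} q_i$ is the number of units in the
   line. Item costs are $u_i q_i$; cargo totals are
   $A_c + L_c + f \cdot |\{\ell \in c\}|$; the shipment total is their sum.

By construction the allocation conserves cost at every level (unit sums
equal cargo totals equal shipment totals), is invariant to reordering items
or cargos, and is homogeneous: rescaling all weights by a constant changes
no share, and scaling a cost total scales its allocations linearly. The
test suite asserts each of these properties, including equality with a
brute-force oracle that enumerates every physical unit and assigns its cost
one unit at a time.

Chargeable weight — the air-freight billing basis,
$\max(G_c, \text{volumetric weight})$ — is computed and reported for
inspection, but gross and net weight are the allocation bases throughout:
billing structure and causal allocation are deliberately decoupled, since
most of the chargeable weight is gross weight and the net weight is the
item characteristic that actually scales with what a program imports.

## Parameters that matter

* **Customs fee per line.** Default `usd50`: USD 50 converted at the table
  rate (EUR 45.17 at the 2016 rate of 1.107 USD/EUR). The per-cargo customs
  totals of the fixture (316 / 136 / 45 for 7 / 3 / 1 lines) are consistent
  with a converted USD fee and not with a flat EUR 45 (which would give
  315 / 135 / 45); a flat-fee mode `eur45flat` remains selectable.
* **Nominal-price threshold** (default EUR 0.01): items priced at or below
  it are flagged nominal — their price does not reflect their value (a
  donated item, the nominally priced frozen half of a test kit split across
  cargos) — and are excluded from percentage-cost metrics. Absolute costs
  always include them.
* **Exchange rates.** All arithmetic runs in one base currency (EUR by
  default) at full floating precision; the default table is the 2016
  1 EUR = 1.107 USD = 3282 UZS. Percentage metrics are scale-free in the
  currency choice.
* **Frozen net-weight budget.** Frozen cargo items often lack catalogue
  unit weights entirely; see imputation below.

## Missing unit weights

`impute_unit_weights()` applies three rules in order:

1. **Same active ingredient, matching concentration** — donor taken first
   from an optional reference product list, then from same-cargo-class
   items in the shipment. "Matching concentration" is an exact string match
   after whitespace and case normalisation; fuzzy matching is deliberately
   out of scope, since substitution plausibility is a manual-review
   judgement. Item records carry no packaging-size field, so donor ties are
   broken by preferring an identical packaging type and then the
   lexicographically smallest item id, which keeps builds deterministic.
2. **Median unit weight of identically packaged items** within the same
   cargo; even-sized groups take the arithmetic mean of the two central
   values (the usual convention).
3. **Frozen-cargo uniform weight.** When a frozen cargo's items are all
   unweighted, each unit is assumed to weigh the same: the cargo's
   net-weight budget divided by its total units when a budget is
   configured, else an arbitrary equal weight (1 g). Either way the
   per-unit transport cost becomes identical across the cargo's items, i.e.
   transport allocation degenerates to allocation by the number of units —
   a property the tests assert directly.

Non-missing weights are never touched, so imputation is idempotent, and a
missing weight that no rule covers is a hard error naming the item.

## Contributor classification

Items are grouped by *why* they drive import cost, using a quadrant rule on
the (unit weight, ordered quantity) plane: `costly_by_unit_weight` (heavy,
few — large-volume fluids), `costly_by_number` (light, many — tablets),
`costly_by_weight_times_number` (both — powders, medium-weight fluids in
bulk), and `low_import_cost`. The boundaries are "approximately quadrants"
by nature, so the default thresholds are the within-cargo medians on log10
axes — scale-invariant and parameter-free — with fixed thresholds available
through `classification_config()`. Ties exactly at a threshold classify
into the "at or above" side. Sharing an item line with other items lowers
per-unit customs cost and often accompanies the low-cost group; the package
reports that as a `shares_line` annotation rather than a classification
criterion, because it describes the customs mechanics, not the quadrant.

## The golden fixture

The published record of the motivating shipment is cargo-level: per-cargo
items, lines, units, net weight, order value, gross weight, billed air
freight, plus the land lump sum and fee. The item-level composition lives
in a restricted deposit, so the fixture models each customs line as one
synthetic pseudo-item carrying the line's aggregate units, weight, and
value. Every cargo- and shipment-level output is invariant to within-line
composition, which is exactly why the fixture can reproduce all published
aggregates while remaining honest about not reproducing item-level medians.
Within-line splits are chosen deterministically to sum exactly to the
published totals and to hit published per-line medians where those are
determined (the cool cargo's three line sizes are exactly 20, 55, 1143).
Two fixture items are nominal (EUR 0 and EUR 0.01), so percentage
summaries run on 10 of 12 pseudo-items, mirroring the 83-of-85 exclusion
of the source. The frozen cargo's 25 kg gross weight includes 20 kg of dry
ice, kept as a waybill note only — it is cargo packaging and thus excluded
from net weight by definition.

Two open readings of the source record were settled as follows: billed air
totals are treated as all-inclusive of surcharges, and the standard
cargo's EUR 31,155 air freight is taken as the already-split program share
(the Tashkent/Nukus gross-weight split behind it was never published).
With a part split supplied explicitly, the engine also uses the program
part's gross weight as that cargo's land-allocation base, since the truck
carries only the program's part.

## The synthetic generator

`generate_shipment(synthetic_spec(seed = ...))` draws shipments for
property testing: per-cargo log-normal unit weights, quantities, and prices
whose default parameters reproduce the published medians and interquartile
ranges of the motivating shipment (standard-cargo weights median 1.2 g,
IQR 0.7–15 g; quantities median 4000, IQR 450–24,000; and so on); gross
weight as net weight times per-cargo packaging factors 1.1 / 3.5 / 5; air
freight priced per kg gross at roughly the observed per-cargo rates; and a
~9% missing-weight fraction (frozen always fully missing), guarded so every
blanked weight retains an imputation donor. The generator emulates the
*heterogeneity structure* of real shipments, not their realism in detail:
prices and weights are drawn independently (real ones correlate), line
membership is uniform, and no surcharge or fuel-rate structure is
modelled. Passing property tests therefore demonstrates the accounting
identities and invariances of the engine, not predictive validity on any
particular real shipment.

## Numerical choices

* No rounding anywhere in the engine; presentation rounding (money to whole
  units, rates to 2 decimals, percentages to 1 decimal below 10 and
  integers above, matching the conventions of the source tables) happens
  only in `write_report()`.
* Conservation is asserted at 1e-6 relative at cargo level and 1e-9 at
  shipment level; proportional shares sum to their total at floating
  precision.
* Quantiles use linear interpolation between order statistics
  (`stats::quantile()` type 7). The source's quantile convention is
  unstated, so item-level medians/IQRs may differ in the last digit; they
  are treated as descriptive, not as reproduction targets.
* Zero net weight, zero units in a line, and empty shipments are hard
  errors, never silent zeros. A cargo gross weight below the computed net
  weight is a warning, not an error, because published inputs are rounded.
* Cost bands are decades $[10^k, 10^{k+1})$ closed at the lower edge, with
  a small epsilon on the log so exact powers of ten land in their own band.

## Problem sizes in the test suite

The invariant suite runs 100 seeded synthetic shipments (85 items each) for
conservation and frozen-cargo equal-cost checks, 20 small shipments
(14 items, a few hundred units) against the unit-enumeration oracle, and
50 randomised cases for classification monotonicity — sizes chosen so the
whole suite completes in seconds while exercising every rule path.

## Limitations

Allocated costs are generated data: they inherit the allocation-base
assumptions (weight for transport, units-per-line for customs) and the
precision of unit weights, several of which are imputed. Supply-chain
stages outside the import leg — storage, in-country distribution to the
point of care, administration, lead time — and customs duties (exempt for
humanitarian goods in the motivating setting) are out of scope. Results
are best read as orders of magnitude per item and reliable totals per
cargo, which is the resolution the framework is designed for.
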