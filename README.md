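# importcost

Import cost measurement and accounting for medical supply shipments.

Health programs that procure supplies abroad pay for air freight, land
freight, and customs clearance on top of the purchase price — but those
costs arrive as cargo-level bills, truck lump sums, and per-declaration
agent fees, never itemised per product. `importcost` is for health
economists, program logisticians, and costing analysts who need to know
what importing one tablet, one vial, or one test actually costs: it
allocates every import cost down to the unit with activity-based cost
accounting, flags the items that drive the bill, and reports totals,
per-kg averages, and percentage-of-value metrics per cargo and shipment.

## The model

For cargo *c* with billed air freight *A<sub>c</sub>* and gross weight
*G<sub>c</sub>*, land lump sum *L*, and customs fee *f* per item line:

- split any part-split air cargo by the gross weights of its parts and
  keep the program's share;
- allocate land freight across cargos by gross weight:
  *L<sub>c</sub> = L·G<sub>c</sub>/ΣG*;
- compute each cargo's order net weight *W<sub>c</sub> = Σ w<sub>i</sub>
  q<sub>i</sub>* (unit weight × quantity, excluding cargo packaging) and
  the per-kg rates *A<sub>c</sub>/W<sub>c</sub>* and
  *L<sub>c</sub>/W<sub>c</sub>*;
- a unit of item *i* in line ℓ then costs
  *u<sub>i</sub> = (w<sub>i</sub>/1000)(A<sub>c</sub>+L<sub>c</sub>)/W<sub>c</sub> + f/N<sub>ℓ</sub>*,
  with *N<sub>ℓ</sub>* the units in the line.

Item costs are *u<sub>i</sub>q<sub>i</sub>*; cargo and shipment totals are
their conserved sums. Missing unit weights are imputed by ingredient
substitution, packaging-group medians, or a frozen-cargo uniform weight;
items are classified as costly by number, by unit weight, by their
product, or as low-import-cost. See the vignette
(`vignettes/import-cost-accounting.Rmd`) for assumptions and design
choices.

## Worked example

The package ships a golden fixture encoding the published cargo-level
record of a 2016 tuberculosis-program shipment (standard / cool / frozen
cargo) from Amsterdam to Nukus, Uzbekistan:

```r
library(importcost)
a <- allocate_costs(uzbek_tb_shipment())
a
#> <cost_allocation> 12 item(s), 3 cargo(s)
#>     cargo   air    land customs    total
#>  standard 31155 2824.79  316.17 34295.96
#>      cool  1785  151.37  135.50  2071.87
#>    frozen   199    8.84   45.17   253.01
#> shipment total: EUR 36620.84

cm <- cargo_metrics(a)
as.data.frame(cm[, c("scope", "total", "total_per_kg", "pct_of_value")])
#>      scope total total_per_kg pct_of_value
#> 1 standard 34296         4.78         8.90
#> 2     cool  2072        17.12        10.24
#> 3   frozen   253        50.60        28.09
#> 4 shipment 36621         5.02         9.01
```

Reading the output: the EUR 2985 truck cost splits 2825 / 151 / 9 across
cargos by gross weight; customs clearance (USD 50 ≈ EUR 45.17 per item
line) accumulates to 316 / 136 / 45 for 7 / 3 / 1 lines; importing the
shipment cost EUR 36,621, i.e. 9.0% of its EUR 406,296 order value and
EUR 5.02 per kg net weight — but 28% of value for the small frozen cargo,
whose two test items each cost EUR 2.53 per unit to import.

The same pipeline runs from files or the shell:

```sh
Rscript exec/importcost --orders orders.csv --waybills waybills.csv \
  --config config.yaml --out report/
Rscript exec/importcost --fixture uzbekistan-tb-2016 --out report/
#> shipment import total: EUR 36621 (9.0% of order value); reports in report/
```

writing `items.csv` (unit/item costs, percentage cost, cost band,
contributor class), `cargos.csv`, `summary.json`, and a run manifest.

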