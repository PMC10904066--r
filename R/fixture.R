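#' Golden fixture: the 2016 Karakalpakstan TB-program shipment
#'
#' A built-in shipment encoding the published cargo-level aggregates of a
#' major 2016 medical-supply shipment from the MSF Procurement Unit in
#' Amsterdam to a tuberculosis program in Nukus, Karakalpakstan, Uzbekistan:
#' three cargo types (standard / cool / frozen) with 7 / 3 / 1 customs item
#' lines, 1,840,928 / 1218 / 100 units, order net weights 7168 / 121 / 5 kg,
#' order values EUR 385,167 / 20,228 / 901, gross weights 7987 / 428 / 25 kg,
#' billed air freight EUR 31,155 / 1785 / 199, land freight EUR 2985 for the
#' truckload, customs agent fee per item line, and 2016 exchange rates
#' 1 EUR = 1.107 USD = 3282 UZS.
#'
#' The item-level composition of the real shipment is not public at this
#' granularity; the fixture therefore models each customs item line as one
#' synthetic pseudo-item carrying the line's aggregate units, net weight, and
#' value. Every cargo- and shipment-level figure is invariant to that
#' within-line composition (transport allocation depends only on cargo net
#' weight, customs allocation only on lines and units per line), while
#' unit-level operations remain exercisable. Per-line unit counts reproduce
#' the published per-line medians where determined (standard lines include
#' 8000, 35,000 and 595,172 units; cool lines are exactly 20, 55 and 1143).
#' The frozen cargo's billed gross weight of 25 kg includes 20 kg of dry ice
#' (cargo packaging), recorded as a note only; its two items - a reagent set
#' and the nominally priced (EUR 0.01) frozen part of a test kit split
#' across cargos - carry no catalogue unit weight, and the cool cargo holds
#' a donated (EUR 0) item, so percentage costs exclude two items.
#'
#' @param customs_fee_mode `"usd50"` (default): the per-line customs fee is
#'   USD 50, i.e. EUR 45.17 at the 2016 rate, which reproduces the published
#'   per-cargo customs totals of 316 / 136 / 45; `"eur45flat"` uses a flat
#'   EUR 45.
#' @param impute Run [impute_unit_weights()] on the frozen cargo (default
#'   `TRUE`); with `FALSE` the frozen unit weights stay missing, as on the
#'   source documents.
#' @return A [new_shipment()] object.
#' @examples
#' sh <- uzbek_tb_shipment()
#' allocate_costs(sh)
#' @export
uzbek_tb_shipment <- function(customs_fee_mode = c("usd50", "eur45flat"),
                              impute = TRUE) {
  customs_fee_mode <- match.arg(customs_fee_mode)
  ct <- currency_table("EUR", c(USD = 1.107, UZS = 3282))

  std_units <- c(1081756, 595172, 100000, 35000, 20000, 8000, 1000)
  std_net_kg <- c(3000, 2500, 900, 400, 250, 100, 18)
  std_value <- c(150000, 100000, 60000, 40000, 20000, 10000, 5167)
  stopifnot(sum(std_units) == 1840928, sum(std_net_kg) == 7168,
            sum(std_value) == 385167)

  cool_units <- c(1143, 55, 20)
  cool_net_kg <- c(96, 15, 10)
  cool_price <- c((20228 - 57 * 55) / 1143, 57, 0)   # donated item at EUR 0

  frozen_units <- c(20, 80)
  frozen_price <- c(45, 0.01)                        # split test-kit part

  items <- tibble::tibble(
    item_id = c(sprintf("STD-%02d", 1:7), sprintf("COOL-%02d", 1:3),
                sprintf("FRZ-%02d", 1:2)),
    description = c(
      "isoniazid/rifampicin 75/150 mg tablet (line aggregate)",
      "pyrazinamide 400 mg tablet (line aggregate)",
      "sodium chloride 0.9% 100 ml flexible bag (line aggregate)",
      "ringer lactate 500 ml bottle (line aggregate)",
      "rehydration salts powder sachet (line aggregate)",
      "cycloserine 250 mg capsule (line aggregate)",
      "water for injection 10 ml ampulla (line aggregate)",
      "line probe assay kit, cool part (line aggregate)",
      "insulin human 100 IU/ml 10 ml vial (line aggregate)",
      "control reagent panel, donated (line aggregate)",
      "test reagent set, frozen",
      "test kit, frozen part (nominal price)"),
    form = c("tablet", "tablet", "fluid_ge_100ml", "fluid_ge_100ml",
             "powder", "capsule", "fluid_lt_100ml",
             "test_kit", "fluid_lt_100ml", "test_kit",
             "test_kit", "test_kit"),
    packaging = c("capsule_or_tablet", "capsule_or_tablet", "fluid_bag",
                  "bottle", "sachet", "capsule_or_tablet", "ampulla",
                  "test_kit", "vial", "test_kit",
                  "test_kit", "test_kit"),
    active_ingredient = c("isoniazid/rifampicin", "pyrazinamide",
                          "sodium chloride", "ringer lactate",
                          "oral rehydration salts", "cycloserine",
                          "water for injection", NA, "insulin human", NA,
                          NA, NA),
    concentration = c("75/150 mg", "400 mg", "0.9%", NA, NA, "250 mg", NA,
                      NA, "100 IU/ml", NA, NA, NA),
    unit_price = c(std_value / std_units, cool_price, frozen_price),
    currency = "EUR",
    quantity = as.integer(c(std_units, cool_units, frozen_units)),
    unit_weight_g = c(std_net_kg * 1000 / std_units,
                      cool_net_kg * 1000 / cool_units,
                      NA_real_, NA_real_),
    item_line = c(sprintf("3004.%02d", 1:7), sprintf("3822.%02d", 1:3),
                  "3822.50", "3822.50"),
    cargo = c(rep("standard", 7), rep("cool", 3), rep("frozen", 2)))
  items <- as_item_records(items, table = ct, nominal_threshold = 0.01)

  cargos <- tibble::tibble(
    cargo = c("standard", "cool", "frozen"),
    gross_weight_kg = c(7987, 428, 25),
    volume_m3 = c(40, 2.5, 0.1),
    air_freight = c(31155, 1785, 199),   # standard = Nukus share, post-split
    currency = "EUR",
    surcharges = NA_real_,
    note = c(NA, NA, "gross weight includes 20 kg dry ice"))

  fee <- switch(customs_fee_mode,
                usd50 = money(50, "USD"),
                eur45flat = money(45, "EUR"))

  sh <- new_shipment(items, cargos,
                     land_freight = money(2985, "EUR"),
                     customs_fee_per_line = fee,
                     table = ct,
                     frozen_net_weight_kg = 5,
                     nominal_threshold = 0.01)
  if (impute) {
    imp <- impute_unit_weights(sh$items,
                               frozen_net_weight_kg = sh$frozen_net_weight_kg)
    sh$items <- imp$items
  }
  sh
}
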