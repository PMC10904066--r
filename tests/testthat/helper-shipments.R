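# Shared fixtures and an independent brute-force oracle.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_items <- function() {
  tibble::tibble(
    item_id = c("A", "B", "C", "D"),
    description = c("tablet a", "fluid b", "vial c", "kit d"),
    form = c("tablet", "fluid_ge_100ml", "fluid_lt_100ml", "test_kit"),
    packaging = c("capsule_or_tablet", "bottle", "vial", "test_kit"),
    active_ingredient = c("drug-a", "drug-b", "drug-c", NA),
    concentration = c("100 mg", NA, NA, NA),
    unit_price = c(0.5, 2, 30, 45),
    currency = "EUR",
    quantity = c(1000L, 200L, 50L, 10L),
    unit_weight_g = c(1, 500, 20, 100),
    item_line = c("L1", "L1", "L2", "L3"),
    cargo = c("standard", "standard", "cool", "cool"))
}

toy_cargos <- function() {
  tibble::tibble(
    cargo = c("standard", "cool"),
    gross_weight_kg = c(120, 15),
    volume_m3 = c(0.5, 0.05),
    air_freight = c(600, 120),
    currency = "EUR")
}

toy_shipment <- function(items = toy_items(), cargos = toy_cargos(),
                         land = 100, fee = 45, ...) {
  new_shipment(as_item_records(items), cargos,
               land_freight = money(land, "EUR"),
               customs_fee_per_line = money(fee, "EUR"), ...)
}

# Brute-force oracle: expand every physical unit and assign its cost
# unit-by-unit from first principles (plain base-R arithmetic, no package
# allocation calls). Returns per-item totals.
enumerate_item_costs <- function(shipment) {
  it <- shipment$items
  cg <- shipment$cargos[shipment$cargos$cargo %in% it$cargo, ]
  land_share <- shipment$land_freight * cg$gross_weight_kg /
    sum(cg$gross_weight_kg)
  fee <- shipment$customs_fee_per_line
  out <- data.frame(item_id = it$item_id, cargo = it$cargo,
                    air = NA_real_, land = NA_real_, customs = NA_real_)
  for (k in seq_len(nrow(cg))) {
    rows <- which(it$cargo == cg$cargo[k])
    net_kg <- sum(it$unit_weight_g[rows] * it$quantity[rows]) / 1000
    air_rate <- cg$air_freight[k] / net_kg
    land_rate <- land_share[k] / net_kg
    for (i in rows) {
      units_in_line <- sum(it$quantity[it$cargo == cg$cargo[k] &
                                         it$item_line == it$item_line[i]])
      # one entry per physical unit
      per_unit_air <- rep(it$unit_weight_g[i] / 1000 * air_rate,
                          it$quantity[i])
      per_unit_land <- rep(it$unit_weight_g[i] / 1000 * land_rate,
                           it$quantity[i])
      per_unit_customs <- rep(fee / units_in_line, it$quantity[i])
      out$air[i] <- sum(per_unit_air)
      out$land[i] <- sum(per_unit_land)
      out$customs[i] <- sum(per_unit_customs)
    }
  }
  out$total <- out$air + out$land + out$customs
  out
}

# Small-quantity synthetic spec so the unit-enumeration oracle stays cheap.
small_spec <- function(seed) {
  synthetic_spec(
    n_items = c(standard = 8, cool = 4, frozen = 2),
    n_lines = c(standard = 3, cool = 2, frozen = 1),
    meanlog = list(weight = c(standard = log(2), cool = log(100),
                              frozen = log(50)),
                   quantity = c(standard = log(30), cool = log(5),
                                frozen = log(10)),
                   price = c(standard = log(0.5), cool = log(20),
                             frozen = log(20))),
    sdlog = list(weight = c(standard = 1, cool = 0.5, frozen = 0.3),
                 quantity = c(standard = 1, cool = 0.8, frozen = 0.3),
                 price = c(standard = 1, cool = 0.5, frozen = 0.5)),
    seed = seed)
}

impute_all <- function(shipment) {
  shipment$items <- impute_unit_weights(
    shipment$items,
    frozen_net_weight_kg = shipment$frozen_net_weight_kg)$items
  shipment
}
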