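#' Chargeable weight of an air cargo
#'
#' Air freight is billed on the chargeable weight, the maximum of the gross
#' weight and the volumetric weight. The chargeable weight is computed and
#' reported for inspection of the billing basis; cost allocation itself uses
#' gross and net weight.
#'
#' @param gross_kg Gross weight (kg), >= 0.
#' @param volumetric_kg Volumetric weight (kg), >= 0.
#' @return max of the two, elementwise.
#' @export
chargeable_weight <- function(gross_kg, volumetric_kg) {
  if (any(gross_kg < 0) || any(volumetric_kg < 0))
    stop("weights must be >= 0")
  pmax(gross_kg, volumetric_kg)
}

#' Allocate a joint cost in proportion to an allocation base
#'
#' The workhorse of activity-based allocation: each recipient receives
#' `total * weight_i / sum(weights)`. The shares sum to the total exactly up
#' to floating-point precision; no rounding is performed here.
#'
#' @param total Joint cost (base currency), >= 0.
#' @param weights Strictly positive allocation-base values, one per
#'   recipient.
#' @return Numeric vector of allocated amounts, same length as `weights`.
#' @examples
#' allocate_proportional(2985, c(7987, 428, 25))
#' @export
allocate_proportional <- function(total, weights) {
  if (length(weights) == 0L) stop("at least one allocation-base weight required")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("allocation-base weights must be strictly positive")
  if (!is.finite(total) || total < 0) stop("total must be >= 0")
  total * weights / sum(weights)
}

#' Program share of a billed air freight split across shipment parts
#'
#' When one air cargo contains parts with different final destinations, only
#' the part forwarded to the program causes import costs; its share of the
#' billed total is proportional to the gross-weight split between the parts.
#'
#' @param billed Billed air freight for the whole cargo (base currency).
#' @param parts Tibble/data frame with columns `destination` and
#'   `gross_weight_kg`.
#' @param program_part Destination label of the program's part.
#' @return The program part's share of `billed`.
#' @export
split_air_freight_for_part <- function(billed, parts, program_part) {
  idx <- match(program_part, parts$destination)
  if (is.na(idx))
    stop("unknown destination: ", program_part)
  shares <- allocate_proportional(billed, parts$gross_weight_kg)
  shares[idx]
}

#' Order net weight of a set of items
#'
#' Net weight excludes cargo-specific packaging: it is the sum over items of
#' unit weight times ordered quantity.
#'
#' @param items Item-record tibble; all unit weights must be present
#'   (run [impute_unit_weights()] first).
#' @return Net weight in kg.
#' @export
cargo_net_weight <- function(items) {
  if (nrow(items) == 0L) return(0)
  if (anyNA(items$unit_weight_g))
    stop("missing unit weight(s); run impute_unit_weights() before allocation")
  sum(items$unit_weight_g * items$quantity) / 1000
}

#' Average transport cost per kg net weight
#'
#' @param cost Transport cost total allocated to a cargo (base currency).
#' @param net_weight_kg Order net weight of the cargo, > 0.
#' @return Cost per kg.
#' @export
transport_rate_per_kg <- function(cost, net_weight_kg) {
  if (any(net_weight_kg <= 0))
    stop("net weight must be > 0 (cargo with zero net weight cannot carry transport cost)")
  cost / net_weight_kg
}

#' Transport cost of one unit
#'
#' A unit's transport cost is its unit weight times the cargo's per-kg
#' net-weight rate.
#'
#' @param unit_weight_g Unit weight in grams, > 0.
#' @param rate_per_kg Transport rate (base currency per kg).
#' @return Transport cost per unit.
#' @export
unit_transport_cost <- function(unit_weight_g, rate_per_kg) {
  if (any(unit_weight_g <= 0)) stop("unit weight must be > 0")
  unit_weight_g / 1000 * rate_per_kg
}

#' Customs clearance total for a cargo
#'
#' Customs agent fees accrue per declared item line: the cargo total is the
#' number of item lines times the per-line fee (already in base currency).
#'
#' @param n_lines Number of item lines, >= 1.
#' @param fee_per_line Fee per line (base currency), >= 0.
#' @return Customs total for the cargo.
#' @export
customs_total_for_cargo <- function(n_lines, fee_per_line) {
  if (any(n_lines < 1)) stop("a cargo must have at least one item line")
  if (any(fee_per_line < 0)) stop("customs fee must be >= 0")
  n_lines * fee_per_line
}

#' Customs clearance cost of one unit
#'
#' The per-line fee is divided by the number of units imported within the
#' line; every unit in the same line carries the same customs cost.
#'
#' @param fee_per_line Fee per line (base currency).
#' @param units_in_line Units imported within the line, >= 1.
#' @return Customs cost per unit.
#' @export
unit_customs_cost <- function(fee_per_line, units_in_line) {
  if (any(units_in_line < 1)) stop("an item line must contain at least one unit")
  fee_per_line / units_in_line
}

#' Allocate all import costs of a shipment
#'
#' Runs the full allocation: (a) splits any part-split air cargo between
#' destinations by gross weight and keeps the program part; (b) allocates the
#' land-freight lump sum to cargos by gross weight; (c) computes per-cargo
#' air and land rates per kg net weight and per-line unit customs costs; and
#' rolls costs up to unit, item, cargo, and shipment level. All arithmetic is
#' in base currency at full precision; rounding is presentational only.
#'
#' @param shipment A [new_shipment()] with all unit weights present.
#' @return A `cost_allocation` list with elements
#'   \describe{
#'     \item{unit_costs}{per-item tibble of unit-level air/land/customs/total
#'       costs, plus item-level costs (`unit * quantity`).}
#'     \item{cargo_costs}{per-cargo tibble: components, totals, net/gross
#'       weight, chargeable weight, lines, units, order value.}
#'     \item{shipment_total}{one-row tibble of component sums.}
#'     \item{rates}{per-cargo air/land rates (base currency per kg net).}
#'     \item{fee_per_line}{customs fee per line in base currency.}
#'     \item{shipment}{the input shipment.}
#'   }
#' @export
allocate_costs <- function(shipment) {
  stopifnot(inherits(shipment, "shipment"))
  v <- validate_shipment(shipment)
  if (any(v$severity == "error"))
    stop("shipment fails validation:\n  ",
         paste(v$message[v$severity == "error"], collapse = "\n  "))
  items <- shipment$items
  if (nrow(items) == 0L) stop("shipment contains no items")
  if (anyNA(items$unit_weight_g))
    stop("missing unit weight(s); run impute_unit_weights() before allocation")
  cargos <- shipment$cargos[shipment$cargos$cargo %in% items$cargo, ]

  # program-part air freight and effective (program) gross weight per cargo
  air_program <- cargos$air_freight
  gross_program <- cargos$gross_weight_kg
  if (!is.null(shipment$parts)) {
    for (i in seq_len(nrow(cargos))) {
      pp <- shipment$parts[shipment$parts$cargo == cargos$cargo[i], ]
      if (nrow(pp)) {
        air_program[i] <- split_air_freight_for_part(
          cargos$air_freight[i], pp, shipment$program_part)
        gross_program[i] <-
          pp$gross_weight_kg[pp$destination == shipment$program_part]
      }
    }
  }
  land_alloc <- allocate_proportional(shipment$land_freight, gross_program)

  per_cargo <- items |>
    dplyr::group_by(.data$cargo) |>
    dplyr::summarise(
      n_items = dplyr::n(),
      n_lines = dplyr::n_distinct(.data$item_line),
      units = sum(.data$quantity),
      net_weight_kg = sum(.data$unit_weight_g * .data$quantity) / 1000,
      order_value = sum(.data$unit_price * .data$quantity))
  per_cargo <- per_cargo[match(cargos$cargo, per_cargo$cargo), ]

  fee <- shipment$customs_fee_per_line
  rates <- tibble::tibble(
    cargo = cargos$cargo,
    air_rate_per_kg = transport_rate_per_kg(air_program,
                                            per_cargo$net_weight_kg),
    land_rate_per_kg = transport_rate_per_kg(land_alloc,
                                             per_cargo$net_weight_kg))

  line_units <- items |>
    dplyr::group_by(.data$cargo, .data$item_line) |>
    dplyr::summarise(units_in_line = sum(.data$quantity), .groups = "drop")

  unit_costs <- items |>
    dplyr::left_join(rates, by = "cargo") |>
    dplyr::left_join(line_units, by = c("cargo", "item_line")) |>
    dplyr::mutate(
      unit_air = unit_transport_cost(.data$unit_weight_g,
                                     .data$air_rate_per_kg),
      unit_land = unit_transport_cost(.data$unit_weight_g,
                                      .data$land_rate_per_kg),
      unit_customs = unit_customs_cost(fee, .data$units_in_line),
      unit_total = .data$unit_air + .data$unit_land + .data$unit_customs,
      item_air = .data$unit_air * .data$quantity,
      item_land = .data$unit_land * .data$quantity,
      item_customs = .data$unit_customs * .data$quantity,
      item_total = .data$unit_total * .data$quantity) |>
    dplyr::select(dplyr::all_of(c(
      "item_id", "description", "cargo", "item_line", "quantity",
      "unit_weight_g", "unit_price", "nominal_price", "units_in_line",
      "unit_air", "unit_land", "unit_customs", "unit_total",
      "item_air", "item_land", "item_customs", "item_total")))

  cargo_costs <- tibble::tibble(
    cargo = cargos$cargo,
    level = "cargo",
    air = air_program,
    land = land_alloc,
    customs = customs_total_for_cargo(per_cargo$n_lines, fee),
    n_items = per_cargo$n_items,
    n_lines = per_cargo$n_lines,
    units = per_cargo$units,
    net_weight_kg = per_cargo$net_weight_kg,
    gross_weight_kg = gross_program,
    chargeable_weight_kg = chargeable_weight(
      cargos$gross_weight_kg,
      ifelse(is.na(cargos$volume_m3), 0, cargos$volume_m3 * 167)),
    order_value = per_cargo$order_value) |>
    dplyr::mutate(total = .data$air + .data$land + .data$customs,
                  .after = "customs")

  shipment_total <- tibble::tibble(
    level = "shipment",
    air = sum(cargo_costs$air),
    land = sum(cargo_costs$land),
    customs = sum(cargo_costs$customs),
    total = sum(cargo_costs$total),
    units = sum(cargo_costs$units),
    net_weight_kg = sum(cargo_costs$net_weight_kg),
    gross_weight_kg = sum(cargo_costs$gross_weight_kg),
    order_value = sum(cargo_costs$order_value))

  structure(list(unit_costs = unit_costs, cargo_costs = cargo_costs,
                 shipment_total = shipment_total, rates = rates,
                 fee_per_line = fee, shipment = shipment),
            class = "cost_allocation")
}

#' @export
print.cost_allocation <- function(x, ...) {
  cat("<cost_allocation>", nrow(x$unit_costs), "item(s),",
      nrow(x$cargo_costs), "cargo(s)\n")
  df <- as.data.frame(x$cargo_costs[, c("cargo", "air", "land", "customs",
                                        "total")])
  df[-1] <- lapply(df[-1], function(z) round(z, 2))
  print(df, row.names = FALSE)
  cat(sprintf("shipment total: %s %.2f\n", x$shipment$currency$base,
              x$shipment_total$total))
  invisible(x)
}

#' Unit-level import cost breakdowns
#'
#' Convenience wrapper around [allocate_costs()] returning only the unit-level
#' breakdown (air, land, customs, total per unit of each item).
#'
#' @param shipment A [new_shipment()] object with imputed weights.
#' @return Tibble of per-item unit costs (level = unit).
#' @export
unit_import_costs <- function(shipment) {
  allocate_costs(shipment)$unit_costs
}

#' Cargo-level import cost totals
#'
#' @param shipment A [new_shipment()] object with imputed weights.
#' @return Tibble of per-cargo cost breakdowns (level = cargo).
#' @export
cargo_import_totals <- function(shipment) {
  allocate_costs(shipment)$cargo_costs
}

#' Shipment-level import cost total
#'
#' Component-wise sum of the cargo breakdowns for all cargo delivered to the
#' program.
#'
#' @param shipment A [new_shipment()] object with imputed weights.
#' @return One-row tibble (level = shipment).
#' @export
shipment_import_total <- function(shipment) {
  allocate_costs(shipment)$shipment_total
}
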