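#' Item import cost from a unit breakdown
#'
#' The cost of importing an item's full order quantity: each component of the
#' unit breakdown times the quantity.
#'
#' @param unit_cost Named numeric (or one-row data frame) with components
#'   `air`, `land`, `customs` (a `total` element, if present, is recomputed).
#' @param quantity Ordered quantity, >= 1.
#' @return Named numeric vector `air`, `land`, `customs`, `total` at item
#'   level.
#' @export
item_import_cost <- function(unit_cost, quantity) {
  if (quantity < 1) stop("quantity must be >= 1")
  uc <- unlist(unit_cost)
  out <- uc[c("air", "land", "customs")] * quantity
  c(out, total = sum(out))
}

#' Quantity-weighted average price across orders of one item
#'
#' Multiple orders of the same item are combined by summing quantities and
#' averaging prices weighted by quantity.
#'
#' @param prices Unit prices per order (base currency).
#' @param quantities Ordered quantities per order, all > 0.
#' @return List with `price` (weighted average) and `quantity` (combined).
#' @export
quantity_weighted_price <- function(prices, quantities) {
  if (length(prices) == 0L) stop("no orders supplied")
  stopifnot(length(prices) == length(quantities))
  if (any(quantities <= 0)) stop("quantities must be positive")
  list(price = sum(prices * quantities) / sum(quantities),
       quantity = sum(quantities))
}

#' Percentage import cost of a unit
#'
#' Import cost expressed as a percentage of the unit price. Items whose
#' price does not reflect their value (nominal flag) are excluded from
#' percentage metrics and return `NA`; a zero price without the nominal flag
#' is an error.
#'
#' @param unit_cost Unit import cost (base currency).
#' @param unit_price Unit price (base currency), >= 0.
#' @param nominal Logical nominal-price flag.
#' @return Percentage (0-100 scale), or `NA_real_` for excluded items.
#' @export
percentage_unit_cost <- function(unit_cost, unit_price, nominal = FALSE) {
  stopifnot(length(unit_cost) == length(unit_price))
  nominal <- rep_len(nominal, length(unit_cost))
  if (any(unit_price < 0)) stop("unit price must be >= 0")
  if (any(unit_price == 0 & !nominal))
    stop("zero unit price without the nominal-price flag")
  ifelse(nominal, NA_real_, 100 * unit_cost / unit_price)
}

#' Average import cost per kg net weight
#'
#' @param total_cost Import cost total (base currency).
#' @param net_weight_kg Net weight, > 0.
#' @return Cost per kg.
#' @export
average_cost_per_kg <- function(total_cost, net_weight_kg) {
  if (any(net_weight_kg <= 0)) stop("net weight must be > 0")
  total_cost / net_weight_kg
}

#' Gross-to-net weight ratio of a cargo
#'
#' The packaging overhead factor: cargo gross weight (incl. cargo packaging)
#' over order net weight.
#'
#' @param gross_kg Gross weight (kg).
#' @param net_kg Net weight (kg), > 0.
#' @return Ratio.
#' @export
gross_to_net_ratio <- function(gross_kg, net_kg) {
  if (any(net_kg <= 0)) stop("net weight must be > 0")
  gross_kg / net_kg
}

#' Median and interquartile range of a set of values
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param values Non-empty numeric vector (`NA`s dropped).
#' @return Tibble with `median`, `q25`, `q75`, `n`.
#' @export
summarize_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarise")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(median = q[2], q25 = q[1], q75 = q[3],
                 n = length(values))
}

#' Decade cost band of an item import cost
#'
#' Item import costs are grouped into decade bands `[10^k, 10^(k+1))` of the
#' base currency, closed at the lower edge (a cost of exactly 1000 falls in
#' the 1000-10,000 band). A zero cost gets the dedicated `"zero"` band.
#'
#' @param cost Item import cost(s), >= 0.
#' @return Character band labels like `"1000-10000"`.
#' @export
assign_cost_band <- function(cost) {
  if (any(cost < 0)) stop("cost must be >= 0")
  band_one <- function(x) {
    if (x == 0) return("zero")
    k <- floor(log10(x) + 1e-12)
    fmt <- function(p) format(10^p, scientific = FALSE, trim = TRUE,
                              drop0trailing = TRUE)
    paste0(fmt(k), "-", fmt(k + 1))
  }
  vapply(cost, band_one, character(1))
}

#' Per-item metrics table
#'
#' Combines a cost allocation with the derived item metrics: item-level
#' costs, percentage import costs (nominal items excluded), decade cost
#' bands, and - when a classification is supplied - the contributor class.
#'
#' @param allocation A [allocate_costs()] result.
#' @param classification Optional result of [classify_contributors()].
#' @return Tibble with one row per item.
#' @export
item_metrics <- function(allocation, classification = NULL) {
  stopifnot(inherits(allocation, "cost_allocation"))
  out <- allocation$unit_costs |>
    dplyr::mutate(
      pct_unit_cost = percentage_unit_cost(.data$unit_total,
                                           .data$unit_price,
                                           .data$nominal_price),
      cost_band = assign_cost_band(.data$item_total),
      shares_line = .data$units_in_line > .data$quantity)
  if (!is.null(classification))
    out <- dplyr::left_join(out, classification, by = c("item_id", "cargo"))
  out
}

#' Per-cargo and shipment summary table
#'
#' Mirrors the cargo cost-table layout of the framework's reporting: cost
#' components and totals, average costs per kg net weight, the customs fee
#' per line, order value, and the import cost as a percentage of that value;
#' a final `"shipment"` row aggregates all cargos.
#'
#' @param allocation A [allocate_costs()] result.
#' @return Tibble with one row per cargo plus a shipment row.
#' @export
cargo_metrics <- function(allocation) {
  stopifnot(inherits(allocation, "cost_allocation"))
  cc <- allocation$cargo_costs
  rows <- cc |>
    dplyr::transmute(
      scope = .data$cargo,
      air = .data$air, land = .data$land, customs = .data$customs,
      total = .data$total,
      n_items = .data$n_items, n_lines = .data$n_lines, units = .data$units,
      net_weight_kg = .data$net_weight_kg,
      gross_weight_kg = .data$gross_weight_kg,
      gross_to_net = gross_to_net_ratio(.data$gross_weight_kg,
                                        .data$net_weight_kg),
      air_per_kg = average_cost_per_kg(.data$air, .data$net_weight_kg),
      land_per_kg = average_cost_per_kg(.data$land, .data$net_weight_kg),
      total_per_kg = average_cost_per_kg(.data$total, .data$net_weight_kg),
      customs_per_line = allocation$fee_per_line,
      order_value = .data$order_value,
      pct_of_value = 100 * .data$total / .data$order_value)
  st <- allocation$shipment_total
  ship <- tibble::tibble(
    scope = "shipment",
    air = st$air, land = st$land, customs = st$customs, total = st$total,
    n_items = sum(cc$n_items), n_lines = sum(cc$n_lines), units = st$units,
    net_weight_kg = st$net_weight_kg,
    gross_weight_kg = st$gross_weight_kg,
    gross_to_net = gross_to_net_ratio(st$gross_weight_kg, st$net_weight_kg),
    air_per_kg = average_cost_per_kg(st$air, st$net_weight_kg),
    land_per_kg = average_cost_per_kg(st$land, st$net_weight_kg),
    total_per_kg = average_cost_per_kg(st$total, st$net_weight_kg),
    customs_per_line = allocation$fee_per_line,
    order_value = st$order_value,
    pct_of_value = 100 * st$total / st$order_value)
  dplyr::bind_rows(rows, ship)
}
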