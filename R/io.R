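#' Read an orders table
#'
#' Reads a comma-separated orders file (UTF-8, header row, decimal point,
#' no thousands separators) with one row per ordered item. Required columns:
#' `item_id`, `description`, `form`, `packaging`, `active_ingredient`,
#' `concentration`, `unit_price`, `currency`, `quantity`, `unit_weight_g`,
#' `item_line`, `cargo`. Empty `unit_weight_g` cells are preserved as
#' missing (to be filled by [impute_unit_weights()]); enum columns are
#' validated with the offending row and value named. Rows are never silently
#' dropped.
#'
#' @param path Path to the CSV file.
#' @return Tibble of raw item records (prices still in their order
#'   currencies; pass through [as_item_records()] to convert and flag).
#' @export
read_orders <- function(path) {
  if (!file.exists(path)) stop("orders file not found: ", path)
  df <- readr::read_csv(path, col_types = readr::cols(
    item_id = readr::col_character(),
    description = readr::col_character(),
    form = readr::col_character(),
    packaging = readr::col_character(),
    active_ingredient = readr::col_character(),
    concentration = readr::col_character(),
    unit_price = readr::col_double(),
    currency = readr::col_character(),
    quantity = readr::col_integer(),
    unit_weight_g = readr::col_double(),
    item_line = readr::col_character(),
    cargo = readr::col_character()), progress = FALSE)
  missing_cols <- setdiff(item_columns, names(df))
  if (length(missing_cols))
    stop("orders file missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("form", "packaging", "cargo")) {
    allowed <- switch(col, form = pharma_forms, packaging = packaging_types,
                      cargo = cargo_types)
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad))
      stop(sprintf("orders row %d: unknown %s value \"%s\"", bad[1], col,
                   df[[col]][bad[1]]))
  }
  df
}

#' Write an orders table
#'
#' Inverse of [read_orders()]: writing a parsed table and re-reading it
#' yields identical records.
#'
#' @param items Item-record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_orders <- function(items, path) {
  readr::write_csv(items[, item_columns], path, progress = FALSE)
  invisible(path)
}

#' Read a waybills table
#'
#' One row per cargo type with columns `cargo`, `air_freight`, `currency`,
#' `gross_weight_kg` and optionally `volume_m3`, `rate_per_kg`,
#' `surcharges`. Returns cargo shells; items are attached later by cargo
#' type when the shipment is assembled.
#'
#' @param path Path to the CSV file.
#' @return Tibble of cargo shells.
#' @export
read_waybills <- function(path) {
  if (!file.exists(path)) stop("waybills file not found: ", path)
  df <- readr::read_csv(path, col_types = readr::cols(
    cargo = readr::col_character(),
    air_freight = readr::col_double(),
    currency = readr::col_character(),
    gross_weight_kg = readr::col_double(),
    .default = readr::col_double()), progress = FALSE)
  req <- c("cargo", "air_freight", "currency", "gross_weight_kg")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("waybills file missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!df$cargo %in% cargo_types)
  if (length(bad))
    stop(sprintf("waybills row %d: unknown cargo value \"%s\"", bad[1],
                 df$cargo[bad[1]]))
  dup <- df$cargo[duplicated(df$cargo)]
  if (length(dup))
    stop("duplicate cargo type in waybills: ", paste(dup, collapse = ", "))
  df
}

#' Write a waybills table
#'
#' @param cargos Cargo tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waybills <- function(cargos, path) {
  readr::write_csv(cargos, path, progress = FALSE)
  invisible(path)
}

config_defaults <- list(
  nominal_price_threshold = 0.01,
  customs_fee_per_line = list(amount = 50, currency = "USD"),
  currency = list(base = "EUR", rates = list(USD = 1.107, UZS = 3282)))

#' Read a shipment configuration
#'
#' Reads a YAML configuration with the land-freight lump sum, the customs
#' fee per item line, exchange rates, and optional blocks: a part split of a
#' cargo between destinations (with the program's destination), a frozen
#' net-weight budget, classification thresholds, and the nominal-price
#' threshold. Omitted optional blocks get defaults (customs fee USD 50/line,
#' 2016 rates 1 EUR = 1.107 USD = 3282 UZS, nominal threshold EUR 0.01).
#'
#' @param path Path to the YAML file.
#' @return A `shipment_config` list with elements `land_freight` ([money()]),
#'   `customs_fee_per_line` ([money()]), `currency` ([currency_table()]),
#'   `parts` (tibble or `NULL`), `program_part`, `frozen_net_weight_kg`,
#'   `nominal_price_threshold`, `classification` (or `NULL`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(config_defaults, raw)
  if (is.null(cfg$land_freight))
    stop("config must specify land_freight (amount + currency)")
  as_money <- function(x, what) {
    if (is.numeric(x)) x <- list(amount = x, currency = "EUR")
    if (is.null(x$amount) || x$amount < 0)
      stop(what, " must have a non-negative amount")
    money(x$amount, x$currency %||% "EUR")
  }
  rates <- unlist(cfg$currency$rates)
  table <- currency_table(cfg$currency$base %||% "EUR", rates)
  land <- as_money(cfg$land_freight, "land_freight")
  fee <- as_money(cfg$customs_fee_per_line, "customs_fee_per_line")
  for (m in list(land, fee))
    convert_currency(m$amount, m$currency, table)  # errors on unknown code
  parts <- NULL
  if (!is.null(cfg$parts)) {
    parts <- dplyr::bind_rows(lapply(names(cfg$parts), function(cg) {
      dplyr::bind_rows(lapply(cfg$parts[[cg]], tibble::as_tibble)) |>
        dplyr::mutate(cargo = cg, .before = 1)
    }))
    if (is.null(cfg$program_part))
      stop("config with a part split must name program_part")
  }
  structure(list(
    land_freight = land,
    customs_fee_per_line = fee,
    currency = table,
    parts = parts,
    program_part = cfg$program_part,
    frozen_net_weight_kg = cfg$frozen_net_weight_kg,
    nominal_price_threshold = cfg$nominal_price_threshold,
    classification = cfg$classification
  ), class = "shipment_config")
}

#' Assemble a shipment from orders, waybills, and config files
#'
#' @param orders_path,waybills_path CSV paths (see [read_orders()],
#'   [read_waybills()]).
#' @param config_path YAML path (see [read_config()]).
#' @return A [new_shipment()] object (weights not yet imputed).
#' @export
load_shipment <- function(orders_path, waybills_path, config_path) {
  for (p in c(orders_path, waybills_path, config_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  cfg <- read_config(config_path)
  items <- as_item_records(read_orders(orders_path), table = cfg$currency,
                           nominal_threshold = cfg$nominal_price_threshold)
  cargos <- read_waybills(waybills_path)
  new_shipment(items, cargos,
               land_freight = cfg$land_freight,
               customs_fee_per_line = cfg$customs_fee_per_line,
               table = cfg$currency,
               parts = cfg$parts,
               program_part = cfg$program_part,
               frozen_net_weight_kg = cfg$frozen_net_weight_kg,
               nominal_threshold = cfg$nominal_price_threshold)
}

# Presentation rounding mirroring the published tables: money totals to
# whole base-currency units, per-kg and per-unit rates to 2 significant-ish
# decimals, percentages to 1 decimal below 10 and integer at or above.
round_money <- function(x) round(x)
round_rate <- function(x) round(x, 2)
round_pct <- function(x) ifelse(is.na(x), NA_real_,
                                ifelse(abs(x) < 10, round(x, 1), round(x)))

#' Write report tables for a cost allocation
#'
#' Emits, under `dir`: `items.csv` (per-item unit and item costs, percentage
#' cost, cost band, contributor class), `cargos.csv` (per-cargo cost blocks
#' plus a shipment row), `summary.json` (machine-readable shipment summary).
#' With `round = TRUE` the CSV numbers follow the presentation policy (money
#' totals to whole units, rates to 2 decimals, percentages to 1 decimal
#' below 10 and integers above); the JSON always keeps full precision.
#'
#' @param allocation A [allocate_costs()] result.
#' @param dir Output directory (created if needed).
#' @param classification Optional [classify_contributors()] result to merge
#'   into the item table; computed with defaults when `NULL`.
#' @param round Apply presentation rounding to the CSVs.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(allocation, dir, classification = NULL,
                         round = TRUE) {
  stopifnot(inherits(allocation, "cost_allocation"))
  if (nrow(allocation$unit_costs) == 0L)
    stop("nothing to report: allocation contains no items")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  if (is.null(classification))
    classification <- classify_contributors(allocation$shipment$items)
  items <- item_metrics(allocation, classification)
  cargos <- cargo_metrics(allocation)

  if (round) {
    money_cols <- c("item_air", "item_land", "item_customs", "item_total")
    items[money_cols] <- lapply(items[money_cols], round_rate)
    items$pct_unit_cost <- round_pct(items$pct_unit_cost)
    for (col in c("air", "land", "customs", "total", "order_value"))
      cargos[[col]] <- round_money(cargos[[col]])
    for (col in c("air_per_kg", "land_per_kg", "total_per_kg",
                  "customs_per_line", "gross_to_net"))
      cargos[[col]] <- round_rate(cargos[[col]])
    cargos$pct_of_value <- round_pct(cargos$pct_of_value)
  }

  paths <- c(items = file.path(dir, "items.csv"),
             cargos = file.path(dir, "cargos.csv"),
             summary = file.path(dir, "summary.json"))
  readr::write_csv(items, paths[["items"]], progress = FALSE)
  readr::write_csv(cargos, paths[["cargos"]], progress = FALSE)
  st <- allocation$shipment_total
  summary <- list(
    base_currency = allocation$shipment$currency$base,
    shipment = as.list(st),
    cargo_totals = allocation$cargo_costs[, c("cargo", "air", "land",
                                              "customs", "total")],
    customs_fee_per_line = allocation$fee_per_line,
    average_cost_per_kg = average_cost_per_kg(st$total, st$net_weight_kg),
    pct_of_order_value = 100 * st$total / st$order_value)
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
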