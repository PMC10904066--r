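#' Controlled vocabularies for item records
#'
#' Pharmaceutical forms, packaging types, cargo handling classes, and unit
#' weight provenance codes accepted throughout the package.
#'
#' @name vocabularies
#' @keywords internal
NULL

pharma_forms <- c("capsule", "fluid_lt_100ml", "fluid_ge_100ml", "tablet",
                  "ointment", "powder", "test_kit", "wipe")
packaging_types <- c("ampulla", "bottle", "capsule_or_tablet", "fluid_bag",
                     "sachet", "tube", "vial", "test_kit")
cargo_types <- c("standard", "cool", "frozen")
weight_provenances <- c("measured", "substituted_same_ingredient",
                        "median_of_packaging", "uniform_assumed")

item_columns <- c("item_id", "description", "form", "packaging",
                  "active_ingredient", "concentration", "unit_price",
                  "currency", "quantity", "unit_weight_g", "item_line",
                  "cargo")

#' Build a validated item-record table
#'
#' Coerces a data frame of ordered items into the canonical item-record
#' tibble: enums are checked, unit prices are converted to the base currency
#' of `table`, weight provenance is initialised (`"measured"` where a weight
#' is present, `NA` otherwise), and the nominal-price flag is set for items
#' whose unit price does not reflect their value (price at or below
#' `nominal_threshold` in base currency).
#'
#' @param df Data frame with columns `item_id`, `description`, `form`,
#'   `packaging`, `active_ingredient`, `concentration`, `unit_price`,
#'   `currency`, `quantity`, `unit_weight_g`, `item_line`, `cargo`.
#' @param table A [currency_table()] for price conversion.
#' @param nominal_threshold Price (base currency) at or below which an item
#'   is flagged nominal and excluded from percentage import costs. Default
#'   0.01 euro, the nominal price carried by a split test-kit part in the
#'   motivating shipment.
#' @return A tibble of item records with `unit_price` in base currency and
#'   added `weight_provenance` and `nominal_price` columns.
#' @export
as_item_records <- function(df, table = currency_table(),
                            nominal_threshold = 0.01) {
  missing_cols <- setdiff(item_columns, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  df <- tibble::as_tibble(df)

  check_enum <- function(values, allowed, what) {
    bad <- which(!values %in% allowed)
    if (length(bad))
      stop(sprintf("row %d: unknown %s value \"%s\"", bad[1], what,
                   values[bad[1]]))
  }
  check_enum(df$form, pharma_forms, "form")
  check_enum(df$packaging, packaging_types, "packaging")
  check_enum(df$cargo, cargo_types, "cargo")

  df$quantity <- as.integer(df$quantity)
  df$unit_weight_g <- as.numeric(df$unit_weight_g)
  price_eur <- convert_currency(as.numeric(df$unit_price), df$currency, table)

  dplyr::mutate(
    df,
    unit_price = price_eur,
    currency = table$base,
    weight_provenance = ifelse(is.na(.data$unit_weight_g), NA_character_,
                               "measured"),
    nominal_price = .data$unit_price <= nominal_threshold
  )
}

#' Assemble a shipment
#'
#' A shipment bundles the item records, one waybill row per cargo type, the
#' land-freight lump sum, the per-item-line customs fee, the exchange-rate
#' table, and any part split of a cargo between final destinations (only the
#' part forwarded to the program causes import costs).
#'
#' @param items Item-record tibble from [as_item_records()] (or with the
#'   same columns).
#' @param cargos Tibble with one row per cargo type: `cargo`,
#'   `gross_weight_kg`, `volume_m3` (optional, may be `NA`), `air_freight`
#'   (billed total), `currency`, optional `surcharges` (informational).
#' @param land_freight [money()] (or base-currency number): lump sum for the
#'   truck leg.
#' @param customs_fee_per_line [money()] (or base-currency number): customs
#'   agent fee accrued per declared item line.
#' @param table A [currency_table()].
#' @param parts Optional tibble `cargo`, `destination`, `gross_weight_kg`
#'   describing a split of a cargo between destinations (at most one split
#'   per cargo type).
#' @param program_part Destination label identifying the part forwarded to
#'   the program; required when `parts` is given.
#' @param frozen_net_weight_kg Optional measured/assumed net-weight budget of
#'   the frozen cargo, used by the uniform-weight fallback of
#'   [impute_unit_weights()].
#' @param nominal_threshold Nominal-price threshold in base currency.
#' @return An object of class `shipment`.
#' @export
new_shipment <- function(items, cargos, land_freight, customs_fee_per_line,
                         table = currency_table(), parts = NULL,
                         program_part = NULL, frozen_net_weight_kg = NULL,
                         nominal_threshold = 0.01) {
  stopifnot(inherits(table, "currency_table"))
  cargos <- tibble::as_tibble(cargos)
  if (!"volume_m3" %in% names(cargos)) cargos$volume_m3 <- NA_real_
  if (!"surcharges" %in% names(cargos)) cargos$surcharges <- NA_real_
  if (!"currency" %in% names(cargos)) cargos$currency <- table$base
  cargos$air_freight <- convert_currency(as.numeric(cargos$air_freight),
                                         cargos$currency, table)
  cargos$currency <- table$base
  if (!is.null(parts)) {
    parts <- tibble::as_tibble(parts)
    if (is.null(program_part))
      stop("program_part must identify the destination forwarded to the program")
  }
  structure(list(
    items = tibble::as_tibble(items),
    cargos = cargos,
    land_freight = to_base(land_freight, table),
    customs_fee_per_line = to_base(customs_fee_per_line, table),
    currency = table,
    parts = parts,
    program_part = program_part,
    frozen_net_weight_kg = frozen_net_weight_kg,
    nominal_threshold = nominal_threshold
  ), class = "shipment")
}

#' @export
print.shipment <- function(x, ...) {
  cat("<shipment>", nrow(x$items), "item(s) across",
      nrow(x$cargos), "cargo(s)\n")
  counts <- dplyr::count(x$items, .data$cargo)
  for (i in seq_len(nrow(x$cargos))) {
    cg <- x$cargos[i, ]
    n_it <- counts$n[match(cg$cargo, counts$cargo)]
    cat(sprintf("  %-8s gross %g kg, air freight %s %g, %d item(s)\n",
                cg$cargo, cg$gross_weight_kg, cg$currency, cg$air_freight,
                ifelse(is.na(n_it), 0L, n_it)))
  }
  cat(sprintf("  land freight %s %g; customs fee/line %s %.2f\n",
              x$currency$base, x$land_freight, x$currency$base,
              x$customs_fee_per_line))
  if (!is.null(x$parts))
    cat("  part split:", paste(unique(x$parts$destination), collapse = " / "),
        "(program:", x$program_part, ")\n")
  invisible(x)
}

finding <- function(severity, field, message) {
  tibble::tibble(severity = severity, field = field, message = message)
}

#' Validate a shipment
#'
#' Checks all structural invariants and returns findings rather than raising
#' errors, so that data problems can be reviewed together. Severity `"error"`
#' marks a violated invariant; `"warning"` marks a plausibility issue (e.g. a
#' cargo gross weight below its computed net weight, which can arise from
#' rounded inputs). Validation never mutates its input.
#'
#' @param shipment A [new_shipment()] object.
#' @return Tibble with columns `severity`, `field`, `message`; zero rows when
#'   every invariant holds.
#' @export
validate_shipment <- function(shipment) {
  stopifnot(inherits(shipment, "shipment"))
  out <- finding(character(), character(), character())
  it <- shipment$items
  cg <- shipment$cargos

  bad_q <- which(is.na(it$quantity) | it$quantity < 1L)
  if (length(bad_q))
    out <- dplyr::bind_rows(out, finding(
      "error", "quantity",
      sprintf("item %s: quantity must be >= 1", it$item_id[bad_q])))
  bad_w <- which(!is.na(it$unit_weight_g) & it$unit_weight_g <= 0)
  if (length(bad_w))
    out <- dplyr::bind_rows(out, finding(
      "error", "unit_weight_g",
      sprintf("item %s: unit weight, when present, must be > 0",
              it$item_id[bad_w])))
  bad_p <- which(is.na(it$unit_price) | it$unit_price < 0)
  if (length(bad_p))
    out <- dplyr::bind_rows(out, finding(
      "error", "unit_price",
      sprintf("item %s: unit price must be >= 0", it$item_id[bad_p])))
  bad_flag <- which(it$unit_price <= shipment$nominal_threshold &
                      !it$nominal_price)
  if (length(bad_flag))
    out <- dplyr::bind_rows(out, finding(
      "error", "nominal_price",
      sprintf("item %s: price at or below the nominal threshold must be flagged nominal",
              it$item_id[bad_flag])))
  orphan <- setdiff(unique(it$cargo), cg$cargo)
  if (length(orphan))
    out <- dplyr::bind_rows(out, finding(
      "error", "cargo",
      sprintf("items reference cargo \"%s\" with no waybill row", orphan)))

  if (anyDuplicated(cg$cargo))
    out <- dplyr::bind_rows(out, finding(
      "error", "cargo", "duplicate cargo type in waybills"))
  bad_g <- which(is.na(cg$gross_weight_kg) | cg$gross_weight_kg <= 0)
  if (length(bad_g))
    out <- dplyr::bind_rows(out, finding(
      "error", "gross_weight_kg",
      sprintf("cargo %s: gross weight must be > 0", cg$cargo[bad_g])))
  bad_af <- which(is.na(cg$air_freight) | cg$air_freight < 0)
  if (length(bad_af))
    out <- dplyr::bind_rows(out, finding(
      "error", "air_freight",
      sprintf("cargo %s: air freight must be >= 0", cg$cargo[bad_af])))

  if (shipment$land_freight < 0)
    out <- dplyr::bind_rows(out, finding(
      "error", "land_freight", "land freight must be >= 0"))
  if (shipment$customs_fee_per_line < 0)
    out <- dplyr::bind_rows(out, finding(
      "error", "customs_fee_per_line", "customs fee must be >= 0"))

  if (!is.null(shipment$parts)) {
    pp <- shipment$parts
    if (any(pp$gross_weight_kg <= 0))
      out <- dplyr::bind_rows(out, finding(
        "error", "parts", "shipment-part gross weights must be > 0"))
    if (!is.null(shipment$program_part) &&
        !shipment$program_part %in% pp$destination)
      out <- dplyr::bind_rows(out, finding(
        "error", "parts",
        sprintf("program part \"%s\" not among part destinations",
                shipment$program_part)))
    if (anyDuplicated(paste(pp$cargo, pp$destination)))
      out <- dplyr::bind_rows(out, finding(
        "error", "parts", "duplicate cargo/destination in part split"))
  }

  # plausibility: printed gross weights are rounded, so gross < net is only
  # flagged, not rejected
  net <- it |>
    dplyr::group_by(.data$cargo) |>
    dplyr::summarise(
      net = sum(.data$unit_weight_g * .data$quantity, na.rm = TRUE) / 1000,
      all_present = !anyNA(.data$unit_weight_g)) |>
    dplyr::inner_join(cg[, c("cargo", "gross_weight_kg")], by = "cargo")
  low <- which(net$all_present & net$gross_weight_kg < net$net)
  if (length(low))
    out <- dplyr::bind_rows(out, finding(
      "warning", "gross_weight_kg",
      sprintf("cargo %s: gross weight (%g kg) below computed net weight (%g kg)",
              net$cargo[low], net$gross_weight_kg[low], net$net[low])))
  out
}
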