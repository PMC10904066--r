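#' Run the full import-costing pipeline
#'
#' Binds ingestion, validation, weight imputation, cost allocation,
#' contributor classification, and report writing. The shipment comes from
#' one of three sources: CSV/YAML input files, the built-in golden fixture
#' (`fixture = "uzbekistan-tb-2016"`), or the synthetic generator
#' (`synthetic = ` a YAML file or a [synthetic_spec()]). Every run writes a
#' `manifest.json` recording inputs, versions, seed, and warnings.
#'
#' @param orders,waybills,config Input file paths (ignored when `fixture` or
#'   `synthetic` is given).
#' @param out_dir Output directory for the report files.
#' @param fixture Name of a built-in fixture (`"uzbekistan-tb-2016"`).
#' @param synthetic A [synthetic_spec()] or the path of a YAML file whose
#'   keys are `synthetic_spec()` arguments (at minimum `seed`).
#' @param customs_fee_mode `NULL` to use the configured fee, `"usd50"` or
#'   `"eur45flat"` to override.
#' @param round Apply presentation rounding to the report CSVs.
#' @param reference Optional unit-weight reference list (tibble or CSV path)
#'   for [impute_unit_weights()].
#' @return The `cost_allocation`, invisibly.
#' @export
run_import_costing <- function(orders = NULL, waybills = NULL, config = NULL,
                               out_dir, fixture = NULL, synthetic = NULL,
                               customs_fee_mode = NULL, round = TRUE,
                               reference = NULL) {
  seed_used <- NULL
  if (!is.null(fixture)) {
    if (!identical(fixture, "uzbekistan-tb-2016"))
      stop("unknown fixture: ", fixture)
    shipment <- uzbek_tb_shipment(
      customs_fee_mode = customs_fee_mode %||% "usd50", impute = FALSE)
  } else if (!is.null(synthetic)) {
    if (is.character(synthetic)) {
      args <- yaml::read_yaml(synthetic)
      if (!is.null(args$customs_fee))
        args$customs_fee <- money(args$customs_fee$amount,
                                  args$customs_fee$currency %||% "EUR")
      for (nm in c("n_items", "n_lines", "packaging_factor",
                   "air_rate_per_kg_gross"))
        if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
      synthetic <- do.call(synthetic_spec, args)
    }
    shipment <- generate_shipment(synthetic)
    seed_used <- synthetic$seed
  } else {
    if (is.null(orders) || is.null(waybills) || is.null(config))
      stop("either input files (orders, waybills, config), a fixture, ",
           "or a synthetic spec must be given")
    shipment <- load_shipment(orders, waybills, config)
    if (!is.null(customs_fee_mode)) {
      shipment$customs_fee_per_line <- switch(
        customs_fee_mode,
        usd50 = convert_currency(50, "USD", shipment$currency),
        eur45flat = 45,
        stop("unknown customs fee mode: ", customs_fee_mode))
    }
  }

  findings <- validate_shipment(shipment)
  if (any(findings$severity == "error"))
    stop("shipment fails validation:\n  ",
         paste(findings$message[findings$severity == "error"],
               collapse = "\n  "))
  for (msg in findings$message[findings$severity == "warning"])
    warning(msg, call. = FALSE)

  if (is.character(reference)) reference <- readr::read_csv(
    reference, show_col_types = FALSE, progress = FALSE)
  imp <- impute_unit_weights(shipment$items, reference = reference,
                             frozen_net_weight_kg = shipment$frozen_net_weight_kg)
  shipment$items <- imp$items

  allocation <- allocate_costs(shipment)
  classification <- classify_contributors(shipment$items)
  paths <- write_report(allocation, out_dir, classification = classification,
                        round = round)

  manifest <- list(
    inputs = list(orders = orders, waybills = waybills, config = config,
                  fixture = fixture,
                  synthetic_seed = seed_used),
    package_version = as.character(utils::packageVersion("importcost")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    imputed_weights = nrow(imp$report),
    warnings = findings$message[findings$severity == "warning"],
    outputs = as.list(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(allocation)
}
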