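#' Specification for a synthetic shipment
#'
#' Describes a randomly generated shipment used for property testing and
#' simulation. Unit weights, ordered quantities, and unit prices are drawn
#' from per-cargo log-normal distributions whose defaults reproduce the
#' published medians and interquartile ranges of the motivating shipment
#' (e.g. standard-cargo unit weights with median 1.2 g and IQR 0.7-15 g,
#' quantities with median 4000 and IQR 450-24,000). Gross weight is net
#' weight times a per-cargo packaging factor (defaults 1.1 / 3.5 / 5); air
#' freight is billed per kg gross weight at per-cargo rates; the land
#' freight lump sum is priced per kg total gross weight. A fraction of
#' standard/cool unit weights is blanked to exercise imputation; frozen
#' weights are always blanked (they are uniform by assumption).
#'
#' @param n_items Named integer vector: items per cargo type.
#' @param n_lines Named integer vector: customs item lines per cargo type.
#' @param meanlog,sdlog Named lists of per-cargo log-normal parameters for
#'   `weight` (g), `quantity` (units), `price` (EUR).
#' @param packaging_factor Named gross/net ratios per cargo.
#' @param air_rate_per_kg_gross Named billed air rates (EUR/kg gross).
#' @param land_rate_per_kg_gross Land lump-sum rate (EUR/kg total gross).
#' @param customs_fee [money()] per item line.
#' @param missing_weight_fraction Fraction of standard/cool unit weights
#'   blanked for imputation testing.
#' @param nominal_item_prob Probability that an item carries a nominal
#'   (EUR 0.01) price.
#' @param seed Mandatory integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(
    n_items = c(standard = 69, cool = 14, frozen = 2),
    n_lines = c(standard = 7, cool = 3, frozen = 1),
    meanlog = list(
      weight = c(standard = log(1.2), cool = log(126), frozen = log(50)),
      quantity = c(standard = log(4000), cool = log(4), frozen = log(50)),
      price = c(standard = log(0.10), cool = log(26), frozen = log(24))),
    sdlog = list(
      weight = c(standard = 2.27, cool = 1.26, frozen = 0.5),
      quantity = c(standard = 2.95, cool = 2.46, frozen = 0.5),
      price = c(standard = 2.20, cool = 1.34, frozen = 1.0)),
    packaging_factor = c(standard = 1.1, cool = 3.5, frozen = 5),
    air_rate_per_kg_gross = c(standard = 3.9, cool = 4.2, frozen = 8.0),
    land_rate_per_kg_gross = 0.35,
    customs_fee = money(50, "USD"),
    missing_weight_fraction = 0.09,
    nominal_item_prob = 0.02,
    seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducible generation")
  if (any(n_items < 1)) stop("each cargo needs at least one item")
  if (any(n_lines < 1) || any(n_lines > n_items[names(n_lines)]))
    stop("lines per cargo must be between 1 and the number of items")
  stopifnot(all(packaging_factor > 0), all(air_rate_per_kg_gross >= 0),
            land_rate_per_kg_gross >= 0,
            missing_weight_fraction >= 0, missing_weight_fraction <= 1)
  structure(list(n_items = n_items, n_lines = n_lines, meanlog = meanlog,
                 sdlog = sdlog, packaging_factor = packaging_factor,
                 air_rate_per_kg_gross = air_rate_per_kg_gross,
                 land_rate_per_kg_gross = land_rate_per_kg_gross,
                 customs_fee = customs_fee,
                 missing_weight_fraction = missing_weight_fraction,
                 nominal_item_prob = nominal_item_prob,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic shipment
#'
#' Draws a shipment from a [synthetic_spec()]. The generator is fully
#' reproducible: the same spec (including seed) yields the identical
#' shipment. The frozen cargo's true net weight is recorded as the
#' shipment's frozen net-weight budget before its unit weights are blanked,
#' mirroring how a real frozen cargo's weight is known only at cargo level.
#' Blanking of standard/cool weights never empties a cargo/packaging donor
#' group, so the imputation hierarchy always has a rule to apply.
#'
#' @param spec A [synthetic_spec()].
#' @return A [new_shipment()] object (with missing weights to impute).
#' @export
generate_shipment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  cargos_present <- names(spec$n_items)[spec$n_items > 0]
  forms_pool <- setdiff(pharma_forms, "test_kit")

  gen_cargo <- function(cg) {
    n <- spec$n_items[[cg]]
    k <- spec$n_lines[[cg]]
    w <- stats::rlnorm(n, spec$meanlog$weight[[cg]], spec$sdlog$weight[[cg]])
    q <- as.integer(pmin(1e8, pmax(1, ceiling(
      stats::rlnorm(n, spec$meanlog$quantity[[cg]], spec$sdlog$quantity[[cg]])))))
    p <- stats::rlnorm(n, spec$meanlog$price[[cg]], spec$sdlog$price[[cg]])
    nominal <- stats::runif(n) < spec$nominal_item_prob
    p[nominal] <- 0.01
    # every line occupied, remaining items assigned uniformly
    line_of <- c(seq_len(k), sample.int(k, max(0, n - k), replace = TRUE))
    form <- if (cg == "frozen") rep("test_kit", n)
            else sample(forms_pool, n, replace = TRUE)
    pkg <- if (cg == "frozen") rep("test_kit", n)
           else sample(setdiff(packaging_types, "test_kit"), n, replace = TRUE)
    tibble::tibble(
      item_id = sprintf("%s-%03d", toupper(substr(cg, 1, 3)), seq_len(n)),
      description = sprintf("synthetic %s item %d", cg, seq_len(n)),
      form = form, packaging = pkg,
      active_ingredient = sprintf("ingredient-%s-%d", cg, seq_len(n)),
      concentration = NA_character_,
      unit_price = p, currency = "EUR", quantity = q,
      unit_weight_g = w,
      item_line = sprintf("%s-L%02d", toupper(substr(cg, 1, 3)), line_of),
      cargo = cg)
  }
  items <- dplyr::bind_rows(lapply(cargos_present, gen_cargo))

  net_by_cargo <- items |>
    dplyr::group_by(.data$cargo) |>
    dplyr::summarise(net = sum(.data$unit_weight_g * .data$quantity) / 1000)
  frozen_net <- if ("frozen" %in% net_by_cargo$cargo)
    net_by_cargo$net[net_by_cargo$cargo == "frozen"] else NULL

  # blank weights: frozen entirely; standard/cool a sampled fraction, while
  # keeping at least one donor per cargo/packaging group
  blank <- items$cargo == "frozen"
  cand <- which(!blank)
  cand <- cand[stats::runif(length(cand)) < spec$missing_weight_fraction]
  for (i in cand) {
    grp <- which(items$cargo == items$cargo[i] &
                   items$packaging == items$packaging[i] & !blank)
    if (length(grp) > 1L) blank[i] <- TRUE
  }
  items$unit_weight_g[blank] <- NA_real_

  gross <- net_by_cargo$net *
    unname(spec$packaging_factor[net_by_cargo$cargo])
  cargos <- tibble::tibble(
    cargo = net_by_cargo$cargo,
    gross_weight_kg = gross,
    volume_m3 = gross / 167 * stats::runif(nrow(net_by_cargo), 0.7, 1.1),
    air_freight = gross * unname(spec$air_rate_per_kg_gross[net_by_cargo$cargo]),
    currency = "EUR")

  sh <- new_shipment(
    as_item_records(items),
    cargos,
    land_freight = money(sum(gross) * spec$land_rate_per_kg_gross, "EUR"),
    customs_fee_per_line = spec$customs_fee,
    table = currency_table(),
    frozen_net_weight_kg = frozen_net)
  attr(sh, "seed") <- spec$seed
  sh
}
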