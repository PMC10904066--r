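#' Impute missing unit weights
#'
#' Fills missing unit weights with a three-rule hierarchy:
#' \enumerate{
#'   \item \strong{Same-ingredient substitution}: a donor with the same
#'     active ingredient and matching concentration (exact match after
#'     whitespace/case normalisation), searched first in an optional
#'     reference product list, then among same-cargo-class items in the
#'     shipment. In-shipment donor ties prefer an identical packaging type,
#'     then the lexicographically smallest item id.
#'   \item \strong{Packaging-group median}: the median unit weight of items
#'     with the identical packaging type within the same cargo (even-sized
#'     groups use the mean of the two central values).
#'   \item \strong{Frozen-cargo uniform weight}: frozen cargo items may all
#'     lack weights; every unit is then assumed to weigh the same. With a
#'     configured frozen net-weight budget the uniform weight is
#'     budget / total frozen units; without one an arbitrary equal weight
#'     (1 g) is used, under which transport allocation reduces exactly to
#'     allocation by the imported number of units.
#' }
#' Non-missing weights are never modified, so the operation is idempotent.
#'
#' @param items Item-record tibble (see [as_item_records()]).
#' @param reference Optional reference list tibble with columns
#'   `active_ingredient`, `concentration`, `packaging`, `unit_weight_g`
#'   (a stand-in for a standard product catalogue).
#' @param frozen_net_weight_kg Net-weight budget for the frozen-cargo
#'   fallback (kg); `NULL` for the per-unit-equivalent default.
#' @return List with `items` (weights filled, provenance recorded) and
#'   `report`, a tibble with one row per initially missing weight
#'   (`item_id`, `rule`, `donor_item_id`, `imputed_weight_g`).
#' @export
impute_unit_weights <- function(items, reference = NULL,
                                frozen_net_weight_kg = NULL) {
  items <- tibble::as_tibble(items)
  report <- tibble::tibble(item_id = character(), rule = character(),
                           donor_item_id = character(),
                           imputed_weight_g = numeric())
  missing_idx <- which(is.na(items$unit_weight_g))
  if (length(missing_idx) == 0L)
    return(list(items = items, report = report))

  norm <- function(x) tolower(gsub("\\s+", " ", trimws(ifelse(is.na(x), "", x))))
  if (!is.null(reference)) {
    reference <- tibble::as_tibble(reference)
    reference$.ing <- norm(reference$active_ingredient)
    reference$.conc <- norm(reference$concentration)
  }
  donors <- items[!is.na(items$unit_weight_g), ]
  donors$.ing <- norm(donors$active_ingredient)
  donors$.conc <- norm(donors$concentration)

  filled <- items$unit_weight_g
  prov <- items$weight_provenance
  unresolved <- integer()

  for (i in missing_idx) {
    ing <- norm(items$active_ingredient[i])
    conc <- norm(items$concentration[i])
    pkg <- items$packaging[i]
    value <- NA_real_
    rule <- NA_character_
    donor_id <- NA_character_

    # rule 1: same active ingredient + concentration, reference list first
    if (nzchar(ing)) {
      if (!is.null(reference)) {
        hit <- reference[reference$.ing == ing & reference$.conc == conc, ]
        if (nrow(hit)) {
          value <- hit$unit_weight_g[1]
          rule <- "substituted_same_ingredient"
        }
      }
      if (is.na(value)) {
        hit <- donors[donors$.ing == ing & donors$.conc == conc, ]
        if (nrow(hit)) {
          hit <- hit[order(hit$packaging != pkg, hit$item_id), ]
          value <- hit$unit_weight_g[1]
          donor_id <- hit$item_id[1]
          rule <- "substituted_same_ingredient"
        }
      }
    }
    # rule 2: median unit weight of identically packaged items, same cargo
    if (is.na(value)) {
      grp <- donors$unit_weight_g[donors$packaging == pkg &
                                    donors$cargo == items$cargo[i]]
      if (length(grp)) {
        value <- stats::median(grp)
        rule <- "median_of_packaging"
      }
    }
    if (is.na(value) && items$cargo[i] != "frozen") unresolved <- c(unresolved, i)
    if (!is.na(value)) {
      filled[i] <- value
      prov[i] <- rule
      report <- dplyr::bind_rows(report, tibble::tibble(
        item_id = items$item_id[i], rule = rule, donor_item_id = donor_id,
        imputed_weight_g = value))
    }
  }

  # rule 3: frozen-cargo uniform weight for whatever is still missing there
  frozen_missing <- which(is.na(filled) & items$cargo == "frozen")
  if (length(frozen_missing)) {
    total_units <- sum(items$quantity[items$cargo == "frozen"])
    w <- if (!is.null(frozen_net_weight_kg)) {
      frozen_net_weight_kg * 1000 / total_units
    } else 1
    filled[frozen_missing] <- w
    prov[frozen_missing] <- "uniform_assumed"
    report <- dplyr::bind_rows(report, tibble::tibble(
      item_id = items$item_id[frozen_missing], rule = "uniform_assumed",
      donor_item_id = NA_character_, imputed_weight_g = w))
  }

  if (length(unresolved))
    stop("no imputation rule applies for item(s): ",
         paste(items$item_id[unresolved], collapse = ", "))

  items$unit_weight_g <- filled
  items$weight_provenance <- prov
  list(items = items, report = report)
}
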