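#' Configuration for import-cost-contributor classification
#'
#' Items are classified on the (unit weight, ordered quantity) plane into
#' four quadrants. Thresholds default to the within-cargo medians on log10
#' axes; fixed thresholds (grams / unit count) may be supplied instead.
#'
#' @param weight_rule `"cargo_median"` or `"fixed"`.
#' @param quantity_rule `"cargo_median"` or `"fixed"`.
#' @param weight_threshold_g Fixed weight threshold (g), required when
#'   `weight_rule = "fixed"`.
#' @param quantity_threshold Fixed quantity threshold, required when
#'   `quantity_rule = "fixed"`.
#' @param log_scale Compute median thresholds on log10 axes (default);
#'   immaterial for the quadrant assignment itself since log10 is monotone,
#'   but reported thresholds are on the stated scale.
#' @return A `classification_config` list.
#' @export
classification_config <- function(weight_rule = c("cargo_median", "fixed"),
                                  quantity_rule = c("cargo_median", "fixed"),
                                  weight_threshold_g = NULL,
                                  quantity_threshold = NULL,
                                  log_scale = TRUE) {
  weight_rule <- match.arg(weight_rule)
  quantity_rule <- match.arg(quantity_rule)
  if (weight_rule == "fixed" &&
      (is.null(weight_threshold_g) || weight_threshold_g <= 0))
    stop("fixed weight threshold must be a positive number of grams")
  if (quantity_rule == "fixed" &&
      (is.null(quantity_threshold) || quantity_threshold <= 0))
    stop("fixed quantity threshold must be a positive count")
  structure(list(weight_rule = weight_rule, quantity_rule = quantity_rule,
                 weight_threshold_g = weight_threshold_g,
                 quantity_threshold = quantity_threshold,
                 log_scale = log_scale),
            class = "classification_config")
}

contributor_classes <- c("costly_by_number", "costly_by_unit_weight",
                         "costly_by_weight_times_number", "low_import_cost")

#' Classify items by how they contribute to import costs
#'
#' Each item of a cargo is assigned exactly one of four contributor groups
#' by a quadrant rule on the (unit weight, ordered quantity) plane:
#' \describe{
#'   \item{costly_by_unit_weight}{weight >= threshold, quantity < threshold
#'     (e.g. large-volume fluids ordered in low numbers).}
#'   \item{costly_by_number}{weight < threshold, quantity >= threshold
#'     (e.g. tablets ordered by the hundred thousand).}
#'   \item{costly_by_weight_times_number}{both at or above threshold (e.g.
#'     powders, medium-weight fluids in high quantity).}
#'   \item{low_import_cost}{both below threshold.}
#' }
#' Ties (exactly at a threshold) classify into the ">=" side. Thresholds are
#' computed per cargo (default: median on log10 axes), so multiplying all
#' weights by a constant changes no class.
#'
#' @param items Item-record tibble with unit weights present (one or more
#'   cargos; thresholds are always within-cargo).
#' @param config A [classification_config()].
#' @return Tibble `item_id`, `cargo`, `class`, plus the thresholds used
#'   (`weight_threshold_g`, `quantity_threshold`).
#' @export
classify_contributors <- function(items, config = classification_config()) {
  stopifnot(inherits(config, "classification_config"))
  items <- tibble::as_tibble(items)
  if (nrow(items) == 0L) stop("no items to classify")
  if (anyNA(items$unit_weight_g))
    stop("unit weights must be imputed before classification")

  classify_cargo <- function(df) {
    w_thr <- if (config$weight_rule == "fixed") config$weight_threshold_g
             else if (config$log_scale) 10^stats::median(log10(df$unit_weight_g))
             else stats::median(df$unit_weight_g)
    q_thr <- if (config$quantity_rule == "fixed") config$quantity_threshold
             else if (config$log_scale) 10^stats::median(log10(df$quantity))
             else stats::median(df$quantity)
    # ">=" wins ties; comparison on the raw scale (log10 is monotone) with a
    # relative epsilon so that an exact median hit is not lost to log/exp
    # round-trip noise
    hi_w <- df$unit_weight_g >= w_thr * (1 - 1e-12)
    hi_q <- df$quantity >= q_thr * (1 - 1e-12)
    cls <- dplyr::case_when(
      hi_w & hi_q ~ "costly_by_weight_times_number",
      hi_w & !hi_q ~ "costly_by_unit_weight",
      !hi_w & hi_q ~ "costly_by_number",
      TRUE ~ "low_import_cost")
    tibble::tibble(item_id = df$item_id, cargo = df$cargo, class = cls,
                   weight_threshold_g = w_thr, quantity_threshold = q_thr)
  }
  items |>
    dplyr::group_by(.data$cargo) |>
    dplyr::group_split() |>
    purrr::map(classify_cargo) |>
    dplyr::bind_rows()
}
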