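quadrant_items <- function() {
  # one archetype per quadrant: heavy/low-count fluid, light/high-count
  # tablet, medium-heavy/high-count fluid bag, light/low-count tablet
  tibble::tibble(
    item_id = c("fluid", "tablet", "bag", "small"),
    description = c("ringer lactate 500 ml", "pyrazinamide tablet",
                    "sodium chloride 100 ml bag", "levothyroxine tablet"),
    form = c("fluid_ge_100ml", "tablet", "fluid_ge_100ml", "tablet"),
    packaging = c("bottle", "capsule_or_tablet", "fluid_bag",
                  "capsule_or_tablet"),
    active_ingredient = NA_character_, concentration = NA_character_,
    unit_price = 1, currency = "EUR",
    quantity = c(200L, 500000L, 15000L, 300L),
    unit_weight_g = c(550, 0.5, 110, 0.1),
    item_line = c("L1", "L2", "L1", "L2"),
    cargo = "standard")
}

test_that("quadrant rule reproduces the four contributor archetypes", {
  cls <- classify_contributors(as_item_records(quadrant_items()))
  got <- setNames(cls$class, cls$item_id)
  expect_equal(got[["fluid"]], "costly_by_unit_weight")
  expect_equal(got[["tablet"]], "costly_by_number")
  expect_equal(got[["bag"]], "costly_by_weight_times_number")
  expect_equal(got[["small"]], "low_import_cost")
})

test_that("classification is exhaustive, exclusive, and per-cargo", {
  sh <- impute_all(generate_shipment(small_spec(5)))
  cls <- classify_contributors(sh$items)
  expect_equal(nrow(cls), nrow(sh$items))
  expect_equal(anyDuplicated(paste(cls$item_id, cls$cargo)), 0)
  expect_true(all(cls$class %in% c(
    "costly_by_number", "costly_by_unit_weight",
    "costly_by_weight_times_number", "low_import_cost")))
})

test_that("two items symmetric about both medians split deterministically", {
  items <- quadrant_items()[1:2, ]
  items$unit_weight_g <- c(100, 1)
  items$quantity <- c(10L, 1000L)
  cls <- classify_contributors(as_item_records(items))
  # geometric-median thresholds land between the two; >= wins ties
  expect_setequal(cls$class, c("costly_by_unit_weight", "costly_by_number"))
  cls2 <- classify_contributors(as_item_records(items))
  expect_identical(cls, cls2)
})

test_that("ties at a threshold classify into the >= side", {
  items <- quadrant_items()[1:3, ]
  items$unit_weight_g <- c(1, 10, 100)   # median item sits on the threshold
  items$quantity <- c(100L, 10L, 1L)
  cls <- classify_contributors(as_item_records(items))
  expect_equal(cls$class[cls$item_id == "tablet"],
               "costly_by_weight_times_number")
})

test_that("classification is monotone in weight and quantity under fixed thresholds", {
  cfg <- classification_config(weight_rule = "fixed", quantity_rule = "fixed",
                               weight_threshold_g = 10,
                               quantity_threshold = 1000)
  rank_q <- c(low_import_cost = 0, costly_by_unit_weight = 0,
              costly_by_number = 1, costly_by_weight_times_number = 1)
  rank_w <- c(low_import_cost = 0, costly_by_number = 0,
              costly_by_unit_weight = 1, costly_by_weight_times_number = 1)
  set.seed(17)
  base <- quadrant_items()
  for (i in 1:50) {
    base$unit_weight_g <- 10^runif(4, -1, 3)
    base$quantity <- as.integer(10^runif(4, 1, 5))
    before <- classify_contributors(as_item_records(base), cfg)
    pick <- sample(4, 1)
    bumped <- base
    bumped$quantity[pick] <- bumped$quantity[pick] * 5L
    after_q <- classify_contributors(as_item_records(bumped), cfg)
    expect_gte(rank_q[[after_q$class[pick]]], rank_q[[before$class[pick]]])
    bumped <- base
    bumped$unit_weight_g[pick] <- bumped$unit_weight_g[pick] * 5
    after_w <- classify_contributors(as_item_records(bumped), cfg)
    expect_gte(rank_w[[after_w$class[pick]]], rank_w[[before$class[pick]]])
  }
})

test_that("median-split classes are invariant to rescaling all weights", {
  sh <- impute_all(generate_shipment(small_spec(31)))
  cls1 <- classify_contributors(sh$items)
  scaled <- sh$items
  scaled$unit_weight_g <- scaled$unit_weight_g * 37.5
  cls2 <- classify_contributors(scaled)
  expect_equal(cls1$class, cls2$class)
})

test_that("fixed-threshold configuration validates", {
  expect_error(classification_config(weight_rule = "fixed"), "positive")
  expect_error(classify_contributors(toy_items()[0, ]), "no items")
})
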