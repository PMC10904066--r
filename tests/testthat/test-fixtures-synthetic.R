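test_that("golden fixture carries the documented shipment characteristics", {
  sh <- uzbek_tb_shipment()
  it <- sh$items
  by_cargo <- split(it, factor(it$cargo, c("standard", "cool", "frozen")))
  expect_equal(vapply(by_cargo, function(d) length(unique(d$item_line)),
                      integer(1)),
               c(standard = 7, cool = 3, frozen = 1))
  expect_equal(vapply(by_cargo, function(d) sum(d$quantity), numeric(1)),
               c(standard = 1840928, cool = 1218, frozen = 100))
  expect_equal(vapply(by_cargo, cargo_net_weight, numeric(1)),
               c(standard = 7168, cool = 121, frozen = 5))
  expect_equal(vapply(by_cargo, function(d) sum(d$unit_price * d$quantity),
                      numeric(1)),
               c(standard = 385167, cool = 20228, frozen = 900.8),
               tolerance = 1e-9)
  expect_equal(sh$cargos$gross_weight_kg, c(7987, 428, 25))
  expect_equal(sh$cargos$air_freight, c(31155, 1785, 199))
  expect_equal(sh$land_freight, 2985)
  expect_equal(sh$customs_fee_per_line, 50 / 1.107)
  expect_equal(sum(it$nominal_price), 2)   # donated item + split kit part
  expect_equal(nrow(validate_shipment(sh)), 0)
})

test_that("fixture frozen weights are imputed uniformly from the cargo budget", {
  raw <- uzbek_tb_shipment(impute = FALSE)
  expect_true(all(is.na(raw$items$unit_weight_g[raw$items$cargo == "frozen"])))
  sh <- uzbek_tb_shipment()
  frz <- sh$items[sh$items$cargo == "frozen", ]
  expect_equal(frz$unit_weight_g, c(50, 50))
  expect_equal(frz$weight_provenance, rep("uniform_assumed", 2))
})

test_that("flat EUR 45 fee mode is selectable", {
  sh <- uzbek_tb_shipment(customs_fee_mode = "eur45flat")
  a <- allocate_costs(sh)
  expect_equal(a$cargo_costs$customs, c(315, 135, 45))
})

test_that("fixture round-trips through the CSV/YAML schemas", {
  dir <- withr::local_tempdir()
  sh <- uzbek_tb_shipment(impute = FALSE)
  write_orders(sh$items, file.path(dir, "orders.csv"))
  write_waybills(sh$cargos[, c("cargo", "gross_weight_kg", "volume_m3",
                               "air_freight", "currency")],
                 file.path(dir, "waybills.csv"))
  yaml::write_yaml(list(
    land_freight = list(amount = 2985, currency = "EUR"),
    customs_fee_per_line = list(amount = 50, currency = "USD"),
    frozen_net_weight_kg = 5), file.path(dir, "config.yaml"))
  sh2 <- load_shipment(file.path(dir, "orders.csv"),
                       file.path(dir, "waybills.csv"),
                       file.path(dir, "config.yaml"))
  sh2$items <- impute_unit_weights(
    sh2$items, frozen_net_weight_kg = sh2$frozen_net_weight_kg)$items
  a1 <- allocate_costs(uzbek_tb_shipment())
  a2 <- allocate_costs(sh2)
  expect_equal(a2$cargo_costs$total, a1$cargo_costs$total, tolerance = 1e-9)
  expect_equal(a2$unit_costs$unit_total, a1$unit_costs$unit_total,
               tolerance = 1e-9)
})

test_that("generator is deterministic given a seed and requires one", {
  expect_error(synthetic_spec(), "seed")
  s1 <- generate_shipment(small_spec(1))
  s2 <- generate_shipment(small_spec(1))
  expect_identical(s1$items, s2$items)
  expect_identical(s1$cargos, s2$cargos)
  s3 <- generate_shipment(small_spec(2))
  expect_false(identical(s1$items$unit_weight_g, s3$items$unit_weight_g))
})

test_that("generator leaves global RNG state untouched and validates output", {
  set.seed(123)
  before <- .Random.seed
  sh <- generate_shipment(small_spec(9))
  expect_identical(.Random.seed, before)
  f <- validate_shipment(sh)
  expect_equal(sum(f$severity == "error"), 0)
})

test_that("generated shipments emulate the configured structure", {
  spec <- synthetic_spec(seed = 4)
  sh <- generate_shipment(spec)
  it <- sh$items
  cg_order <- c("standard", "cool", "frozen")
  counts <- vapply(cg_order, function(cg) sum(it$cargo == cg), numeric(1))
  expect_equal(unname(counts), unname(as.numeric(spec$n_items[cg_order])))
  lines <- vapply(cg_order, function(cg)
    length(unique(it$item_line[it$cargo == cg])), numeric(1))
  expect_equal(unname(lines), unname(as.numeric(spec$n_lines[cg_order])))
  # gross weight = net weight x packaging factor (net taken before blanking)
  expect_true(all(is.na(it$unit_weight_g[it$cargo == "frozen"])))
  expect_equal(sh$cargos$gross_weight_kg[sh$cargos$cargo == "frozen"],
               sh$frozen_net_weight_kg * 5)
  expect_error(generate_shipment(synthetic_spec(
    n_items = c(standard = 0, cool = 0, frozen = 0), seed = 1)),
    "at least one")
})

test_that("missing-weight blanking tracks the configured fraction", {
  n_missing <- vapply(1:20, function(s) {
    sh <- generate_shipment(synthetic_spec(seed = s,
                                           missing_weight_fraction = 0.1))
    sum(is.na(sh$items$unit_weight_g) & sh$items$cargo != "frozen")
  }, numeric(1))
  # 83 standard+cool items at 10%: binomial mean ~8.3 per shipment, minus
  # the donor-preserving guard
  expect_gt(mean(n_missing), 3)
  expect_lt(mean(n_missing), 14)
})
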