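test_that("chargeable weight is the max of gross and volumetric weight", {
  expect_equal(chargeable_weight(7987, 1200), 7987)
  expect_equal(chargeable_weight(25, 40), 40)
  expect_equal(chargeable_weight(10, 10), 10)
  expect_error(chargeable_weight(-1, 5), ">= 0")
})

test_that("proportional allocation matches direct arithmetic and conserves", {
  w <- c(7987, 428, 25)
  got <- allocate_proportional(2985, w)
  expect_equal(got, 2985 * w / sum(w))          # independent closed form
  expect_equal(sum(got), 2985, tolerance = 1e-12)
  expect_equal(allocate_proportional(100, c(50, 50)), c(50, 50))
  expect_equal(allocate_proportional(77, 123), 77)
  expect_error(allocate_proportional(10, numeric()), "at least one")
  expect_error(allocate_proportional(10, c(1, 0)), "positive")
})

test_that("proportional allocation is homogeneous and scale-equivariant", {
  set.seed(7)
  for (i in 1:25) {
    w <- runif(sample(2:8, 1), 0.1, 100)
    total <- runif(1, 0, 1e4)
    c1 <- runif(1, 0.1, 10)
    expect_equal(allocate_proportional(total, c1 * w),
                 allocate_proportional(total, w), tolerance = 1e-12)
    expect_equal(allocate_proportional(c1 * total, w),
                 c1 * allocate_proportional(total, w), tolerance = 1e-12)
  }
})

test_that("part-split air freight returns the program part's share", {
  parts <- tibble::tibble(destination = c("Nukus", "Tashkent"),
                          gross_weight_kg = c(60, 40))
  expect_equal(split_air_freight_for_part(100, parts, "Nukus"), 60)
  expect_equal(split_air_freight_for_part(
    100, parts[1, ], "Nukus"), 100)               # no split takes all
  shares <- c(split_air_freight_for_part(100, parts, "Nukus"),
              split_air_freight_for_part(100, parts, "Tashkent"))
  expect_equal(sum(shares), 100)
  expect_error(split_air_freight_for_part(100, parts, "Khiva"), "Khiva")
})

test_that("net weight, rates, and unit costs follow the per-kg arithmetic", {
  one <- toy_items()[1, ]
  one$quantity <- 1000L
  one$unit_weight_g <- 0.9
  expect_equal(cargo_net_weight(as_item_records(one)), 0.9)
  expect_equal(cargo_net_weight(toy_items()[0, ]), 0)
  two <- toy_items()[1:2, ]
  two$unit_weight_g <- c(1, 2)
  two$quantity <- c(500L, 250L)
  expect_equal(cargo_net_weight(two), 1)
  miss <- toy_items()
  miss$unit_weight_g[2] <- NA
  expect_error(cargo_net_weight(miss), "impute")

  expect_equal(transport_rate_per_kg(31155, 7168), 31155 / 7168)
  expect_equal(round(transport_rate_per_kg(31155, 7168), 2), 4.35)
  expect_equal(round(transport_rate_per_kg(199, 5)), 40)
  expect_equal(transport_rate_per_kg(0, 10), 0)
  expect_error(transport_rate_per_kg(10, 0), "net weight")

  expect_equal(unit_transport_cost(0.9, (31155 + 2826) / 7168),
               0.9 / 1000 * (31155 + 2826) / 7168)
  expect_equal(unit_transport_cost(50, (199 + 8.84) / 5),
               50 / 1000 * (199 + 8.84) / 5)
  expect_error(unit_transport_cost(0, 4), "> 0")
  # doubling unit weight doubles the transport component
  expect_equal(unit_transport_cost(1.8, 4.74), 2 * unit_transport_cost(0.9, 4.74))
})

test_that("customs allocation is per line and per unit within a line", {
  fee_usd50 <- convert_currency(50, "USD", currency_table())
  expect_equal(round(customs_total_for_cargo(7, fee_usd50), 2), 316.17)
  expect_equal(round(customs_total_for_cargo(1, fee_usd50), 2), 45.17)
  expect_equal(customs_total_for_cargo(3, 0), 0)
  expect_error(customs_total_for_cargo(0, 45), "at least one")

  expect_equal(round(unit_customs_cost(fee_usd50, 100), 4), 0.4517)
  expect_equal(unit_customs_cost(45.17, 1), 45.17)
  # summing over the units of a line recovers the per-line fee
  expect_equal(unit_customs_cost(fee_usd50, 100) * 100, fee_usd50)
  expect_error(unit_customs_cost(45, 0), "at least one")
})

test_that("allocation conserves costs at item, cargo, and shipment level", {
  sh <- toy_shipment()
  a <- allocate_costs(sh)
  by_cargo <- aggregate(cbind(item_air, item_land, item_customs, item_total) ~
                          cargo, data = a$unit_costs, FUN = sum)
  by_cargo <- by_cargo[match(a$cargo_costs$cargo, by_cargo$cargo), ]
  expect_equal(by_cargo$item_air, a$cargo_costs$air, tolerance = 1e-6)
  expect_equal(by_cargo$item_land, a$cargo_costs$land, tolerance = 1e-6)
  expect_equal(by_cargo$item_customs, a$cargo_costs$customs, tolerance = 1e-6)
  expect_equal(by_cargo$item_total, a$cargo_costs$total, tolerance = 1e-6)
  expect_equal(sum(a$cargo_costs$total), a$shipment_total$total,
               tolerance = 1e-9)
  expect_equal(a$shipment_total$land, sh$land_freight, tolerance = 1e-9)
})

test_that("allocation equals the brute-force unit-enumeration oracle", {
  sh <- toy_shipment()
  a <- allocate_costs(sh)
  oracle <- enumerate_item_costs(sh)
  expect_equal(a$unit_costs$item_air, oracle$air, tolerance = 1e-9)
  expect_equal(a$unit_costs$item_land, oracle$land, tolerance = 1e-9)
  expect_equal(a$unit_costs$item_customs, oracle$customs, tolerance = 1e-9)
  expect_equal(a$unit_costs$item_total, oracle$total, tolerance = 1e-9)
})

test_that("reordering items and cargos changes no allocated number", {
  sh <- toy_shipment()
  a1 <- allocate_costs(sh)
  sh2 <- sh
  set.seed(1)
  sh2$items <- sh2$items[sample(nrow(sh2$items)), ]
  sh2$cargos <- sh2$cargos[rev(seq_len(nrow(sh2$cargos))), ]
  a2 <- allocate_costs(sh2)
  key1 <- a1$unit_costs[order(a1$unit_costs$item_id), ]
  key2 <- a2$unit_costs[order(a2$unit_costs$item_id), ]
  expect_equal(key1$unit_total, key2$unit_total, tolerance = 1e-12)
  expect_equal(a1$shipment_total$total, a2$shipment_total$total,
               tolerance = 1e-12)
})

test_that("a part split routes only the program share into the allocation", {
  parts <- tibble::tibble(cargo = "standard",
                          destination = c("Nukus", "Tashkent"),
                          gross_weight_kg = c(90, 30))
  sh <- toy_shipment(parts = parts, program_part = "Nukus")
  a <- allocate_costs(sh)
  std <- a$cargo_costs[a$cargo_costs$cargo == "standard", ]
  expect_equal(std$air, 600 * 90 / 120)
  expect_equal(std$gross_weight_kg, 90)
  # land allocation uses the program part's gross weight
  expect_equal(std$land, 100 * 90 / (90 + 15))
})

test_that("degenerate shipments fail loudly", {
  sh <- toy_shipment()
  sh$items <- sh$items[0, ]
  expect_error(allocate_costs(sh), "no items")
  sh2 <- toy_shipment()
  sh2$items$unit_weight_g[3] <- NA
  sh2$items$weight_provenance[3] <- NA
  expect_error(allocate_costs(sh2), "impute")
})

test_that("zero-freight cargo yields a customs-only breakdown", {
  cargos <- toy_cargos()
  cargos$air_freight <- 0
  sh <- toy_shipment(cargos = cargos, land = 0, fee = 45)
  a <- allocate_costs(sh)
  expect_equal(a$cargo_costs$air, c(0, 0))
  expect_equal(a$cargo_costs$land, c(0, 0))
  expect_equal(a$cargo_costs$total, a$cargo_costs$customs)
  expect_equal(a$shipment_total$total, 3 * 45)   # three item lines
})
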