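# Costing engine: capacity cost rates, step pricing, consumable rules,
# breakdown assembly, ART stability, annualisation.

test_that("capacity cost rate is annual cost over practical capacity", {
  r <- tibble::tibble(
    resource_id = c("a", "b", "c"),
    facility_id = "F01",
    category = "human_resources",
    annual_cost_usd = c(120000, 0, 9600),
    practical_capacity_min = c(120000, 100000, 96000))
  rates <- capacity_cost_rate(r)$rate_usd_per_min
  expect_equal(rates[1], 1.00)
  expect_equal(rates[2], 0)
  # independent integer-arithmetic oracle: 9600 USD = 960000 cents over
  # 96000 min -> exactly 10 cents/min
  expect_identical(960000L %/% 96000L, 10L)
  expect_equal(rates[3], 0.10)
})

test_that("capacity and cost validation errors are classed", {
  base <- tibble::tibble(resource_id = "a", facility_id = "F01",
                         category = "human_resources",
                         annual_cost_usd = 100, practical_capacity_min = 100)
  zero_cap <- base; zero_cap$practical_capacity_min <- 0
  expect_error(capacity_cost_rate(zero_cap), class = "tdabc_capacity_error")
  neg_cap <- base; neg_cap$practical_capacity_min <- -5
  expect_error(capacity_cost_rate(neg_cap), class = "tdabc_capacity_error")
  neg_cost <- base; neg_cost$annual_cost_usd <- -1
  expect_error(capacity_cost_rate(neg_cost), class = "tdabc_validation_error")
  bad_cat <- base; bad_cat$category <- "vehicles"
  expect_error(capacity_cost_rate(bad_cat), class = "tdabc_validation_error")
})

test_that("practical capacity is the availability-discounted minute product", {
  expect_equal(practical_capacity_minutes(240, 8, 1.0), 115200)
  expect_equal(practical_capacity_minutes(240, 8, 0.8), 240 * 8 * 60 * 0.8)
  expect_equal(practical_capacity_minutes(240, 8, 0.8), 92160)
  expect_error(practical_capacity_minutes(0, 8, 1.0),
               class = "tdabc_validation_error")
  expect_error(practical_capacity_minutes(240, 8, 0),
               class = "tdabc_validation_error")
  expect_error(practical_capacity_minutes(240, 8, 1.2),
               class = "tdabc_validation_error")
})

test_that("step cost is rate times minutes, zero for zero time", {
  rates <- capacity_cost_rate(rate_resources(
    c(nurse = 0.10), "human_resources"))
  steps <- tibble::tibble(encounter_id = "E1", step_index = 1:2,
                          activity = c("a", "b"), resource_id = "nurse",
                          duration_min = c(0, 10), client_facing = TRUE)
  priced <- step_cost(steps, rates)
  expect_equal(priced$cost_usd, c(0, 1.00))
})

test_that("step costs match a brute-force loop oracle on a random fixture", {
  fx <- random_costing_fixture(10, seed = 42, steps_per_encounter = 5)
  priced <- step_cost(fx$steps, capacity_cost_rate(fx$resources))
  rate_of <- setNames(fx$resources$annual_cost_usd /
                        fx$resources$practical_capacity_min,
                      fx$resources$resource_id)
  for (j in seq_len(nrow(fx$steps))) {
    expect_equal(priced$cost_usd[j],
                 rate_of[[fx$steps$resource_id[j]]] * fx$steps$duration_min[j],
                 tolerance = 1e-12)
  }
})

test_that("steps with unknown resources or duplicate indices are rejected", {
  rates <- capacity_cost_rate(rate_resources(c(nurse = 0.1),
                                             "human_resources"))
  steps <- tibble::tibble(encounter_id = "E1", step_index = 1, activity = "a",
                          resource_id = "ghost", duration_min = 5,
                          client_facing = TRUE)
  expect_error(step_cost(steps, rates), class = "tdabc_lookup_error")
  dup <- tibble::tibble(encounter_id = "E1", step_index = c(1, 1),
                        activity = "a", resource_id = "nurse",
                        duration_min = 5, client_facing = TRUE)
  expect_error(step_cost(dup, rates), class = "tdabc_validation_error")
})

test_that("indirects are proportional to direct human-resources cost", {
  expect_equal(allocate_indirects(0, 0.5), 0)
  expect_equal(allocate_indirects(10.00, 0.08), 0.80)
  expect_error(allocate_indirects(10, -0.1), class = "tdabc_validation_error")
  set.seed(7)
  hr <- round(runif(50, 0, 40), 2)
  got <- allocate_indirects(hr, 0.08)
  for (i in seq_along(hr)) expect_equal(got[i], hr[i] * 0.08)
})

test_that("consumables are fixed per line and conditional on receipt", {
  schedule <- tibble::tibble(service_line = c("hct", "vmmc"),
                             fixed_cost_usd = c(6.00, 25.48),
                             basis = "per_visit")
  enc <- rbind(simple_encounter("E1", "hct", received = FALSE),
               simple_encounter("E2", "hct", received = TRUE),
               simple_encounter("E3", "vmmc", received = TRUE))
  expect_equal(consumables_cost(enc, schedule), c(0, 6.00, 25.48))
  expect_error(consumables_cost(simple_encounter("E4", "prep"), schedule),
               class = "tdabc_config_error")
})

test_that("an encounter with no steps and no consumables costs nothing", {
  enc <- simple_encounter("E1", "hct", received = FALSE)
  resources <- rate_resources(c(nurse = 0.1), "human_resources")
  schedule <- tibble::tibble(service_line = "hct", fixed_cost_usd = 6,
                             basis = "per_visit")
  empty_steps <- tibble::tibble(encounter_id = character(),
                                step_index = integer(), activity = character(),
                                resource_id = character(),
                                duration_min = numeric(),
                                client_facing = logical())
  bd <- encounter_cost(enc, empty_steps, resources, schedule)
  expect_equal(bd$human_resources, 0)
  expect_equal(bd$space_equipment, 0)
  expect_equal(bd$indirects, 0)
  expect_equal(bd$consumables, 0)
  expect_equal(bd$total, 0)
  expect_equal(bd$total_provider_minutes, 0)
  expect_equal(bd$basis, "per_visit")
})

test_that("component fixtures reproduce known per-visit service totals", {
  # HCT-shaped encounter: 1.93 + 0.09 + 0.16 + 6.00 = 8.18
  resources <- rate_resources(c(counsellor = 0.193, room = 0.009),
                              c("human_resources", "space_equipment"))
  steps <- tibble::tibble(encounter_id = "E1", step_index = 1:2,
                          activity = c("counselling", "room"),
                          resource_id = c("counsellor", "room"),
                          duration_min = 10, client_facing = c(TRUE, FALSE))
  schedule <- tibble::tibble(service_line = "hct", fixed_cost_usd = 6.00,
                             basis = "per_visit")
  bd <- encounter_cost(simple_encounter("E1", "hct"), steps, resources,
                       schedule, indirect_rate = 0.16 / 1.93)
  expect_equal(bd$human_resources, 1.93)
  expect_equal(bd$space_equipment, 0.09)
  expect_equal(bd$indirects, 0.16)
  expect_equal(bd$consumables, 6.00)
  expect_equal(bd$total, 8.18)

  # VMMC-shaped encounter: 6.42 + 0.06 + 0.32 + 25.48 = 32.28
  resources2 <- rate_resources(c(surgeon = 0.642, theatre = 0.006),
                               c("human_resources", "space_equipment"))
  steps2 <- tibble::tibble(encounter_id = "E1", step_index = 1:2,
                           activity = c("surgery", "theatre"),
                           resource_id = c("surgeon", "theatre"),
                           duration_min = 10, client_facing = c(TRUE, FALSE))
  schedule2 <- tibble::tibble(service_line = "vmmc", fixed_cost_usd = 25.48,
                              basis = "per_visit")
  bd2 <- encounter_cost(simple_encounter("E1", "vmmc"), steps2, resources2,
                        schedule2, indirect_rate = 0.32 / 6.42)
  expect_equal(bd2$total, 32.28)
})

test_that("encounter costs equal the brute-force loop oracle to the cent", {
  fx <- random_costing_fixture(120, seed = 99)
  got <- encounter_cost(fx$encounters, fx$steps, fx$resources, fx$schedule,
                        indirect_rate = 0.08)
  want <- brute_force_costs(fx, indirect_rate = 0.08)
  expect_equal(got$encounter_id, want$encounter_id)
  for (col in c("human_resources", "space_equipment", "indirects",
                "consumables", "total")) {
    expect_lt(max(abs(got[[col]] - want[[col]])), 0.011)
  }
})

test_that("breakdown totals conserve the component sum exactly in cents", {
  fx <- random_costing_fixture(200, seed = 3)
  bd <- encounter_cost(fx$encounters, fx$steps, fx$resources, fx$schedule)
  lhs <- usd_cents(bd$total)
  rhs <- usd_cents(bd$human_resources) + usd_cents(bd$space_equipment) +
    usd_cents(bd$indirects) + usd_cents(bd$consumables)
  expect_identical(lhs, rhs)
})

test_that("scaling all annual costs by k scales non-consumable components", {
  fx <- random_costing_fixture(40, seed = 11)
  base <- encounter_cost(fx$encounters, fx$steps, fx$resources, fx$schedule)
  k <- 3
  scaled_resources <- fx$resources
  scaled_resources$annual_cost_usd <- scaled_resources$annual_cost_usd * k
  scaled <- encounter_cost(fx$encounters, fx$steps, scaled_resources,
                           fx$schedule)
  for (col in c("human_resources", "space_equipment", "indirects")) {
    expect_lt(max(abs(scaled[[col]] - k * base[[col]])), 0.02 + 1e-9)
  }
  expect_equal(scaled$consumables, base$consumables)
})

test_that("zero-time encounters cost exactly the consumables component", {
  fx <- random_costing_fixture(10, seed = 5)
  fx$steps$duration_min <- 0
  bd <- encounter_cost(fx$encounters, fx$steps, fx$resources, fx$schedule)
  expect_equal(bd$total, bd$consumables)
  expect_true(all(bd$human_resources == 0))
})

test_that("orphan steps and duplicate encounters are rejected", {
  fx <- random_costing_fixture(5, seed = 1)
  orphan <- fx$steps
  orphan$encounter_id[1] <- "E9999"
  expect_error(encounter_cost(fx$encounters, orphan, fx$resources,
                              fx$schedule),
               class = "tdabc_validation_error")
  dup_enc <- rbind(fx$encounters, fx$encounters[1, ])
  expect_error(encounter_cost(dup_enc, fx$steps, fx$resources, fx$schedule),
               class = "tdabc_validation_error")
  bad_line <- fx$encounters
  bad_line$service_line[1] <- "outreach"
  expect_error(encounter_cost(bad_line, fx$steps, fx$resources, fx$schedule),
               class = "tdabc_validation_error")
})

test_that("ART stability is the strict conjunction of the five criteria", {
  expect_equal(classify_art_stability(stable_record()), "stable")
  # viral load criterion is strictly below 1000
  expect_equal(classify_art_stability(stable_record(viral_load = 1000)),
               "unstable")
  expect_equal(classify_art_stability(stable_record(viral_load = 999.9)),
               "stable")
  expect_equal(classify_art_stability(stable_record(months_on_art = 5)),
               "unstable")
  expect_equal(classify_art_stability(stable_record(months_on_art = 6)),
               "stable")
  expect_equal(classify_art_stability(stable_record(adherence_pct = 94.9)),
               "unstable")
  expect_equal(classify_art_stability(stable_record(adherence_pct = 95)),
               "stable")

  # flipping any single failing criterion back to passing toggles the result
  failing <- list(
    months_on_art = 3, adherence_pct = 80, oi_stage34 = TRUE,
    viral_load = 5000, regimen_line = "other")
  for (criterion in names(failing)) {
    args <- failing[criterion]
    rec <- do.call(stable_record, args)
    expect_equal(classify_art_stability(rec), "unstable")
  }
})

test_that("stability classification refuses missing data", {
  rec <- stable_record()
  rec$viral_load <- NA
  expect_error(classify_art_stability(rec), class = "tdabc_validation_error")
})

test_that("annualisation multiplies components by the visit count", {
  bd <- manual_breakdowns(hr = c(1.90, 1.98), se = c(0.07, 0.10),
                          ind = c(0.15, 0.17), cons = c(41.31, 18.54),
                          service_line = c("art_stable", "art_unstable"))
  annual <- annualize_cost(bd, c("stable", "unstable"))
  expect_equal(annual$human_resources, c(1.90 * 4, 1.98 * 12))
  expect_equal(annual$total, c(43.43 * 4, 20.79 * 12))
  expect_equal(annual$basis, c("annual", "annual"))
  # component-sum identity survives annualisation
  expect_identical(usd_cents(annual$total),
                   usd_cents(annual$human_resources) +
                     usd_cents(annual$space_equipment) +
                     usd_cents(annual$indirects) +
                     usd_cents(annual$consumables))
})

test_that("annualisation rejects non-ART lines and non-per-visit bases", {
  bd <- manual_breakdowns(1, 0.1, 0.1, 5, service_line = "hct")
  expect_error(annualize_cost(bd, "stable"), class = "tdabc_usage_error")
  art <- manual_breakdowns(1, 0.1, 0.1, 5, service_line = "art_stable")
  annual <- annualize_cost(art, "stable")
  expect_error(annualize_cost(annual, "stable"), class = "tdabc_usage_error")
  expect_error(annualize_cost(art, c("stable", "stable")),
               class = "tdabc_usage_error")
})
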