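# TDABC costing engine: capacity cost rates, step costs, consumable rules,
# per-encounter cost breakdowns, ART stability and annualisation.

#' Capacity cost rates from annual resource costs
#'
#' The unit of account in time-driven activity-based costing is the capacity
#' cost rate (CCR): the annual cost of a resource (a staff cadre, a room, a
#' piece of equipment) divided by its practical capacity — the minutes per
#' year the resource is actually available to clients. The CCR is money per
#' minute; multiplying it by observed minutes prices any activity the
#' resource performs.
#'
#' @param resources tibble with columns `resource_id`, `facility_id`,
#'   `category` (`"human_resources"` or `"space_equipment"`),
#'   `annual_cost_usd` (>= 0) and `practical_capacity_min` (> 0).
#' @return the input with an added `rate_usd_per_min` column.
#' @examples
#' r <- tibble::tibble(resource_id = "nurse", facility_id = "F01",
#'                     category = "human_resources",
#'                     annual_cost_usd = 9600, practical_capacity_min = 96000)
#' capacity_cost_rate(r)$rate_usd_per_min  # 0.10
#' @export
capacity_cost_rate <- function(resources) {
  resources <- validate_resources(resources)
  dplyr::mutate(resources,
                rate_usd_per_min = .data$annual_cost_usd / .data$practical_capacity_min)
}

validate_resources <- function(resources) {
  resources <- as_tibble(resources)
  require_columns(resources,
                  c("resource_id", "facility_id", "category",
                    "annual_cost_usd", "practical_capacity_min"),
                  "resources table")
  bad_cat <- setdiff(unique(resources$category), RESOURCE_CATEGORIES)
  if (length(bad_cat) > 0) {
    abort_validation(sprintf("unknown resource category: %s",
                             paste(bad_cat, collapse = ", ")))
  }
  if (anyNA(resources$annual_cost_usd) || any(resources$annual_cost_usd < 0)) {
    abort_validation("annual_cost_usd must be non-negative and non-missing")
  }
  if (anyNA(resources$practical_capacity_min) ||
      any(resources$practical_capacity_min <= 0)) {
    abort_capacity("practical_capacity_min must be strictly positive")
  }
  if (anyDuplicated(resources$resource_id)) {
    abort_validation("resource_id must be unique across the resources table")
  }
  resources
}

#' Practical capacity in minutes per year
#'
#' Practical capacity discounts theoretical availability for the share of
#' paid time a resource can actually face clients (leave, training,
#' administration, idle intervals). The estimate used here is
#' `days_per_year * hours_per_day * 60 * availability_fraction`.
#'
#' @param days_per_year working days per year (> 0).
#' @param hours_per_day working hours per day (> 0).
#' @param availability_fraction fraction of paid time available to clients,
#'   in (0, 1].
#' @return minutes per year.
#' @examples
#' practical_capacity_minutes(240, 8, 0.8) # 92160
#' @export
practical_capacity_minutes <- function(days_per_year, hours_per_day,
                                       availability_fraction = 0.8) {
  if (any(days_per_year <= 0) || any(hours_per_day <= 0)) {
    abort_validation("days_per_year and hours_per_day must be positive")
  }
  if (any(availability_fraction <= 0) || any(availability_fraction > 1)) {
    abort_validation("availability_fraction must lie in (0, 1]")
  }
  days_per_year * hours_per_day * 60 * availability_fraction
}

#' Price timed pathway steps at capacity cost rates
#'
#' Each observed step allocates one resource for a stopwatch-timed number of
#' minutes; its cost is the resource's capacity cost rate times the minutes.
#'
#' @param steps tibble with columns `encounter_id`, `step_index`, `activity`,
#'   `resource_id`, `duration_min` (>= 0) and `client_facing` (logical).
#' @param rates output of [capacity_cost_rate()].
#' @return `steps` with added `category`, `rate_usd_per_min` and `cost_usd`.
#' @export
step_cost <- function(steps, rates) {
  steps <- as_tibble(steps)
  require_columns(steps,
                  c("encounter_id", "step_index", "activity", "resource_id",
                    "duration_min", "client_facing"),
                  "steps table")
  require_columns(rates, c("resource_id", "category", "rate_usd_per_min"),
                  "rates table")
  if (anyNA(steps$duration_min) || any(steps$duration_min < 0)) {
    abort_validation("duration_min must be non-negative and non-missing")
  }
  dup <- duplicated(steps[, c("encounter_id", "step_index")])
  if (any(dup)) {
    abort_validation(sprintf(
      "duplicated step_index within encounter: %s",
      paste(unique(steps$encounter_id[dup]), collapse = ", ")))
  }
  unknown <- setdiff(unique(steps$resource_id), rates$resource_id)
  if (length(unknown) > 0) {
    abort_lookup(sprintf("steps reference unknown resource_id: %s",
                         paste(unknown, collapse = ", ")))
  }
  out <- dplyr::left_join(
    steps,
    dplyr::select(rates, "resource_id", "category", "rate_usd_per_min"),
    by = "resource_id")
  dplyr::mutate(out, cost_usd = .data$rate_usd_per_min * .data$duration_min)
}

#' Allocate indirect (administrative/overhead) costs to an encounter
#'
#' Indirects are allocated proportionally to the encounter's direct
#' human-resources cost: `indirects = direct_hr_cost * indirect_rate`. A
#' cost-proportional overhead rate is the standard TDABC convention when
#' overheads are not traced activity by activity.
#'
#' @param direct_hr_cost direct human-resources cost of the encounter (USD).
#' @param indirect_rate overhead rate as a proportion (>= 0).
#' @return allocated indirect cost (USD, unrounded).
#' @export
allocate_indirects <- function(direct_hr_cost, indirect_rate) {
  if (any(indirect_rate < 0) || anyNA(indirect_rate)) {
    abort_validation("indirect_rate must be non-negative")
  }
  if (any(direct_hr_cost < 0)) {
    abort_validation("direct_hr_cost must be non-negative")
  }
  direct_hr_cost * indirect_rate
}

#' Fixed consumable cost conditional on receipt
#'
#' Consumables (medications, laboratory tests, disposables) are costed as a
#' fixed amount per service line, charged only to encounters flagged as
#' having received the associated consumables.
#'
#' @param encounters tibble with columns `encounter_id`, `service_line`,
#'   `received_consumables` (logical).
#' @param schedule tibble with columns `service_line`, `fixed_cost_usd`.
#' @return numeric vector of consumable costs, one per encounter row.
#' @export
consumables_cost <- function(encounters, schedule) {
  encounters <- as_tibble(encounters)
  require_columns(encounters,
                  c("encounter_id", "service_line", "received_consumables"),
                  "encounters table")
  require_columns(schedule, c("service_line", "fixed_cost_usd"),
                  "consumables schedule")
  if (any(schedule$fixed_cost_usd < 0)) {
    abort_validation("consumable fixed_cost_usd must be non-negative")
  }
  missing <- setdiff(unique(encounters$service_line), schedule$service_line)
  if (length(missing) > 0) {
    abort_config(sprintf("no consumable schedule entry for service line(s): %s",
                         paste(missing, collapse = ", ")))
  }
  idx <- match(encounters$service_line, schedule$service_line)
  ifelse(encounters$received_consumables, schedule$fixed_cost_usd[idx], 0)
}

#' Per-encounter cost breakdowns
#'
#' Aggregates priced steps into the four cost categories of a breakdown.
#' Human-resources and space/equipment costs are the step costs summed by
#' resource category; indirects are allocated from the human-resources
#' subtotal via [allocate_indirects()]; consumables come from
#' [consumables_cost()]. Each component is rounded to the cent once, and the
#' total is the exact cent-sum of the four components, so `total ==
#' human_resources + space_equipment + indirects + consumables` holds in
#' fixed-point money units for every row.
#'
#' `total_provider_minutes` sums duration over client-facing steps only:
#' concurrent space/equipment occupancy and non-client-facing provider work
#' are costed but do not count as provider-client interaction time.
#'
#' @param encounters tibble with columns `encounter_id`, `client_id`,
#'   `facility_id`, `service_line`, `received_consumables`.
#' @param steps steps table (see [step_cost()]); every `encounter_id` must
#'   appear in `encounters`.
#' @param resources resources table (see [capacity_cost_rate()]).
#' @param schedule consumable schedule (see [consumables_cost()]).
#' @param indirect_rate overhead rate applied to direct human-resources cost.
#' @return tibble with one row per encounter: identifiers, the four money
#'   components, `total`, `total_provider_minutes` and `basis = "per_visit"`.
#' @export
encounter_cost <- function(encounters, steps, resources, schedule,
                           indirect_rate = 0.08) {
  encounters <- as_tibble(encounters)
  require_columns(encounters,
                  c("encounter_id", "client_id", "facility_id",
                    "service_line", "received_consumables"),
                  "encounters table")
  if (anyDuplicated(encounters$encounter_id)) {
    abort_validation("encounter_id must be unique in the encounters table")
  }
  bad_line <- setdiff(unique(encounters$service_line), SERVICE_LINES)
  if (length(bad_line) > 0) {
    abort_validation(sprintf("unknown service line: %s",
                             paste(bad_line, collapse = ", ")))
  }
  steps <- as_tibble(steps)
  orphan <- setdiff(unique(steps$encounter_id), encounters$encounter_id)
  if (length(orphan) > 0) {
    abort_validation(sprintf("steps reference unknown encounter_id: %s",
                             paste(head(orphan, 5), collapse = ", ")))
  }

  rates <- capacity_cost_rate(resources)
  priced <- step_cost(steps, rates)

  per_cat <- priced |>
    dplyr::group_by(.data$encounter_id, .data$category) |>
    dplyr::summarise(cost_usd = sum(.data$cost_usd), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "category", values_from = "cost_usd",
                       values_fill = 0)
  for (cat in RESOURCE_CATEGORIES) {
    if (!cat %in% names(per_cat)) per_cat[[cat]] <- numeric(nrow(per_cat))
  }

  minutes <- priced |>
    dplyr::filter(.data$client_facing) |>
    dplyr::group_by(.data$encounter_id) |>
    dplyr::summarise(total_provider_minutes = sum(.data$duration_min),
                     .groups = "drop")

  out <- encounters |>
    dplyr::left_join(per_cat, by = "encounter_id") |>
    dplyr::left_join(minutes, by = "encounter_id") |>
    dplyr::mutate(
      human_resources = dplyr::coalesce(.data$human_resources, 0),
      space_equipment = dplyr::coalesce(.data$space_equipment, 0),
      total_provider_minutes = dplyr::coalesce(.data$total_provider_minutes, 0))

  hr_c   <- usd_cents(out$human_resources)
  se_c   <- usd_cents(out$space_equipment)
  ind_c  <- usd_cents(allocate_indirects(out$human_resources, indirect_rate))
  cons_c <- usd_cents(consumables_cost(out, schedule))

  tibble(
    encounter_id = out$encounter_id,
    client_id = out$client_id,
    facility_id = out$facility_id,
    service_line = out$service_line,
    human_resources = cents_usd(hr_c),
    space_equipment = cents_usd(se_c),
    indirects = cents_usd(ind_c),
    consumables = cents_usd(cons_c),
    total = cents_usd(hr_c + se_c + ind_c + cons_c),
    total_provider_minutes = out$total_provider_minutes,
    basis = "per_visit")
}

#' Classify ART clients as stable or unstable
#'
#' A client on antiretroviral therapy is "stable" only if all criteria hold:
#' at least 6 months on ART, adherence of at least 95% over the previous 6
#' months, no stage 3 or 4 opportunistic infection, a viral load strictly
#' below 1000 copies/mL, and a first- or second-line regimen. Failing any
#' single criterion makes the client "unstable". Stability drives the
#' assumed visit frequency (quarterly vs monthly) used in annualisation.
#'
#' @param clinical tibble with columns `months_on_art`, `adherence_pct`,
#'   `oi_stage34` (logical), `viral_load`, `regimen_line`
#'   (`"first"`, `"second"` or `"other"`). No missing values are allowed;
#'   classification never imputes.
#' @return character vector, `"stable"` or `"unstable"`, one per row.
#' @export
classify_art_stability <- function(clinical) {
  clinical <- as_tibble(clinical)
  req <- c("months_on_art", "adherence_pct", "oi_stage34", "viral_load",
           "regimen_line")
  require_columns(clinical, req, "clinical table")
  if (anyNA(clinical[req])) {
    abort_validation("clinical records contain missing values; stability cannot be classified")
  }
  if (any(clinical$adherence_pct < 0 | clinical$adherence_pct > 100)) {
    abort_validation("adherence_pct must lie in [0, 100]")
  }
  if (any(clinical$viral_load < 0) || any(clinical$months_on_art < 0)) {
    abort_validation("viral_load and months_on_art must be non-negative")
  }
  stable <- clinical$months_on_art >= 6 &
    clinical$adherence_pct >= 95 &
    !clinical$oi_stage34 &
    clinical$viral_load < 1000 &
    clinical$regimen_line %in% c("first", "second")
  ifelse(stable, "stable", "unstable")
}

#' Annualise per-visit ART cost breakdowns
#'
#' Stable clients are assumed to attend quarterly (4 visits/year) and
#' unstable clients monthly (12 visits/year). Every money component is
#' multiplied by the integer visit count in cents, so the component-sum
#' identity is preserved exactly. Only ART breakdowns may be annualised;
#' all other services are single encounters.
#'
#' @param breakdowns per-visit breakdowns from [encounter_cost()].
#' @param stability character vector (`"stable"`/`"unstable"`), one per row.
#' @param visit_multipliers named integer vector, default
#'   `c(stable = 4, unstable = 12)`.
#' @return breakdowns with money columns scaled and `basis = "annual"`.
#' @export
annualize_cost <- function(breakdowns, stability,
                           visit_multipliers = c(stable = 4, unstable = 12)) {
  breakdowns <- as_tibble(breakdowns)
  require_columns(breakdowns, c(COST_CATEGORIES, "total", "basis"),
                  "breakdowns table")
  if (!all(breakdowns$basis == "per_visit")) {
    abort_usage("annualize_cost() requires per-visit breakdowns")
  }
  if (length(stability) != nrow(breakdowns)) {
    abort_usage("stability must have one entry per breakdown row")
  }
  if (!all(stability %in% names(visit_multipliers))) {
    abort_usage("stability values must match names(visit_multipliers)")
  }
  if (any(visit_multipliers <= 0) ||
      any(visit_multipliers != round(visit_multipliers))) {
    abort_config("visit multipliers must be positive integers")
  }
  if ("service_line" %in% names(breakdowns)) {
    non_art <- setdiff(unique(breakdowns$service_line),
                       c("art_stable", "art_unstable"))
    if (length(non_art) > 0) {
      abort_usage(sprintf(
        "annualisation applies only to ART service lines, got: %s",
        paste(non_art, collapse = ", ")))
    }
  }
  k <- as.integer(visit_multipliers[stability])
  for (col in c(COST_CATEGORIES, "total")) {
    breakdowns[[col]] <- cents_usd(usd_cents(breakdowns[[col]]) * k)
  }
  breakdowns$basis <- "annual"
  breakdowns
}
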