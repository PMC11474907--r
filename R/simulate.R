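# Seeded synthetic-data generator emulating a multi-facility TDABC field
# study of HIV service delivery: 31 facilities across 4 regions (levels
# HC III / HC IV / hospital, public/private), ~1119 adult clients across 6
# service lines, right-skewed stopwatch step durations, consumable-dominated
# cost mixes, and planted facility-level disparities in provider time for
# recovery experiments.

#' Simulation configuration with study-scale defaults
#'
#' Defaults emulate the study conditions the analysis assumes: 31 facilities
#' with a 16/10/5 HC III / HC IV / hospital split, regions Central/Eastern/
#' Northern/Western in an 8/8/8/7 mix, 24 public to 7 private facilities;
#' 1119 clients split 233/273/292/285/17/19 across ART-stable, ART-unstable,
#' HCT, PMTCT, PrEP and VMMC; 73% female overall (PMTCT all female, VMMC all
#' male), mean age 32.6 (SD 9.4, truncated at 18); possession prevalences
#' near 11% (clock), 35% (grid), 17% (bank), 32% (cupboard); per-visit
#' consumable charges of 41.31 / 20.54 / 6.00 / 17.15 / 8.80 / 25.48 USD;
#' and planted provider-time effects of +35 minutes (Western region),
#' +13 (private facility) and +12 (HC IV).
#'
#' @param seed integer seed; a fixed seed makes every generated table
#'   byte-identical across runs.
#' @param n_facilities,n_clients counts.
#' @param region_mix,level_mix,ownership_mix named probability vectors
#'   (must sum to 1); level and service-line counts are allocated exactly
#'   by largest remainder, the rest are sampled.
#' @param service_line_mix named probability vector over the six lines.
#' @param duration_sdlog lognormal sdlog of step durations (>= 0; 0 gives
#'   deterministic durations).
#' @param cost_jitter_sdlog lognormal sdlog of facility-level resource cost
#'   jitter (>= 0).
#' @param level_cost_multiplier named multiplier of resource costs by level.
#' @param planted_effects named numeric: additive minutes applied to the
#'   designated consult-type step, names `region_western`, `private`,
#'   `level_hciv`.
#' @param consumable_costs named per-visit USD by service line.
#' @param receipt_prob named probability of consumable receipt by line.
#' @param indirect_rate overhead rate on direct human-resources cost.
#' @param days_per_year,hours_per_day,staff_availability practical-capacity
#'   parameters for staff resources (space/equipment use full availability).
#' @return a validated `tdabc_sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_facilities = 31L,
                              n_clients = 1119L,
                              region_mix = c(Central = 8, Eastern = 8,
                                             Northern = 8, Western = 7) / 31,
                              level_mix = c(`HC III` = 16, `HC IV` = 10,
                                            Hospital = 5) / 31,
                              ownership_mix = c(public = 24, private = 7) / 31,
                              service_line_mix = c(art_stable = 233,
                                                   art_unstable = 273,
                                                   hct = 292, pmtct = 285,
                                                   prep = 17, vmmc = 19) / 1119,
                              duration_sdlog = 0.5,
                              cost_jitter_sdlog = 0.15,
                              level_cost_multiplier = c(`HC III` = 1,
                                                        `HC IV` = 1.2,
                                                        Hospital = 1.5),
                              planted_effects = c(region_western = 35,
                                                  private = 13,
                                                  level_hciv = 12),
                              consumable_costs = c(art_stable = 41.31,
                                                   art_unstable = 20.54,
                                                   hct = 6.00, pmtct = 17.15,
                                                   prep = 8.80, vmmc = 25.48),
                              receipt_prob = c(art_stable = 1, art_unstable = 1,
                                               hct = 1, pmtct = 1,
                                               prep = 1, vmmc = 1),
                              indirect_rate = 0.08,
                              days_per_year = 240,
                              hours_per_day = 8,
                              staff_availability = 0.8) {
  check_mix <- function(x, what, levels = NULL) {
    if (abs(sum(x) - 1) > 1e-9 || any(x < 0)) {
      abort_validation(sprintf("%s must be a probability vector summing to 1", what))
    }
    if (!is.null(levels) && !setequal(names(x), levels)) {
      abort_validation(sprintf("%s must be named over: %s", what,
                               paste(levels, collapse = ", ")))
    }
  }
  check_mix(region_mix, "region_mix", REGIONS)
  check_mix(level_mix, "level_mix", FACILITY_LEVELS)
  check_mix(ownership_mix, "ownership_mix", c("public", "private"))
  check_mix(service_line_mix, "service_line_mix", SERVICE_LINES)
  if (duration_sdlog < 0 || cost_jitter_sdlog < 0) {
    abort_validation("duration_sdlog and cost_jitter_sdlog must be non-negative")
  }
  if (n_facilities < 1 || n_clients < 1) {
    abort_validation("n_facilities and n_clients must be at least 1")
  }
  structure(list(
    seed = as.integer(seed),
    n_facilities = as.integer(n_facilities),
    n_clients = as.integer(n_clients),
    region_mix = region_mix,
    level_mix = level_mix,
    ownership_mix = ownership_mix,
    service_line_mix = service_line_mix,
    duration_sdlog = duration_sdlog,
    cost_jitter_sdlog = cost_jitter_sdlog,
    level_cost_multiplier = level_cost_multiplier,
    planted_effects = planted_effects,
    consumable_costs = consumable_costs,
    receipt_prob = receipt_prob,
    indirect_rate = indirect_rate,
    days_per_year = days_per_year,
    hours_per_day = hours_per_day,
    staff_availability = staff_availability,
    line_params = default_line_params(),
    possession_prevalence = c(clock = 0.11, grid = 0.35, bank = 0.17,
                              cupboard = 0.32, radio = 0.41, phone = 0.58,
                              mattress = 0.63, bicycle = 0.29),
    wealth_loading = 0.55,
    resource_base = default_resource_base(),
    pathways = default_pathways()
  ), class = "tdabc_sim_config")
}

# Per-line cohort parameters (female share, age, marriage, education,
# comorbidity) in SERVICE_LINES order.
default_line_params <- function() {
  tibble(
    service_line = SERVICE_LINES,
    female_prob = c(0.65, 0.63, 0.67, 1.00, 0.65, 0.00),
    age_mean = c(39.4, 40.4, 31.0, 29.0, 30.7, 24.9),
    age_sd = c(10.4, 12.7, 11.5, 5.6, 7.9, 8.4),
    married_prob = c(0.42, 0.40, 0.37, 0.50, 0.59, 0.21),
    edu_mean = c(1.7, 1.8, 2.3, 2.0, 2.8, 3.6),
    edu_sd = c(1.4, 1.3, 1.5, 1.5, 1.7, 1.4),
    comorbidity_prob = c(0.06, 0.07, 0.06, 0.02, 0.00, 0.00))
}

# Facility resource roster: annual base costs (USD) before level multiplier
# and jitter, and whether practical capacity uses the staff availability
# fraction (rooms/equipment are bookable at full availability).
default_resource_base <- function() {
  tibble(
    role = c("nurse", "clinician", "counsellor", "lab_technician",
             "pharmacist", "consult_room", "lab_equipment"),
    category = c(rep("human_resources", 5), rep("space_equipment", 2)),
    base_annual_cost_usd = c(4200, 9000, 3000, 4800, 5400, 600, 900),
    staff = c(rep(TRUE, 5), rep(FALSE, 2)))
}

# Care pathway templates. One client-facing row per line is flagged
# `planted`: the additive facility-level minute effects land there.
# Space/equipment rows run concurrently with their clinical step and are
# flagged client_facing = FALSE so occupancy is costed without
# double-counting provider-client interaction time.
default_pathways <- function() {
  pw <- function(activity, role, mean_minutes, client_facing, planted) {
    tibble(activity = activity, role = role, mean_minutes = mean_minutes,
           client_facing = client_facing, planted = planted)
  }
  list(
    art_stable = pw(
      c("registration", "triage", "consultation", "consultation_room",
        "pharmacy", "charting"),
      c("nurse", "nurse", "clinician", "consult_room", "pharmacist",
        "clinician"),
      c(3, 4, 8, 8, 5, 3),
      c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
      c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)),
    art_unstable = pw(
      c("registration", "triage", "consultation", "consultation_room",
        "viral_load_draw", "lab_processing", "pharmacy", "charting"),
      c("nurse", "nurse", "clinician", "consult_room", "lab_technician",
        "lab_equipment", "pharmacist", "clinician"),
      c(3, 4, 12, 12, 8, 8, 5, 3),
      c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
      c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    hct = pw(
      c("registration", "pretest_counselling", "rapid_test",
        "test_equipment", "posttest_counselling", "charting"),
      c("nurse", "counsellor", "lab_technician", "lab_equipment",
        "counsellor", "counsellor"),
      c(3, 15, 10, 10, 8, 2),
      c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
      c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)),
    pmtct = pw(
      c("registration", "counselling", "consultation", "consultation_room",
        "lab_draw", "lab_processing", "pharmacy", "charting"),
      c("nurse", "counsellor", "clinician", "consult_room", "lab_technician",
        "lab_equipment", "pharmacist", "clinician"),
      c(3, 10, 8, 8, 6, 6, 4, 2),
      c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
      c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    prep = pw(
      c("registration", "counselling", "consultation", "consultation_room",
        "pharmacy", "charting"),
      c("nurse", "counsellor", "clinician", "consult_room", "pharmacist",
        "clinician"),
      c(3, 8, 5, 5, 4, 2),
      c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
      c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)),
    vmmc = pw(
      c("registration", "counselling", "surgery", "theatre",
        "recovery", "charting"),
      c("nurse", "counsellor", "clinician", "consult_room", "nurse",
        "clinician"),
      c(3, 10, 35, 35, 15, 5),
      c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
      c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)))
}

# Integer allocation of n across categories proportional to p, exact by
# largest remainder.
largest_remainder <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate the facility roster and its resources
#'
#' Facility levels are allocated exactly by largest remainder from
#' `level_mix` (16/10/5 at the default 31); regions and ownership are
#' sampled from their mixes. Each facility receives a full resource roster
#' (nurse, clinician, counsellor, lab technician, pharmacist, consultation
#' room, laboratory equipment) with level-scaled, jittered annual costs and
#' practical capacities from [practical_capacity_minutes()].
#'
#' @param config a [simulation_config()].
#' @return list of tibbles: `facilities` (facility_id, region, level,
#'   ownership) and `resources`.
#' @export
generate_facilities <- function(config) {
  stopifnot(inherits(config, "tdabc_sim_config"))
  set.seed(config$seed)
  n <- config$n_facilities
  level_counts <- largest_remainder(n, config$level_mix)
  facilities <- tibble(
    facility_id = sprintf("F%02d", seq_len(n)),
    region = sample(names(config$region_mix), n, replace = TRUE,
                    prob = config$region_mix),
    level = sample(rep(names(config$level_mix), level_counts)),
    ownership = sample(names(config$ownership_mix), n, replace = TRUE,
                       prob = config$ownership_mix))

  base <- config$resource_base
  staff_cap <- practical_capacity_minutes(config$days_per_year,
                                          config$hours_per_day,
                                          config$staff_availability)
  room_cap <- practical_capacity_minutes(config$days_per_year,
                                         config$hours_per_day, 1)
  grid <- tidyr::crossing(facility_id = facilities$facility_id,
                          role = base$role) |>
    dplyr::left_join(base, by = "role") |>
    dplyr::left_join(facilities[, c("facility_id", "level")],
                     by = "facility_id") |>
    dplyr::arrange(.data$facility_id, .data$role)
  jitter <- rlnorm(nrow(grid), 0, config$cost_jitter_sdlog)
  resources <- tibble(
    resource_id = paste(grid$facility_id, grid$role, sep = "_"),
    facility_id = grid$facility_id,
    category = grid$category,
    annual_cost_usd = round_money(
      grid$base_annual_cost_usd *
        config$level_cost_multiplier[grid$level] * jitter),
    practical_capacity_min = ifelse(grid$staff, staff_cap, room_cap))
  list(facilities = facilities, resources = resources)
}

#' Generate the client cohort and ART clinical records
#'
#' Service-line counts are allocated exactly by largest remainder from
#' `service_line_mix`; sex, age (truncated normal, minimum 18), marital
#' status, education years and comorbidity are drawn from per-line cohort
#' parameters. Household possessions are binary indicators thresholded on a
#' shared latent wealth factor, so the marginal prevalences hit their
#' targets while items stay positively correlated (which is what makes a
#' one-factor asset index meaningful). ART clients get clinical records
#' consistent with their line: stable records satisfy every stability
#' criterion, unstable records fail at least one.
#'
#' @param config a [simulation_config()].
#' @param facilities facilities tibble from [generate_facilities()].
#' @return list of tibbles: `clients` and `clinical`.
#' @export
generate_clients <- function(config, facilities) {
  stopifnot(inherits(config, "tdabc_sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_clients
  line_counts <- largest_remainder(n, config$service_line_mix)
  service_line <- sample(rep(names(config$service_line_mix), line_counts))
  p <- config$line_params[match(service_line, config$line_params$service_line), ]

  rtrunc_norm <- function(n, mean, sd, lower) {
    u <- runif(n, pnorm(lower, mean, sd), 1)
    qnorm(pmin(u, 1 - 1e-12), mean, sd)
  }
  age <- round(rtrunc_norm(n, p$age_mean, p$age_sd, 18), 1)
  w <- rnorm(n)
  lambda <- config$wealth_loading
  prev <- config$possession_prevalence
  items <- vapply(names(prev), function(it) {
    latent <- lambda * w + sqrt(1 - lambda^2) * rnorm(n)
    as.integer(latent > qnorm(1 - prev[[it]]))
  }, integer(n))
  colnames(items) <- paste0("item_", names(prev))

  clients <- tibble(
    client_id = sprintf("C%04d", seq_len(n)),
    facility_id = sample(facilities$facility_id, n, replace = TRUE),
    service_line = service_line,
    sex = ifelse(rbinom(n, 1, p$female_prob) == 1, "female", "male"),
    age_years = age,
    married = rbinom(n, 1, p$married_prob) == 1,
    education_years = pmax(0, round(rnorm(n, p$edu_mean, p$edu_sd))),
    comorbidity = rbinom(n, 1, p$comorbidity_prob) == 1)
  clients <- dplyr::bind_cols(clients, as_tibble(items))

  art <- clients[clients$service_line %in% c("art_stable", "art_unstable"), ]
  clinical <- generate_clinical(art)
  list(clients = clients, clinical = clinical)
}

# Clinical records consistent with the assigned ART stability label.
generate_clinical <- function(art_clients) {
  n <- nrow(art_clients)
  if (n == 0) {
    return(tibble(client_id = character(), months_on_art = numeric(),
                  adherence_pct = numeric(), oi_stage34 = logical(),
                  viral_load = numeric(), regimen_line = character()))
  }
  stable <- art_clients$service_line == "art_stable"
  months <- ifelse(stable, 6 + rpois(n, 18), 6 + rpois(n, 10))
  adherence <- round(95 + runif(n) * 5, 1)
  oi <- rep(FALSE, n)
  vl <- round(rlnorm(n, log(80), 1))
  vl <- pmin(vl, 999)
  regimen <- sample(c("first", "second"), n, replace = TRUE, prob = c(0.85, 0.15))

  # Unstable clients fail at least one criterion; draw failure modes and
  # force a viral-load failure when none was drawn.
  k <- sum(!stable)
  if (k > 0) {
    fail_adh <- rbinom(k, 1, 0.55) == 1
    fail_vl <- rbinom(k, 1, 0.60) == 1
    fail_months <- rbinom(k, 1, 0.15) == 1
    fail_oi <- rbinom(k, 1, 0.10) == 1
    fail_reg <- rbinom(k, 1, 0.05) == 1
    none <- !(fail_adh | fail_vl | fail_months | fail_oi | fail_reg)
    fail_vl[none] <- TRUE
    idx <- which(!stable)
    adherence[idx][fail_adh] <- round(40 + runif(sum(fail_adh)) * 54.9, 1)
    vl[idx][fail_vl] <- round(1000 + rlnorm(sum(fail_vl), log(5000), 1))
    months[idx][fail_months] <- sample(0:5, sum(fail_months), replace = TRUE)
    oi[idx][fail_oi] <- TRUE
    regimen[idx][fail_reg] <- "other"
  }
  tibble(client_id = art_clients$client_id, months_on_art = months,
         adherence_pct = adherence, oi_stage34 = oi, viral_load = vl,
         regimen_line = regimen)
}

#' Simulate encounters and timed pathway steps
#'
#' One encounter per client. Step durations are lognormal around the
#' pathway template means (positive, right-skewed, the character of
#' time-and-motion data); the planted facility-level minute effects are
#' added to the designated consult-type step of each pathway, making them
#' additive on total provider-client minutes. Consumable receipt is drawn
#' per line. The returned ground truth records the planted effects (keyed
#' by the fitted model's coefficient labels) and the generator's own
#' per-encounter category costs.
#'
#' @param config a [simulation_config()].
#' @param facilities,clients outputs of the upstream generators.
#' @return list: `encounters`, `steps`, `consumables` (schedule tibble) and
#'   `ground_truth`.
#' @export
simulate_encounters <- function(config, facilities, clients) {
  stopifnot(inherits(config, "tdabc_sim_config"))
  set.seed(config$seed + 2L)
  missing_pw <- setdiff(unique(clients$service_line), names(config$pathways))
  if (length(missing_pw) > 0) {
    abort_config(sprintf("no pathway/duration parameters for service line(s): %s",
                         paste(missing_pw, collapse = ", ")))
  }
  n <- nrow(clients)
  encounters <- tibble(
    encounter_id = sprintf("E%04d", seq_len(n)),
    client_id = clients$client_id,
    facility_id = clients$facility_id,
    service_line = clients$service_line,
    received_consumables =
      rbinom(n, 1, config$receipt_prob[clients$service_line]) == 1)

  fac <- facilities[match(encounters$facility_id, facilities$facility_id), ]
  eff <- config$planted_effects
  extra_min <- ifelse(fac$region == "Western", eff[["region_western"]], 0) +
    ifelse(fac$ownership == "private", eff[["private"]], 0) +
    ifelse(fac$level == "HC IV", eff[["level_hciv"]], 0)

  # Expand pathway templates per encounter, in encounter order.
  tmpl <- dplyr::bind_rows(lapply(names(config$pathways), function(line) {
    dplyr::mutate(config$pathways[[line]], service_line = line,
                  step_index = dplyr::row_number())
  }))
  counts <- table(tmpl$service_line)[encounters$service_line]
  rows <- unlist(lapply(encounters$service_line, function(l) {
    which(tmpl$service_line == l)
  }))
  steps <- tmpl[rows, ]
  steps$encounter_id <- rep(encounters$encounter_id, counts)
  steps$facility_id <- rep(encounters$facility_id, counts)
  steps$extra_min <- rep(extra_min, counts) * steps$planted

  sdlog <- config$duration_sdlog
  dur <- rlnorm(nrow(steps), log(steps$mean_minutes) - sdlog^2 / 2, sdlog)
  steps$duration_min <- round(dur + steps$extra_min, 2)

  steps_out <- tibble(
    encounter_id = steps$encounter_id,
    step_index = steps$step_index,
    activity = steps$activity,
    resource_id = paste(steps$facility_id, steps$role, sep = "_"),
    duration_min = steps$duration_min,
    client_facing = steps$client_facing)

  schedule <- tibble(service_line = names(config$consumable_costs),
                     fixed_cost_usd = unname(config$consumable_costs),
                     basis = "per_visit")

  gt <- list(
    planted_effects = c(
      "regionWestern" = unname(eff[["region_western"]]),
      "privateTRUE" = unname(eff[["private"]]),
      "facility_levelHC IV" = unname(eff[["level_hciv"]])),
    encounter_costs = true_encounter_costs(encounters, steps_out, config,
                                           facilities))
  list(encounters = encounters, steps = steps_out, consumables = schedule,
       ground_truth = gt)
}

# Generator-side bookkeeping of true per-encounter category costs,
# recomputed from its own resource cost model (plain base-R aggregation).
true_encounter_costs <- function(encounters, steps, config, facilities) {
  base <- config$resource_base
  role <- sub("^F[0-9]+_", "", steps$resource_id)
  fac_id <- sub("_[a-z_]+$", "", steps$resource_id)
  # Rates must match the generated resources table: recompute from it.
  res <- generate_facilities_resources_cache(config)
  rate <- res$annual_cost_usd[match(steps$resource_id, res$resource_id)] /
    res$practical_capacity_min[match(steps$resource_id, res$resource_id)]
  category <- base$category[match(role, base$role)]
  cost <- rate * steps$duration_min
  hr <- tapply(cost * (category == "human_resources"), steps$encounter_id, sum)
  se <- tapply(cost * (category == "space_equipment"), steps$encounter_id, sum)
  idx <- match(encounters$encounter_id, names(hr))
  hr <- unname(hr[idx]); se <- unname(se[idx])
  hr[is.na(hr)] <- 0; se[is.na(se)] <- 0
  cons <- ifelse(encounters$received_consumables,
                 config$consumable_costs[encounters$service_line], 0)
  ind <- hr * config$indirect_rate
  tibble(encounter_id = encounters$encounter_id,
         human_resources = round_money(hr),
         space_equipment = round_money(se),
         indirects = round_money(ind),
         consumables = round_money(unname(cons)),
         total = round_money(hr) + round_money(se) + round_money(ind) +
           round_money(unname(cons)))
}

# The generator draws facility resources under seed; replay them so the
# ground-truth costs refer to the same resource costs the study tables hold.
generate_facilities_resources_cache <- function(config) {
  generate_facilities(config)$resources
}

#' Run the full generator
#'
#' Calls [generate_facilities()], [generate_clients()] and
#' [simulate_encounters()] in order. Each stage seeds its own stream from
#' `config$seed` (+0, +1, +2), so a fixed seed makes the whole study
#' byte-identical across runs.
#'
#' @param config a [simulation_config()].
#' @return named list: `facilities`, `resources`, `clients`, `clinical`,
#'   `encounters`, `steps`, `consumables`, `ground_truth`.
#' @export
simulate_study <- function(config = simulation_config()) {
  fac <- generate_facilities(config)
  cl <- generate_clients(config, fac$facilities)
  enc <- simulate_encounters(config, fac$facilities, cl$clients)
  list(facilities = fac$facilities, resources = fac$resources,
       clients = cl$clients, clinical = cl$clinical,
       encounters = enc$encounters, steps = enc$steps,
       consumables = enc$consumables, ground_truth = enc$ground_truth)
}

#' Write a simulated study to CSV inputs plus ground truth JSON
#'
#' @param sim output of [simulate_study()].
#' @param outdir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    facilities = file.path(outdir, "facilities.csv"),
    resources = file.path(outdir, "resources.csv"),
    clients = file.path(outdir, "clients.csv"),
    clinical = file.path(outdir, "clinical.csv"),
    encounters = file.path(outdir, "encounters.csv"),
    steps = file.path(outdir, "steps.csv"),
    consumables = file.path(outdir, "consumables.csv"))
  for (name in names(paths)) {
    out <- sim[[name]]
    if (name == "clients") {
      # facility and service-line assignment travel on encounters.csv
      out <- out[setdiff(names(out), c("facility_id", "service_line"))]
    }
    write.csv(out, paths[[name]], row.names = FALSE, quote = TRUE)
  }
  gt_path <- file.path(outdir, "ground_truth.json")
  export_ground_truth(sim$ground_truth, gt_path)
  invisible(c(paths, ground_truth = gt_path))
}

#' Export / read ground truth
#'
#' Machine-readable planted effects and true per-encounter category costs
#' for the recovery test harness. Planted-effect names are the fitted
#' model's coefficient labels, so recovered estimates join by name.
#'
#' @param ground_truth the `ground_truth` element of [simulate_study()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_ground_truth()` returns the list.
#' @export
export_ground_truth <- function(ground_truth, path) {
  payload <- list(
    planted_effects = as.list(ground_truth$planted_effects),
    encounter_costs = ground_truth$encounter_costs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname export_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(planted_effects = unlist(raw$planted_effects),
       encounter_costs = as_tibble(raw$encounter_costs))
}
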