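# Shared fixture builders and independent oracles. The oracles deliberately
# avoid every package code path they check: plain loops, sorted-array
# percentiles, eigendecompositions.

# Resources whose capacity cost rate is exactly `rate` (capacity 100000).
rate_resources <- function(rates, categories, facility_id = "F01") {
  tibble::tibble(
    resource_id = names(rates),
    facility_id = facility_id,
    category = categories,
    annual_cost_usd = unname(rates) * 100000,
    practical_capacity_min = 100000)
}

simple_encounter <- function(encounter_id = "E1", service_line = "hct",
                             received = TRUE, facility_id = "F01") {
  tibble::tibble(encounter_id = encounter_id, client_id = paste0("C", encounter_id),
                 facility_id = facility_id, service_line = service_line,
                 received_consumables = received)
}

# Random multi-encounter fixture over a small resource pool.
random_costing_fixture <- function(n_encounters, seed,
                                   steps_per_encounter = 2:6) {
  set.seed(seed)
  rates <- c(nurse = 0.0456, clinician = 0.0977, counsellor = 0.0326,
             room = 0.0052, lab = 0.0078)
  resources <- rate_resources(
    rates, c("human_resources", "human_resources", "human_resources",
             "space_equipment", "space_equipment"))
  lines <- sample(c("art_stable", "art_unstable", "hct", "pmtct", "prep",
                    "vmmc"), n_encounters, replace = TRUE)
  encounters <- tibble::tibble(
    encounter_id = sprintf("E%04d", seq_len(n_encounters)),
    client_id = sprintf("C%04d", seq_len(n_encounters)),
    facility_id = "F01",
    service_line = lines,
    received_consumables = runif(n_encounters) < 0.8)
  steps <- do.call(rbind, lapply(seq_len(n_encounters), function(i) {
    k <- sample(steps_per_encounter, 1)
    data.frame(
      encounter_id = encounters$encounter_id[i],
      step_index = seq_len(k),
      activity = "step",
      resource_id = sample(names(rates), k, replace = TRUE),
      duration_min = round(rlnorm(k, log(8), 0.6), 2),
      client_facing = runif(k) < 0.8)
  }))
  schedule <- tibble::tibble(
    service_line = c("art_stable", "art_unstable", "hct", "pmtct", "prep",
                     "vmmc"),
    fixed_cost_usd = c(41.31, 20.54, 6.00, 17.15, 8.80, 25.48),
    basis = "per_visit")
  list(encounters = encounters, steps = tibble::as_tibble(steps),
       resources = resources, schedule = schedule)
}

# Brute-force per-encounter costing: explicit loops, cent rounding at the
# component level, fully independent of encounter_cost().
brute_force_costs <- function(fx, indirect_rate = 0.08) {
  res <- as.data.frame(fx$resources)
  rate_of <- setNames(res$annual_cost_usd / res$practical_capacity_min,
                      res$resource_id)
  cat_of <- setNames(res$category, res$resource_id)
  out <- data.frame(encounter_id = fx$encounters$encounter_id,
                    human_resources = 0, space_equipment = 0,
                    indirects = 0, consumables = 0, total = 0)
  for (i in seq_len(nrow(fx$encounters))) {
    eid <- fx$encounters$encounter_id[i]
    hr <- 0; se <- 0
    sub <- fx$steps[fx$steps$encounter_id == eid, ]
    for (j in seq_len(nrow(sub))) {
      c_ij <- rate_of[[sub$resource_id[j]]] * sub$duration_min[j]
      if (cat_of[[sub$resource_id[j]]] == "human_resources") {
        hr <- hr + c_ij
      } else {
        se <- se + c_ij
      }
    }
    cons <- 0
    if (fx$encounters$received_consumables[i]) {
      cons <- fx$schedule$fixed_cost_usd[
        fx$schedule$service_line == fx$encounters$service_line[i]]
    }
    hr_c <- round(hr * 100); se_c <- round(se * 100)
    ind_c <- round(hr * indirect_rate * 100); cons_c <- round(cons * 100)
    out$human_resources[i] <- hr_c / 100
    out$space_equipment[i] <- se_c / 100
    out$indirects[i] <- ind_c / 100
    out$consumables[i] <- cons_c / 100
    out$total[i] <- (hr_c + se_c + ind_c + cons_c) / 100
  }
  out
}

# Naive type-7 percentile on a sorted array.
naive_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

naive_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Breakdown rows with prescribed components (cent-exact), for summaries.
manual_breakdowns <- function(hr, se, ind, cons, service_line = "hct",
                              basis = "per_visit", facility_id = "F01") {
  n <- length(hr)
  tibble::tibble(
    encounter_id = sprintf("E%03d", seq_len(n)),
    client_id = sprintf("C%03d", seq_len(n)),
    facility_id = facility_id,
    service_line = service_line,
    human_resources = hr, space_equipment = se, indirects = ind,
    consumables = cons, total = hr + se + ind + cons,
    total_provider_minutes = 30, basis = basis)
}

# A stable ART clinical record meeting every stability criterion.
stable_record <- function(...) {
  rec <- list(months_on_art = 12, adherence_pct = 96, oi_stage34 = FALSE,
              viral_load = 400, regimen_line = "first")
  mods <- list(...)
  rec[names(mods)] <- mods
  tibble::as_tibble(rec)
}
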