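# CSV schemas, validated readers/writers and the pipeline driver
# (cost -> summarize -> equity).

#' Input table schemas
#'
#' Named list describing the expected columns, types and key of every input
#' CSV. `clients` additionally accepts any number of `item_*` possession
#' columns (integer 0/1). All files are UTF-8 with a header row, decimal
#' point `"."` and no thousands separators.
#'
#' @return named list of schema descriptions.
#' @export
tdabc_schemas <- function() {
  list(
    resources = list(
      cols = c(resource_id = "character", facility_id = "character",
               category = "character", annual_cost_usd = "numeric",
               practical_capacity_min = "numeric"),
      key = "resource_id"),
    steps = list(
      cols = c(encounter_id = "character", step_index = "integer",
               activity = "character", resource_id = "character",
               duration_min = "numeric", client_facing = "logical"),
      key = c("encounter_id", "step_index")),
    encounters = list(
      cols = c(encounter_id = "character", client_id = "character",
               facility_id = "character", service_line = "character",
               received_consumables = "logical"),
      key = "encounter_id"),
    consumables = list(
      cols = c(service_line = "character", fixed_cost_usd = "numeric",
               basis = "character"),
      key = "service_line"),
    clinical = list(
      cols = c(client_id = "character", months_on_art = "numeric",
               adherence_pct = "numeric", oi_stage34 = "logical",
               viral_load = "numeric", regimen_line = "character"),
      key = "client_id"),
    clients = list(
      cols = c(client_id = "character", sex = "character",
               age_years = "numeric", married = "logical",
               education_years = "numeric", comorbidity = "logical"),
      key = "client_id", extra_pattern = "^item_", extra_type = "integer"),
    facilities = list(
      cols = c(facility_id = "character", region = "character",
               level = "character", ownership = "character"),
      key = "facility_id"))
}

coerce_column <- function(x, type, col, path) {
  parsed <- switch(type,
    character = x,
    numeric = suppressWarnings(as.numeric(x)),
    integer = suppressWarnings(as.integer(x)),
    logical = {
      up <- toupper(trimws(x))
      out <- rep(NA, length(x))
      out[up %in% c("TRUE", "T", "1")] <- TRUE
      out[up %in% c("FALSE", "F", "0")] <- FALSE
      out
    })
  bad <- which(is.na(parsed) & !is.na(x) & nzchar(x))
  if (length(bad) > 0) {
    abort_schema(sprintf("%s: column '%s' row %d: cannot parse '%s' as %s",
                         basename(path), col, bad[1], x[bad[1]], type))
  }
  parsed
}

#' Read and validate an input CSV against its schema
#'
#' @param path file path.
#' @param schema one of `names(tdabc_schemas())`, or a schema description.
#' @return typed tibble; schema violations (missing columns, unparseable
#'   values, duplicate keys) raise errors naming the offending row.
#' @export
read_table <- function(path, schema) {
  if (is.character(schema)) {
    schema <- tdabc_schemas()[[match.arg(schema, names(tdabc_schemas()))]]
  }
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  stringsAsFactors = FALSE)
  missing <- setdiff(names(schema$cols), names(raw))
  if (length(missing) > 0) {
    abort_schema(sprintf("%s: missing column(s): %s", basename(path),
                         paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(raw), names(schema$cols))
  if (!is.null(schema$extra_pattern)) {
    unknown <- extra[!grepl(schema$extra_pattern, extra)]
  } else {
    unknown <- extra
  }
  if (length(unknown) > 0) {
    abort_schema(sprintf("%s: unexpected column(s): %s", basename(path),
                         paste(unknown, collapse = ", ")))
  }
  out <- raw
  for (col in names(schema$cols)) {
    out[[col]] <- coerce_column(raw[[col]], schema$cols[[col]], col, path)
  }
  for (col in extra) {
    out[[col]] <- coerce_column(raw[[col]], schema$extra_type, col, path)
  }
  out <- as_tibble(out)
  if (nrow(out) > 0 && !is.null(schema$key)) {
    keys <- do.call(paste, c(out[schema$key], sep = "\r"))
    dup <- which(duplicated(keys))
    if (length(dup) > 0) {
      abort_schema(sprintf("%s: duplicate key (%s) at row %d",
                           basename(path),
                           paste(schema$key, collapse = "+"), dup[1]))
    }
  }
  na_key <- if (!is.null(schema$key)) which(!complete.cases(out[schema$key])) else integer()
  if (length(na_key) > 0) {
    abort_schema(sprintf("%s: missing key value at row %d", basename(path),
                         na_key[1]))
  }
  out
}

#' Pipeline configuration
#'
#' @param indirect_rate overhead rate on direct human-resources cost.
#' @param visit_multipliers annual visit counts by ART stability.
#' @param quantile_type IQR convention for [summarize_service_lines()].
#' @param service_line_ref reference service line for the equity models.
#' @param facility_fe,cluster passed to [fit_equity_models()].
#' @return a `tdabc_pipeline_config` list.
#' @export
pipeline_config <- function(indirect_rate = 0.08,
                            visit_multipliers = c(stable = 4, unstable = 12),
                            quantile_type = 7,
                            service_line_ref = "hct",
                            facility_fe = FALSE,
                            cluster = NULL) {
  if (any(visit_multipliers <= 0) ||
      any(visit_multipliers != round(visit_multipliers))) {
    abort_config("visit multipliers must be positive integers")
  }
  structure(list(indirect_rate = indirect_rate,
                 visit_multipliers = visit_multipliers,
                 quantile_type = quantile_type,
                 service_line_ref = service_line_ref,
                 facility_fe = facility_fe,
                 cluster = cluster),
            class = "tdabc_pipeline_config")
}

#' Write / read per-encounter cost breakdowns as CSV
#'
#' Money is serialised with two decimals (it is cent-exact internally) and
#' minutes with two decimals, so a write-read round trip is lossless.
#'
#' @param breakdowns breakdown tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_breakdowns <- function(breakdowns, path) {
  out <- breakdowns
  for (col in c(COST_CATEGORIES, "total")) out[[col]] <- fmt_usd(out[[col]])
  if ("total_provider_minutes" %in% names(out)) {
    out$total_provider_minutes <- sprintf("%.2f", out$total_provider_minutes)
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_breakdowns
#' @export
read_breakdowns <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c(COST_CATEGORIES, "total", "total_provider_minutes")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  as_tibble(df)
}

#' Run the full costing pipeline on a directory of input CSVs
#'
#' Stages, in order: read and validate the seven input tables; cost every
#' encounter per visit and annualise ART encounters by clinical stability;
#' summarise service lines (ART on the annual basis, other lines per
#' visit); fit the three equity models. Outputs `breakdowns.csv` (per-visit
#' rows for all encounters plus annual rows for ART), `summary.csv`,
#' `equity_table.csv` and `run_log.txt` (configuration echo, config hash,
#' row counts, listwise exclusions; no timestamps, so reruns are
#' byte-identical). Any stage error removes partial outputs and aborts with
#' the stage name.
#'
#' @param indir directory containing the input CSVs (as written by
#'   [write_simulation()]).
#' @param outdir output directory.
#' @param config a [pipeline_config()].
#' @return invisible list with the in-memory results
#'   (`breakdowns`, `summary`, `equity`, `paths`).
#' @export
run_pipeline <- function(indir, outdir, config = pipeline_config()) {
  stopifnot(inherits(config, "tdabc_pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out_paths <- file.path(outdir, c("breakdowns.csv", "summary.csv",
                                   "equity_table.csv", "run_log.txt"))
  written <- character()
  stage <- "read"
  result <- tryCatch({
    facilities <- read_table(file.path(indir, "facilities.csv"), "facilities")
    resources <- read_table(file.path(indir, "resources.csv"), "resources")
    clients <- read_table(file.path(indir, "clients.csv"), "clients")
    clinical <- read_table(file.path(indir, "clinical.csv"), "clinical")
    encounters <- read_table(file.path(indir, "encounters.csv"), "encounters")
    steps <- read_table(file.path(indir, "steps.csv"), "steps")
    schedule <- read_table(file.path(indir, "consumables.csv"), "consumables")

    stage <- "cost"
    per_visit <- encounter_cost(encounters, steps, resources, schedule,
                                indirect_rate = config$indirect_rate)
    art <- per_visit[per_visit$service_line %in%
                       c("art_stable", "art_unstable"), ]
    annual <- NULL
    if (nrow(art) > 0) {
      rec <- clinical[match(art$client_id, clinical$client_id), ]
      if (anyNA(rec$client_id)) {
        abort_validation("ART encounters without clinical records")
      }
      stability <- classify_art_stability(rec)
      annual <- annualize_cost(art, stability, config$visit_multipliers)
    }
    breakdowns <- dplyr::bind_rows(per_visit, annual)
    write_breakdowns(breakdowns, out_paths[1])
    written <- c(written, out_paths[1])

    stage <- "summarize"
    non_art <- per_visit[!per_visit$service_line %in%
                           c("art_stable", "art_unstable"), ]
    pieces <- list()
    if (!is.null(annual) && nrow(annual) > 0) {
      pieces <- c(pieces, list(summarize_service_lines(annual,
                                                       config$quantile_type)))
    }
    if (nrow(non_art) > 0) {
      pieces <- c(pieces, list(summarize_service_lines(non_art,
                                                       config$quantile_type)))
    }
    summary_tbl <- build_cost_table(dplyr::bind_rows(pieces))
    write_cost_table(summary_tbl, out_paths[2])
    written <- c(written, out_paths[2])

    stage <- "equity"
    frame <- equity_model_frame(per_visit, clients, facilities,
                                service_line_ref = config$service_line_ref)
    models <- fit_equity_models(frame, facility_fe = config$facility_fe,
                                cluster = config$cluster)
    equity_tbl <- build_equity_table(models)
    write_equity_table(equity_tbl, out_paths[3])
    written <- c(written, out_paths[3])

    stage <- "log"
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA, null = "null")
    cfg_file <- tempfile(fileext = ".json")
    writeLines(as.character(cfg_json), cfg_file)
    cfg_hash <- unname(tools::md5sum(cfg_file))
    unlink(cfg_file)
    log_lines <- c(
      "tdabc pipeline run",
      sprintf("config: %s", cfg_json),
      sprintf("config_hash: %s", cfg_hash),
      sprintf("n_facilities: %d", nrow(facilities)),
      sprintf("n_clients: %d", nrow(clients)),
      sprintf("n_encounters: %d", nrow(encounters)),
      sprintf("n_steps: %d", nrow(steps)),
      sprintf("n_excluded_missing_covariates: %d",
              attr(frame, "n_excluded")),
      "stages: read cost summarize equity log",
      "status: ok")
    writeLines(log_lines, out_paths[4])
    written <- c(written, out_paths[4])

    list(breakdowns = breakdowns, summary = summary_tbl,
         equity = equity_tbl, paths = setNames(
           out_paths, c("breakdowns", "summary", "equity", "log")))
  }, error = function(e) {
    unlink(written)
    tdabc_abort(sprintf("pipeline failed at stage '%s': %s", stage,
                        conditionMessage(e)),
                "tdabc_pipeline_error")
  })
  invisible(result)
}
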