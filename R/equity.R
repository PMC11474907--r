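# Equity analysis: household wealth asset index (first principal component
# of binary possession indicators), covariate encoding with the reporting
# reference levels, and the three fixed-effects OLS models (provider-client
# minutes; cost with consumables; cost without consumables).

#' Household wealth asset index by principal component analysis
#'
#' The asset index is the first principal component of the column-
#' standardised possession matrix — equivalently, PCA on the correlation
#' matrix, the standard construction for wealth indices from binary asset
#' indicators. Scores are sign-oriented so that a higher index means more
#' possessions (positive correlation with the row sum), then standardised
#' to mean 0 and unit variance over the fitted sample.
#'
#' @param possessions tibble or matrix of 0/1 indicators, clients in rows.
#'   A `client_id` column, if present, is carried through.
#' @return tibble with `client_id` (row index if absent) and `asset_index`.
#' @export
compute_asset_index <- function(possessions) {
  possessions <- as_tibble(possessions)
  ids <- if ("client_id" %in% names(possessions)) {
    possessions$client_id
  } else {
    seq_len(nrow(possessions))
  }
  mat <- as.matrix(possessions[setdiff(names(possessions), "client_id")])
  storage.mode(mat) <- "numeric"
  if (anyNA(mat)) abort_validation("possession matrix contains missing values")
  if (!all(mat %in% c(0, 1))) {
    abort_validation("possession indicators must be 0/1")
  }
  vars <- apply(mat, 2, stats::var)
  keep <- vars > 0
  if (sum(keep) < 2) {
    abort_degenerate("asset index needs at least 2 possession items with non-zero variance")
  }
  if (any(!keep)) {
    warning(sprintf("dropping constant possession item(s): %s",
                    paste(colnames(mat)[!keep], collapse = ", ")),
            call. = FALSE)
    mat <- mat[, keep, drop = FALSE]
  }
  std <- scale(mat)
  pc <- prcomp(std, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  wealth_rank <- rowSums(mat)
  if (stats::var(wealth_rank) > 0 &&
      stats::cov(score, wealth_rank) < 0) {
    score <- -score
  }
  score <- as.numeric(scale(score))
  tibble(client_id = ids, asset_index = score)
}

#' Encode client covariates for the disparity models
#'
#' Bins age (18-30 reference, 31-50, 51-70, 71+) and formal education
#' (0 reference, 1-2, 3-4, 5+ years), and encodes female, married and
#' comorbidity indicators. The asset index is computed from the `item_*`
#' columns via [compute_asset_index()].
#'
#' @param clients tibble with `client_id`, `sex` (`"male"`/`"female"`),
#'   `age_years` (>= 18), `married` (logical), `education_years`,
#'   `comorbidity` (logical) and `item_*` possession columns.
#' @return tibble of encoded client-level covariates; missing covariate
#'   values are propagated (deletion happens at model-frame assembly).
#' @export
encode_covariates <- function(clients) {
  clients <- as_tibble(clients)
  require_columns(clients,
                  c("client_id", "sex", "age_years", "married",
                    "education_years", "comorbidity"),
                  "clients table")
  if (any(clients$age_years < 18, na.rm = TRUE)) {
    abort_eligibility("clients aged under 18 are not eligible")
  }
  item_cols <- grep("^item_", names(clients), value = TRUE)
  if (length(item_cols) < 2) {
    abort_validation("clients table needs at least 2 item_* possession columns")
  }
  asset <- compute_asset_index(clients[c("client_id", item_cols)])
  enc <- tibble(
    client_id = clients$client_id,
    female = clients$sex == "female",
    age_group = cut(clients$age_years, breaks = c(18, 31, 51, 71, Inf),
                    right = FALSE, labels = c("18-30", "31-50", "51-70", "71+")),
    married = as.logical(clients$married),
    education_group = cut(clients$education_years,
                          breaks = c(-Inf, 0, 2, 4, Inf),
                          labels = c("0", "1-2", "3-4", "5+")),
    comorbidity = as.logical(clients$comorbidity))
  dplyr::left_join(enc, asset, by = "client_id")
}

#' Assemble the encounter-level model frame for the equity regressions
#'
#' Joins per-visit cost breakdowns with encoded client covariates and
#' facility attributes, derives the three outcomes (`total_minutes`,
#' `cost_with_consumables`, `cost_without_consumables` — the latter equal,
#' row by row, to the former minus the consumables component) and applies
#' listwise deletion of rows with missing covariates, recording the count.
#'
#' @param breakdowns per-visit breakdowns from [encounter_cost()] (with
#'   `total_provider_minutes`).
#' @param clients clients table (see [encode_covariates()]).
#' @param facilities tibble with `facility_id`, `region`, `level`,
#'   `ownership` (`"public"`/`"private"`).
#' @param service_line_ref reference service line, default `"hct"`.
#' @return tibble ready for [fit_equity_model()]; attribute `n_excluded`
#'   carries the number of listwise-deleted rows.
#' @export
equity_model_frame <- function(breakdowns, clients, facilities,
                               service_line_ref = "hct") {
  breakdowns <- as_tibble(breakdowns)
  facilities <- as_tibble(facilities)
  require_columns(facilities, c("facility_id", "region", "level", "ownership"),
                  "facilities table")
  bad_region <- setdiff(unique(facilities$region), REGIONS)
  if (length(bad_region) > 0) {
    abort_validation(sprintf("unknown region: %s",
                             paste(bad_region, collapse = ", ")))
  }
  if (!service_line_ref %in% breakdowns$service_line) {
    abort_usage(sprintf("reference service line '%s' absent from the data",
                        service_line_ref))
  }
  enc <- encode_covariates(clients)
  frame <- breakdowns |>
    dplyr::left_join(enc, by = "client_id") |>
    dplyr::left_join(facilities, by = "facility_id") |>
    dplyr::mutate(
      total_minutes = .data$total_provider_minutes,
      cost_with_consumables = .data$total,
      cost_without_consumables = .data$total - .data$consumables,
      region = factor(.data$region, levels = REGIONS),
      facility_level = factor(.data$level, levels = FACILITY_LEVELS),
      private = .data$ownership == "private",
      service_line = stats::relevel(factor(.data$service_line),
                                    ref = service_line_ref))
  covars <- c("female", "age_group", "married", "education_group",
              "comorbidity", "asset_index", "region", "facility_level",
              "private", "service_line")
  for (col in names(frame)) {
    if (is.factor(frame[[col]])) frame[[col]] <- droplevels(frame[[col]])
  }
  complete <- complete.cases(frame[covars])
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message(sprintf("excluding %d encounter(s) with missing covariates (listwise deletion)",
                    n_excluded))
  }
  out <- frame[complete, ]
  attr(out, "n_excluded") <- n_excluded
  out
}

equity_formula <- function(outcome, facility_fe = FALSE, covariates = NULL) {
  if (is.null(covariates)) {
    client_terms <- c("female", "age_group", "married", "education_group",
                      "comorbidity", "asset_index")
    facility_terms <- if (facility_fe) {
      "facility_id"
    } else {
      c("region", "facility_level", "private")
    }
    covariates <- c(client_terms, facility_terms, "service_line")
  }
  as.formula(paste(outcome, "~", paste(covariates, collapse = " + ")))
}

#' Fit one fixed-effects disparity regression
#'
#' Ordinary least squares of the chosen outcome on client covariates,
#' facility attributes (region, level, ownership) and service-line
#' indicators; p-values are two-tailed. With `facility_fe = TRUE` the three
#' facility attributes are replaced by facility intercept dummies (they
#' would otherwise be collinear with them). Standard errors are
#' conventional OLS by default; `cluster = "facility_id"` switches to
#' cluster-robust (CR0/HC of \code{sandwich::vcovCL}).
#'
#' @param frame output of [equity_model_frame()].
#' @param outcome one of `"total_minutes"`, `"cost_with_consumables"`,
#'   `"cost_without_consumables"`.
#' @param facility_fe replace facility attributes with facility dummies.
#' @param cluster optional column name to cluster standard errors on.
#' @param covariates optional character vector of right-hand-side terms
#'   overriding the default design (mainly for controlled experiments).
#' @return tibble: `outcome`, `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value` (intercept included); attribute `fit` carries the `lm` object.
#' @export
fit_equity_model <- function(frame,
                             outcome = c("total_minutes",
                                         "cost_with_consumables",
                                         "cost_without_consumables"),
                             facility_fe = FALSE, cluster = NULL,
                             covariates = NULL) {
  outcome <- match.arg(outcome)
  frame <- as_tibble(frame)
  if (anyNA(frame[[outcome]])) {
    abort_validation(sprintf("outcome '%s' has missing values", outcome))
  }
  fml <- equity_formula(outcome, facility_fe, covariates)
  fit <- lm(fml, data = frame)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort_collinear(sprintf("design is rank deficient; aliased term(s): %s",
                            paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  if (length(cf) >= nrow(frame)) {
    abort_usage("more parameters than observations")
  }
  vc <- if (is.null(cluster)) {
    vcov(fit)
  } else {
    sandwich::vcovCL(fit, cluster = frame[[cluster]])
  }
  se <- sqrt(diag(vc))
  tstat <- cf / se
  pval <- 2 * pt(-abs(tstat), df = fit$df.residual)
  out <- tibble(outcome = outcome, term = names(cf), estimate = unname(cf),
                std_error = unname(se), statistic = unname(tstat),
                p_value = unname(pval))
  attr(out, "fit") <- fit
  out
}

#' Fit the three disparity models
#'
#' @inheritParams fit_equity_model
#' @return named list of coefficient tables
#'   (`minutes`, `cost_with`, `cost_without`).
#' @export
fit_equity_models <- function(frame, facility_fe = FALSE, cluster = NULL) {
  list(
    minutes = fit_equity_model(frame, "total_minutes", facility_fe, cluster),
    cost_with = fit_equity_model(frame, "cost_with_consumables",
                                 facility_fe, cluster),
    cost_without = fit_equity_model(frame, "cost_without_consumables",
                                    facility_fe, cluster))
}

#' Combine the three coefficient tables into one reporting table
#'
#' @param models named list from [fit_equity_models()] (or three coefficient
#'   tables with identical term sets).
#' @return tibble: `term`, then coefficient/p-value column pairs for cost
#'   with consumables, cost without consumables, and minutes; term order
#'   follows the cost-with-consumables model.
#' @export
build_equity_table <- function(models) {
  needed <- c("minutes", "cost_with", "cost_without")
  if (!all(needed %in% names(models))) {
    abort_usage("models must be a named list with minutes, cost_with, cost_without")
  }
  terms <- lapply(models[needed], function(m) m$term)
  if (!all(vapply(terms, identical, logical(1), terms[[1]]))) {
    abort_alignment("coefficient tables have mismatched term sets")
  }
  tibble(
    term = models$cost_with$term,
    coef_cost_with = models$cost_with$estimate,
    p_cost_with = models$cost_with$p_value,
    coef_cost_without = models$cost_without$estimate,
    p_cost_without = models$cost_without$p_value,
    coef_minutes = models$minutes$estimate,
    p_minutes = models$minutes$p_value)
}

#' Write / read an equity coefficient table as CSV
#'
#' Full double precision is preserved (round-trip lossless); rounding to
#' presentation precision is left to reporting.
#'
#' @param equity_table output of [build_equity_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_equity_table <- function(equity_table, path) {
  out <- equity_table
  for (col in setdiff(names(out), "term")) {
    out[[col]] <- format(out[[col]], digits = 17, scientific = TRUE,
                         trim = TRUE)
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_equity_table
#' @export
read_equity_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in setdiff(names(df), "term")) df[[col]] <- as.numeric(df[[col]])
  as_tibble(df)
}
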