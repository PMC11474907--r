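# Service-line summary tables: mean/SD/IQR of totals and per-category
# means, SDs and percentage shares of total cost.

#' Percentage share of a cost category
#'
#' Computed on unrounded means and only then rounded to two decimals — the
#' one order of operations under which the printed category shares of a
#' conserved breakdown set sum to 100.
#'
#' @param category_mean mean cost of one category (USD).
#' @param total_mean mean total cost (USD, > 0).
#' @return share in percent, rounded to 2 decimals.
#' @examples
#' category_share(165.24, 173.72) # 95.12
#' @export
category_share <- function(category_mean, total_mean) {
  if (any(total_mean <= 0)) {
    abort_share("category share undefined for non-positive total mean")
  }
  round(100 * category_mean / total_mean, 2)
}

#' Summarise cost breakdowns by service line
#'
#' For each service line present, computes the mean, sample SD (n-1
#' denominator) and IQR (25th/75th percentiles) of the total cost, and the
#' mean, SD, IQR and percentage share for each of the four cost categories.
#' Shares are computed from unrounded means. A component whose value is
#' uniform across all encounters of a line (e.g. a fixed consumable charge)
#' gets `NA` IQR bounds, read as "not applicable". With a single encounter
#' the SD is reported as 0 with a warning and the IQR is degenerate.
#'
#' @param breakdowns tibble of cost breakdowns (see [encounter_cost()]);
#'   basis must be homogeneous within each service line.
#' @param quantile_type quantile algorithm passed to [stats::quantile()];
#'   default 7 (linear interpolation between order statistics).
#' @return long tibble: `service_line`, `basis`, `n`, `component` (`"total"`
#'   or a category), `mean_usd`, `sd_usd`, `pct_of_total`, `iqr_low_usd`,
#'   `iqr_high_usd`.
#' @export
summarize_service_lines <- function(breakdowns, quantile_type = 7) {
  breakdowns <- as_tibble(breakdowns)
  if (nrow(breakdowns) == 0) {
    abort_nodata("no breakdowns to summarise")
  }
  require_columns(breakdowns,
                  c("service_line", COST_CATEGORIES, "total", "basis"),
                  "breakdowns table")
  pieces <- split(breakdowns, breakdowns$service_line)
  out <- lapply(names(pieces), function(line) {
    summarize_one_line(pieces[[line]], line, quantile_type)
  })
  dplyr::bind_rows(out)
}

summarize_one_line <- function(df, line, quantile_type) {
  if (length(unique(df$basis)) > 1) {
    abort_usage(sprintf("mixed basis within service line '%s'", line))
  }
  n <- nrow(df)
  if (n == 1) {
    warning(sprintf("service line '%s' has a single encounter; SD reported as 0",
                    line), call. = FALSE)
  }
  one_sd <- function(x) if (length(x) > 1) sd(x) else 0
  total_mean <- mean(df$total)
  comp_stats <- function(x, component, share) {
    q <- quantile(x, c(0.25, 0.75), type = quantile_type, names = FALSE)
    constant <- diff(range(x)) < 0.005  # uniform to the half-cent
    tibble(
      component = component,
      mean_usd = mean(x),
      sd_usd = one_sd(x),
      pct_of_total = share,
      iqr_low_usd = if (component != "total" && constant) NA_real_ else q[1],
      iqr_high_usd = if (component != "total" && constant) NA_real_ else q[2])
  }
  rows <- dplyr::bind_rows(
    comp_stats(df$total, "total", 100),
    dplyr::bind_rows(lapply(COST_CATEGORIES, function(cat) {
      comp_stats(df[[cat]], cat, category_share(mean(df[[cat]]), total_mean))
    })))
  dplyr::mutate(rows,
                service_line = line, basis = df$basis[1], n = n,
                .before = 1)
}

#' Render service-line summaries as a fixed-layout cost table
#'
#' Orders rows deterministically (ART-stable, ART-unstable, HCT, PMTCT,
#' PrEP, VMMC; within each line: total, human resources, space/equipment,
#' indirects, consumables) and rounds money and shares to two decimals.
#'
#' @param summaries output of [summarize_service_lines()].
#' @return tibble in presentation order with rounded values.
#' @export
build_cost_table <- function(summaries) {
  summaries <- as_tibble(summaries)
  if (nrow(summaries) == 0) abort_nodata("no summaries to tabulate")
  line_order <- c(SERVICE_LINES, setdiff(unique(summaries$service_line),
                                         SERVICE_LINES))
  comp_order <- c("total", COST_CATEGORIES)
  summaries |>
    dplyr::mutate(
      service_line = factor(.data$service_line, levels = line_order),
      component = factor(.data$component, levels = comp_order)) |>
    dplyr::arrange(.data$service_line, .data$component) |>
    dplyr::mutate(
      service_line = as.character(.data$service_line),
      component = as.character(.data$component),
      dplyr::across(c("mean_usd", "sd_usd", "pct_of_total",
                      "iqr_low_usd", "iqr_high_usd"),
                    function(x) round(x, 2)))
}

#' Write / read a cost table as CSV
#'
#' Money and shares are serialised with exactly two decimals so that a
#' write-read round trip is lossless.
#'
#' @param cost_table output of [build_cost_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cost_table <- function(cost_table, path) {
  out <- cost_table
  for (col in c("mean_usd", "sd_usd", "pct_of_total",
                "iqr_low_usd", "iqr_high_usd")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "na", fmt_usd(out[[col]]))
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cost_table
#' @export
read_cost_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("mean_usd", "sd_usd", "pct_of_total",
                "iqr_low_usd", "iqr_high_usd")) {
    df[[col]] <- suppressWarnings(as.numeric(ifelse(df[[col]] == "na",
                                                    NA, df[[col]])))
  }
  as_tibble(df)
}
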