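# Classed error helpers: every user-facing failure carries a condition class
# so callers (and tests) can distinguish validation from lookup from usage.

tdabc_abort <- function(message, class) {
  stop(errorCondition(paste(message, collapse = "\n"),
                      class = c(class, "tdabc_error", "error", "condition")))
}

abort_validation  <- function(msg) tdabc_abort(msg, "tdabc_validation_error")
abort_capacity    <- function(msg) tdabc_abort(msg, "tdabc_capacity_error")
abort_lookup      <- function(msg) tdabc_abort(msg, "tdabc_lookup_error")
abort_config      <- function(msg) tdabc_abort(msg, "tdabc_config_error")
abort_usage       <- function(msg) tdabc_abort(msg, "tdabc_usage_error")
abort_nodata      <- function(msg) tdabc_abort(msg, "tdabc_nodata_error")
abort_share       <- function(msg) tdabc_abort(msg, "tdabc_share_error")
abort_degenerate  <- function(msg) tdabc_abort(msg, "tdabc_degenerate_error")
abort_eligibility <- function(msg) tdabc_abort(msg, "tdabc_eligibility_error")
abort_collinear   <- function(msg) tdabc_abort(msg, "tdabc_collinearity_error")
abort_schema      <- function(msg) tdabc_abort(msg, "tdabc_schema_error")
abort_alignment   <- function(msg) tdabc_abort(msg, "tdabc_alignment_error")

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_validation(sprintf("%s is missing required column(s): %s",
                             what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
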