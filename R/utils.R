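# Condition helpers: every error the package raises carries class "dtc_error"
# so the command-line wrapper can map data errors to exit code 1 and usage
# errors (class "dtc_usage_error") to exit code 2.

dtc_abort <- function(message, class = "dtc_data_error", ...) {
  rlang::abort(message, class = c(class, "dtc_error"), ...)
}

dtc_abort_format <- function(message, ...) {
  dtc_abort(message, class = "dtc_format_error", ...)
}

dtc_abort_param <- function(message, ...) {
  dtc_abort(message, class = "dtc_parameter_error", ...)
}

dtc_abort_usage <- function(message, ...) {
  rlang::abort(message, class = c("dtc_usage_error", "dtc_error"), ...)
}

#' Canonicalize a pathway-layer entity name
#'
#' Pathway nodes (and gene lists queried against them) are matched
#' case-insensitively: names are trimmed and upper-cased. Drug/target IDs at
#' the DTI layer are *not* canonicalized; they stay opaque case-sensitive
#' strings.
#'
#' @param x Character vector of entity names.
#' @return Character vector of canonical (upper-case, trimmed) names.
#' @export
canonical_entity <- function(x) {
  toupper(trimws(as.character(x)))
}

# Require named columns in a data frame read from disk, naming the first
# missing one in the error.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    dtc_abort_format(sprintf(
      "%s: missing required column '%s'", what, missing[[1]]
    ))
  }
  invisible(df)
}

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  na = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
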