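# Internal validation helpers. The index feeds irrigation decisions, so the
# policy is strict errors rather than silent NaN propagation.

stop_invalid <- function(..., class = "cwsifusion_validation_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_invalid(name, " must be finite numeric (got ",
                 paste(utils::head(x, 3), collapse = ", "), ")")
  }
  invisible(x)
}

check_range <- function(x, lo, hi, name) {
  check_finite(x, name)
  if (any(x < lo | x > hi)) {
    stop_invalid(name, " must lie in [", lo, ", ", hi, "]")
  }
  invisible(x)
}

check_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_invalid("missing required column(s): ",
                 paste(missing, collapse = ", "),
                 class = "cwsifusion_schema_error")
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
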