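#' @keywords internal
"_PACKAGE"

# Classed conditions so callers and the CLI can dispatch on failure kind.
ricb_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ricb_error")))
}

ricb_warn <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...), class = c(class, "ricb_warning")))
}

# Round half away from zero (round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

# CSV writer used for every tabular output: unquoted fields so headers match
# the published layouts byte for byte. Fields must therefore be comma-free.
write_plain_csv <- function(df, path) {
  chr <- vapply(df, function(col) is.character(col) || is.factor(col), logical(1))
  for (nm in names(df)[chr]) {
    if (any(grepl(",", df[[nm]], fixed = TRUE), na.rm = TRUE)) {
      ricb_stop("ricb_format_error",
                "column '%s' contains a comma; cannot write unquoted CSV", nm)
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
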