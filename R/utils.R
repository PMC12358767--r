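`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("triplerx_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("triplerx_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_data(what, " is missing required column(s): ",
              paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Deterministic child seed derivation: one master seed per run, stage-specific
# substreams so partial re-runs reproduce (31-bit, R integers are 32-bit).
derive_seed <- function(seed, stream) {
  x <- (as.double(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(stream))) {
    x <- (x * 69069 + ch) %% 2147483647
  }
  as.integer(x)
}

as_iso_date <- function(x) {
  if (inherits(x, "IDate")) return(as.Date(as.integer(x), origin = "1970-01-01"))
  if (inherits(x, "Date")) return(x)
  as.Date(x, format = "%Y-%m-%d")
}

# Calendar month index (year*12 + month), ignoring day of month.
month_index_of <- function(dates) {
  lt <- as.POSIXlt(dates)
  (lt$year + 1900L) * 12L + lt$mon
}
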