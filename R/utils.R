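# classed conditions so callers (and the command-line wrapper) can map
# failure modes to exit codes without string matching

stop_proxiscore <- function(msg, class) {
  stop(structure(
    class = c(class, "proxiscore_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_schema     <- function(msg) stop_proxiscore(msg, "proxiscore_schema_error")
stop_parse      <- function(msg) stop_proxiscore(msg, "proxiscore_parse_error")
stop_integrity  <- function(msg) stop_proxiscore(msg, "proxiscore_integrity_error")
stop_config     <- function(msg) stop_proxiscore(msg, "proxiscore_config_error")
stop_degenerate <- function(msg) stop_proxiscore(msg, "proxiscore_degenerate_error")
stop_alignment  <- function(msg) stop_proxiscore(msg, "proxiscore_alignment_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# first matching column name, or NULL
first_col <- function(df, candidates) {
  hit <- candidates[candidates %in% names(df)]
  if (length(hit)) hit[[1]] else NULL
}
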