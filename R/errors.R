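# Classed conditions used throughout the package.
#
# Every user-facing failure is signalled as a condition inheriting from
#' `pvz_error`, with a subclass naming the failure family so callers (and the
#' CLI) can react programmatically:
# `pvz_input_error`, `pvz_detection_error`, `pvz_config_error`,
# `pvz_data_error`, `pvz_unit_error`, `pvz_selection_error`,
# `pvz_range_error`, `pvz_render_error`, `pvz_io_error`.
pvz_stop <- function(subclass, message, ...) {
  stop(structure(
    class = c(subclass, "pvz_error", "error", "condition"),
    list(message = sprintf(message, ...), call = sys.call(-1))
  ))
}

# re-signal a pvz_error with a context prefix (stage label, capture kind)
# while keeping its class so callers can still dispatch on it
pvz_rethrow <- function(expr, prefix) {
  withCallingHandlers(
    expr,
    pvz_error = function(e) {
      stop(structure(
        class = class(e),
        list(message = paste0(prefix, ": ", conditionMessage(e)),
             call = conditionCall(e))
      ))
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
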