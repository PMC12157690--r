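# Classed conditions so callers (and the CLI) can map failures to exit
# statuses without string-matching messages.
#   barcodify_usage_error : bad flag combinations, invalid spec parameters
#   barcodify_io_error    : missing/unreadable/unwritable files
#   barcodify_parse_error : malformed FASTQ (carries a line number when known)
#   barcodify_data_error  : valid FASTQ that violates the requested geometry
#                           (short reads under the fail policy, bad barcode)

stop_barcodify <- function(subclass, msg, call. = FALSE, ...) {
  cnd <- structure(
    class = c(subclass, "barcodify_error", "error", "condition"),
    list(message = msg, call = NULL, ...)
  )
  stop(cnd)
}

stop_usage <- function(msg, ...) stop_barcodify("barcodify_usage_error", msg, ...)
stop_io    <- function(msg, ...) stop_barcodify("barcodify_io_error", msg, ...)
stop_parse <- function(msg, line = NA_integer_, ...) {
  stop_barcodify("barcodify_parse_error", msg, line = line, ...)
}
stop_data  <- function(msg, ...) stop_barcodify("barcodify_data_error", msg, ...)
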