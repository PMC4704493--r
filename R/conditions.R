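# Structured condition helpers. Every error raised by the package carries a
# specific class under the common "mimicscreen_error" superclass so callers
# (and tests) can distinguish schema problems from integrity violations,
# degenerate inputs, and so on.

ms_stop <- function(msg, class, ...) {
  cnd <- structure(
    class = c(class, "mimicscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cnd)
}

# input file/table does not have the expected columns
ms_schema_error <- function(msg, ...) ms_stop(msg, "mimicscreen_schema_error", ...)
# duplicate keys, inconsistent cross-references
ms_integrity_error <- function(msg, ...) ms_stop(msg, "mimicscreen_integrity_error", ...)
# unparseable cell contents
ms_parse_error <- function(msg, ...) ms_stop(msg, "mimicscreen_parse_error", ...)
# invalid parameter combinations
ms_config_error <- function(msg, ...) ms_stop(msg, "mimicscreen_config_error", ...)
# mathematically degenerate input (zero SD, constant rows, empty groups)
ms_degenerate_error <- function(msg, ...) ms_stop(msg, "mimicscreen_degenerate_error", ...)
# value-level validation failures (negative times, ratios, ...)
ms_validation_error <- function(msg, ...) ms_stop(msg, "mimicscreen_validation_error", ...)
# empty structures where content is required
ms_empty_error <- function(msg, ...) ms_stop(msg, "mimicscreen_empty_error", ...)
# hits lacking annotation records
ms_annotation_error <- function(msg, ...) ms_stop(msg, "mimicscreen_annotation_error", ...)
# message passing failed to settle on exemplars
ms_convergence_error <- function(msg, ...) ms_stop(msg, "mimicscreen_convergence_error", ...)
# set elements outside the declared universe
ms_membership_error <- function(msg, ...) ms_stop(msg, "mimicscreen_membership_error", ...)
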