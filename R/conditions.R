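# Structured error helpers. All package errors inherit from "rxn_error" so
# callers can distinguish pipeline failures from programming errors.

abort_rxn <- function(message, class, call. = FALSE) {
  stop(errorCondition(message, class = c(class, "rxn_error")))
}

abort_invalid_molecule <- function(s, why = "cannot be parsed") {
  abort_rxn(
    sprintf("invalid molecule string %s: %s", deparse(substr(s, 1, 60)), why),
    class = "rxn_invalid_molecule"
  )
}

abort_config <- function(message) abort_rxn(message, class = "rxn_config_error")

abort_undefined_metric <- function(message) {
  abort_rxn(message, class = "rxn_undefined_metric")
}
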