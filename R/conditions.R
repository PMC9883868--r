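# Condition classes shared across the package. Validation errors cover bad
# inputs (schema, invariants); computation errors cover well-formed inputs on
# which the requested quantity is undefined (saturated distances, F = 0/0).

stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("endodiv_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_computation <- function(msg, ...) {
  stop(structure(
    class = c("endodiv_computation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
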