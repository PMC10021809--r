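# Structured error conditions; the CLI maps these classes to exit codes.

.err <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "sewersheds_error")))
}

configError <- function(msg, ...) .err("sewersheds_config_error", msg, ...)
schemaError <- function(msg, ...) .err("sewersheds_schema_error", msg, ...)
geometryError <- function(msg, ...) .err("sewersheds_geometry_error", msg, ...)
ioError <- function(msg, ...) .err("sewersheds_io_error", msg, ...)
referenceError <- function(msg, ...) .err("sewersheds_reference_error", msg, ...)
domainError <- function(msg, ...) .err("sewersheds_domain_error", msg, ...)
emptyInputError <- function(msg, ...) .err("sewersheds_empty_input_error", msg, ...)
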