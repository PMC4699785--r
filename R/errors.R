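# Condition helpers. Each error carries a class the CLI maps to a distinct
# exit code: validation (2), domain (2), infeasibility (3), I/O (4), state (2).

.err <- function(class, msg, call. = FALSE) {
    stop(structure(
        class = c(class, "nirsova_error", "error", "condition"),
        list(message = msg, call = if (call.) sys.call(-1) else NULL)
    ))
}

.valErr <- function(msg) .err("nirsova_validation_error", msg)
.domErr <- function(msg) .err("nirsova_domain_error", msg)
.infeasErr <- function(msg) .err("nirsova_infeasibility_error", msg)
.ioErr <- function(msg) .err("nirsova_io_error", msg)
.stateErr <- function(msg) .err("nirsova_state_error", msg)
.fmtErr <- function(msg) .err("nirsova_format_error", msg)
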