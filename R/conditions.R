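# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish bad parameters (2) from degenerate inputs (3).

tmStop <- function(class, msg) {
    stop(structure(
        class = c(class, "turingMimicError", "error", "condition"),
        list(message = msg, call = NULL)))
}

invalidParameter <- function(msg) tmStop("invalidParameterError", msg)
degenerateInput <- function(msg) tmStop("degenerateInputError", msg)
internalError <- function(msg) tmStop("internalInvariantError", msg)
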