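# Classed conditions so callers (and the CLI) can map error families to
# exit codes without string matching.

abort_affect <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "affectau_error"), call = call))
}

abort_config <- function(msg) abort_affect(msg, "affectau_config_error")
abort_format <- function(msg) abort_affect(msg, "affectau_format_error")
abort_data   <- function(msg) abort_affect(msg, "affectau_data_error")
abort_domain <- function(msg) abort_affect(msg, "affectau_domain_error")
abort_state  <- function(msg) abort_affect(msg, "affectau_state_error")

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
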