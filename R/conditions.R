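# Classed conditions so callers and tests can distinguish failure modes:
#   tbakit_domain_error    - value outside its mathematical domain (e.g. ic50 <= 0)
#   tbakit_format_error    - unparseable token (unknown unit, malformed file)
#   tbakit_input_error     - structurally valid but unusable input (too few points)
#   tbakit_structure_error - inconsistent tree topology (cycles, duplicate ids)
tba_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "tbakit_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_domain <- function(message) tba_error("tbakit_domain_error", message)
abort_format <- function(message) tba_error("tbakit_format_error", message)
abort_input <- function(message) tba_error("tbakit_input_error", message)
abort_structure <- function(message) tba_error("tbakit_structure_error", message)

# Evaluate `code` with a private RNG stream; the caller's .Random.seed is
# untouched. Every stochastic routine in the package funnels through here.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_domain("a single numeric seed is required for reproducibility")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_blank <- function(x) {
  is.null(x) || length(x) == 0L || is.na(x) || (is.character(x) && !nzchar(trimws(x)))
}
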