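# Internal helpers: classed errors and reproducible RNG scoping.

ratbex_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ratbex_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# A NULL seed runs the code under the ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one integer seed, keeping every
# value inside the 32-bit signed range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
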