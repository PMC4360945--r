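# Typed condition helper: all package errors carry class "vsf_error" plus
# an optional more specific class usable with tryCatch().
vsf_stop <- function(msg, class = NULL) {
  stop(structure(class = c(class, "vsf_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream (the generator contract: all randomness flows from one seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
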