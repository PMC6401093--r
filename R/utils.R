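# Seeded functions must not derail the caller's random stream: register
# restoration of the current .Random.seed in the calling function's exit
# handlers, then the caller may set.seed freely.  Without this, a seeded
# call inside a simulation loop would silently make the loop repeat
# itself.
restore_rng_on_exit <- function(envir = parent.frame()) {
  old <- get0(".Random.seed", globalenv())
  expr <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible()
}

# standard prologue for a function with an optional integer seed
use_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(FALSE))
  restore_rng_on_exit(envir)
  set.seed(as.integer(seed))
  invisible(TRUE)
}
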