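# Scoped seeding: set the RNG seed for the duration of the calling
# function and restore the caller's RNG state on exit, so seeded helpers
# are deterministic without clobbering the ambient random stream.
# seed = NULL leaves the current stream untouched (and consumes it).
set_seed_scoped <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  restore <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(seed)
  invisible(NULL)
}
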