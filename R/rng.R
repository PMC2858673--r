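# Seed plumbing shared by all stochastic operations.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded package operations never perturb the
#' caller's random stream. A `NULL` seed evaluates `code` against the
#' current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a stream-specific child seed
#'
#' Maps (master seed, stream id, index) to a deterministic child seed below
#' 2^31. Distinct stream ids keep the image seeds used for template building
#' disjoint from those used for test trials and tuning surfaces, so test
#' stimuli are never drawn from the template image set.
#'
#' @param master integer master seed.
#' @param stream small integer stream identifier.
#' @param index non-negative integer within the stream.
#' @return integer seed.
#' @export
derive_seed <- function(master, stream, index = 0L) {
  s <- (as.numeric(master) * 97003 + as.numeric(stream) * 10000019 +
          as.numeric(index) * 7919 + 12345) %% 2147483629
  as.integer(s)
}
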