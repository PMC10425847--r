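# Private RNG stream: all randomized paths draw from a stream seeded
# explicitly, without touching the caller's .Random.seed.

local_rng <- function(seed) {
  if (is.null(seed) || is.na(seed)) stopf("an explicit integer rng seed is required")
  env <- new.env(parent = emptyenv())
  g <- globalenv()
  old <- if (exists(".Random.seed", envir = g, inherits = FALSE))
    get(".Random.seed", envir = g) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = g)
  if (is.null(old)) rm(".Random.seed", envir = g)
  else assign(".Random.seed", old, envir = g)

  with_state <- function(f) {
    outer <- if (exists(".Random.seed", envir = g, inherits = FALSE))
      get(".Random.seed", envir = g) else NULL
    assign(".Random.seed", env$state, envir = g)
    on.exit({
      env$state <- get(".Random.seed", envir = g)
      if (is.null(outer)) rm(".Random.seed", envir = g)
      else assign(".Random.seed", outer, envir = g)
    })
    f()
  }

  list(
    sample_int = function(n, k) with_state(function() sample.int(n, k)),
    sample = function(x, k) with_state(function() sample(x, k)),
    runif = function(n, min = 0, max = 1) with_state(function() runif(n, min, max)),
    rbinom = function(n, size, prob) with_state(function() rbinom(n, size, prob)),
    derive = function() with_state(function() sample.int(2147483646L, 1L))
  )
}
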