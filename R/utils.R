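# Seed handling: set a temporary RNG state and restore the caller's state
# afterwards, so seeded helpers do not perturb the global RNG stream.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  if (!is.null(seed)) set.seed(seed)
  invisible(old)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Derive per-stage child seeds from one root seed; keeps every source of
# randomness reproducible from a single integer while avoiding stream
# collisions between stages. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(generate = 101L, split = 211L, kmeans = 307L, loop = 401L,
               shap = 503L, cv = 601L, downsample = 701L, model = 809L,
               tune = 907L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
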