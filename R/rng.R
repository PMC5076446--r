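# Seed handling: every stochastic operation runs on its own stream, derived
# from the caller's seed plus a fixed per-operation offset, and restores the
# caller's RNG state afterwards. Adding a new generator therefore never
# perturbs the draws of an existing one.

.SEED_OFFSETS <- c(
  truth          = 101L,
  counts         = 211L,
  transcript_map = 307L,
  go_universe    = 401L,
  resample       = 503L,
  library_sizes  = 601L,
  pipeline       = 701L
)

.derive_seed <- function(seed, stream) {
  off <- .SEED_OFFSETS[[stream]]
  as.integer((as.numeric(seed) + off) %% (.Machine$integer.max - 1L))
}

.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
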