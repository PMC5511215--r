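# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a per-scene seed from the run seed; kept below 2^31 so set.seed()
# accepts it. Independent of scenario parameters so that layouts can be
# cached and random numbers shared across grid nodes.
scene_seed <- function(seed, scene, stream = 0L) {
  (as.double(seed) * 2047 + as.double(scene) * 13 + stream) %% 2147483629
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (x < lower || x > upper)
    abort(sprintf("`%s` must be in [%g, %g], got %g.", name, lower, upper, x))
  if (!allow_zero && x == 0)
    abort(sprintf("`%s` must be non-zero.", name))
  invisible(x)
}

# Amplitude-weighted mean intrinsic lifetime of a multi-exponential donor.
mean_lifetime <- function(amplitudes, lifetimes) {
  sum(amplitudes * lifetimes) / sum(amplitudes)
}
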