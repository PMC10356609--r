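# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validate a 3D volume argument and return it as a plain array.
as_volume <- function(x, what = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop(sprintf("`%s` must be a 3D array with dim = (z, y, x)", what), call. = FALSE)
  }
  x
}

same_dim <- function(a, b) identical(dim(a), dim(b))

# Round half away from zero (bit-stable across platforms, unlike round()'s
# round-half-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
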